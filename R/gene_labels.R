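#' Cancer-gene label set
#'
#' Holds the identifiers of known cancer-associated genes and, optionally, a
#' disjoint set of recently reported genes held out for validation. An
#' identifier claimed by both sets is assigned to the recent set and removed
#' from the known set, so the known list never contains recently reported
#' genes.
#'
#' @param cancer_genes Character vector of known cancer-gene identifiers.
#' @param recent_genes Optional character vector of recently reported genes.
#' @return An object of class \code{"gene_label_set"} with character-vector
#'   elements \code{cancer_genes} and \code{recent_genes} (duplicates
#'   collapsed, original first-seen order kept).
#' @examples
#' gene_label_set(c("TP53", "EGFR"), recent_genes = "TP53")
#' @export
gene_label_set <- function(cancer_genes, recent_genes = character()) {
  cancer_genes <- unique(as.character(cancer_genes))
  recent_genes <- unique(as.character(recent_genes))
  cancer_genes <- setdiff(cancer_genes, recent_genes)
  structure(list(cancer_genes = cancer_genes, recent_genes = recent_genes),
            class = "gene_label_set")
}

#' @export
print.gene_label_set <- function(x, ...) {
  cat(sprintf("gene_label_set: %d known cancer genes, %d recent genes\n",
              length(x$cancer_genes), length(x$recent_genes)))
  invisible(x)
}

#' Read a gene label list from a plain-text file
#'
#' One identifier per line, optionally followed by a tab and a tag
#' (\code{known} or \code{recent}); untagged lines are taken as known.
#' Lines starting with \code{#} are ignored. An identifier tagged both ways
#' ends up in the recent set only.
#'
#' @param path Path to the label file.
#' @return A \code{\link{gene_label_set}}.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty gene list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  tags <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "known", "")
  bad <- setdiff(unique(tags), c("known", "recent"))
  if (length(bad)) stop("unknown tag(s) in gene list: ", paste(bad, collapse = ", "))
  gene_label_set(ids[tags == "known"], ids[tags == "recent"])
}

#' Write a gene label list
#'
#' @param labels A \code{\link{gene_label_set}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_list <- function(labels, path) {
  stopifnot(inherits(labels, "gene_label_set"))
  out <- c(paste0(labels$cancer_genes, "\tknown"),
           if (length(labels$recent_genes)) paste0(labels$recent_genes, "\trecent"))
  writeLines(out, path)
  invisible(path)
}
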