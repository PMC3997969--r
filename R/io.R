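#' Read a gene-by-sample expression matrix
#'
#' Reads either a plain TSV matrix (header row \code{gene_id<TAB>sample ids},
#' one gene per row) or the table section of a GEO-series-matrix-style file
#' (metadata lines starting with \code{!}, table delimited by
#' \code{!series_matrix_table_begin} / \code{!series_matrix_table_end}, first
#' column \code{ID_REF}). Sample-to-group assignment comes from a sidecar
#' annotation TSV with columns \code{sample_id} and \code{group} (AN or T).
#'
#' Duplicate gene rows are rejected. Genes with any missing value are dropped
#' with a message stating how many. Files whose rows look like samples (all
#' row identifiers appear in the annotation's sample ids) are rejected as
#' transposed rather than silently re-oriented.
#'
#' @param path Path to the matrix file.
#' @param annotation Path to the sample-annotation TSV, or a data frame with
#'   columns \code{sample_id} and \code{group}.
#' @param format \code{"tsv"} or \code{"series_matrix"}.
#' @param level Declared processing level of the values.
#' @return An \code{\link{expression_dataset}}.
#' @export
read_expression_matrix <- function(path, annotation,
                                   format = c("tsv", "series_matrix"),
                                   level = c("log2", "raw", "normalized")) {
  format <- match.arg(format)
  level <- match.arg(level)
  ann <- read_sample_annotation(annotation)

  lines <- readLines(path, warn = FALSE)
  if (format == "series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("format error: no series-matrix table section in ", path)
    lines <- lines[(beg + 1L):(end - 1L)]
    lines[1L] <- sub("^\"?ID_REF\"?", "gene_id", lines[1L])
    lines <- gsub("\"", "", lines, fixed = TRUE)
  } else {
    lines <- lines[!startsWith(lines, "!")]
  }
  if (length(lines) < 2L) stop("format error: no data rows in ", path)

  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop("format error: header is not tab-delimited in ", path)
  sample_ids <- header[-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncell <- lengths(body)
  if (any(ncell != length(header)))
    stop("format error: row ", which(ncell != length(header))[1L] + 1L,
         " has ", ncell[ncell != length(header)][1L], " fields, expected ", length(header))
  gene_ids <- vapply(body, `[`, "", 1L)

  # transposed-file heuristic: row identifiers that are annotation sample ids
  if (all(gene_ids %in% ann$sample_id) && !all(sample_ids %in% ann$sample_id))
    stop("format error: file appears transposed (rows are sample ids); ",
         "expected genes as rows, samples as columns")

  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene row(s): ", paste(dup, collapse = ", "))

  vals <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE))),
    nrow = length(gene_ids), byrow = TRUE,
    dimnames = list(gene_ids, sample_ids))

  missing_ids <- setdiff(sample_ids, ann$sample_id)
  if (length(missing_ids))
    stop("annotation error: sample(s) not in annotation: ",
         paste(missing_ids, collapse = ", "))
  group <- ann$group[match(sample_ids, ann$sample_id)]

  incomplete <- !stats::complete.cases(vals)
  if (any(incomplete)) {
    message(sum(incomplete), " gene(s) dropped for missing values")
    vals <- vals[!incomplete, , drop = FALSE]
  }
  if (!nrow(vals)) stop("format error: no complete gene rows in ", path)
  expression_dataset(vals, group, level = level)
}

read_sample_annotation <- function(annotation) {
  ann <- if (is.data.frame(annotation)) annotation else
    utils::read.delim(annotation, header = TRUE, stringsAsFactors = FALSE,
                      comment.char = "#")
  if (!all(c("sample_id", "group") %in% names(ann)))
    stop("annotation error: need columns 'sample_id' and 'group'")
  ann$sample_id <- as.character(ann$sample_id)
  ann$group <- as.character(ann$group)
  ann
}

#' Write an expression dataset as TSV matrix plus annotation
#'
#' Writes the value matrix (\code{gene_id} first column) and a two-column
#' sample annotation. \code{read_expression_matrix} on the pair round-trips
#' the dataset.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param matrix_path,annotation_path Output paths.
#' @return \code{matrix_path}, invisibly.
#' @export
write_expression_matrix <- function(dataset, matrix_path, annotation_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = rownames(dataset$values), dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample_id = colnames(dataset$values),
                    group = as.character(dataset$group))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Write an analysis report as TSV with a provenance header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param provenance Named list recorded on the first line as a \code{#}
#'   comment (e.g. command, seed, version).
#' @return \code{path}, invisibly.
#' @export
write_report <- function(df, path, provenance = list()) {
  prov <- c(list(package = "hetrank",
                 version = as.character(utils::packageVersion("hetrank"))),
            provenance)
  hdr <- paste0("# ", paste(names(prov), unlist(lapply(prov, format)),
                            sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
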