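#' Two-group expression dataset
#'
#' Container for a genes-by-samples expression matrix with a per-sample
#' group label (adjacent normal \code{"AN"} or tumor \code{"T"}) and a
#' processing-level tag.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene (or probe) identifiers, column names sample identifiers.
#' @param group Character vector, one of \code{"AN"}/\code{"T"} per sample
#'   (same length and order as \code{ncol(values)}).
#' @param level Processing level of the values: \code{"raw"} (linear scale,
#'   strictly positive), \code{"log2"}, or \code{"normalized"}.
#'
#' @return An object of class \code{"expression_dataset"}: a list with
#'   elements \code{values}, \code{group} (factor with levels AN, T) and
#'   \code{level}.
#' @examples
#' m <- matrix(rnorm(12, 7, 0.6), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c("AN", "AN", "T", "T"), level = "log2")
#' ds
#' @export
expression_dataset <- function(values, group, level = c("log2", "raw", "normalized")) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (length(group) != ncol(values))
    stop("'group' must have one label per sample column")
  group <- as.character(group)
  bad <- setdiff(unique(group), c("AN", "T"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), " (expected AN or T)")
  if (level == "raw" && any(values <= 0, na.rm = TRUE))
    stop("raw-level values must be strictly positive (log2 must be applicable)")
  structure(list(values = values,
                 group = factor(group, levels = c("AN", "T")),
                 level = level),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d AN, %d T), level = %s\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "AN"), sum(x$group == "T"), x$level))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Log2-transform a raw-level expression dataset
#'
#' Replaces every value by its base-2 logarithm and flips the processing
#' level from \code{"raw"} to \code{"log2"}. Dimensions, identifiers and
#' group labels are unchanged.
#'
#' @param dataset An \code{\link{expression_dataset}} with \code{level = "raw"}.
#' @return The dataset with log2 values and \code{level = "log2"}.
#' @export
log2_transform <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$level != "raw")
    stop("log2_transform requires level = 'raw', got '", dataset$level, "'")
  nonpos <- which(dataset$values <= 0, arr.ind = TRUE)
  if (nrow(nonpos))
    stop(sprintf("non-positive value at gene '%s', sample '%s'",
                 rownames(dataset$values)[nonpos[1, 1]],
                 colnames(dataset$values)[nonpos[1, 2]]))
  dataset$values <- log2(dataset$values)
  dataset$level <- "log2"
  dataset
}

# Split sample columns by group; errors if a group is below a minimum size.
group_columns <- function(dataset, min_per_group = 1L) {
  an <- which(dataset$group == "AN")
  tu <- which(dataset$group == "T")
  if (length(an) < min_per_group || length(tu) < min_per_group)
    stop(sprintf("each group needs >= %d samples (AN: %d, T: %d)",
                 min_per_group, length(an), length(tu)))
  list(an = an, t = tu)
}
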