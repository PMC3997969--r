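# Row means and sample SDs (n-1 denominator) over a column subset,
# vectorized so predictor tables stay cheap on 10^4-gene cohorts.
row_group_stats <- function(values, cols) {
  n <- length(cols)
  x <- values[, cols, drop = FALSE]
  m <- rowMeans(x)
  if (n < 2L) return(list(mean = m, sd = rep(NA_real_, nrow(x))))
  ss <- rowSums((x - m)^2)
  list(mean = m, sd = sqrt(ss / (n - 1)))
}

#' Per-gene group means and standard deviations
#'
#' Arithmetic means and sample standard deviations (n-1 denominator) of each
#' gene's expression in the adjacent-normal and tumor groups: the m(AN),
#' m(T), SD(AN), SD(T) predictors.
#'
#' @param dataset An \code{\link{expression_dataset}} with at least 2 samples
#'   per group.
#' @return Data frame with columns \code{gene_id}, \code{m_an}, \code{m_t},
#'   \code{sd_an}, \code{sd_t}, one row per gene in input order.
#' @export
group_stats <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  gc <- group_columns(dataset, min_per_group = 2L)
  an <- row_group_stats(dataset$values, gc$an)
  tu <- row_group_stats(dataset$values, gc$t)
  data.frame(gene_id = rownames(dataset$values),
             m_an = an$mean, m_t = tu$mean, sd_an = an$sd, sd_t = tu$sd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' -log10 p-value of the pooled two-sample Student t test
#'
#' Equal-variance two-sided t test with n1 + n2 - 2 degrees of freedom,
#' returned as -log10(p). Degenerate inputs with zero pooled variance give 0
#' when the group means are equal (p = 1) and the cap value when they
#' differ; all values are capped at 300 so rankings remain well defined.
#'
#' @param an_values,t_values Numeric vectors, each of length >= 2.
#' @return The -log10 p-value (scalar).
#' @export
student_t_neglogp <- function(an_values, t_values) {
  if (length(an_values) < 2L || length(t_values) < 2L)
    stop("insufficient replication: each group needs >= 2 values")
  neglogp_vec(matrix(an_values, nrow = 1), matrix(t_values, nrow = 1))
}

# Vectorized pooled-t -log10(p) over rows of two matrices.
neglogp_vec <- function(an_mat, t_mat, cap = 300) {
  n1 <- ncol(an_mat); n2 <- ncol(t_mat)
  m1 <- rowMeans(an_mat); m2 <- rowMeans(t_mat)
  ss1 <- rowSums((an_mat - m1)^2); ss2 <- rowSums((t_mat - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- abs(m2 - m1) / se
  # log-scale survival keeps precision for extreme t before capping
  nlp <- -(stats::pt(tt, df, lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
  nlp[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 0, cap)
  pmin(nlp, cap)
}

#' Fold change from two log2 group means
#'
#' Direction-agnostic: \code{log_fc = |m_t - m_an|} and \code{fc = 2^log_fc},
#' so two-fold up- and two-fold down-regulation both give fc = 2. The two
#' forms are monotone transforms of each other and rank genes identically.
#'
#' @param m_an,m_t Group mean log2 expression (vectors recycle as usual).
#' @return Data frame with columns \code{log_fc} and \code{fc}.
#' @export
fold_change <- function(m_an, m_t) {
  log_fc <- abs(m_t - m_an)
  data.frame(log_fc = log_fc, fc = 2^log_fc)
}

#' Compute the six-predictor table for a two-group dataset
#'
#' Per gene: mean and SD of expression in adjacent normal tissue (m(AN),
#' SD(AN)) and in tumors (m(T), SD(T)), absolute log2 fold change and its
#' linear form, and -log10 p from the pooled two-sample t test. Row order
#' follows the input dataset.
#'
#' @param dataset An \code{\link{expression_dataset}} with >= 2 samples per
#'   group.
#' @return A data frame of class \code{"predictor_table"} with columns
#'   \code{gene_id, m_an, m_t, sd_an, sd_t, log_fc, fc, neglogp}.
#' @examples
#' coh <- generate_null_cohort(cohort_config(n_genes = 100, seed = 1))
#' head(compute_predictor_table(coh$dataset))
#' @export
compute_predictor_table <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  gc <- group_columns(dataset, min_per_group = 2L)
  tab <- group_stats(dataset)
  tab <- cbind(tab, fold_change(tab$m_an, tab$m_t))
  tab$neglogp <- neglogp_vec(dataset$values[, gc$an, drop = FALSE],
                             dataset$values[, gc$t, drop = FALSE])
  class(tab) <- c("predictor_table", "data.frame")
  tab
}

# The six rankable predictor column names, in declaration order (used for
# tie-breaking predictor ranks).
PREDICTORS <- c("m_an", "m_t", "fc", "neglogp", "sd_an", "sd_t")

#' @export
print.predictor_table <- function(x, ...) {
  cat(sprintf("predictor_table: %d genes x 6 predictors\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
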