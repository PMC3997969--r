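#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' U is reported for sample \code{a} under the rank-sum convention
#' (\code{U = R_a - n_a(n_a+1)/2}, i.e. the number of pairs in which the
#' \code{a} value exceeds the \code{b} value, ties counting one half), so
#' \code{mann_whitney(a, b)$U + mann_whitney(b, a)$U = length(a) * length(b)}.
#' Z uses the normal approximation with tie-corrected variance and no
#' continuity correction; the two-sided p comes from the normal CDF.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with elements \code{U}, \code{Z}, \code{p}.
#' @examples
#' mann_whitney(c(1, 3, 5, 7), c(2, 4, 6))
#' @export
mann_whitney <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  if (!n_a || !n_b) stop("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  N <- n_a + n_b
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (n_a * n_b / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, Z = 0, p = 1))
  Z <- (U - n_a * n_b / 2) / sqrt(sigma2)
  list(U = U, Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Top-fraction enrichment of labeled genes under a predictor ranking
#'
#' Genes are sorted by the predictor value, largest first (ties keep input
#' order; no extra genes are pulled in at the cutoff). With
#' \code{k = ceiling(top_frac * n)}, the enrichment factor is the proportion
#' of labeled cancer genes among the top k divided by \code{top_frac}; EF = 1
#' means the ranking does no better than random selection.
#'
#' @param table A \code{\link{compute_predictor_table}} result.
#' @param predictor One of \code{"m_an", "m_t", "fc", "neglogp", "sd_an",
#'   "sd_t"} (\code{"log_fc"} is accepted and equivalent to \code{"fc"}).
#' @param labels A \code{\link{gene_label_set}}.
#' @param top_frac Ranked fraction to inspect (default 0.05).
#' @return List with \code{top_prop} (labeled proportion among top k),
#'   \code{ef} (\code{top_prop / top_frac}) and \code{k}.
#' @export
rank_enrichment <- function(table, predictor, labels, top_frac = 0.05) {
  if (!predictor %in% c(PREDICTORS, "log_fc"))
    stop("unknown predictor: ", predictor)
  if (nrow(table) < 20L) stop("need at least 20 genes to rank")
  stopifnot(top_frac > 0, top_frac <= 1)
  k <- ceiling(top_frac * nrow(table))
  ord <- order(table[[predictor]], decreasing = TRUE, method = "radix")
  top <- table$gene_id[ord[seq_len(k)]]
  top_prop <- mean(top %in% labels$cancer_genes)
  list(top_prop = top_prop, ef = top_prop / top_frac, k = k)
}

#' Compare all six predictors between cancer and other genes
#'
#' For each predictor: the Mann-Whitney test of cancer-labeled genes against
#' all other genes (tie-corrected Z), group means, the top-5% enrichment
#' factor, and a rank 1..6 by |Z| descending (ties broken by predictor
#' declaration order m(AN), m(T), FC, -LOG(P), SD(AN), SD(T)).
#'
#' @param table A \code{\link{compute_predictor_table}} result.
#' @param labels A \code{\link{gene_label_set}}; at least 2 labeled and 2
#'   unlabeled genes must be present in the table.
#' @param top_frac Ranked fraction for the enrichment factor.
#' @return A data frame of class \code{"enrichment_report"}, one row per
#'   predictor, with columns \code{predictor, mean_cancer, mean_other, mw_u,
#'   mw_z, mw_p, rank, top_prop, ef}.
#' @examples
#' coh <- generate_heterogeneous_cohort(cohort_config(seed = 1))
#' tab <- compute_predictor_table(coh$dataset)
#' predictor_comparison(tab, coh$labels)
#' @export
predictor_comparison <- function(table, labels, top_frac = 0.05) {
  is_cancer <- table$gene_id %in% labels$cancer_genes
  if (!any(is_cancer))
    stop("label set is disjoint from the table's genes")
  if (sum(is_cancer) < 2L || sum(!is_cancer) < 2L)
    stop("need >= 2 cancer and >= 2 other genes")
  rows <- lapply(PREDICTORS, function(p) {
    v <- table[[p]]
    mw <- mann_whitney(v[is_cancer], v[!is_cancer])
    re <- rank_enrichment(table, p, labels, top_frac)
    data.frame(predictor = p,
               mean_cancer = mean(v[is_cancer]), mean_other = mean(v[!is_cancer]),
               mw_u = mw$U, mw_z = mw$Z, mw_p = mw$p,
               top_prop = re$top_prop, ef = re$ef,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  # |Z| descending; ties resolved by declaration order (row order here)
  rep$rank <- rank(-abs(rep$mw_z), ties.method = "first")
  rep <- rep[, c("predictor", "mean_cancer", "mean_other", "mw_u", "mw_z",
                 "mw_p", "rank", "top_prop", "ef")]
  class(rep) <- c("enrichment_report", "data.frame")
  rep
}

#' @export
print.enrichment_report <- function(x, digits = 4, ...) {
  cat("Predictor comparison, cancer vs other genes (Mann-Whitney, top-5% EF)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df[order(df$rank), ], row.names = FALSE, ...)
  invisible(x)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-adjusted Kendall correlation over all pairs, used to compare per-gene
#' variance estimates across data-processing levels (raw, log2, normalized).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return The tau-b coefficient.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 2L) stop("need at least 2 observations")
  stats::cor(x, y, method = "kendall")
}

#' Robustness of the SD(T) association under tumor subsampling
#'
#' Repeatedly draws a small subset of tumors without replacement, recomputes
#' SD(T) on the subset, and Mann-Whitney-compares cancer versus other genes.
#' Returns the fraction of replicates reaching two-sided significance --
#' the check that a variance signal visible at full sample size survives at
#' a handful of tumors.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param labels A \code{\link{gene_label_set}}.
#' @param k_tumors Tumors drawn per replicate (default 9).
#' @param n_reps Number of replicates (default 20).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed.
#' @return List with \code{fraction_significant} and the per-replicate
#'   p-values \code{p}.
#' @export
subsample_robustness <- function(dataset, labels, k_tumors = 9L, n_reps = 20L,
                                 alpha = 0.05, seed = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (k_tumors < 2L) stop("k_tumors must be >= 2")
  t_cols <- which(dataset$group == "T")
  if (k_tumors > length(t_cols))
    stop("k_tumors (", k_tumors, ") exceeds available tumors (", length(t_cols), ")")
  is_cancer <- rownames(dataset$values) %in% labels$cancer_genes
  if (!any(is_cancer) || all(is_cancer))
    stop("need both cancer and other genes present in the dataset")
  with_seed(seed, {
    p <- vapply(seq_len(n_reps), function(i) {
      cols <- sample(t_cols, k_tumors)
      sd_t <- row_group_stats(dataset$values, cols)$sd
      mann_whitney(sd_t[is_cancer], sd_t[!is_cancer])$p
    }, numeric(1))
    list(fraction_significant = mean(p < alpha), p = p)
  })
}
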