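#' Call tumor expression outliers against the adjacent-normal band
#'
#' For each gene, the adjacent-normal samples give the reference mean m(N)
#' and standard deviation SD(N) (n-1 denominator); a tumor is an outlier for
#' that gene iff its value is strictly below m(N) - k_sd * SD(N) or strictly
#' above m(N) + k_sd * SD(N). Band edges are not outliers. Genes with
#' SD(N) = 0 cannot define a band; they are flagged degenerate and excluded
#' from downstream rate comparisons.
#'
#' @param dataset An \code{\link{expression_dataset}} with >= 2 AN samples.
#' @param k_sd Band half-width in adjacent-normal SDs (default 4).
#' @return A data frame of class \code{"outlier_report"} with columns
#'   \code{gene_id, m_n, sd_n, band_low, band_high, n_outliers, pct_outliers,
#'   degenerate}; \code{attr(, "n_tumors")} records the tumor count.
#' @examples
#' m <- matrix(c(5, 6, 7, 1, 6, 11), 1, 6,
#'             dimnames = list("g1", paste0("s", 1:6)))
#' ds <- expression_dataset(m, c("AN", "AN", "AN", "T", "T", "T"))
#' call_outliers(ds)
#' @export
call_outliers <- function(dataset, k_sd = 4) {
  stopifnot(inherits(dataset, "expression_dataset"), k_sd > 0)
  gc <- group_columns(dataset, min_per_group = 2L)
  an <- row_group_stats(dataset$values, gc$an)
  band_low <- an$mean - k_sd * an$sd
  band_high <- an$mean + k_sd * an$sd
  tum <- dataset$values[, gc$t, drop = FALSE]
  n_out <- rowSums(tum < band_low | tum > band_high)
  degenerate <- an$sd == 0
  if (any(degenerate))
    message(sum(degenerate), " gene(s) with SD(N) = 0 flagged degenerate")
  rep <- data.frame(gene_id = rownames(dataset$values),
                    m_n = an$mean, sd_n = an$sd,
                    band_low = band_low, band_high = band_high,
                    n_outliers = n_out,
                    pct_outliers = 100 * n_out / length(gc$t),
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(rep, "n_tumors") <- length(gc$t)
  class(rep) <- c("outlier_report", "data.frame")
  rep
}

#' Match each cancer gene to differential-expression-comparable controls
#'
#' Cancer genes are more differentially expressed, which alone makes them
#' more likely to be outliers. To control for that, genes are sorted by
#' -log10(p) from largest to smallest (ties keep input order) and each
#' cancer gene is paired with the nearest non-cancer gene strictly above and
#' strictly below it in the sorted list, skipping intervening cancer genes.
#' At a list boundary the missing side is replaced by the next-nearest
#' non-cancer gene on the available side, so every cancer gene gets two
#' controls whenever two non-cancer genes exist.
#'
#' @param table A \code{\link{compute_predictor_table}} result.
#' @param labels A \code{\link{gene_label_set}}.
#' @return Named list mapping each cancer gene id to a character vector of
#'   control gene ids.
#' @export
matched_controls <- function(table, labels) {
  is_cancer <- table$gene_id %in% labels$cancer_genes
  if (all(is_cancer)) stop("no non-cancer genes available as controls")
  if (!any(is_cancer)) return(structure(list(), names = character()))
  ord <- order(table$neglogp, decreasing = TRUE, method = "radix")
  ids <- table$gene_id[ord]
  cancer_pos <- which(is_cancer[ord])
  noncancer_pos <- which(!is_cancer[ord])
  ctrl <- lapply(cancer_pos, function(p) {
    above <- noncancer_pos[noncancer_pos < p]   # larger neglogp side
    below <- noncancer_pos[noncancer_pos > p]
    picks <- c(if (length(above)) max(above),
               if (length(below)) min(below))
    if (length(picks) < 2L) {
      if (!length(above)) picks <- utils::head(below, 2L)
      else picks <- utils::tail(above, 2L)
    }
    ids[picks]
  })
  names(ctrl) <- ids[cancer_pos]
  ctrl
}

#' Compare outlier rates between cancer genes and matched controls
#'
#' Means and standard errors of the per-gene tumor-outlier percentage for
#' the cancer genes and for the pooled, de-duplicated control set, with a
#' Mann-Whitney comparison of the two per-gene percentage vectors. Genes
#' flagged degenerate in the outlier report are excluded.
#'
#' @param report A \code{\link{call_outliers}} result.
#' @param labels A \code{\link{gene_label_set}}.
#' @param controls A \code{\link{matched_controls}} map.
#' @return List with \code{mean_pct_cancer, se_cancer, n_cancer,
#'   mean_pct_control, se_control, n_control, Z, p} (two-sided) and
#'   \code{p_one_sided} for the direction cancer > control.
#' @export
compare_outlier_rates <- function(report, labels, controls) {
  stopifnot(inherits(report, "outlier_report"))
  usable <- report[!report$degenerate, , drop = FALSE]
  cancer <- usable$pct_outliers[usable$gene_id %in% labels$cancer_genes]
  pooled_ids <- unique(unlist(controls, use.names = FALSE))
  control <- usable$pct_outliers[usable$gene_id %in% pooled_ids]
  if (!length(cancer) || !length(control))
    stop("empty cancer or control group after excluding degenerate genes")
  mw <- mann_whitney(cancer, control)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  list(mean_pct_cancer = mean(cancer), se_cancer = se(cancer),
       n_cancer = length(cancer),
       mean_pct_control = mean(control), se_control = se(control),
       n_control = length(control),
       Z = mw$Z, p = mw$p,
       p_one_sided = stats::pnorm(-mw$Z))
}
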