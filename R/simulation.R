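#' Configuration for the identification-efficacy simulation study
#'
#' Defaults reproduce the study conditions of the simulation: 1000 genes (50
#' cancer, 950 non-cancer), 20 adjacent normal and 20 tumor samples,
#' baseline log2 expression Normal(7.0, 0.6), and mean shifts s of 0.07,
#' 0.35 and 0.7 log2 units.
#'
#' @param n_genes,n_cancer,n_an,n_t Cohort dimensions.
#' @param base_mean,base_sd Baseline log2 expression parameters.
#' @param shifts Numeric vector of tumor mean shifts s (log2 units, >= 0).
#' @param n_reps Replicates per model and shift.
#' @param d_target Target per-outlier shift magnitude for the outliers model
#'   (log2 units); the outlier count is chosen so the tumor-group mean shift
#'   still equals s exactly.
#' @param two_sided If \code{TRUE}, each cancer gene's shift direction is a
#'   fair coin; default is upregulation only.
#' @param seed Integer seed for the whole experiment.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 1000L, n_cancer = 50L, n_an = 20L, n_t = 20L,
                       base_mean = 7.0, base_sd = 0.6,
                       shifts = c(0.07, 0.35, 0.7), n_reps = 100L,
                       d_target = 3.5, two_sided = FALSE, seed = NULL) {
  if (any(shifts < 0)) stop("shifts must be >= 0")
  cfg <- list(n_genes = as.integer(n_genes), n_cancer = as.integer(n_cancer),
              n_an = as.integer(n_an), n_t = as.integer(n_t),
              base_mean = base_mean, base_sd = base_sd,
              shifts = shifts, n_reps = as.integer(n_reps),
              d_target = d_target, two_sided = two_sided, seed = seed)
  if (cfg$n_cancer < 0L || cfg$n_cancer > cfg$n_genes)
    stop("need 0 <= n_cancer <= n_genes")
  class(cfg) <- "sim_config"
  cfg
}

sim_base_cohort <- function(cfg) {
  sk <- cohort_skeleton(cfg)
  vals <- matrix(stats::rnorm(cfg$n_genes * (cfg$n_an + cfg$n_t),
                              cfg$base_mean, cfg$base_sd),
                 nrow = cfg$n_genes, dimnames = list(sk$gene_ids, sk$sample_ids))
  cancer <- seq_len(cfg$n_cancer)   # labels carry no information; first block
  list(vals = vals, sk = sk, cancer = cancer,
       t_cols = cfg$n_an + seq_len(cfg$n_t))
}

gene_signs <- function(cfg, n) if (cfg$two_sided) ifelse(stats::runif(n) < 0.5, 1, -1) else rep(1, n)

#' Simulate the shifting-means model of tumor expression
#'
#' Homogeneous tumors: every tumor sample of a cancer gene is drawn from
#' Normal(base_mean + s, base_sd), so the group mean moves by s while the
#' within-group SD stays at base_sd. Non-cancer genes and all adjacent
#' normal samples are baseline.
#'
#' @param s Tumor mean shift in log2 units (>= 0).
#' @param config A \code{\link{sim_config}}.
#' @param rep_seed Optional integer seed for this replicate.
#' @return A list with \code{dataset} and \code{labels}, as the cohort
#'   generators.
#' @export
simulate_shifting_means <- function(s, config = sim_config(), rep_seed = NULL) {
  stopifnot(inherits(config, "sim_config"), s >= 0)
  with_seed(rep_seed, {
    b <- sim_base_cohort(config)
    if (length(b$cancer) && s > 0) {
      sg <- gene_signs(config, length(b$cancer))
      b$vals[b$cancer, b$t_cols] <- matrix(
        stats::rnorm(length(b$cancer) * config$n_t,
                     config$base_mean, config$base_sd),
        nrow = length(b$cancer)) + sg * s
    }
    list(dataset = expression_dataset(b$vals, b$sk$group, level = "log2"),
         labels = gene_label_set(b$sk$gene_ids[b$cancer]))
  })
}

#' Outlier count and per-outlier shift for the outliers model
#'
#' The outliers model must match the shifting-means model's tumor-group mean
#' shift: n_out * d / n_t = s. The count is n_out = max(1,
#' round(n_t * s / d_target)) and d = n_t * s / n_out exactly, so the mean
#' constraint holds for every s while each outlier's shift stays near
#' d_target.
#'
#' @param s Target mean shift (> 0).
#' @param n_t Tumor count.
#' @param d_target Preferred per-outlier shift magnitude.
#' @return List with \code{n_out} and \code{d}.
#' @export
outlier_split <- function(s, n_t, d_target = 3.5) {
  stopifnot(s > 0, n_t >= 1)
  n_out <- max(1L, as.integer(round(n_t * s / d_target)))
  n_out <- min(n_out, as.integer(n_t))
  list(n_out = n_out, d = n_t * s / n_out)
}

#' Simulate the outliers (tumor-heterogeneity) model
#'
#' Each cancer gene is extreme in only \code{n_out} tumors, drawn uniformly
#' without replacement; those tumors come from Normal(base_mean + d,
#' base_sd) with \code{n_out * d / n_t = s}, so the tumor-group mean shift
#' equals the shifting-means model's s while the within-group variance is
#' inflated by the mixture (sigma^2 + p(1-p) d^2 with p = n_out / n_t).
#'
#' @inheritParams simulate_shifting_means
#' @param s Target tumor-group mean shift (>= 0; 0 gives a pure null).
#' @export
simulate_outliers_model <- function(s, config = sim_config(), rep_seed = NULL) {
  stopifnot(inherits(config, "sim_config"), s >= 0)
  with_seed(rep_seed, {
    b <- sim_base_cohort(config)
    if (length(b$cancer) && s > 0) {
      sp <- outlier_split(s, config$n_t, config$d_target)
      sg <- gene_signs(config, length(b$cancer))
      for (i in seq_along(b$cancer)) {
        hit <- sample.int(config$n_t, sp$n_out)
        b$vals[b$cancer[i], b$t_cols[hit]] <- stats::rnorm(
          sp$n_out, config$base_mean + sg[i] * sp$d, config$base_sd)
      }
    }
    list(dataset = expression_dataset(b$vals, b$sk$group, level = "log2"),
         labels = gene_label_set(b$sk$gene_ids[b$cancer]))
  })
}

#' Recovery proportion of true cancer genes in a top-ranked list
#'
#' Ranks genes by the given statistic, largest first (ties keep input
#' order), and returns the fraction of the true cancer genes found among the
#' top \code{top_n}.
#'
#' @param table A \code{\link{compute_predictor_table}} result.
#' @param labels A \code{\link{gene_label_set}}.
#' @param statistic A predictor column name, typically \code{"sd_t"} or
#'   \code{"neglogp"}.
#' @param top_n List length inspected; defaults to the number of labeled
#'   genes (recovery at k = #true).
#' @return Proportion in [0, 1].
#' @export
recovery_proportion <- function(table, labels, statistic, top_n = NULL) {
  if (!statistic %in% c(PREDICTORS, "log_fc"))
    stop("unknown statistic: ", statistic)
  n_cancer <- sum(table$gene_id %in% labels$cancer_genes)
  if (is.null(top_n)) top_n <- n_cancer
  if (top_n > nrow(table)) stop("top_n exceeds the number of genes")
  if (n_cancer == 0L) stop("no labeled genes present in the table")
  ord <- order(table[[statistic]], decreasing = TRUE, method = "radix")
  top <- table$gene_id[ord[seq_len(top_n)]]
  sum(top %in% labels$cancer_genes) / n_cancer
}

#' Run the full identification-efficacy simulation experiment
#'
#' For each model (shifting-means, outliers), shift s and replicate:
#' generate a cohort, compute the predictor table, and score the recovery of
#' true cancer genes by SD(T) and by -log10(p). Replicate datasets are
#' generated independently for the two models.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{"hetrank_sim"}: a data frame with one
#'   row per (model, s, replicate, statistic) and columns \code{model, s,
#'   rep, statistic, recovery}; \code{summary()} aggregates means and
#'   Monte-Carlo standard errors per cell.
#' @examples
#' sim <- run_simulation_experiment(sim_config(n_reps = 5, seed = 1))
#' summary(sim)
#' @export
run_simulation_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    grid <- expand.grid(model = c("shifting", "outliers"),
                        s = config$shifts, rep = seq_len(config$n_reps),
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      coh <- if (g$model == "shifting")
        simulate_shifting_means(g$s, config)
      else simulate_outliers_model(g$s, config)
      tab <- compute_predictor_table(coh$dataset)
      data.frame(model = g$model, s = g$s, rep = g$rep,
                 statistic = c("sd_t", "neglogp"),
                 recovery = c(recovery_proportion(tab, coh$labels, "sd_t"),
                              recovery_proportion(tab, coh$labels, "neglogp")),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    class(res) <- c("hetrank_sim", "data.frame")
    attr(res, "config") <- config
    res
  })
}

#' @export
summary.hetrank_sim <- function(object, ...) {
  agg <- stats::aggregate(recovery ~ model + s + statistic, data = object,
                   FUN = function(x) c(mean = mean(x),
                                       se = stats::sd(x) / sqrt(length(x)),
                                       n = length(x)))
  out <- data.frame(agg[c("model", "s", "statistic")],
                    mean_recovery = agg$recovery[, "mean"],
                    mc_se = agg$recovery[, "se"],
                    n_reps = agg$recovery[, "n"])
  out[order(out$model, out$s, out$statistic), ]
}

#' @export
print.hetrank_sim <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("identification-efficacy simulation: %d genes (%d cancer), %d+%d samples, %d reps\n",
              cfg$n_genes, cfg$n_cancer, cfg$n_an, cfg$n_t, cfg$n_reps))
  s <- summary(x)
  s[c("mean_recovery", "mc_se")] <- lapply(s[c("mean_recovery", "mc_se")], round, 4)
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}

#' Mean recovery curves for a simulation experiment
#'
#' One panel per model, recovery vs shift s, one line per ranking statistic,
#' with +/- 1 Monte-Carlo SE bars.
#'
#' @param x A \code{\link{run_simulation_experiment}} result.
#' @param ... Passed to \code{matplot}.
#' @return \code{x}, invisibly.
#' @export
plot.hetrank_sim <- function(x, ...) {
  s <- summary(x)
  models <- unique(s$model)
  op <- graphics::par(mfrow = c(1, length(models)))
  on.exit(graphics::par(op))
  for (m in models) {
    sm <- s[s$model == m, ]
    wide <- stats::reshape(sm[c("s", "statistic", "mean_recovery")],
                    idvar = "s", timevar = "statistic", direction = "wide")
    graphics::matplot(wide$s, wide[-1], type = "b", pch = 16, lty = 1,
                      xlab = "mean shift s (log2 units)",
                      ylab = "recovery of true cancer genes",
                      main = paste(m, "model"), ylim = c(0, 1), ...)
    graphics::legend("topleft", legend = sub("mean_recovery\\.", "", names(wide)[-1]),
                     col = seq_len(ncol(wide) - 1), lty = 1, pch = 16, bty = "n")
    for (i in seq_len(nrow(sm)))
      graphics::segments(sm$s[i], sm$mean_recovery[i] - sm$mc_se[i],
                         sm$s[i], sm$mean_recovery[i] + sm$mc_se[i])
  }
  invisible(x)
}
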