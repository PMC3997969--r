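# Run code under a fixed, fully specified RNG state, restoring the caller's
# state afterwards. Kind is pinned so a given seed is reproducible across
# platforms and sessions.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Configuration for synthetic two-group expression cohorts
#'
#' Defaults encode the study conditions used throughout the package's
#' synthetic analyses: 1000 genes of which 50 are cancer genes, 20 adjacent
#' normal and 20 tumor samples, baseline expression Normal(7, 0.6) on the
#' log2 scale, and for heterogeneous cohorts a 3.0 log2-unit dysregulation
#' hitting each tumor independently with probability 0.2.
#'
#' @param n_genes Total number of genes.
#' @param n_cancer Number of genes labeled as cancer genes.
#' @param n_an,n_t Adjacent-normal and tumor sample counts.
#' @param base_mean,base_sd Baseline log2 expression mean and SD.
#' @param outlier_fraction Probability that a given tumor is dysregulated for
#'   a given cancer gene (heterogeneous cohorts only).
#' @param outlier_shift Magnitude of the dysregulation shift in log2 units;
#'   direction (up or down) is drawn once per gene.
#' @param an_sd_inflation Multiplicative SD factor for cancer genes in AN
#'   tissue; 1 keeps adjacent normal tissue at baseline variability.
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @return A list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_genes = 1000L, n_cancer = 50L, n_an = 20L, n_t = 20L,
                          base_mean = 7.0, base_sd = 0.6,
                          outlier_fraction = 0.2, outlier_shift = 3.0,
                          an_sd_inflation = 1.0, seed = NULL) {
  cfg <- list(n_genes = as.integer(n_genes), n_cancer = as.integer(n_cancer),
              n_an = as.integer(n_an), n_t = as.integer(n_t),
              base_mean = base_mean, base_sd = base_sd,
              outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
              an_sd_inflation = an_sd_inflation, seed = seed)
  if (cfg$n_cancer < 0L || cfg$n_cancer > cfg$n_genes)
    stop("need 0 <= n_cancer <= n_genes")
  if (cfg$outlier_fraction < 0 || cfg$outlier_fraction > 1)
    stop("outlier_fraction must be in [0, 1]")
  if (cfg$base_sd <= 0) stop("base_sd must be positive")
  if (cfg$an_sd_inflation < 1) stop("an_sd_inflation must be >= 1")
  if (cfg$n_genes < 1L || cfg$n_an < 1L || cfg$n_t < 1L)
    stop("n_genes, n_an and n_t must be positive")
  class(cfg) <- "cohort_config"
  cfg
}

cohort_skeleton <- function(cfg) {
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  sample_ids <- c(sprintf("AN%03d", seq_len(cfg$n_an)),
                  sprintf("T%03d", seq_len(cfg$n_t)))
  group <- rep(c("AN", "T"), c(cfg$n_an, cfg$n_t))
  list(gene_ids = gene_ids, sample_ids = sample_ids, group = group)
}

#' Generate a null cohort (no expression--label association)
#'
#' Every value, for every gene and sample, is drawn i.i.d. from
#' Normal(\code{base_mean}, \code{base_sd}); cancer-gene labels are assigned
#' uniformly at random, independently of the values. Used to calibrate the
#' no-signal behavior of every downstream statistic (enrichment factor 1,
#' uniform p-values).
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A list with elements \code{dataset}
#'   (\code{\link{expression_dataset}}, level \code{"log2"}) and
#'   \code{labels} (\code{\link{gene_label_set}}).
#' @export
generate_null_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    sk <- cohort_skeleton(config)
    n_s <- config$n_an + config$n_t
    vals <- matrix(stats::rnorm(config$n_genes * n_s, config$base_mean, config$base_sd),
                   nrow = config$n_genes,
                   dimnames = list(sk$gene_ids, sk$sample_ids))
    cancer <- sort(sample.int(config$n_genes, config$n_cancer))
    list(dataset = expression_dataset(vals, sk$group, level = "log2"),
         labels = gene_label_set(sk$gene_ids[cancer]))
  })
}

#' Generate a heterogeneous (outlier-driven) cohort
#'
#' Non-cancer genes are baseline Normal(\code{base_mean}, \code{base_sd})
#' everywhere. Each cancer gene keeps baseline behavior in adjacent normal
#' tissue (SD optionally inflated by \code{an_sd_inflation}) and is
#' dysregulated in each tumor independently with probability
#' \code{outlier_fraction}; dysregulated values are drawn from
#' Normal(\code{base_mean} +/- \code{outlier_shift}, \code{base_sd}), the
#' sign fixed per gene by a fair coin. This is the generative picture of
#' tumor heterogeneity: different tumors are driven by different genes, so a
#' driver is extreme in only a fraction of tumors, inflating SD(T) with
#' little mean shift.
#'
#' @param config A \code{\link{cohort_config}} with
#'   \code{outlier_fraction > 0} and \code{outlier_shift != 0}.
#' @return As \code{\link{generate_null_cohort}}.
#' @export
generate_heterogeneous_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  # outlier_fraction = 0 (or shift 0) degenerates to the null cohort
  with_seed(config$seed, {
    sk <- cohort_skeleton(config)
    n_s <- config$n_an + config$n_t
    vals <- matrix(stats::rnorm(config$n_genes * n_s, config$base_mean, config$base_sd),
                   nrow = config$n_genes,
                   dimnames = list(sk$gene_ids, sk$sample_ids))
    cancer <- sort(sample.int(config$n_genes, config$n_cancer))
    if (length(cancer)) {
      an_cols <- seq_len(config$n_an)
      t_cols <- config$n_an + seq_len(config$n_t)
      if (config$an_sd_inflation > 1)
        vals[cancer, an_cols] <- matrix(
          stats::rnorm(length(cancer) * config$n_an, config$base_mean,
                       config$an_sd_inflation * config$base_sd),
          nrow = length(cancer))
      sign <- ifelse(stats::runif(length(cancer)) < 0.5, 1, -1)
      for (i in seq_along(cancer)) {
        hit <- stats::runif(config$n_t) < config$outlier_fraction
        if (any(hit))
          vals[cancer[i], t_cols[hit]] <- stats::rnorm(
            sum(hit), config$base_mean + sign[i] * config$outlier_shift,
            config$base_sd)
      }
    }
    list(dataset = expression_dataset(vals, sk$group, level = "log2"),
         labels = gene_label_set(sk$gene_ids[cancer]))
  })
}
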