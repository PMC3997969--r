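#' Run the full prioritization pipeline and write TSV reports
#'
#' Orchestrates the end-to-end analysis: in \code{"real"} mode it reads an
#' expression matrix, sample annotation and cancer-gene label list; in
#' \code{"synthetic-cohort"} mode it first generates a heterogeneous cohort;
#' in \code{"simulation"} mode it runs the identification-efficacy
#' simulation experiment instead. The analysis modes then compute the
#' predictor table, the predictor comparison (Mann-Whitney + enrichment
#' factors), the 4-SD outlier report with matched-control comparison, and
#' the stepwise-forward LR logistic model, each written as TSV with a
#' provenance header, plus a run manifest. Each stochastic stage draws from
#' its own stream derived from the master seed by a fixed offset, so adding
#' a stage never perturbs another stage's draws.
#'
#' @param mode One of \code{"real"}, \code{"synthetic-cohort"},
#'   \code{"simulation"}.
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param matrix_path,annotation_path,labels_path Inputs for \code{"real"}
#'   mode.
#' @param level Declared processing level of a real input matrix; raw input
#'   is log2-transformed before analysis.
#' @param cohort Cohort configuration for \code{"synthetic-cohort"} mode
#'   (its \code{seed} field is overridden by the derived stream).
#' @param sim Simulation configuration for \code{"simulation"} mode
#'   (likewise).
#' @param k_sd Outlier band half-width in AN SDs.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(mode = c("real", "synthetic-cohort", "simulation"),
                         out_dir, seed = 1L,
                         matrix_path = NULL, annotation_path = NULL,
                         labels_path = NULL, level = "log2",
                         cohort = cohort_config(), sim = sim_config(),
                         k_sd = 4) {
  mode <- match.arg(mode)
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- function(stage) list(mode = mode, stage = stage, seed = seed)
  paths <- list()

  if (mode == "simulation") {
    sim$seed <- seed + 2000L
    res <- run_simulation_experiment(sim)
    paths$simulation <- file.path(out_dir, "simulation.tsv")
    write_report(as.data.frame(res), paths$simulation, prov("simulation"))
    paths$simulation_summary <- file.path(out_dir, "simulation_summary.tsv")
    write_report(summary(res), paths$simulation_summary, prov("simulation_summary"))
  } else {
    if (mode == "real") {
      if (is.null(matrix_path) || is.null(annotation_path) || is.null(labels_path))
        stop("real mode needs matrix_path, annotation_path and labels_path")
      dataset <- read_expression_matrix(matrix_path, annotation_path, level = level)
      if (dataset$level == "raw") dataset <- log2_transform(dataset)
      labels <- read_gene_list(labels_path)
    } else {
      cohort$seed <- seed + 1000L
      coh <- generate_heterogeneous_cohort(cohort)
      dataset <- coh$dataset
      labels <- coh$labels
      paths$matrix <- file.path(out_dir, "cohort_matrix.tsv")
      paths$annotation <- file.path(out_dir, "cohort_annotation.tsv")
      write_expression_matrix(dataset, paths$matrix, paths$annotation)
      paths$labels <- file.path(out_dir, "cohort_labels.txt")
      write_gene_list(labels, paths$labels)
    }

    tab <- tryCatch(compute_predictor_table(dataset),
                    error = function(e) stop("stage 'predictors' failed: ",
                                             conditionMessage(e), call. = FALSE))
    paths$predictors <- file.path(out_dir, "predictors.tsv")
    write_report(as.data.frame(tab), paths$predictors, prov("predictors"))

    enr <- tryCatch(predictor_comparison(tab, labels),
                    error = function(e) stop("stage 'enrichment' failed: ",
                                             conditionMessage(e), call. = FALSE))
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    write_report(as.data.frame(enr), paths$enrichment, prov("enrichment"))

    out <- tryCatch({
      rep <- call_outliers(dataset, k_sd = k_sd)
      ctrl <- matched_controls(tab, labels)
      cmp <- compare_outlier_rates(rep, labels, ctrl)
      list(rep = rep, cmp = cmp)
    }, error = function(e) stop("stage 'outliers' failed: ",
                                conditionMessage(e), call. = FALSE))
    paths$outliers <- file.path(out_dir, "outliers.tsv")
    write_report(as.data.frame(out$rep), paths$outliers, prov("outliers"))
    paths$outlier_comparison <- file.path(out_dir, "outlier_comparison.tsv")
    write_report(as.data.frame(out$cmp), paths$outlier_comparison,
                 prov("outlier_comparison"))

    step <- tryCatch(stepwise_forward_lr(tab, labels),
                     error = function(e) stop("stage 'model_selection' failed: ",
                                              conditionMessage(e), call. = FALSE))
    paths$stepwise <- file.path(out_dir, "stepwise.tsv")
    write_report(step$steps, paths$stepwise, prov("model_selection"))
  }

  manifest <- data.frame(
    key = c("mode", "seed", "package_version", "r_version",
            names(paths)),
    value = c(mode, seed, as.character(utils::packageVersion("hetrank")),
              paste(R.version$major, R.version$minor, sep = "."),
              unlist(paths, use.names = FALSE)),
    stringsAsFactors = FALSE)
  paths$manifest <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
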