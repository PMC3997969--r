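#' Maximum-likelihood binary logistic fit
#'
#' Thin wrapper around \code{stats::glm(family = binomial)} with tight
#' convergence control (log-likelihood change < 1e-8, up to 100 iterations).
#' Non-convergence is reported via warning and flagged, never silently
#' accepted. Perfect or quasi-perfect separation is detected (fitted
#' probabilities pinned to 0/1 or runaway coefficients); reported
#' coefficients are then capped at +/- 30 and the fit flagged.
#'
#' @param y Binary outcome (0/1 or logical), both classes present.
#' @param X Numeric matrix or data frame of predictors (may have zero
#'   columns for an intercept-only fit).
#' @return List with \code{coefficients} (intercept first),
#'   \code{log_likelihood}, \code{converged}, \code{separation}, and the
#'   underlying \code{glm} object as \code{fit}.
#' @examples
#' y <- rep(c(0, 1), c(70, 30))
#' fit_logistic(y, matrix(numeric(0), 100, 0))$coefficients  # log(0.3/0.7)
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  if (length(unique(y)) < 2L) stop("y contains a single class")
  X <- as.data.frame(X)
  if (ncol(X) && !all(vapply(X, function(col) all(is.finite(col)), TRUE)))
    stop("predictor columns must be finite")
  if (length(y) <= ncol(X) + 1L) stop("need n > p + 1 observations")
  dat <- cbind(.y = y, X)
  fml <- if (ncol(X)) stats::as.formula(paste(".y ~", paste(sprintf("`%s`", names(X)), collapse = " + ")))
    else .y ~ 1
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat,
                                     control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  sep <- any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10) ||
    isTRUE(any(abs(stats::coef(fit)[-1]) > 30, na.rm = TRUE))
  if (!fit$converged) warning("logistic fit did not converge")
  if (sep) warning("possible separation: coefficients capped at +/- 30")
  cf <- stats::coef(fit)
  if (sep) cf <- pmax(pmin(cf, 30), -30)
  list(coefficients = cf, log_likelihood = as.numeric(stats::logLik(fit)),
       converged = fit$converged, separation = sep, fit = fit)
}

#' Stepwise-forward likelihood-ratio logistic selection of predictors
#'
#' Cancer-gene status is the outcome and the six per-gene predictors are the
#' candidates. Starting from the intercept-only model, each step fits every
#' excluded predictor on top of the current model, computes the
#' likelihood-ratio chi-square (2 x log-likelihood gain, 1 df), and admits
#' the predictor with the smallest p-value if it is below \code{entry_p};
#' selection stops when no candidate qualifies. No removal step is
#' performed.
#'
#' @param table A \code{\link{compute_predictor_table}} result.
#' @param labels A \code{\link{gene_label_set}} with >= 2 labeled and >= 2
#'   unlabeled genes in the table.
#' @param entry_p Entry threshold on the LR p-value (default 0.05).
#' @param predictors Candidate column names (default the six predictors).
#' @return An object of class \code{"hetrank_stepwise"}: list with
#'   \code{selected} (names in entry order), \code{steps} (data frame of
#'   \code{predictor, lr_chi2, p_entry, log_likelihood}), \code{coefficients}
#'   of the final model, \code{log_likelihood}, \code{null_log_likelihood},
#'   and the final \code{glm} fit.
#' @examples
#' coh <- generate_heterogeneous_cohort(cohort_config(seed = 1))
#' tab <- compute_predictor_table(coh$dataset)
#' stepwise_forward_lr(tab, coh$labels)
#' @export
stepwise_forward_lr <- function(table, labels, entry_p = 0.05,
                                predictors = PREDICTORS) {
  y <- as.numeric(table$gene_id %in% labels$cancer_genes)
  if (sum(y) < 2L || sum(1 - y) < 2L)
    stop("need >= 2 cancer and >= 2 other genes")
  X <- as.data.frame(table)[predictors]
  selected <- character()
  current <- fit_logistic(y, X[character(0)])
  null_ll <- current$log_likelihood
  steps <- list()
  repeat {
    candidates <- setdiff(predictors, selected)
    if (!length(candidates)) break
    trials <- lapply(candidates, function(p) {
      f <- fit_logistic(y, X[c(selected, p)])
      chi2 <- max(0, 2 * (f$log_likelihood - current$log_likelihood))
      list(p = p, fit = f, chi2 = chi2,
           pval = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
    })
    pvals <- vapply(trials, `[[`, numeric(1), "pval")
    best <- trials[[which.min(pvals)]]
    if (best$pval >= entry_p) break
    selected <- c(selected, best$p)
    current <- best$fit
    steps[[length(steps) + 1L]] <- data.frame(
      predictor = best$p, lr_chi2 = best$chi2, p_entry = best$pval,
      log_likelihood = best$fit$log_likelihood, stringsAsFactors = FALSE)
  }
  structure(list(selected = selected,
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame(predictor = character(), lr_chi2 = numeric(),
                                         p_entry = numeric(), log_likelihood = numeric()),
                 coefficients = current$coefficients,
                 log_likelihood = current$log_likelihood,
                 null_log_likelihood = null_ll,
                 entry_p = entry_p, n = length(y), n_cancer = sum(y),
                 fit = current$fit),
            class = "hetrank_stepwise")
}

#' @export
print.hetrank_stepwise <- function(x, ...) {
  cat(sprintf("stepwise-forward LR logistic model (%d genes, %d cancer; entry p < %g)\n",
              x$n, x$n_cancer, x$entry_p))
  if (!length(x$selected)) {
    cat("no predictor met the entry criterion\n")
  } else {
    st <- x$steps
    st[c("lr_chi2", "log_likelihood")] <- lapply(st[c("lr_chi2", "log_likelihood")], round, 3)
    st$p_entry <- signif(st$p_entry, 3)
    print.data.frame(st, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.hetrank_stepwise <- function(object, ...) {
  cat("Selected predictors (entry order):",
      if (length(object$selected)) paste(object$selected, collapse = ", ") else "none", "\n")
  cat(sprintf("log-likelihood: %.3f (intercept-only %.3f)\n",
              object$log_likelihood, object$null_log_likelihood))
  cat("Final model coefficients:\n")
  print(round(object$coefficients, 4))
  invisible(object)
}

#' @export
coef.hetrank_stepwise <- function(object, ...) object$coefficients

#' @export
predict.hetrank_stepwise <- function(object, newdata = NULL,
                                     type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(stats::predict(object$fit, type = type))
  stats::predict(object$fit, newdata = as.data.frame(newdata), type = type)
}

#' @export
logLik.hetrank_stepwise <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients), class = "logLik")
}
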