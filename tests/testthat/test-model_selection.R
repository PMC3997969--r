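test_that("logistic fits recover closed-form solutions", {
  # intercept-only MLE is the log-odds of the positive rate
  y <- rep(c(1, 0), c(30, 70))
  f0 <- fit_logistic(y, data.frame(row.names = seq_along(y)))
  expect_equal(unname(f0$coefficients[1]), log(0.3 / 0.7), tolerance = 1e-6)
  expect_equal(f0$log_likelihood,
               30 * log(0.3) + 70 * log(0.7), tolerance = 1e-6)

  # grouped binary predictor with odds ratio 4: slope = log 4
  y2 <- c(rep(c(1, 0), c(20, 80)), rep(c(1, 0), c(50, 50)))
  x2 <- rep(c(0, 1), each = 100)
  f2 <- fit_logistic(y2, data.frame(x = x2))
  expect_equal(unname(f2$coefficients["x"]), log(4), tolerance = 1e-6)
  expect_equal(unname(f2$coefficients[1]), log(0.25), tolerance = 1e-6)

  # null data: slope near 0, LL near the Bernoulli baseline
  set.seed(12)
  y3 <- rbinom(500, 1, 0.3)
  f3 <- fit_logistic(y3, data.frame(x = rnorm(500)))
  base_ll <- fit_logistic(y3, data.frame(row.names = 1:500))$log_likelihood
  expect_lt(abs(unname(f3$coefficients["x"])), 0.5)
  expect_lt(2 * (f3$log_likelihood - base_ll), qchisq(0.999, 1))

  expect_error(fit_logistic(rep(1, 10), data.frame(x = rnorm(10))), "single class")
  expect_error(fit_logistic(c(1, 0), data.frame(x = 1:2, z = 2:3)), "n > p")
})

test_that("logistic slope matches a direct likelihood-maximization oracle", {
  nll <- function(par, y, x) -sum(y * (par[1] + par[2] * x) -
                                    log1p(exp(par[1] + par[2] * x)))
  ngr <- function(par, y, x) {
    p <- plogis(par[1] + par[2] * x)
    -c(sum(y - p), sum((y - p) * x))
  }
  set.seed(20)
  for (i in 1:20) {
    n <- sample(20:50, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    f <- fit_logistic(y, data.frame(x = x))
    if (f$separation) next
    orc <- optim(c(0, 0), nll, gr = ngr, y = y, x = x, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_equal(unname(f$coefficients["x"]), orc$par[2], tolerance = 1e-4)
  }
})

test_that("perfect separation is flagged and coefficients capped", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  expect_warning(f <- fit_logistic(y, data.frame(x = x)), "separation")
  expect_true(f$separation)
  expect_true(all(abs(f$coefficients) <= 30))
})

test_that("stepwise forward LR selects the variance signal and resists collinearity", {
  coh <- generate_heterogeneous_cohort(cohort_config(seed = 41))
  tab <- compute_predictor_table(coh$dataset)
  fit <- suppressWarnings(stepwise_forward_lr(tab, coh$labels))
  expect_identical(fit$selected[1], "sd_t")
  expect_true(all(fit$steps$p_entry < 0.05))
  expect_true(all(fit$steps$lr_chi2 >= 0))

  # entry LR chi-squares reproduce from independent full refits
  y <- as.numeric(tab$gene_id %in% coh$labels$cancer_genes)
  X <- as.data.frame(tab)
  for (i in seq_along(fit$selected)) {
    with_i <- suppressWarnings(fit_logistic(y, X[fit$selected[seq_len(i)]]))$log_likelihood
    without <- suppressWarnings(fit_logistic(y, X[fit$selected[seq_len(i - 1)]]))$log_likelihood
    expect_equal(fit$steps$lr_chi2[i], 2 * (with_i - without), tolerance = 1e-6)
  }

  # duplicated sd_t column: the copy adds no likelihood and never both enter
  tab2 <- as.data.frame(tab)
  tab2$sd_t_copy <- tab2$sd_t
  fit2 <- suppressWarnings(
    stepwise_forward_lr(tab2, coh$labels,
                        predictors = c("sd_t", "sd_t_copy", "neglogp")))
  expect_equal(sum(c("sd_t", "sd_t_copy") %in% fit2$selected), 1L)
})

test_that("z-scoring predictors changes coefficients but not selection or LR statistics", {
  coh <- generate_heterogeneous_cohort(cohort_config(n_genes = 500, n_cancer = 30, seed = 43))
  tab <- compute_predictor_table(coh$dataset)
  fit <- suppressWarnings(stepwise_forward_lr(tab, coh$labels))
  tabz <- as.data.frame(tab)
  six <- c("m_an", "m_t", "fc", "neglogp", "sd_an", "sd_t")
  tabz[six] <- lapply(tabz[six], function(v) (v - mean(v)) / sd(v))
  fitz <- suppressWarnings(stepwise_forward_lr(tabz, coh$labels, predictors = six))
  expect_identical(fitz$selected, fit$selected)
  expect_equal(fitz$steps$lr_chi2, fit$steps$lr_chi2, tolerance = 1e-5)
})

test_that("null cohorts keep per-predictor entry rates near the nominal level", {
  six <- c("m_an", "m_t", "fc", "neglogp", "sd_an", "sd_t")
  sel <- matrix(FALSE, 60, 6, dimnames = list(NULL, six))
  empty <- logical(60)
  for (s in 1:60) {
    coh <- generate_null_cohort(cohort_config(n_genes = 500, n_cancer = 25,
                                              seed = 9000 + s))
    tab <- compute_predictor_table(coh$dataset)
    fit <- suppressWarnings(stepwise_forward_lr(tab, coh$labels))
    sel[s, fit$selected] <- TRUE
    empty[s] <- length(fit$selected) == 0L
  }
  # marginal inclusion of any single predictor stays near the 5% entry level
  expect_true(all(colMeans(sel) <= 0.18))
  # family-wise: empty at least as often as six independent 5% tests allow,
  # minus Monte-Carlo slack
  expect_gte(mean(empty), 0.95^6 - 3 * sqrt(0.25 / 60))
})
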