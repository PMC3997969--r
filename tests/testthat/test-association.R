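test_that("Mann-Whitney U matches brute-force pair counting and its identities", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney(c(5), c(5))$U, 0.5)

  mw <- mann_whitney(c(1, 3, 5, 7), c(2, 4, 6))
  expect_equal(mw$U, bf_mw_u(c(1, 3, 5, 7), c(2, 4, 6)))
  expect_equal(mw$Z, 0, tolerance = 1e-10)
  expect_equal(mw$p, 1, tolerance = 1e-10)

  set.seed(5)
  for (i in 1:200) {
    a <- sample(1:6, sample(1:5, 1), replace = TRUE)
    b <- sample(1:6, sample(1:5, 1), replace = TRUE)
    ua <- mann_whitney(a, b)$U
    expect_equal(ua, bf_mw_u(a, b))
    expect_equal(ua + mann_whitney(b, a)$U, length(a) * length(b))
  }

  # tie-free p agrees with the classic normal-approximation test
  set.seed(6)
  a <- rnorm(15); b <- rnorm(12) + 0.8
  ref <- suppressWarnings(wilcox.test(a, b, correct = FALSE, exact = FALSE))
  expect_equal(mann_whitney(a, b)$p, ref$p.value, tolerance = 1e-10)

  expect_error(mann_whitney(numeric(0), 1), "non-empty")
  expect_equal(mann_whitney(c(2, 2), c(2, 2))$p, 1)  # all tied, zero variance
})

test_that("top-5% enrichment follows the ceiling rule and transform invariance", {
  tab <- make_table(gene_id = paste0("g", 1:100), sd_t = 100:1)
  labs <- labels_for(paste0("g", 1:5))  # the 5 largest values
  re <- rank_enrichment(tab, "sd_t", labs)
  expect_equal(re$k, 5)
  expect_equal(re$top_prop, 1.0)
  expect_equal(re$ef, 20)

  # EF = 1 baseline: exactly the expected share of labels in the top bin
  labs2 <- labels_for(paste0("g", c(3, 25, 50, 70, 95) * 1))
  re2 <- rank_enrichment(make_table(gene_id = paste0("g", 1:100), sd_t = 100:1),
                         "sd_t", labels_for(c("g2", "g30", "g55", "g78", "g99")))
  expect_equal(re2$ef, re2$top_prop / 0.05)

  tab3 <- make_table(gene_id = paste0("g", 1:200), sd_t = sample(200))
  labs3 <- labels_for(tab3$gene_id[order(tab3$sd_t, decreasing = TRUE)][c(1, 5, 9, 30, 40, 60, 80, 120, 150, 190)])
  re3 <- rank_enrichment(tab3, "sd_t", labs3)   # exactly 3 of 10 labels in top 10
  expect_equal(re3$top_prop, 0.3)
  expect_equal(re3$ef, 6)

  # strictly increasing transform leaves the ranking untouched
  tab3b <- tab3
  tab3b$sd_t <- exp(tab3$sd_t / 50)
  expect_equal(rank_enrichment(tab3b, "sd_t", labs3), re3)

  expect_error(rank_enrichment(tab3, "banana", labs3), "unknown predictor")
  expect_error(rank_enrichment(tab[1:10, ], "sd_t", labs), "20")
})

test_that("predictor comparison ranks by |Z| and flags degenerate label sets", {
  coh <- generate_null_cohort(cohort_config(n_genes = 300, n_cancer = 0, seed = 4))
  tab <- compute_predictor_table(coh$dataset)
  labs <- labels_for(tab$gene_id[order(tab$sd_t, decreasing = TRUE)][1:20])
  rep <- predictor_comparison(tab, labs)
  expect_setequal(rep$rank, 1:6)
  expect_identical(rep$predictor[rep$rank == 1], "sd_t")
  expect_gt(rep$ef[rep$predictor == "sd_t"], 10)

  expect_error(predictor_comparison(tab, labels_for(c("nope1", "nope2"))), "disjoint")
})

test_that("Kendall tau equals exhaustive pair enumeration, with and without ties", {
  expect_equal(kendall_tau(1:5, 1:5), 1)
  expect_equal(kendall_tau(1:5, 5:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  set.seed(10)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_tau(x, y), bf_kendall(x, y), tolerance = 1e-12)
  }
  expect_error(kendall_tau(1:3, 1:4), "length mismatch")
})

test_that("subsampling a few tumors preserves a strong SD(T) signal but not a null", {
  coh <- generate_heterogeneous_cohort(
    cohort_config(n_genes = 1000, n_cancer = 50, outlier_fraction = 0.3,
                  outlier_shift = 3.0, seed = 21))
  rob <- subsample_robustness(coh$dataset, coh$labels, k_tumors = 9,
                              n_reps = 20, seed = 22)
  expect_gte(rob$fraction_significant, 0.9)

  nul <- generate_null_cohort(cohort_config(n_genes = 1000, n_cancer = 50, seed = 23))
  rob0 <- subsample_robustness(nul$dataset, nul$labels, k_tumors = 9,
                               n_reps = 20, seed = 24)
  expect_lte(rob0$fraction_significant, 0.25)

  expect_error(subsample_robustness(coh$dataset, coh$labels, n_reps = 0), "n_reps")
  expect_error(subsample_robustness(coh$dataset, coh$labels, k_tumors = 50),
               "exceeds")
})
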