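# Fixture builders and independent brute-force oracles shared by the tests.

# One-or-more-gene dataset from per-group value lists.
make_dataset <- function(an, t, gene_ids = NULL) {
  an <- if (is.list(an)) an else list(an)
  t <- if (is.list(t)) t else list(t)
  stopifnot(length(an) == length(t))
  vals <- t(mapply(c, an, t))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_along(an))
  n_an <- length(an[[1]]); n_t <- length(t[[1]])
  dimnames(vals) <- list(gene_ids,
                         c(paste0("AN", seq_len(n_an)), paste0("T", seq_len(n_t))))
  expression_dataset(vals, rep(c("AN", "T"), c(n_an, n_t)), level = "log2")
}

# Bare predictor table with chosen columns, for ranking/matching tests.
make_table <- function(...) {
  tab <- data.frame(..., stringsAsFactors = FALSE)
  class(tab) <- c("predictor_table", "data.frame")
  tab
}

labels_for <- function(ids) gene_label_set(ids)

# Brute-force Mann-Whitney U for sample a: pairs a_i > b_j, ties half.
bf_mw_u <- function(a, b) {
  cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  sum(cmp)
}

# Kendall tau-b by exhaustive pair enumeration.
bf_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
    if (sx != 0 && sy != 0) {
      if (sx == sy) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# -log10 two-sided pooled-t p via numeric integration of the t density
# (independent of pt()).
bf_neglogp <- function(an, t) {
  n1 <- length(an); n2 <- length(t)
  sp2 <- (sum((an - mean(an))^2) + sum((t - mean(t))^2)) / (n1 + n2 - 2)
  tt <- abs(mean(t) - mean(an)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::integrate(function(x) stats::dt(x, n1 + n2 - 2),
                            tt, Inf, rel.tol = 1e-10)$value
  -log10(p)
}

# Write a TSV matrix + annotation fixture; returns the two paths.
write_fixture <- function(dataset, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "matrix.tsv")
  ap <- file.path(dir, "annotation.tsv")
  write_expression_matrix(dataset, mp, ap)
  list(matrix = mp, annotation = ap)
}
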