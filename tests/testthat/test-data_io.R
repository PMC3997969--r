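test_that("TSV matrix reading honors shape, groups, duplicates and missing values", {
  dir <- withr::local_tempdir()
  mat <- c("gene_id\ts1\ts2\ts3\ts4",
           "g1\t5.1\t5.2\t6.1\t6.3",
           "g2\t7.0\t7.1\t7.2\t7.3",
           "g3\t4.0\t4.1\t4.2\t4.3")
  ann <- c("sample_id\tgroup", "s1\tAN", "s2\tAN", "s3\tT", "s4\tT")
  writeLines(mat, file.path(dir, "m.tsv"))
  writeLines(ann, file.path(dir, "a.tsv"))

  ds <- read_expression_matrix(file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  expect_identical(dim(ds), c(3L, 4L))
  expect_identical(as.character(ds$group), c("AN", "AN", "T", "T"))
  expect_identical(rownames(ds$values), c("g1", "g2", "g3"))

  writeLines(c(mat, "g2\t1\t1\t1\t1"), file.path(dir, "dup.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "dup.tsv"), file.path(dir, "a.tsv")),
               "g2")

  mat_na <- mat
  mat_na[3] <- "g2\t7.0\tNA\t7.2\t7.3"
  writeLines(mat_na, file.path(dir, "na.tsv"))
  expect_message(
    ds_na <- read_expression_matrix(file.path(dir, "na.tsv"), file.path(dir, "a.tsv")),
    "1 gene")
  expect_identical(rownames(ds_na$values), c("g1", "g3"))

  # sample missing from the annotation
  writeLines(ann[1:4], file.path(dir, "a_short.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "m.tsv"), file.path(dir, "a_short.tsv")),
               "annotation")

  # transposed file: rows are sample ids
  writeLines(c("gene_id\tg1\tg2\tg3",
               "s1\t5.1\t7.0\t4.0", "s2\t5.2\t7.1\t4.1",
               "s3\t6.1\t7.2\t4.2", "s4\t6.3\t7.3\t4.3"),
             file.path(dir, "t.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "t.tsv"), file.path(dir, "a.tsv")),
               "transposed")
})

test_that("series-matrix-style files parse via the table section", {
  dir <- withr::local_tempdir()
  lines <- c("!Series_title\t\"synthetic example\"",
             "!Sample_geo_accession\t\"s1\"\t\"s2\"\t\"s3\"\t\"s4\"",
             "!series_matrix_table_begin",
             "\"ID_REF\"\t\"s1\"\t\"s2\"\t\"s3\"\t\"s4\"",
             "\"g1\"\t5.1\t5.2\t6.1\t6.3",
             "\"g2\"\t7.0\t7.1\t7.2\t7.3",
             "!series_matrix_table_end")
  writeLines(lines, file.path(dir, "sm.txt"))
  ann <- data.frame(sample_id = paste0("s", 1:4), group = c("AN", "AN", "T", "T"))
  ds <- read_expression_matrix(file.path(dir, "sm.txt"), ann, format = "series_matrix")
  expect_identical(dim(ds), c(2L, 4L))
  expect_equal(ds$values["g1", "s3"], 6.1)
  writeLines(lines[1:2], file.path(dir, "bad.txt"))
  expect_error(read_expression_matrix(file.path(dir, "bad.txt"), ann,
                                      format = "series_matrix"), "format")
})

test_that("write/read round trip preserves values and labels", {
  coh <- generate_null_cohort(cohort_config(n_genes = 30, n_cancer = 5,
                                            n_an = 4, n_t = 5, seed = 7))
  fx <- write_fixture(coh$dataset)
  back <- read_expression_matrix(fx$matrix, fx$annotation)
  expect_identical(rownames(back$values), rownames(coh$dataset$values))
  expect_identical(colnames(back$values), colnames(coh$dataset$values))
  expect_identical(as.character(back$group), as.character(coh$dataset$group))
  expect_equal(back$values, coh$dataset$values, tolerance = 1e-6)
})

test_that("log2 transform is exact, reversible and validates its domain", {
  ds <- make_dataset(list(c(8, 1, 7), c(4, 4, 4)), list(c(4, 2, 16), c(2, 2, 2)))
  ds$level <- "raw"
  lg <- log2_transform(ds)
  expect_equal(lg$values[1, ], c(AN1 = 3, AN2 = 0, AN3 = 2.807355, T1 = 2, T2 = 1, T3 = 4),
               tolerance = 1e-6)
  expect_identical(lg$level, "log2")

  # round trip through pointwise 2^x
  coh <- generate_null_cohort(cohort_config(n_genes = 20, n_cancer = 2, n_an = 3, n_t = 3, seed = 1))
  raw <- coh$dataset
  raw$values <- 2^raw$values
  raw$level <- "raw"
  expect_equal(log2_transform(raw)$values, coh$dataset$values, tolerance = 1e-12)

  bad <- ds
  bad$values["g2", "T1"] <- -1
  expect_error(log2_transform(bad), "g2.*T1")
  expect_error(log2_transform(coh$dataset), "raw")
})

test_that("gene lists read with tags, duplicates and the recent-exclusion rule", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "genes.txt")

  writeLines(c("# known drivers", "TP53", "EGFR", "TP53"), p)
  ls1 <- read_gene_list(p)
  expect_setequal(ls1$cancer_genes, c("TP53", "EGFR"))
  expect_length(ls1$recent_genes, 0)

  writeLines(c("TP53\tknown", "XYZ\trecent"), p)
  ls2 <- read_gene_list(p)
  expect_identical(ls2$cancer_genes, "TP53")
  expect_identical(ls2$recent_genes, "XYZ")

  writeLines(c("TP53\tknown", "TP53\trecent"), p)
  ls3 <- read_gene_list(p)
  expect_length(ls3$cancer_genes, 0)
  expect_identical(ls3$recent_genes, "TP53")

  writeLines(character(), p)
  expect_error(read_gene_list(p), "empty")

  ls4 <- gene_label_set(c("A", "B"))
  p2 <- file.path(dir, "out.txt")
  write_gene_list(ls4, p2)
  expect_setequal(read_gene_list(p2)$cancer_genes, c("A", "B"))
})
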