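test_that("wide and long layouts round-trip exactly", {
  m <- matrix(c(20.1, 21.2, 19.9, 22.4, 23.0, 21.5), 2, 3, byrow = TRUE,
              dimnames = list(c("ACT", "GAPDH"), c("s1", "s2", "s3")))
  tab <- ct_table(m, data.frame(sample_id = c("s1", "s2", "s3"),
                                subset = "NaCl", time_point = c(0, 1, 6)))
  expect_identical(dim(tab), c(2L, 3L))
  expect_identical(tab$genes, c("ACT", "GAPDH"))

  for (layout in c("wide", "long")) {
    f <- tempfile(fileext = ".csv")
    write_ct_table(tab, f, layout = layout)
    back <- read_ct_table(f, layout = layout)
    expect_equal(back$ct, tab$ct)
    expect_identical(back$genes, tab$genes)
    if (layout == "long")
      expect_equal(back$samples$time_point, tab$samples$time_point)
    unlink(f)
  }
})

test_that("validation rejects bad gene symbols, Ct values and missing cells", {
  m <- matrix(c(20, 21, 22, 23), 2, 2,
              dimnames = list(c("g1", "g1"), NULL))
  expect_error(ct_table(m), "duplicate gene symbol")

  m2 <- matrix(c(20, 50, 22, 23), 2, 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(ct_table(m2), "outside \\(0, 45\\]")

  f <- tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,20,NA", "g2,21,22"), f)
  expect_error(read_ct_table(f), "completeness error.*g1.*s2")
  expect_silent(tab <- suppressMessages(read_ct_table(f, allow_missing = TRUE)))
  unlink(f)

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,20,oops", "g2,21,22"), f2)
  expect_error(read_ct_table(f2), "non-numeric Ct.*g1")
  unlink(f2)
})

test_that("technical replicates collapse by arithmetic mean", {
  m <- matrix(c(20.0, 20.2, 20.4, 18, 18, 18), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  ann <- data.frame(sample_id = "s1", tech_replicate = 1:3)
  col <- collapse_technical_replicates(ct_table(m, ann))
  expect_equal(unname(col$ct["g1", 1]), 20.2)
  expect_equal(unname(col$ct["g2", 1]), 18)
  expect_null(col$samples$tech_replicate)

  # single technical replicate: identity
  one <- ct_table(matrix(19.7, 1, 1, dimnames = list("g1", "s1")))
  expect_equal(unname(collapse_technical_replicates(one)$ct[1, 1]), 19.7)

  # dispersion beyond 0.5 cycles is flagged
  wide_m <- matrix(c(19.0, 19.8), 1, 2, dimnames = list("g1", NULL))
  wide_ann <- data.frame(sample_id = "s1", tech_replicate = 1:2)
  expect_warning(collapse_technical_replicates(ct_table(wide_m, wide_ann)),
                 "dispersion")
})

test_that("collapsing technical replicates commutes with column permutation", {
  set.seed(42)
  m <- matrix(stats::rnorm(4 * 6, 20, 0.1), 4, 6,
              dimnames = list(paste0("g", 1:4), NULL))
  ann <- data.frame(sample_id = rep(c("s1", "s2"), each = 3),
                    tech_replicate = rep(1:3, 2))
  a <- collapse_technical_replicates(ct_table(m, ann))
  perm <- c(4, 2, 6, 1, 3, 5)
  b <- collapse_technical_replicates(
    ct_table(m[, perm], ann[perm, , drop = FALSE]))
  expect_equal(a$ct, b$ct[, colnames(a$ct)])
})

test_that("summarize_ct matches direct computation and ignores column order", {
  expect_equal(summarize_ct(make_ct(matrix(20, 1, 3)))$sd, 0)

  s <- summarize_ct(make_ct(matrix(c(18, 19, 20, 21), 1)))
  expect_equal(s$mean, 19.5)
  expect_equal(s$sd, sqrt(5 / 3), tolerance = 1e-12)

  set.seed(7)
  m <- matrix(stats::runif(5 * 9, 15, 30), 5, 9,
              dimnames = list(paste0("g", 1:5), NULL))
  s1 <- summarize_ct(make_ct(m))
  expect_equal(s1$mean, rowMeans(m), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(s1$sd,
               sqrt(rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)),
               ignore_attr = TRUE, tolerance = 1e-12)
  s2 <- summarize_ct(make_ct(m[, sample(9)]))
  expect_equal(s1[-1], s2[-1], tolerance = 1e-12)
})

test_that("primer table parses with validation and range warnings", {
  pt <- read_primer_table(table1_path())
  expect_s3_class(pt, "primer_table")
  expect_equal(nrow(pt), 15)
  expect_equal(sum(pt$is_candidate_reference), 14)
  expect_identical(pt$gene_symbol[!pt$is_candidate_reference], "CYP72A1")

  f <- tempfile(fileext = ".csv")
  writeLines(c("gene_symbol,gene_id,forward_primer,reverse_primer,amplicon_bp,efficiency,r_squared",
               "X1,id1,AAA,TTT,90,1.9,0.99"), f)
  expect_warning(read_primer_table(f), "100-250")
  writeLines(c("gene_symbol,gene_id,forward_primer,reverse_primer,amplicon_bp,efficiency,r_squared",
               "X1,id1,AAA,TTT,150,2.3,0.99"), f)
  expect_error(read_primer_table(f), "efficiency outside")
  writeLines(c("gene_symbol,gene_id,forward_primer,reverse_primer,amplicon_bp,efficiency,r_squared",
               "X1,id1,AAA,TTT,150,1.9,0.99", "X1,id2,AAA,TTT,150,1.9,0.99"), f)
  expect_error(read_primer_table(f), "duplicate gene symbol")
  unlink(f)
})
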