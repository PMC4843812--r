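mk_course <- function(target_ct, ref_ct, tp = c(0, 6, 24)) {
  m <- rbind(tgt = target_ct, ref1 = ref_ct)
  ct_table(m, data.frame(sample_id = paste0("s", seq_along(tp)),
                         time_point = tp))
}

test_that("fold changes match the ddCt hand calculations", {
  # everything constant: all fold changes 1
  fc0 <- normalized_expression(mk_course(c(20, 20, 20), c(18, 18, 18)),
                               "tgt", "ref1", control = 0)
  expect_equal(fc0$fold_change, c(1, 1, 1))

  # target drops 1 cycle at 6 h, references flat: fold change 2
  fc <- normalized_expression(mk_course(c(20, 19, 20), c(18, 18, 18)),
                              "tgt", "ref1", control = 0)
  expect_equal(fc$fold_change[fc$condition == 6], 2, tolerance = 1e-12)
  expect_equal(fc$fold_change[fc$condition == 0], 1)
})

test_that("multi-reference normalization uses the geometric mean", {
  m <- rbind(tgt = c(20, 19), ref1 = c(18, 18), ref2 = c(20, 22))
  tab <- ct_table(m, data.frame(sample_id = c("a", "b"),
                                time_point = c(0, 6)))
  two <- normalized_expression(tab, "tgt", c("ref1", "ref2"), control = 0)
  # one reference whose q equals the geometric mean of the two
  q <- delta_ct_transform(tab)$q
  gm <- sqrt(q["ref1", ] * q["ref2", ])
  one_ct <- rbind(tgt = m["tgt", ], gref = -log2(gm) + 25)
  one <- normalized_expression(
    ct_table(one_ct, data.frame(sample_id = c("a", "b"),
                                time_point = c(0, 6))),
    "tgt", "gref", control = 0)
  expect_equal(two$fold_change, one$fold_change, tolerance = 1e-12)
})

test_that("argument validation", {
  tab <- mk_course(c(20, 20, 20), c(18, 18, 18))
  expect_error(normalized_expression(tab, "tgt", character(0), control = 0),
               "empty reference")
  expect_error(normalized_expression(tab, "tgt", "tgt", control = 0),
               "reference equal to target")
  expect_error(normalized_expression(tab, "tgt", "ref1", control = 99),
               "control selects no samples")
})

test_that("shared loading effects cancel in fold changes", {
  set.seed(88)
  tp <- rep(c(0, 1, 6, 24), each = 2)
  base <- rbind(tgt = 20 - (tp == 6) * 1.5, ref1 = rep(18, 8),
                ref2 = rep(22, 8))
  loading <- stats::rnorm(8, 0, 2)
  ann <- data.frame(sample_id = paste0("s", 1:8), time_point = tp)
  clean <- normalized_expression(ct_table(base, ann), "tgt",
                                 c("ref1", "ref2"), control = 0)
  noisy <- normalized_expression(ct_table(sweep(base, 2, -loading), ann),
                                 "tgt", c("ref1", "ref2"), control = 0)
  expect_equal(noisy$fold_change, clean$fold_change, tolerance = 1e-10)
  expect_equal(clean$fold_change[clean$condition == 6], 2^1.5,
               tolerance = 1e-10)
})

test_that("a reference proportional to the target flattens the series", {
  tp <- c(0, 1, 6, 24)
  tgt <- c(20, 19, 18, 21)
  tab <- ct_table(rbind(tgt = tgt, refp = tgt + 3),
                  data.frame(sample_id = paste0("s", 1:4), time_point = tp))
  fc <- normalized_expression(tab, "tgt", "refp", control = 0)
  expect_equal(fc$fold_change, rep(1, 4), tolerance = 1e-12)
})

test_that("distortion ratios quantify unstable-reference bias", {
  tp <- c(0, 1, 6, 24)
  stable_tab <- ct_table(rbind(tgt = rep(20, 4), refS = rep(18, 4),
                               refU = c(18, 18, 18, 19)),
                         data.frame(sample_id = paste0("s", 1:4),
                                    time_point = tp))
  s_stable <- normalized_expression(stable_tab, "tgt", "refS", control = 0)
  s_unstable <- normalized_expression(stable_tab, "tgt", "refU", control = 0)
  d <- reference_choice_distortion(s_stable, s_unstable)
  expect_equal(d$ratio, c(1, 1, 1, 2), tolerance = 1e-12)
  expect_equal(reference_choice_distortion(s_stable, s_stable)$ratio,
               rep(1, 4))
  other <- normalized_expression(mk_course(c(20, 20, 20), c(18, 18, 18)),
                                 "tgt", "ref1", control = 0)
  expect_error(reference_choice_distortion(s_stable, other),
               "condition mismatch")
})
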