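test_that("pairwise V matches hand calculations and is symmetric", {
  expect_equal(pairwise_v(c(1, 2, 4, 8), c(2, 4, 8, 16)), 0)
  expect_equal(pairwise_v(c(1, 2, 4, 8), c(1, 1, 1, 1)), sqrt(5 / 3),
               tolerance = 1e-12)
  set.seed(3)
  a <- stats::runif(6); b <- stats::runif(6)
  expect_equal(pairwise_v(a, b), pairwise_v(b, a))
  expect_error(pairwise_v(a, b[-1]), "length mismatch")
  expect_error(pairwise_v(a, -b), "nonpositive")
})

test_that("stability M on the three-gene worked example", {
  q <- rbind(g1 = c(1, 2, 4, 8), g2 = c(2, 4, 8, 16), g3 = c(1, 1, 1, 1))
  m <- stability_m(q)
  v <- sqrt(5 / 3)
  expect_equal(unname(m), c(v / 2, v / 2, v), tolerance = 1e-12)

  # duplicated rows share the minimal M
  qd <- rbind(q, g4 = c(1, 2, 4, 8))
  md <- stability_m(qd)
  expect_equal(md[["g1"]], md[["g4"]])
  expect_true(all(md[c("g1", "g4")] <= md[c("g2", "g3")]))

  # per-sample global scaling leaves M unchanged
  qs <- q; qs[, 2] <- qs[, 2] * 37
  expect_equal(stability_m(qs), m, tolerance = 1e-12)
})

test_that("stepwise elimination removes the constant gene first", {
  q <- rbind(g1 = c(1, 2, 4, 8), g2 = c(2, 4, 8, 16), g3 = c(1, 1, 1, 1))
  gn <- genorm(q)
  expect_identical(gn$elimination_order, "g3")
  expect_setequal(gn$final_pair, c("g1", "g2"))
  expect_equal(unname(gn$ranking$ranks[c("g1", "g2", "g3")]), c(1, 1, 3))
})

test_that("genorm agrees with a brute-force oracle on random tables", {
  set.seed(101)
  for (i in 1:30) {
    q <- random_q(5, 8)
    gn <- genorm(q)
    or <- oracle_genorm(q)
    expect_identical(gn$elimination_order, or$elimination_order)
    expect_setequal(gn$final_pair, or$final_pair)
    expect_equal(gn$m_values, oracle_m(q, rownames(q)), tolerance = 1e-10)
    expect_equal(gn$v_series, oracle_v_series(q, gn$ranked_genes),
                 tolerance = 1e-10)
  }
})

test_that("normalization factors behave like geometric means", {
  q <- rbind(g1 = c(1, 0.5), g2 = c(0.25, 0.5), g3 = c(0.5, 0.125))
  expect_error(normalization_factor(q, rownames(q), 1), "out of range")
  expect_equal(unname(normalization_factor(q, c("g1", "g2"), 2)[1]), 0.5)
  # NF over all genes is invariant to gene order
  expect_equal(normalization_factor(q, c("g3", "g1", "g2"), 3),
               normalization_factor(q, c("g1", "g2", "g3"), 3),
               tolerance = 1e-12)
})

test_that("identical genes give an all-zero V series and n = 2", {
  q <- matrix(rep(c(1, 0.5, 0.25, 0.125), 4), 4, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), NULL))
  gn <- genorm(q)
  expect_equal(unname(gn$v_series), rep(0, 2))
  expect_identical(gn$recommended_n, 2L)

  ps <- pairwise_variation_series(q, rownames(q))
  expect_equal(ps$v_series, gn$v_series)
})

test_that("M and V are invariant to per-sample scaling; M to per-gene scaling", {
  set.seed(5)
  q <- random_q(6, 10)
  gn <- genorm(q)
  q2 <- q
  q2[, 3] <- q2[, 3] * 10   # global loading change in one sample
  q2[2, ] <- q2[2, ] * 0.2  # per-gene rescale
  gn2 <- genorm(q2)
  expect_equal(gn2$m_values, gn$m_values, tolerance = 1e-10)
  expect_equal(gn2$v_series, gn$v_series, tolerance = 1e-10)
  # M bounded by the largest pairwise V; zero iff proportional to all
  vmax <- max(unlist(lapply(1:5, function(j) sapply((j + 1):6, function(k)
    pairwise_v(q[j, ], q[k, ])))))
  expect_true(all(gn$m_values <= vmax + 1e-12))
  expect_true(all(gn$m_values >= 0))
})

test_that("an injected high-noise gene is eliminated first", {
  set.seed(2024)
  hits <- 0L
  for (s in 1:60) {
    cfg <- synthetic_config(n_genes = 6, noise_sd = c(rep(0.1, 5), 2.0),
                            loading_sd = 0.5, n_bio_replicates = 2)
    sim <- simulate_ct(cfg)
    gn <- genorm(delta_ct_transform(sim$table)$q)
    if (gn$elimination_order[1] == "gene06") hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.95)
})
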