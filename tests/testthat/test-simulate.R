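test_that("the generator is deterministic given a seed", {
  cfg <- synthetic_config(n_genes = 6, seed = 42)
  a <- simulate_ct(cfg)
  b <- simulate_ct(cfg)
  expect_identical(a$table$ct, b$table$ct)
  expect_identical(a$truth$true_order, b$truth$true_order)

  s1 <- simulate_study(seed = 7)
  s2 <- simulate_study(seed = 7)
  expect_identical(s1$table$ct, s2$table$ct)
})

test_that("a degenerate generator produces perfectly stable genes", {
  cfg <- synthetic_config(n_genes = 4, noise_sd = 0, loading_sd = 0,
                          seed = 1)
  sim <- simulate_ct(cfg)
  q <- delta_ct_transform(sim$table)$q
  expect_true(all(q == 1))          # every gene constant => all q = 1
  expect_equal(unname(genorm(q)$v_series), rep(0, 2))
  expect_equal(unname(normfinder(q)$sv), rep(0, 4))
})

test_that("config validation rejects impossible designs", {
  expect_error(synthetic_config(n_bio_replicates = 0), ">= 1")
  expect_error(synthetic_config(noise_sd = -1), ">= 0")
  expect_error(synthetic_config(effects = list(nope = c(0, 0, 0, 1))),
               "named by gene")
  expect_error(synthetic_config(effects = list(gene01 = c(0, 1))),
               "per condition")
})

test_that("true stability scores combine noise and condition effects", {
  cfg <- synthetic_config(n_genes = 3, noise_sd = c(0.1, 0.5, 0.1),
                          effects = list(gene03 = c(0, 1, 2, 2)), seed = 3)
  tr <- simulate_ct(cfg)$truth
  expect_equal(unname(tr$true_score[1]), 0.1)
  expect_equal(unname(tr$true_score[2]), 0.5)
  shifts <- c(0, 1, 2, 2)
  expect_equal(unname(tr$true_score[3]),
               sqrt(0.01 + mean((shifts - mean(shifts))^2)))
  expect_identical(tr$true_order[1], "gene01")
})

test_that("simulated FPKM recovers requested moments and cv ordering", {
  sim <- simulate_fpkm(c(u1 = 10), cv = 0, n_conditions = 5, seed = 1)
  expect_equal(unname(sim$table$fpkm[1, ]), rep(10, 5))

  sim2 <- simulate_fpkm(c(u1 = 10), cv = 0.3, n_conditions = 1000, seed = 2)
  st <- fpkm_stats(sim2$table)
  expect_lt(abs(st$cv - 0.3) / 0.3, 0.10)
  expect_lt(abs(st$mv - 10) / 10, 0.05)

  cvs <- seq(0.05, 1, length.out = 20)
  sim3 <- simulate_fpkm(stats::setNames(rep(20, 20), paste0("u", 1:20)),
                        cv = cvs, n_conditions = 50, seed = 3)
  st3 <- fpkm_stats(sim3$table)
  expect_gte(stats::cor(st3$cv, cvs, method = "spearman"), 0.9)

  expect_error(simulate_fpkm(c(u1 = -2), 0.1, 5), "means must be > 0")
  expect_error(simulate_fpkm(c(u1 = 2), -0.1, 5), "cv must be >= 0")
})

test_that("loading effects cancel in ratio statistics but not in raw Ct", {
  set.seed(15)
  reps <- 25
  delta_m <- delta_sv <- bk_lo <- bk_hi <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg0 <- synthetic_config(n_genes = 8, loading_sd = 0, noise_sd = 0.3)
    cfg2 <- synthetic_config(n_genes = 8, loading_sd = 2, noise_sd = 0.3)
    lo <- simulate_ct(cfg0)
    hi <- simulate_ct(cfg2)
    m_lo <- mean(genorm(delta_ct_transform(lo$table)$q)$m_values)
    m_hi <- mean(genorm(delta_ct_transform(hi$table)$q)$m_values)
    sv_lo <- mean(normfinder(delta_ct_transform(lo$table)$q)$sv)
    sv_hi <- mean(normfinder(delta_ct_transform(hi$table)$q)$sv)
    delta_m[i] <- m_hi - m_lo
    delta_sv[i] <- sv_hi - sv_lo
    bk_lo[i] <- mean(bestkeeper(lo$table, sd_method = "sample")$stats$sd)
    bk_hi[i] <- mean(bestkeeper(hi$table, sd_method = "sample")$stats$sd)
  }
  # ratio/centering statistics barely move when loading noise grows 0 -> 2
  expect_lt(abs(mean(delta_m)), 0.05)
  expect_lt(abs(mean(delta_sv)), 0.05)
  # ...while the BestKeeper spread grows roughly as sqrt(l^2 + s^2)
  expect_equal(mean(bk_hi) / mean(bk_lo), sqrt(4 + 0.09) / 0.3,
               tolerance = 0.15)
})
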