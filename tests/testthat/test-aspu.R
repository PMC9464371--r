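test_that("SPU statistic sums powered Z-scores over available traits", {
  expect_equal(spu_statistic(c(1, -2, 3), 1), 2)
  expect_equal(spu_statistic(c(1, -2, 3), 2), 14)
  expect_equal(spu_statistic(c(1, -2, 3), 3), 20)
  expect_equal(spu_statistic(c(1, NA, 3), 2), 10)
  expect_error(spu_statistic(c(NA, NA), 2), "available")
  expect_error(spu_statistic(1, 0), "gamma")
})

test_that("null-correlation estimation recovers independence and degeneracy", {
  Z <- simulate_null_z(10000, diag(4), seed = 41)
  nc <- estimate_null_corr(Z, thin = 1)
  expect_s3_class(nc, "null_corr")
  expect_true(all(abs(nc$R[upper.tri(nc$R)]) < 0.03))

  Zdup <- cbind(Z[, 1], Z[, 1])
  nc2 <- suppressWarnings(estimate_null_corr(Zdup, thin = 1))
  expect_gte(nc2$R[1, 2], 0.99)

  expect_error(estimate_null_corr(Z[1:50, ], thin = 1), "relax")
})

test_that("truncation bias of the null-correlation estimate matches a brute-force oracle", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  Z <- simulate_null_z(40000, R, seed = 42)
  est <- estimate_null_corr(Z, thin = 1)$R[1, 2]

  # oracle: direct truncated-MVN simulation with the same selection
  set.seed(43)
  Zo <- matrix(rnorm(2 * 200000), ncol = 2) %*% chol(R)
  keep <- abs(Zo[, 1]) < 2 & abs(Zo[, 2]) < 2
  oracle <- cor(Zo[keep, 1], Zo[keep, 2])
  expect_lt(oracle, 0.5)                      # biased toward zero
  expect_lt(abs(est - oracle), 0.03)
})

test_that("SPU(2) Monte-Carlo p-values agree with chi-square oracles", {
  r1 <- aspu_single(1.96, matrix(1, 1, 1), gammas = 2, B = 2e5, seed = 44)
  p_true <- pchisq(1.96^2, df = 1, lower.tail = FALSE)
  expect_lt(abs(r1$p_gamma[["SPU2"]] - p_true), 3 * sqrt(p_true * (1 - p_true) / 2e5))

  r2 <- aspu_single(c(2, 2), diag(2), gammas = 2, B = 1e6, seed = 45)
  p2 <- exp(-4)                                # chi2_2 survival at 8
  expect_lt(abs(r2$p_gamma[["SPU2"]] - p2), 3 * sqrt(p2 * (1 - p2) / 1e6))
})

test_that("degenerate observed vectors give maximal p-values", {
  r <- aspu_single(c(0, 0, 0), diag(3), B = 1000, seed = 46)
  expect_true(all(r$p_gamma > 0.99))
  expect_gt(r$p_aspu, 0.99)
})

test_that("adaptive p respects min-p combination bounds and add-one range", {
  set.seed(47)
  for (i in 1:10) {
    z <- rnorm(3, sd = 2)
    r <- aspu_single(z, diag(3), B = 2000, seed = i)
    mp <- min(r$p_gamma)
    unit <- 1 / (r$B_used + 1)
    expect_gte(r$p_aspu, mp - unit)
    expect_lte(r$p_aspu, length(r$p_gamma) * mp + unit)
    expect_gte(min(r$p_gamma), unit)
    expect_lte(max(r$p_gamma), 1)
  }
})

test_that("even-gamma p-values are monotone in |z| on shared draws", {
  set.seed(48)
  null_z <- matrix(rnorm(4000 * 2), ncol = 2)
  scales <- c(0.5, 1, 2, 4)
  ps <- sapply(scales, function(s) {
    aspu_single(c(1, 1) * s, diag(2), gammas = c(2, 4), null_z = null_z)$p_gamma
  })
  expect_true(all(diff(ps["SPU2", ]) <= 0))
  expect_true(all(diff(ps["SPU4", ]) <= 0))
})

test_that("rank-trick aSPU equals the naive O(B^2) oracle exactly", {
  set.seed(49)
  null_z <- matrix(rnorm(2000 * 2), ncol = 2)
  for (z in list(c(1.5, -0.5), c(2.5, 2.5), c(0.1, 0.2))) {
    fast <- aspu_single(z, diag(2), gammas = 1:8, null_z = null_z)
    slow <- naive_aspu(z, null_z, 1:8)
    expect_equal(unname(fast$p_gamma), slow$p_gamma)
    expect_identical(fast$p_aspu, slow$p_aspu)
  }
})

test_that("chunked deep-stage evaluation matches the in-memory rank trick", {
  Zg <- rbind(c(2.5, -1.5), c(0.3, 0.8), c(3.5, 3.1))
  B <- 20000; seed <- 50
  ch <- pleioscan:::spu_eval_group_chunked(Zg, diag(2), 1:8, B, seed,
                                           chunk = B, k_top = B)
  set.seed(pleioscan:::derive_seed(seed, 7001, 1))
  draws <- pleioscan:::rmvn(B, diag(2))
  tab <- pleioscan:::spu_null_tables(draws, 1:8)
  for (i in seq_len(nrow(Zg))) {
    ev <- pleioscan:::spu_eval_obs(Zg[i, ], 1:8, tab)
    expect_equal(unname(ch$p_gamma[i, ]), unname(ev$p_gamma))
    expect_identical(ch$p_aspu[i], ev$p_aspu)
  }
})

test_that("staged scan escalates strong signals to the Monte-Carlo floor", {
  Z <- rbind(strong = rep(8, 4), weak = rep(0.5, 4))
  out <- aspu_scan(Z, diag(4), schedule = c(1e3, 1e4), seed = 51)
  expect_equal(out$B_used[out$snp_id == "strong"], 1e4)
  expect_equal(out$p_aspu[out$snp_id == "strong"], 1 / (1e4 + 1))
  expect_equal(out$B_used[out$snp_id == "weak"], 1e3)

  out2 <- aspu_scan(Z, diag(4), schedule = c(1e3, 1e4), seed = 51)
  expect_identical(out, out2)
  expect_error(aspu_scan(Z, diag(4), schedule = c(1e4, 1e3)), "increasing")
})

test_that("missing traits use the matching correlation submatrix", {
  R <- matrix(0.3, 4, 4); diag(R) <- 1
  z <- c(2, NA, 1, NA)
  r <- aspu_single(z, R, B = 2000, seed = 52)
  expect_equal(r$traits_used, 2)
  expect_true(r$p_aspu > 0 && r$p_aspu <= 1)
})

test_that("adaptive choice tracks the signal sparsity pattern", {
  set.seed(53)
  null_z <- matrix(rnorm(2000 * 4), ncol = 4)
  sparse <- replicate(40, {
    z <- c(rnorm(1, 4, 0.3), rnorm(3, 0, 1))
    p <- aspu_single(z, diag(4), gammas = c(1, 8), null_z = null_z)$p_gamma
    p["SPU8"] - p["SPU1"]
  })
  dense <- replicate(40, {
    z <- rnorm(4, 1.5, 0.3)
    p <- aspu_single(z, diag(4), gammas = c(1, 8), null_z = null_z)$p_gamma
    p["SPU1"] - p["SPU8"]
  })
  expect_lt(mean(sparse), 0)     # large gamma wins on sparse signal
  expect_lt(mean(dense), 0)      # gamma = 1 competitive on shared-sign dense signal
})
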