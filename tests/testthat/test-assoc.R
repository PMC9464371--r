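test_that("effective sample size follows the imputed-GWAS convention", {
  expect_equal(effective_n(1000, 0.25, 0.8), 300)
  expect_equal(effective_n(1000, 0.3, 0), 0)
  expect_equal(effective_n(60, 0.5, 1), 30)
  expect_equal(effective_n(100, 0.5, 1, formula = function(n, e, i) n), 100)
})

test_that("QC filter applies strict thresholds per rule with an audit", {
  rec <- data.frame(
    snp_id = paste0("s", 1:5),
    eaf = c(0.3, 0.3, 0.3, 0.04, 0.05),      # s4 fails MAF, s5 boundary retained
    info = c(1, 0.39, 1, 1, 1),               # s2 fails info
    n_eff = c(100, 100, 29, 100, 100)         # s3 fails n_eff
  )
  out <- qc_filter(rec)
  expect_equal(out$retained$snp_id, c("s1", "s5"))
  expect_equal(unname(out$audit[c("low_info", "low_neff", "low_maf")]),
               c(1, 1, 1))
  # boundary semantics: exactly 30 / exactly 0.4 / exactly MAF 0.05 retained
  rec2 <- data.frame(snp_id = "b", eaf = 0.05, info = 0.4, n_eff = 30)
  expect_equal(nrow(qc_filter(rec2)$retained), 1)
})

test_that("GWAS sandwich equals the sandwich-package cluster estimator", {
  set.seed(8)
  n <- 400
  cl <- rep(1:100, each = 4)
  u <- rnorm(100)[cl]
  d <- rbinom(n, 2, 0.3)
  pcs <- matrix(rnorm(n * 2), n, 2)
  y <- 0.2 * d + 0.3 * pcs[, 1] + u + rnorm(n)
  D <- cbind(snpA = d)

  ss <- run_gwas(y, D, pcs = pcs, cluster_id = cl)
  fit <- lm(y ~ d + pcs)
  V <- sandwich::vcovCL(fit, cluster = cl, type = "HC0", cadjust = FALSE)
  expect_equal(ss$beta, unname(coef(fit)["d"]), tolerance = 1e-10)
  expect_equal(ss$se, sqrt(unname(V["d", "d"])), tolerance = 1e-10)

  # singleton clusters reduce to plain HC0
  ss2 <- run_gwas(y, D, pcs = pcs, cluster_id = seq_len(n))
  V2 <- sandwich::vcovHC(fit, type = "HC0")
  expect_equal(ss2$se, sqrt(unname(V2["d", "d"])), tolerance = 1e-10)
})

test_that("GWAS recovers a planted effect and flags monomorphic SNPs", {
  set.seed(9)
  n <- 20000
  d <- rbinom(n, 2, 0.3)
  y <- 0.1 * d + rnorm(n)
  D <- cbind(causal = d, mono = rep(1, n))
  ss <- run_gwas(y, D, cluster_id = seq_len(n))
  expect_lt(abs(ss$beta[1] - 0.1), 3 * ss$se[1])
  expect_true(ss$monomorphic[2])
  expect_equal(ss$beta[2], 0)
  expect_true(is.na(ss$se[2]))
})

test_that("null GWAS p-values are calibrated", {
  coh <- tiny_cohort(n = 600, m = 400, seed = 12, beta = 0)
  tr <- prepare_traits(coh)
  ss <- run_gwas(tr$BMI, coh$dosage, cluster_id = coh$covariates$cluster_id,
                 covariates = coh$covariates)
  frac <- mean(ss$p < 0.05)
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("inverse-variance meta-analysis satisfies its algebraic identities", {
  one <- ivw_meta(0.4, 0.1)
  expect_equal(one$beta_meta, 0.4)
  expect_equal(one$se_meta, 0.1)

  eq <- ivw_meta(c(1, 1), c(1, 1))
  expect_equal(eq$beta_meta, 1)
  expect_equal(eq$se_meta, 1 / sqrt(2), tolerance = 1e-12)

  hand <- ivw_meta(c(1, 3), c(1, 1))
  expect_equal(hand$beta_meta, 2)
  expect_equal(hand$se_meta, 1 / sqrt(2), tolerance = 1e-12)

  k <- 7
  idk <- ivw_meta(rep(0.3, k), rep(0.12, k))
  expect_equal(idk$se_meta, 0.12 / sqrt(k), tolerance = 1e-14)

  perm <- ivw_meta(c(3, 1), c(1, 1))
  expect_equal(perm$beta_meta, hand$beta_meta)
  expect_equal(perm$se_meta, hand$se_meta)
  expect_equal(hand$direction, "++")
  expect_error(ivw_meta(numeric(0), numeric(0)), "empty")
  expect_error(ivw_meta(1, 0), "> 0")
})

test_that("lambda-GC is calibrated on uniform p-values and tracks inflation", {
  set.seed(10)
  p <- runif(100000)
  expect_gt(genomic_lambda(p), 0.98)
  expect_lt(genomic_lambda(p), 1.02)

  expect_equal(genomic_lambda(rep(0.5, 200)), 1, tolerance = 1e-10)

  chi <- qchisq(runif(100000), df = 1) * 1.1
  p_infl <- pchisq(chi, df = 1, lower.tail = FALSE)
  expect_lt(abs(genomic_lambda(p_infl) - 1.1), 0.02)
})

test_that("meta-analysis across simulated studies pools evidence", {
  c1 <- tiny_cohort(n = 700, seed = 31, beta = 0.3)
  c2 <- tiny_cohort(n = 700, seed = 32, beta = 0.3)
  stack <- rbind(
    run_gwas(prepare_traits(c1)$CRP, c1$dosage,
             cluster_id = c1$covariates$cluster_id,
             covariates = c1$covariates, study = "s1"),
    run_gwas(prepare_traits(c2)$CRP, c2$dosage,
             cluster_id = c2$covariates$cluster_id,
             covariates = c2$covariates, study = "s2")
  )
  meta <- meta_analyze(stack)
  m1 <- meta[meta$snp_id == "snp0001", ]
  s1 <- stack[stack$snp_id == "snp0001", ]
  expect_equal(m1$k_studies, 2)
  expect_lt(m1$se_meta, min(s1$se))
  expect_lt(m1$p_meta, min(s1$p))
})
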