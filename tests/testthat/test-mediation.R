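test_that("mediation direction follows prior trait knowledge", {
  d1 <- choose_direction("inflammation", "BMI")
  expect_equal(d1, list(mediator = "CRP", outcome = "BMI"))
  d2 <- choose_direction("adiposity", "WHR")
  expect_equal(d2, list(mediator = "WHR", outcome = "CRP"))
  expect_error(choose_direction(NA), "explicit")
  expect_error(choose_direction("lipids"), "explicit")
})

test_that("model fitting recovers path coefficients with robust vcov", {
  dat <- mediation_data(20000, a = 0.5, b = 0.4, c = 0.2, seed = 71)
  fits <- fit_models(dat$g, dat$m, dat$y)
  a_hat <- fits$mediator_model$coefficients[["g"]]
  a_se <- sqrt(fits$mediator_model$vcov["g", "g"])
  expect_lt(abs(a_hat - 0.5), 3 * a_se)
  b_hat <- fits$outcome_model$coefficients[["m"]]
  expect_lt(abs(b_hat - 0.4), 3 * sqrt(fits$outcome_model$vcov["m", "m"]))

  # null outcome: both coefficients near zero
  set.seed(72)
  y0 <- rnorm(20000)
  f0 <- fit_models(dat$g, dat$m, y0)
  expect_lt(abs(f0$outcome_model$coefficients[["g"]]),
            3 * sqrt(f0$outcome_model$vcov["g", "g"]))

  # complete cases only
  m_na <- dat$m; m_na[1:100] <- NA
  fna <- fit_models(dat$g, m_na, dat$y)
  expect_equal(fna$n_complete, 19900)
})

test_that("quasi-Bayesian decomposition is additive draw-wise and reproducible", {
  dat <- mediation_data(20000, a = 0.5, b = 0.4, c = 0.2, seed = 73)
  fits <- fit_models(dat$g, dat$m, dat$y)
  res <- mediate_effects(fits, n_sims = 1000, seed = 74)

  expect_equal(max(abs(res$draws[, "total"] -
                         (res$draws[, "acme"] + res$draws[, "ade"]))), 0)
  expect_lt(abs(res$total$est - (res$acme$est + res$ade$est)), 0.05)

  # truth recovery: ACME -> 0.2, ADE -> 0.2, total -> 0.4
  expect_gt(res$acme$ci[1], 0.2 - 0.05); expect_lt(res$acme$ci[2], 0.2 + 0.05)
  expect_gt(res$ade$ci[1], 0.2 - 0.05); expect_lt(res$ade$ci[2], 0.2 + 0.05)
  expect_true(res$total$ci[1] < 0.4 && 0.4 < res$total$ci[2])

  res2 <- mediate_effects(fits, n_sims = 1000, seed = 74)
  expect_identical(res, res2)
  expect_false(identical(res$acme$est,
                         mediate_effects(fits, n_sims = 1000, seed = 75)$acme$est))
})

test_that("null mediated path: ACME intervals cover zero at near-nominal rate", {
  covered <- vapply(1:30, function(i) {
    dat <- mediation_data(2000, a = 0.5, b = 0, c = 0.3, seed = 760 + i)
    res <- mediate_effects(fit_models(dat$g, dat$m, dat$y), seed = 770 + i)
    res$acme$ci[1] < 0 && 0 < res$acme$ci[2]
  }, TRUE)
  # 95% CIs: allow the binomial spread around 28.5/30
  expect_gte(sum(covered), 25)
})

test_that("published direct and mediated effects add to the reported total", {
  path <- system.file("extdata", "published_mediation_effects.tsv",
                      package = "pleioscan")
  tab <- published_total_effect(path)
  expect_equal(tab$total[tab$snp == "rs439401"], 0.69)
})

test_that("sensitivity curve anchors at the point estimate and locates its zero", {
  dat <- mediation_data(8000, a = 0.5, b = 0.4, c = 0.2, seed = 78)
  fits <- fit_models(dat$g, dat$m, dat$y)
  res <- mediate_effects(fits, seed = 79)
  grid <- seq(-0.9, 0.9, by = 0.05)
  sc <- sensitivity(fits, res, grid)

  expect_equal(length(sc$acme_at_rho), length(grid))
  expect_equal(sc$acme_at_rho[grid == 0], res$acme$est, tolerance = 1e-10)
  # positive ACME: zero crossing is positive and equals the residual correlation
  expect_gt(sc$rho_zero_crossing, 0)
  expect_equal(sc$rho_zero_crossing, sc$rho_tilde)
  # the analytic curve vanishes at rho_tilde
  sc2 <- sensitivity(fits, res, c(sc$rho_tilde - 1e-9, sc$rho_tilde + 1e-9))
  expect_lt(max(abs(sc2$acme_at_rho)), 1e-6)

  expect_error(sensitivity(fits, res, c(0, 1)), "inside")
})

test_that("role swap on purely mediated data moves significance to the direct path", {
  dat <- mediation_data(6000, a = 0.4, b = 0.5, c = 0, seed = 80)
  fwd <- mediate_effects(fit_models(dat$g, dat$m, dat$y), seed = 81)
  expect_lt(fwd$acme$p, 0.05)                 # indirect path carries the effect
  expect_gt(fwd$ade$p, 0.05)                  # no direct effect

  swp <- mediate_effects(fit_models(dat$g, dat$y, dat$m), seed = 82)
  expect_lt(swp$ade$p, 0.05)                  # direct path now non-null
})
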