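test_that("single-exponential fit is exact on noiseless data", {
  t <- seq(0, 60, by = 1)
  tr <- data.frame(time = t, F = 1 * (1 - exp(-0.5 * t)))
  fit <- fit_single_exp(tr)
  expect_equal(fit$k, 0.5, tolerance = 1e-8)
  expect_equal(fit$A, 1, tolerance = 1e-8)
  expect_false(fit$misfit_flag)
})

test_that("single-exponential fit flags biphasic data", {
  t <- seq(0, 120, by = 1)
  tr <- data.frame(time = t, F = 0.5 * (1 - exp(-0.7 * t)) +
                     0.5 * (1 - exp(-0.02 * t)))
  fit <- fit_single_exp(tr)
  expect_true(fit$misfit_flag)
})

test_that("double-exponential fit recovers parameters and orders rates", {
  t <- seq(0, 150, by = 0.5)
  tr <- data.frame(time = t, F = 0.5 * (1 - exp(-0.7 * t)) +
                     0.5 * (1 - exp(-0.03 * t)))
  fit <- fit_double_exp(tr)
  expect_equal(fit$k_fast, 0.7, tolerance = 1e-6)
  expect_equal(fit$k_slow, 0.03, tolerance = 1e-6)
  expect_equal(fit$A_fast, 0.5, tolerance = 1e-6)
  expect_gt(fit$k_fast, fit$k_slow)
})

test_that("nearly equal rates are reported as degenerate", {
  t <- seq(0, 60, by = 1)
  tr <- data.frame(time = t, F = 1 - exp(-0.1 * t))
  expect_warning(fit <- fit_double_exp(tr), "degenerate|single")
  expect_true(fit$degenerate)
})

test_that("invasion model without chase stays flat at zero", {
  mod <- chase_model("invasion", conc0 = list(CaM = 0))
  tr <- simulate_release(mod, seq(0, 60, by = 1))
  expect_true(all(abs(tr$F) < 1e-12))
})

test_that("simulated traces conserve total substrate", {
  for (v in c("spontaneous", "invasion")) {
    mod <- chase_model(v, conc0 = list(CaM = 10))
    tr <- simulate_release(mod, seq(0, 120, by = 0.5))
    tot <- tr$SgtTA + tr$TA + tr$SgtTACaM + tr$CaMTA
    expect_lt(max(abs(tot - 0.05)) / 0.05, 1e-9)
    expect_true(all(diff(tr$time) > 0))
  }
})

test_that("noiseless round trip through trace generation recovers the rate", {
  t <- seq(0, 30, by = 0.25)
  tr <- data.frame(time = t, F = 1 - exp(-0.5 * t))
  fit <- fit_single_exp(tr)
  expect_equal(fit$k, 0.5, tolerance = 1e-8)
  # and through the ODE generator: k_obs approaches k1 as the chase
  # saturates (partial trapping leaves a small reverse-flux excess)
  k_at <- vapply(c(10, 30, 100), function(cam) {
    mod <- chase_model("spontaneous", conc0 = list(CaM = cam))
    fit_single_exp(simulate_chase_trace(mod, seq(0, 300, by = 2)))$k
  }, 1)
  expect_lt(abs(k_at[2] - 0.015) / 0.015, 0.15)
  expect_true(all(diff(abs(k_at - 0.015)) < 0))
  expect_lt(abs(k_at[3] - 0.015) / 0.015, 0.05)
})

test_that("trap mechanism: k_obs independent of chase concentration", {
  # saturating-trap regime (the 14-28 uM chase range): constant k_obs
  cams <- c(14, 21, 28)
  ks <- vapply(cams, function(cam) {
    mod <- chase_model("spontaneous", conc0 = list(CaM = cam))
    fit_single_exp(simulate_release(mod, seq(0, 300, by = 1)))$k
  }, 1)
  expect_lt(max(ks) / min(ks), 1.15)
  line <- kobs_vs_chase(cams, ks)
  expect_lt(abs(line$slope) * max(cams), 0.2 * line$intercept)
})

test_that("invasion mechanism: k_obs grows linearly with chase", {
  cams <- c(2.5, 5, 10, 20, 30)
  ks <- vapply(cams, function(cam) {
    mod <- chase_model("invasion", conc0 = list(CaM = cam))
    fit_single_exp(simulate_release(mod, seq(0, 10, by = 0.1)))$k
  }, 1)
  expect_true(all(diff(ks) > 0))
  line <- kobs_vs_chase(cams, ks)
  expect_gt(line$slope, 0)
  # near-linear: correlation of k_obs with [CaM] is high
  expect_gt(summary(line$fit)$r.squared, 0.99)
})

test_that("k_obs line needs at least three concentrations", {
  expect_error(kobs_vs_chase(c(1, 2), c(0.1, 0.2)), "at least 3")
  line <- kobs_vs_chase(c(1, 2, 3), c(0.2, 0.2, 0.2))
  expect_equal(line$slope, 0, tolerance = 1e-12)
  expect_equal(line$intercept, 0.2, tolerance = 1e-12)
})

test_that("solubilization fit recovers the hyperbola", {
  concs <- c(0.1, 0.25, 0.5, 1, 2, 4, 8)
  s <- 100 * concs / (1 + concs)
  fit <- fit_solubilization(concs, s)
  expect_equal(fit$S_max, 100, tolerance = 1e-6)
  expect_equal(fit$K_soluble, 1, tolerance = 1e-6)
  # half-saturation definition
  expect_equal(100 * fit$K_soluble / (fit$K_soluble + fit$K_soluble) / 100,
               0.5)
  # noisy recovery within 30%
  set.seed(50)
  s_noisy <- s * (1 + rnorm(length(s), 0, 0.1))
  fit2 <- fit_solubilization(concs, s_noisy)
  expect_lt(abs(fit2$K_soluble - 1), 0.3)
})

test_that("chase model rejects unknown species and negative rates", {
  expect_error(chase_model("invasion", conc0 = list(XX = 1)), "unknown")
  expect_error(chase_model("spontaneous", k1 = -1), ">= 0")
})
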