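# Langmuir association/dissociation fitting, photobleaching correction,
# rate-constant regression, Hill isotherm, compaction changepoint.

test_that("fold normalization anchors the baseline at 1 and is scale-free", {
  t <- seq(0, 9.9, by = 0.1)
  tr <- trajectory(t, rep(250, 100), "intensity")
  expect_equal(normalize_fold(tr, 20)$value, rep(1, 100))

  v <- 100 + 50 * (1 - exp(-0.5 * t))
  f1 <- normalize_fold(trajectory(t, v, "intensity"), 5)
  f2 <- normalize_fold(trajectory(t, 2 * v, "intensity"), 5)
  expect_equal(f1$value, f2$value)

  expect_error(normalize_fold(trajectory(t, rep(0, 100), "intensity"), 10),
               "baseline")
})

test_that("photobleaching correction is the exact inverse of decay", {
  t <- seq(0, 600, by = 0.5)
  decayed <- trajectory(t, 1234 * 2^(-t / 300), "intensity")
  corrected <- correct_photobleaching(decayed, 300)
  expect_equal(corrected$value, rep(1234, length(t)))
  # t = t_half doubles; infinite half-life is the identity
  expect_equal(correct_photobleaching(trajectory(c(0, 300), c(1, 1),
                                                 "intensity"), 300)$value,
               c(1, 2))
  id <- correct_photobleaching(decayed, Inf)
  expect_equal(id$value, decayed$value)
})

test_that("association fit recovers exact Langmuir parameters", {
  t <- seq(0, 40, by = 0.1)
  # k_obs = k_on * 100 nM + k_off = 2.1e6 * 1e-7 + 0.16 = 0.37 /s
  F <- langmuir_curve(t, c0 = 1, c1 = 2, k_obs = 0.37)
  fit <- fit_association(trajectory(t, F, "intensity"))
  expect_true(fit$converged)
  expect_equal(fit$c0, 1, tolerance = 1e-6)
  expect_equal(fit$c1, 2, tolerance = 1e-6)
  expect_equal(fit$k_obs, 0.37, tolerance = 1e-6)
  expect_equal(fit$f_max, 3, tolerance = 1e-6)
})

test_that("association fit is identifiable across the k_obs range", {
  t <- seq(0, 60, by = 0.1)
  for (k in c(0.01, 0.05, 0.2, 0.8, 2)) {
    F <- langmuir_curve(t, 1, 1.5, k)
    fit <- fit_association(trajectory(t, F, "intensity"))
    expect_equal(fit$k_obs, k, tolerance = 1e-5)
  }
})

test_that("dissociation fit recovers exact exponential decay", {
  t <- seq(0, 40, by = 0.1)
  I <- 1 + 2 * exp(-0.16 * t)
  fit <- fit_dissociation(trajectory(t, I, "intensity"))
  expect_true(fit$converged)
  expect_equal(fit$A, 1, tolerance = 1e-6)
  expect_equal(fit$B, 2, tolerance = 1e-6)
  expect_equal(fit$k_off, 0.16, tolerance = 1e-6)

  # zero amplitude leaves k_off unidentifiable and is flagged
  flat <- fit_dissociation(trajectory(t, rep(1, length(t)), "intensity"))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$k_off))
})

test_that("rate-constant regression reproduces an exact k_obs line", {
  conc <- c(25, 50, 100, 150, 200)
  kobs <- data.frame(concentration_nM = rep(conc, each = 3),
                     k_obs = rep(2.1e6 * conc * 1e-9 + 0.16, each = 3))
  koff <- data.frame(concentration_nM = rep(c(25, 50, 100), each = 3),
                     k_off = 0.16)
  rc <- estimate_rate_constants(kobs, koff)
  expect_equal(rc$k_on, 2.1e6, tolerance = 1e-9)
  expect_equal(rc$k_off_mean, 0.16, tolerance = 1e-12)
  expect_equal(rc$koff_slope, 0, tolerance = 1e-15)
  # K_d is exactly k_off / k_on by construction
  expect_identical(rc$K_d_M, rc$k_off_mean / rc$k_on)
  expect_equal(rc$K_d_nM, 0.16 / 2.1e6 * 1e9, tolerance = 1e-9)

  expect_error(
    estimate_rate_constants(kobs[kobs$concentration_nM <= 50, ], koff),
    "at least 3")
})

test_that("Hill fit recovers exact isotherms and obeys the midpoint identity", {
  conc <- 10^seq(0.5, 3.5, length.out = 10)
  # n = 1 exact Langmuir isotherm
  th1 <- 2 * conc / (60.5 + conc)
  f1 <- fit_hill(data.frame(concentration_nM = conc, theta = th1))
  expect_equal(f1$kd_nM, 60.5, tolerance = 1e-5)
  expect_equal(f1$n, 1, tolerance = 1e-5)
  # midpoint: theta(K_d) = theta_max / 2 regardless of n
  th2 <- 2 * conc^0.8 / (60.5^0.8 + conc^0.8)
  f2 <- fit_hill(data.frame(concentration_nM = conc, theta = th2))
  expect_equal(f2$theta_max * 0.5,
               f2$theta_max * f2$kd_nM^f2$n / (f2$kd_nM^f2$n + f2$kd_nM^f2$n))
  expect_equal(f2$kd_nM, 60.5, tolerance = 1e-4)
  expect_equal(f2$n, 0.8, tolerance = 1e-4)

  expect_error(fit_hill(data.frame(concentration_nM = c(10, 20, 30),
                                   theta = 1:3)), "4 concentrations")
})

test_that("Hill fit with n fixed at 1 equals the Langmuir-isotherm fit", {
  set.seed(3)
  conc <- 10^seq(0.5, 3.5, length.out = 10)
  theta <- 2 * conc / (60.5 + conc) + rnorm(10, 0, 0.05)
  dat <- data.frame(concentration_nM = conc, theta = theta)
  hf <- fit_hill(dat, fix_n = 1)
  # independent two-parameter Langmuir fit
  lf <- minpack.lm::nlsLM(theta ~ tmax * conc / (kd + conc),
                          data = dat, start = list(tmax = 2, kd = 50))
  expect_lt(abs(hf$sse - sum(resid(lf)^2)), 1e-10)
  expect_equal(hf$kd_nM, coef(lf)[["kd"]], tolerance = 1e-6)
})

test_that("changepoint estimator recovers exact lag and rate", {
  t <- seq(0, 12, by = 0.1)
  L <- ifelse(t < 3.3, 6, pmax(0.5, 6 - 0.51 * (t - 3.3)))
  fit <- estimate_lag_and_rate(trajectory(t, L, "length"), t0 = 0)
  expect_equal(fit$verdict, "compaction")
  expect_lt(abs(fit$t_lag - 3.3), 0.1 + 1e-9)   # within one frame
  expect_equal(fit$rate, 0.51, tolerance = 1e-3)
  expect_equal(fit$L0, 6, tolerance = 1e-6)

  # constant length: no compaction (the bridging-deficient mutant phenotype)
  flat <- estimate_lag_and_rate(trajectory(t, rep(6, length(t)), "length"),
                                t0 = 0)
  expect_equal(flat$verdict, "no_compaction")

  # pure linear decline from t0: degenerate changepoint, zero lag
  lin <- estimate_lag_and_rate(trajectory(t, 6 - 0.3 * t, "length"), t0 = 0)
  expect_equal(lin$t_lag, 0, tolerance = 1e-9)
  expect_equal(lin$rate, 0.3, tolerance = 1e-6)
})
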