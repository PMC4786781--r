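# Sequential two-site binding model: occupancy algebra, predicted curves,
# joint fitting.

hbsu_params <- function() two_state_params(13, 390, 2, 4, 0.4, 0.95)

test_that("occupancy probabilities follow the sequential-binding weights", {
  p <- hbsu_params()
  # empty lattice and saturation limits
  expect_equal(unlist(occupancy_probs(0, p)), c(p0 = 1, p1 = 0, p2 = 0))
  expect_equal(unlist(occupancy_probs(1e9, p)), c(p0 = 0, p1 = 0, p2 = 1),
               tolerance = 1e-4)
  # c = K1: weights (1, 1, c^2/(K1 K2)) = (1, 1, 169/5070)
  probs <- occupancy_probs(13, p)
  w2 <- 169 / 5070
  z <- 2 + w2
  expect_equal(unlist(probs), c(p0 = 1 / z, p1 = 1 / z, p2 = w2 / z),
               tolerance = 1e-12)
  expect_equal(round(unlist(probs), 4),
               c(p0 = 0.4918, p1 = 0.4918, p2 = 0.0164))
  expect_error(occupancy_probs(-5, p), "nonnegative")
})

test_that("probabilities normalize to one across random parameter draws", {
  set.seed(8)
  for (i in 1:25) {
    p <- two_state_params(K1 = 10^runif(1, -1, 4), K2 = 10^runif(1, -1, 4),
                          I1 = runif(1, 0, 5), I2 = runif(1, 0, 5),
                          L1 = runif(1, 0, 2), L2 = runif(1, 0, 2))
    pr <- occupancy_probs(10^runif(5, -2, 5), p)
    expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("predicted curves are the population-weighted fold changes", {
  p <- hbsu_params()
  pred <- predict_twostate_curves(13, p)
  # hand evaluation: p = (0.49180, 0.49180, 0.01639)
  z <- 2 + 169 / 5070
  fi <- (1 + 2 + (169 / 5070) * 4) / z
  fl <- (1 + 0.4 + (169 / 5070) * 0.95) / z
  expect_equal(pred$fold_intensity, fi, tolerance = 1e-12)
  expect_equal(pred$fold_length, fl, tolerance = 1e-12)
  expect_equal(round(c(pred$fold_intensity, pred$fold_length), 4),
               c(1.5410, 0.7041))

  # inert ligand: identical fold 1 everywhere
  inert <- two_state_params(13, 390, 1, 1, 1, 1)
  curves <- predict_twostate_curves(10^seq(-1, 4, length.out = 20), inert)
  expect_equal(curves$fold_intensity, rep(1, 20))
  expect_equal(curves$fold_length, rep(1, 20))
})

test_that("large K2 reduces the model to the one-site isotherm", {
  # doubly-bound weight c^2/(K1 K2) stays below 1e-8 of the singly-bound
  # weight for c <= 10 nM at K2 = 1e9 nM
  p <- two_state_params(13, 1e9, 2, 4, 0.4, 0.95)
  cgrid <- 10^seq(-1, 1, length.out = 20)
  pred <- predict_twostate_curves(cgrid, p)
  one_site <- 1 + (2 - 1) * cgrid / (cgrid + 13)
  expect_equal(pred$fold_intensity, one_site, tolerance = 1e-8)
  # and across the full isotherm the limit holds to the weight ratio itself
  cg2 <- 10^seq(-1, 4, length.out = 30)
  pred2 <- predict_twostate_curves(cg2, p)
  one_site2 <- 1 + (2 - 1) * cg2 / (cg2 + 13)
  expect_lt(max(abs(pred2$fold_intensity - one_site2)), 3 * 1e4 / 1e9)
})

test_that("joint fit recovers noiseless parameters to 1e-4 relative", {
  p <- hbsu_params()
  grid <- 10^seq(0, log10(5000), length.out = 12)
  dat <- predict_twostate_curves(grid, p)
  fit <- fit_twostate(dat, n_starts = 20, seed = 5)
  expect_true(fit$converged)
  truth <- unlist(unclass(p))
  got <- unlist(unclass(fit$params))
  expect_equal(got, truth, tolerance = 1e-4)
})

test_that("joint fit is invariant to concentration-grid order", {
  p <- hbsu_params()
  grid <- 10^seq(0, log10(5000), length.out = 12)
  dat <- simulate_hbsu_steady_state(p, grid, noise_frac = 0.03, seed = 9)
  perm <- c(7, 1, 12, 3, 9, 5, 11, 2, 8, 4, 10, 6)
  f1 <- fit_twostate(dat, n_starts = 8, seed = 4)
  f2 <- fit_twostate(dat[perm, ], n_starts = 8, seed = 4)
  expect_equal(unlist(unclass(f1$params)), unlist(unclass(f2$params)),
               tolerance = 1e-6)
})

test_that("constant length channel pins the length folds near one", {
  p <- two_state_params(13, 390, 2, 4, 1, 1)
  grid <- 10^seq(0, log10(5000), length.out = 12)
  dat <- predict_twostate_curves(grid, p)
  fit <- fit_twostate(dat, n_starts = 20, seed = 6)
  expect_equal(fit$params$L1, 1, tolerance = 0.02)
  expect_equal(fit$params$L2, 1, tolerance = 0.02)

  expect_error(fit_twostate(predict_twostate_curves(c(1, 10, 100, 1000), p)),
               "6 concentrations")
})
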