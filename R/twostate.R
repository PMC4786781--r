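#' Occupancy probabilities of the sequential two-site binding model
#'
#' Each DNA segment binds zero, one or two protein dimers sequentially with
#' stepwise dissociation constants `K1` and `K2` (nM). At concentration `c`
#' the equilibrium statistical weights are `w0 = 1`, `w1 = c / K1`,
#' `w2 = c^2 / (K1 * K2)` and `p_k = w_k / sum(w)`, so `p0 + p1 + p2 = 1`.
#'
#' @param c_nM protein concentration (nM), >= 0; vectorized.
#' @param params a [two_state_params()].
#' @return data.frame with columns `p0`, `p1`, `p2` (one row per
#'   concentration).
#' @export
#' @examples
#' occupancy_probs(13, two_state_params(13, 390, 2, 4, 0.4, 0.95))
occupancy_probs <- function(c_nM, params) {
  stopifnot(inherits(params, "two_state_params"))
  if (any(c_nM < 0)) stop("concentration must be nonnegative", call. = FALSE)
  w1 <- c_nM / params$K1
  w2 <- c_nM^2 / (params$K1 * params$K2)
  z <- 1 + w1 + w2
  data.frame(p0 = 1 / z, p1 = w1 / z, p2 = w2 / z)
}

#' Predicted steady-state fold-intensity and fold-length curves
#'
#' Population-weighted averages over the three segment states:
#' `F_I(c) = p0 + p1 * I1 + p2 * I2` and `F_L(c) = p0 + p1 * L1 + p2 * L2`,
#' with the unbound state at fold 1 in both channels.
#'
#' @param c_grid concentrations (nM), nonnegative.
#' @param params a [two_state_params()].
#' @return data.frame with columns `concentration_nM`, `fold_intensity`,
#'   `fold_length`.
#' @export
predict_twostate_curves <- function(c_grid, params) {
  p <- occupancy_probs(c_grid, params)
  data.frame(
    concentration_nM = c_grid,
    fold_intensity = p$p0 + p$p1 * params$I1 + p$p2 * params$I2,
    fold_length = p$p0 + p$p1 * params$L1 + p$p2 * params$L2
  )
}

#' Joint fit of the sequential two-site model to paired steady-state curves
#'
#' Minimizes the equally weighted sum of squared residuals of the
#' fold-intensity and fold-length channels over the six parameters
#' `(K1, K2, I1, I2, L1, L2)`, using box-constrained quasi-Newton
#' optimization (`optim(method = "L-BFGS-B")`) on `log K` with multi-start:
#' `K` seeds are log-uniform within their bounds and `I`/`L` seeds start at
#' the unbound fold of 1. The best-SSE start wins.
#'
#' @param data data.frame with columns `concentration_nM`, `fold_intensity`,
#'   `fold_length` (as from [simulate_hbsu_steady_state()]); at least 6
#'   concentrations.
#' @param n_starts number of random starts (default 20).
#' @param weight_length relative weight of the length-channel SSE (default 1:
#'   both channels are fold quantities of order one).
#' @param lower,upper named bounds for `K1, K2, I1, I2, L1, L2`.
#' @param seed RNG seed for the start draws.
#' @return Object of class `twostate_fit`: `params` (a
#'   [two_state_params()]), `sse`, `converged`, `starts` (per-start SSE
#'   diagnostics).
#' @export
fit_twostate <- function(data, n_starts = 20, weight_length = 1,
                         lower = c(K1 = 0.1, K2 = 0.1, I1 = 0.5, I2 = 0.5,
                                   L1 = 0.05, L2 = 0.05),
                         upper = c(K1 = 1e5, K2 = 1e5, I1 = 20, I2 = 20,
                                   L1 = 2, L2 = 2),
                         seed = NULL) {
  stopifnot(is.data.frame(data),
            all(c("concentration_nM", "fold_intensity", "fold_length") %in%
                  names(data)))
  if (length(unique(data$concentration_nM)) < 6) {
    stop("need at least 6 concentrations for the 6-parameter model",
         call. = FALSE)
  }
  c_grid <- data$concentration_nM
  obj <- function(theta) {
    p <- two_state_params(K1 = exp(theta[1]), K2 = exp(theta[2]),
                          I1 = theta[3], I2 = theta[4],
                          L1 = theta[5], L2 = theta[6])
    pred <- predict_twostate_curves(c_grid, p)
    sum((pred$fold_intensity - data$fold_intensity)^2) +
      weight_length * sum((pred$fold_length - data$fold_length)^2)
  }
  lo <- c(log(lower[c("K1", "K2")]), lower[c("I1", "I2", "L1", "L2")])
  hi <- c(log(upper[c("K1", "K2")]), upper[c("I1", "I2", "L1", "L2")])
  starts <- with_seed_(seed, {
    lapply(seq_len(n_starts), function(i) {
      c(stats::runif(2, lo[1], hi[1]),   # log-uniform K seeds
        1 + stats::rnorm(4, 0, 0.1))     # unit I/L seeds
    })
  })
  results <- lapply(starts, function(s) {
    s <- pmin(pmax(s, lo), hi)
    tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) {
    return(structure(list(params = NULL, sse = NA_real_, converged = FALSE,
                          starts = NULL),
                     class = "twostate_fit"))
  }
  sses <- vapply(results[ok], function(r) r$value, numeric(1))
  best <- results[ok][[which.min(sses)]]
  th <- best$par
  structure(list(
    params = two_state_params(K1 = exp(th[1]), K2 = exp(th[2]),
                              I1 = th[3], I2 = th[4], L1 = th[5], L2 = th[6]),
    sse = best$value, converged = TRUE,
    starts = data.frame(start = which(ok), sse = sses)
  ), class = "twostate_fit")
}

#' @export
print.twostate_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<twostate_fit> all starts failed\n")
    return(invisible(x))
  }
  cat(sprintf("<twostate_fit> SSE = %.4g\n  ", x$sse))
  print(x$params)
  invisible(x)
}
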