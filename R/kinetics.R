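#' Normalize an intensity trajectory to fold increase
#'
#' Divides the trajectory by its mean over the pre-binding baseline window,
#' so the baseline has mean 1 and the steady-state value reads directly as a
#' fold increase.
#'
#' @param traj intensity [trajectory()].
#' @param baseline_window number of initial frames to average (the pre-protein
#'   baseline).
#' @return A fold-intensity [trajectory()].
#' @export
normalize_fold <- function(traj, baseline_window = 20L) {
  stopifnot(nrow(traj) >= baseline_window, baseline_window >= 1)
  b <- mean(traj$value[seq_len(baseline_window)])
  if (!is.finite(b) || b <= 0) {
    stop("baseline mean is not positive; trajectory excluded", call. = FALSE)
  }
  out <- traj
  out$value <- traj$value / b
  out
}

#' Correct an intensity trajectory for photobleaching
#'
#' Multiplicative half-life correction `I(t) = I0(t) * 2^(t / t_half)`: the
#' exact inverse of exponential photobleaching with half-life `t_half`, so a
#' signal decaying purely by bleaching becomes constant. `time_s` is taken as
#' time since illumination began.
#'
#' @param traj intensity [trajectory()].
#' @param t_half photobleaching half-life (s), > 0; `Inf` is the identity.
#' @return The corrected [trajectory()].
#' @export
correct_photobleaching <- function(traj, t_half) {
  stopifnot(is.numeric(t_half), length(t_half) == 1, t_half > 0)
  out <- traj
  out$value <- traj$value * 2^(traj$time_s / t_half)
  out
}

frame_rate_of <- function(traj) {
  fi <- attr(traj, "frame_interval")
  if (is.null(fi) || !is.finite(fi)) fi <- stats::median(diff(traj$time_s))
  1 / fi
}

#' Fit the Langmuir association model to a fold-intensity trajectory
#'
#' Nonlinear least squares of `F(t) = c0 + c1 * (1 - exp(-k_obs * t))`, with
#' `t` measured from the start of the trajectory (the detected onset of
#' association). `c0` is the minimum binding signal `F_min` at `t = 0` and
#' `c0 + c1` the steady-state maximum `F_max`; `k_obs = k_on * [protein] +
#' k_off` under the 1:1 Langmuir model.
#'
#' @param F_traj fold-intensity [trajectory()] starting at the association
#'   onset; at least 20 frames.
#' @return Object of class `assoc_fit`: `c0`, `c1`, `k_obs`, standard errors,
#'   `sse`, `vcov`, `converged`, `f_max`, and `at_bound` (TRUE when `k_obs`
#'   ended on its upper bound, i.e. the rise is unresolvably fast and the
#'   rate is not identifiable at this frame rate).
#' @export
fit_association <- function(F_traj) {
  stopifnot(nrow(F_traj) >= 20)
  t <- F_traj$time_s - F_traj$time_s[1]
  y <- F_traj$value
  k_max <- 10 * frame_rate_of(F_traj)
  amp <- max(y) - y[1]
  t_half_rise <- t[which(y - y[1] >= amp / 2)[1]]
  if (!is.finite(t_half_rise) || t_half_rise <= 0) t_half_rise <- max(t) / 10
  start <- list(c0 = y[1], c1 = max(amp, 1e-3), k_obs = 1 / t_half_rise)
  start$k_obs <- min(max(start$k_obs, 1e-4), k_max)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c0 + c1 * (1 - exp(-k_obs * t)),
      start = start,
      lower = c(c0 = -Inf, c1 = 0, k_obs = 1e-6),
      upper = c(c0 = Inf, c1 = Inf, k_obs = k_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(c0 = NA_real_, c1 = NA_real_, k_obs = NA_real_,
                          se = c(c0 = NA, c1 = NA, k_obs = NA),
                          sse = NA_real_, vcov = NULL, converged = FALSE,
                          f_max = NA_real_, at_bound = FALSE),
                     class = "assoc_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, 3), names(cf))
  })
  structure(list(c0 = unname(cf["c0"]), c1 = unname(cf["c1"]),
                 k_obs = unname(cf["k_obs"]), se = se,
                 sse = sum(stats::resid(fit)^2),
                 vcov = tryCatch(stats::vcov(fit), error = function(e) NULL),
                 converged = TRUE,
                 f_max = unname(cf["c0"] + cf["c1"]),
                 at_bound = unname(cf["k_obs"]) >= 0.999 * k_max),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf(
    "<assoc_fit> c0 = %.4g, c1 = %.4g, k_obs = %.4g /s (F_max = %.4g)%s\n",
    x$c0, x$c1, x$k_obs, x$f_max,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Fit the exponential dissociation model
#'
#' Least squares of `I(t) = A + B * exp(-k_off * t)` on a normalized,
#' bleach-corrected dissociation trajectory starting at the wash onset
#' (`I(0)` close to 1). `A + B` is the maximum intensity at `t = 0` and `A`
#' the long-time plateau.
#'
#' @param I_traj normalized intensity [trajectory()] of the wash phase.
#' @return Object of class `dissoc_fit`: `A`, `B`, `k_off`, standard errors,
#'   `sse`, `converged`, `degenerate` (TRUE when the decay amplitude is
#'   indistinguishable from zero, leaving `k_off` unidentifiable), and
#'   `at_bound` (TRUE when `k_off` ended on its upper bound: a decay too
#'   fast to resolve at this frame rate).
#' @export
fit_dissociation <- function(I_traj) {
  stopifnot(nrow(I_traj) >= 10)
  t <- I_traj$time_s - I_traj$time_s[1]
  y <- I_traj$value
  n_tail <- max(3L, length(y) %/% 10L)
  A0 <- mean(utils::tail(y, n_tail))
  B0 <- y[1] - A0
  tol <- max(1e-8, 1e-3 * stats::sd(y), na.rm = TRUE)
  if (!is.finite(B0) || abs(B0) <= tol || stats::sd(y) < 1e-12) {
    return(structure(list(A = mean(y), B = 0, k_off = NA_real_,
                          se = c(A = NA, B = NA, k_off = NA),
                          sse = sum((y - mean(y))^2),
                          converged = FALSE, degenerate = TRUE,
                          at_bound = FALSE),
                     class = "dissoc_fit"))
  }
  i_half <- which(abs(y - A0) <= abs(B0) / 2)[1]
  k0 <- if (is.finite(i_half) && t[i_half] > 0) 1 / t[i_half] else 2 / max(t)
  k_max <- 10 * frame_rate_of(I_traj)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A + B * exp(-k_off * t),
      start = list(A = A0, B = B0, k_off = min(k0, k_max)),
      lower = c(A = -Inf, B = 0, k_off = 1e-6),
      upper = c(A = Inf, B = Inf, k_off = k_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(A = NA_real_, B = NA_real_, k_off = NA_real_,
                          se = c(A = NA, B = NA, k_off = NA), sse = NA_real_,
                          converged = FALSE, degenerate = FALSE,
                          at_bound = FALSE),
                     class = "dissoc_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, 3), names(cf))
  })
  structure(list(A = unname(cf["A"]), B = unname(cf["B"]),
                 k_off = unname(cf["k_off"]), se = se,
                 sse = sum(stats::resid(fit)^2), converged = TRUE,
                 degenerate = FALSE,
                 at_bound = unname(cf["k_off"]) >= 0.999 * k_max),
            class = "dissoc_fit")
}

#' @export
print.dissoc_fit <- function(x, ...) {
  cat(sprintf("<dissoc_fit> A = %.4g, B = %.4g, k_off = %.4g /s%s\n",
              x$A, x$B, x$k_off,
              if (isTRUE(x$degenerate)) " [DEGENERATE: no decay]" else ""))
  invisible(x)
}

#' Rate constants from the concentration dependence of k_obs and k_off
#'
#' Within the linear range, `k_obs = k_on * [protein] + k_off`. The
#' association rate constant is the slope of an error-weighted linear
#' regression of per-concentration mean `k_obs` on concentration; the
#' dissociation rate constant is the intercept of the `k_off`-versus-
#' concentration line (its slope is reported with a significance test, as it
#' is expected to be indistinguishable from zero). `K_d = k_off / k_on`.
#'
#' @param kobs data.frame with columns `concentration_nM` and `k_obs`, one
#'   row per DNA (replicates per concentration give the weights); or
#'   pre-summarized with one row per concentration and an extra `sem` column
#'   (e.g. an ensemble-average fit with the per-DNA spread as its error).
#' @param koff optional data.frame with columns `concentration_nM` and
#'   `k_off` (same two accepted forms); when `NULL`, the intercept of the
#'   `k_obs` line is used as the dissociation rate constant.
#' @param linear_range_max concentrations above this (nM) are excluded from
#'   the regression (k_obs saturates at high concentration).
#' @return Object of class `rate_constants`: `k_on` (/M/s) and `k_on_se`;
#'   `k_obs_intercept` (/s); `k_off_mean` (/s) and `k_off_se`;
#'   `koff_slope`, `koff_slope_p`; `K_d_M`, `K_d_nM`, `K_d_se_nM`
#'   (propagated); per-concentration summary tables.
#' @export
estimate_rate_constants <- function(kobs, koff = NULL,
                                    linear_range_max = 200) {
  stopifnot(is.data.frame(kobs),
            all(c("concentration_nM", "k_obs") %in% names(kobs)))
  kobs <- kobs[is.finite(kobs$k_obs) &
                 kobs$concentration_nM <= linear_range_max, ]
  agg <- as_conc_summary(kobs, "k_obs")
  if (nrow(agg) < 3) {
    stop("need at least 3 concentrations within the linear range",
         call. = FALSE)
  }
  fit_obs <- weighted_line(agg)
  # slope in per-nM per-s -> per-M per-s
  k_on <- fit_obs$slope * 1e9
  k_on_se <- fit_obs$slope_se * 1e9

  if (!is.null(koff)) {
    stopifnot(all(c("concentration_nM", "k_off") %in% names(koff)))
    koff <- koff[is.finite(koff$k_off), ]
    agg_off <- as_conc_summary(koff, "k_off")
    if (nrow(agg_off) < 2) {
      stop("need at least 2 concentrations of k_off data", call. = FALSE)
    }
    fit_off <- weighted_line(agg_off)
    k_off_mean <- fit_off$intercept
    k_off_se <- fit_off$intercept_se
    koff_slope <- fit_off$slope
    koff_slope_p <- fit_off$slope_p
  } else {
    agg_off <- NULL
    k_off_mean <- fit_obs$intercept
    k_off_se <- fit_obs$intercept_se
    koff_slope <- NA_real_
    koff_slope_p <- NA_real_
  }
  K_d_M <- k_off_mean / k_on
  K_d_nM <- K_d_M * 1e9
  K_d_se_nM <- abs(K_d_nM) *
    sqrt((k_off_se / k_off_mean)^2 + (k_on_se / k_on)^2)
  structure(list(k_on = k_on, k_on_se = k_on_se,
                 k_obs_intercept = fit_obs$intercept,
                 k_obs_intercept_se = fit_obs$intercept_se,
                 k_off_mean = k_off_mean, k_off_se = k_off_se,
                 koff_slope = koff_slope, koff_slope_p = koff_slope_p,
                 K_d_M = K_d_M, K_d_nM = K_d_nM, K_d_se_nM = K_d_se_nM,
                 kobs_summary = agg, koff_summary = agg_off),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("<rate_constants>\n  k_on  = %.3g +/- %.2g /M/s\n", x$k_on,
              x$k_on_se))
  cat(sprintf("  k_off = %.3g +/- %.2g /s (slope p = %.2g)\n", x$k_off_mean,
              x$k_off_se, x$koff_slope_p))
  cat(sprintf("  K_d   = %.3g +/- %.2g nM\n", x$K_d_nM, x$K_d_se_nM))
  invisible(x)
}

# Accept either per-DNA rows (aggregate) or pre-summarized rows with `sem`.
as_conc_summary <- function(df, col) {
  if ("sem" %in% names(df)) {
    stopifnot(!anyDuplicated(df$concentration_nM))
    return(data.frame(concentration_nM = df$concentration_nM,
                      mean = df[[col]], sem = df$sem,
                      n = if ("n" %in% names(df)) df$n else NA_integer_))
  }
  summarize_by_conc(df, col)
}

# Mean / sem / n per concentration.
summarize_by_conc <- function(df, col) {
  sp <- split(df[[col]], df$concentration_nM)
  data.frame(
    concentration_nM = as.numeric(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v) {
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    }, numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL
  )
}

# Error-weighted straight line through per-concentration means; unweighted
# when any sem is zero (e.g. single replicate). With measured per-point
# errors the parameter errors are propagated from those errors directly
# (known-variance weighted least squares) and inflated by sqrt(chi2/dof)
# when the scatter exceeds the stated errors; residual-based errors with
# n - 2 as low as 1-3 degrees of freedom are too unstable to report.
weighted_line <- function(agg) {
  x <- agg$concentration_nM
  y <- agg$mean
  n <- length(x)
  if (any(agg$sem == 0)) {
    fit <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit)$coefficients)
    return(list(intercept = sm[1, 1], intercept_se = sm[1, 2],
                slope = sm[2, 1], slope_se = sm[2, 2],
                slope_p = sm[2, 4]))
  }
  w <- 1 / agg$sem^2
  Sw <- sum(w); Swx <- sum(w * x); Swx2 <- sum(w * x^2)
  Swy <- sum(w * y); Swxy <- sum(w * x * y)
  D <- Sw * Swx2 - Swx^2
  slope <- (Sw * Swxy - Swx * Swy) / D
  intercept <- (Swx2 * Swy - Swx * Swxy) / D
  chi2_red <- sum(w * (y - intercept - slope * x)^2) / (n - 2)
  scale <- max(1, sqrt(chi2_red))
  slope_se <- sqrt(Sw / D) * scale
  intercept_se <- sqrt(Swx2 / D) * scale
  slope_p <- if (n > 2) {
    2 * stats::pt(abs(slope / slope_se), df = n - 2, lower.tail = FALSE)
  } else NA_real_  # two points leave no dof for a slope test
  list(intercept = intercept, intercept_se = intercept_se,
       slope = slope, slope_se = slope_se, slope_p = slope_p)
}

#' Fit the Hill equation to steady-state binding signals
#'
#' Least squares of `theta = theta_max * c^n / (K_d^n + c^n)`. `K_d` is
#' seeded from five log-spaced starting values spanning the concentration
#' range and the best-SSE solution is kept; `n` is bounded to `[0.1, 10]`
#' and `K_d` to `(0, 100 * max(c)]`.
#'
#' @param data data.frame with columns `concentration_nM` and `theta`
#'   (the binding signal; replicates allowed).
#' @param subtract_baseline subtract the unbound baseline (1 fold) from
#'   `theta` before fitting.
#' @param fix_n fix the Hill coefficient at this value instead of fitting it
#'   (`fix_n = 1` gives the two-parameter Langmuir isotherm fit).
#' @return Object of class `hill_fit`: `theta_max`, `kd_nM`, `n`, standard
#'   errors, `sse`, `converged`.
#' @export
fit_hill <- function(data, subtract_baseline = FALSE, fix_n = NULL) {
  stopifnot(is.data.frame(data),
            all(c("concentration_nM", "theta") %in% names(data)))
  cvals <- unique(data$concentration_nM)
  if (length(cvals) < 4 || max(cvals) / max(min(cvals), 1e-12) < 10) {
    stop("need >= 4 concentrations spanning at least a 10-fold range",
         call. = FALSE)
  }
  c_ <- data$concentration_nM
  y <- data$theta - if (subtract_baseline) 1 else 0
  kd_hi <- 100 * max(c_)
  kd_seeds <- exp(seq(log(max(min(c_[c_ > 0]), 1e-3)), log(max(c_)),
                      length.out = 5))
  best <- NULL
  for (kd0 in kd_seeds) {
    fit <- tryCatch(
      if (is.null(fix_n)) {
        minpack.lm::nlsLM(
          y ~ theta_max * c_^n / (kd^n + c_^n),
          start = list(theta_max = max(y), kd = kd0, n = 1),
          lower = c(theta_max = 1e-6, kd = 1e-6, n = 0.1),
          upper = c(theta_max = Inf, kd = kd_hi, n = 10),
          control = minpack.lm::nls.lm.control(maxiter = 300)
        )
      } else {
        n_fixed <- fix_n
        minpack.lm::nlsLM(
          y ~ theta_max * c_^n_fixed / (kd^n_fixed + c_^n_fixed),
          start = list(theta_max = max(y), kd = kd0),
          lower = c(theta_max = 1e-6, kd = 1e-6),
          upper = c(theta_max = Inf, kd = kd_hi),
          control = minpack.lm::nls.lm.control(maxiter = 300)
        )
      },
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    return(structure(list(theta_max = NA_real_, kd_nM = NA_real_,
                          n = NA_real_, se = c(theta_max = NA, kd = NA, n = NA),
                          sse = NA_real_, converged = FALSE),
                     class = "hill_fit"))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e) {
    stats::setNames(rep(NA_real_, length(cf)), names(cf))
  })
  structure(list(theta_max = unname(cf["theta_max"]),
                 kd_nM = unname(cf["kd"]),
                 n = if (is.null(fix_n)) unname(cf["n"]) else fix_n,
                 se = se, sse = best$sse, converged = TRUE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> theta_max = %.3g, K_d = %.3g nM, n = %.3g%s\n",
              x$theta_max, x$kd_nM, x$n,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Estimate compaction lag time and rate by exhaustive changepoint search
#'
#' Fits the continuous two-segment model `L(t) = L0` for `t <= t0 + t_lag`
#' and `L0 - r * (t - t0 - t_lag)` afterwards, scanning every frame as the
#' candidate changepoint and solving the conditionally linear `(L0, r)` by
#' least squares; the changepoint minimizing the SSE wins. Frames after the
#' trajectory has fully compacted (fallen below `min_frac` of its initial
#' level) are excluded, since the plateau at the tether point is outside the
#' two-segment model.
#'
#' @param lengths length [trajectory()] covering the onset of association
#'   through compaction (>= 30 frames after `t0`).
#' @param t0 association onset time (s); lag is reported relative to it.
#' @param min_frac fraction of the initial length below which frames are
#'   treated as fully compacted and dropped from the fit.
#' @param min_drop minimum total length decrease (um) required to call
#'   compaction; 0 accepts any positive fitted rate.
#' @return Object of class `compaction_fit`: `t_lag` (s), `rate` (um/s),
#'   `L0` (um), `changepoint_time_s`, `sse`, `verdict` (`"compaction"` or
#'   `"no_compaction"`), `n_used`.
#' @export
estimate_lag_and_rate <- function(lengths, t0 = 0, min_frac = 0.2,
                                  min_drop = 0) {
  keep <- lengths$time_s >= t0
  t <- lengths$time_s[keep] - t0
  y <- lengths$value[keep]
  if (length(y) < 30) stop("need >= 30 frames after t0", call. = FALSE)
  l_init <- stats::median(y[seq_len(min(5L, length(y)))])
  smoothed <- running_mean(y, 3L)
  floor_hit <- which(smoothed < min_frac * l_init)[1]
  if (is.finite(floor_hit) && floor_hit > 10) {
    t <- t[seq_len(floor_hit - 1L)]
    y <- y[seq_len(floor_hit - 1L)]
  }
  n <- length(y)
  best <- list(sse = Inf, k = NA_integer_, L0 = NA_real_, r = NA_real_)
  for (k in seq_len(n - 2L)) {
    tk <- t[k]
    ramp <- pmax(t - tk, 0)
    X <- cbind(1, -ramp)
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    sse <- sum((y - X %*% cf)^2)
    if (sse < best$sse) best <- list(sse = sse, k = k, L0 = cf[1], r = cf[2])
  }
  if (!is.finite(best$sse)) stop("changepoint search failed", call. = FALSE)
  total_drop <- best$r * (t[n] - t[best$k])
  # rate must exceed numerical zero: an exactly flat trajectory solves the
  # least squares with r at rounding error
  verdict <- if (best$r > 1e-12 && total_drop >= min_drop) "compaction"
             else "no_compaction"
  structure(list(
    t_lag = if (verdict == "compaction") t[best$k] else NA_real_,
    rate = if (verdict == "compaction") unname(best$r) else NA_real_,
    L0 = unname(best$L0), changepoint_time_s = t[best$k] + t0,
    sse = best$sse, verdict = verdict, n_used = n
  ), class = "compaction_fit")
}

#' @export
print.compaction_fit <- function(x, ...) {
  if (x$verdict == "compaction") {
    cat(sprintf("<compaction_fit> t_lag = %.3g s, rate = %.3g um/s, L0 = %.3g um\n",
                x$t_lag, x$rate, x$L0))
  } else {
    cat("<compaction_fit> no compaction detected (DNA remained extended)\n")
  }
  invisible(x)
}
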