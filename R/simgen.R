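#' Simulate per-site protein occupancy as independent two-state Markov chains
#'
#' Each dye-adjacent binding site on the DNA is an independent reversible
#' two-state chain. With free protein in vast excess, the per-frame switching
#' probabilities are `p_on = 1 - exp(-k_on * c * dt)` and
#' `p_off = 1 - exp(-k_off * dt)`, so the mean occupancy relaxes towards the
#' Langmuir equilibrium `c / (c + K_d)` with observed rate
#' `k_obs = k_on * c + k_off`.
#'
#' @param preset a [sim_preset()]; uses `k_on`, `k_off`, `concentration_nM`,
#'   `frame_rate`, `dna_length_bp`, `n_dyes_per_kb`.
#' @param duration simulated time (s), > 0.
#' @param init initial condition: `"unbound"` (protein just introduced),
#'   `"equilibrium"` (sites start from the stationary law of the simulated
#'   concentration), or a numeric probability in `[0, 1]` with which each
#'   site starts bound (e.g. the pre-wash equilibrium occupancy when
#'   simulating a dissociation phase at `concentration_nM = 0`).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `occupancy_matrix`: list with `values`
#'   (binary `T x n_sites` matrix), `dt` (s), `time_s`.
#' @export
#' @examples
#' occ <- simulate_occupancy(sim_preset_named("r82a"), duration = 5, seed = 1)
#' mean(occ$values)
simulate_occupancy <- function(preset, duration,
                               init = c("unbound", "equilibrium"),
                               seed = preset$seed) {
  stopifnot(inherits(preset, "sim_preset"))
  p_init <- NULL
  if (is.numeric(init)) {
    stopifnot(length(init) == 1, init >= 0, init <= 1)
    p_init <- init
    init <- "numeric"
  } else {
    init <- match.arg(init)
  }
  dt <- 1 / preset$frame_rate
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be a positive number of seconds", call. = FALSE)
  }
  n_frames <- max(1L, as.integer(round(duration * preset$frame_rate)))
  n_sites <- n_sites_of(preset)
  c_molar <- preset$concentration_nM * 1e-9
  p_on <- 1 - exp(-preset$k_on * c_molar * dt)
  p_off <- 1 - exp(-preset$k_off * dt)

  values <- with_seed_(seed, {
    m <- matrix(0L, n_frames, n_sites)
    state <- if (init == "numeric") {
      as.integer(stats::runif(n_sites) < p_init)
    } else if (init == "equilibrium" && (p_on + p_off) > 0) {
      as.integer(stats::runif(n_sites) < p_on / (p_on + p_off))
    } else {
      integer(n_sites)
    }
    u <- matrix(stats::runif(n_frames * n_sites), n_frames, n_sites)
    for (t in seq_len(n_frames)) {
      state <- ifelse(state == 1L,
                      as.integer(u[t, ] >= p_off),
                      as.integer(u[t, ] < p_on))
      m[t, ] <- state
    }
    m
  })
  structure(list(values = values, dt = dt,
                 time_s = (seq_len(n_frames) - 1L) * dt),
            class = "occupancy_matrix")
}

# Per-dye brightness matrix [T x n_dyes]: baseline brightness, binary PIFE
# enhancement while the adjacent site is occupied, irreversible per-dye
# photobleaching with half-life t_half (no additive noise here).
dye_brightness_matrix <- function(occ, preset, seed = NULL) {
  n_frames <- nrow(occ$values)
  n_dyes <- ncol(occ$values)
  p_bleach <- 1 - 2^(-occ$dt / preset$t_half_bleach)
  with_seed_(seed, {
    surv <- matrix(1, n_frames, n_dyes)
    if (p_bleach > 0) {
      alive <- rep(TRUE, n_dyes)
      for (t in seq_len(n_frames)) {
        alive <- alive & (stats::runif(n_dyes) >= p_bleach)
        surv[t, ] <- as.numeric(alive)
      }
    }
    preset$dye_brightness *
      (1 + (preset$pife_factor - 1) * occ$values) * surv
  })
}

#' Simulate an integrated-intensity trajectory from a site-occupancy matrix
#'
#' Sums per-dye brightness over the DNA. Each dye is `pife_factor`-fold
#' brighter in frames where its site is occupied, photobleaches irreversibly
#' with per-frame probability `1 - 2^(-dt / t_half)`, and Gaussian noise of
#' s.d. `noise_sd` is added to the summed signal.
#'
#' @param occ an `occupancy_matrix` from [simulate_occupancy()].
#' @param preset the [sim_preset()] that produced `occ`.
#' @param seed RNG seed for bleaching and noise.
#' @return A list with `trajectory` (intensity [trajectory()]) and `truth`
#'   (list: per-frame mean occupancy, per-dye bleach survival matrix,
#'   unbound-baseline intensity).
#' @export
simulate_intensity_trajectory <- function(occ, preset, seed = preset$seed) {
  stopifnot(inherits(occ, "occupancy_matrix"), inherits(preset, "sim_preset"))
  if (nrow(occ$values) < 1) stop("empty occupancy matrix", call. = FALSE)
  bright <- dye_brightness_matrix(occ, preset, seed = derive_seed(seed, 1))
  signal <- rowSums(bright)
  noisy <- with_seed_(derive_seed(seed, 2),
                      signal + stats::rnorm(length(signal), 0, preset$noise_sd))
  baseline <- preset$dye_brightness * ncol(occ$values)
  list(
    trajectory = trajectory(occ$time_s, noisy, kind = "intensity",
                            concentration_nM = preset$concentration_nM,
                            frame_interval = occ$dt),
    truth = list(
      occupancy_fraction = rowMeans(occ$values),
      survival = bright > 0,
      baseline_intensity = baseline,
      per_dye_brightness = bright
    )
  )
}

#' Simulate a DNA-compaction length trajectory
#'
#' Draws a lag time and a compaction rate from zero-truncated Gaussians, then
#' evaluates the piecewise-linear model: constant at `l0_um` until the lag
#' elapses, linear shortening at the drawn rate afterwards, clamped at
#' `l_floor_um`. Additive Gaussian length noise emulates measurement error.
#'
#' @param preset a [sim_preset()]; uses `lag_mean`, `lag_sd`, `rate_mean`,
#'   `rate_sd`, `l0_um`, `l_floor_um`, `length_noise_sd`, `frame_rate`.
#' @param duration simulated time (s); must exceed `lag_mean`.
#' @param seed RNG seed.
#' @return List with `trajectory` (length [trajectory()]) and `truth`
#'   (list: `t_lag` s, `rate` um/s, `l0` um).
#' @export
#' @examples
#' sim <- simulate_compaction_trajectory(sim_preset_named("spo0j_wt"),
#'                                       duration = 12, seed = 7)
#' sim$truth$t_lag
simulate_compaction_trajectory <- function(preset, duration,
                                           seed = preset$seed) {
  stopifnot(inherits(preset, "sim_preset"))
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be a positive number of seconds", call. = FALSE)
  }
  if (duration <= preset$lag_mean) {
    stop("`duration` must exceed the mean lag time", call. = FALSE)
  }
  dt <- 1 / preset$frame_rate
  time_s <- seq(0, duration, by = dt)
  draws <- with_seed_(derive_seed(seed, 1), {
    list(t_lag = rnorm_trunc0(1, preset$lag_mean, preset$lag_sd),
         rate = rnorm_trunc0(1, preset$rate_mean, preset$rate_sd))
  })
  len <- ifelse(time_s < draws$t_lag, preset$l0_um,
                pmax(preset$l_floor_um,
                     preset$l0_um - draws$rate * (time_s - draws$t_lag)))
  noisy <- with_seed_(derive_seed(seed, 2),
                      len + stats::rnorm(length(len), 0, preset$length_noise_sd))
  list(
    trajectory = trajectory(time_s, noisy, kind = "length",
                            concentration_nM = preset$concentration_nM,
                            frame_interval = dt),
    truth = list(t_lag = draws$t_lag, rate = draws$rate, l0 = preset$l0_um)
  )
}

#' Simulate paired steady-state fold-intensity and fold-length curves
#'
#' Evaluates the sequential two-site model ([predict_twostate_curves()]) on a
#' concentration grid and perturbs both channels with multiplicative Gaussian
#' noise of fractional s.d. `noise_frac`.
#'
#' @param params a [two_state_params()].
#' @param conc_grid protein concentrations (nM), nonnegative.
#' @param noise_frac fractional Gaussian noise s.d. (e.g. 0.03 for 3\%).
#' @param seed RNG seed.
#' @return A `data.frame` with columns `concentration_nM`, `fold_intensity`,
#'   `fold_length`, plus attribute `truth` holding `params` and the noiseless
#'   curves.
#' @export
simulate_hbsu_steady_state <- function(params, conc_grid, noise_frac = 0.03,
                                       seed = 1L) {
  stopifnot(inherits(params, "two_state_params"), length(conc_grid) >= 1)
  if (any(conc_grid < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  clean <- predict_twostate_curves(conc_grid, params)
  out <- with_seed_(seed, {
    k <- length(conc_grid)
    data.frame(
      concentration_nM = conc_grid,
      fold_intensity = clean$fold_intensity *
        (1 + stats::rnorm(k, 0, noise_frac)),
      fold_length = clean$fold_length * (1 + stats::rnorm(k, 0, noise_frac))
    )
  })
  attr(out, "truth") <- list(params = params, clean = clean)
  out
}

#' Simulate steady-state binding signals from a Hill isotherm
#'
#' Draws `n_rep` noisy replicates of the baseline-subtracted binding signal
#' `theta = theta_max * c^n / (K_d^n + c^n)` at each concentration, emulating
#' per-DNA steady-state fold-increase measurements.
#'
#' @param conc_grid concentrations (nM).
#' @param theta_max saturating signal (baseline-subtracted fold increase).
#' @param kd apparent dissociation constant (nM).
#' @param n Hill coefficient.
#' @param n_rep replicates (DNAs) per concentration.
#' @param noise_frac fractional Gaussian noise s.d. relative to `theta_max`.
#' @param seed RNG seed.
#' @return `data.frame(concentration_nM, theta, replicate)` with attribute
#'   `truth`.
#' @export
simulate_hill_steady_state <- function(conc_grid, theta_max = 2, kd = 60.5,
                                       n = 0.8, n_rep = 25, noise_frac = 0.05,
                                       seed = 1L) {
  stopifnot(all(conc_grid >= 0), theta_max > 0, kd > 0, n > 0, n_rep >= 1)
  clean <- theta_max * conc_grid^n / (kd^n + conc_grid^n)
  out <- with_seed_(seed, {
    data.frame(
      concentration_nM = rep(conc_grid, each = n_rep),
      theta = rep(clean, each = n_rep) +
        stats::rnorm(length(conc_grid) * n_rep, 0, noise_frac * theta_max),
      replicate = rep(seq_len(n_rep), times = length(conc_grid))
    )
  })
  attr(out, "truth") <- list(theta_max = theta_max, kd = kd, n = n)
  out
}
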