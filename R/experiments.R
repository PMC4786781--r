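#' Simulate a full association-phase intensity trajectory
#'
#' Prepends a protein-free baseline (all sites unbound) to a stochastic
#' association phase at the preset concentration, then renders the summed
#' dye intensity with PIFE, photobleaching and noise. This is the raw input
#' of the association analysis chain (onset detection, fold normalization,
#' Langmuir fit).
#'
#' @param preset a [sim_preset()].
#' @param duration association-phase duration (s).
#' @param baseline_s protein-free baseline duration (s).
#' @param seed RNG seed.
#' @return List with `trajectory` (intensity), `truth` (list incl.
#'   `onset_index`, `onset_time_s`, `k_obs` = `k_on * c + k_off`,
#'   `eq_occupancy`).
#' @export
simulate_association_trajectory <- function(preset, duration = 40,
                                            baseline_s = 5,
                                            seed = preset$seed) {
  stopifnot(inherits(preset, "sim_preset"), duration > 0, baseline_s > 0)
  n_base <- as.integer(round(baseline_s * preset$frame_rate))
  occ_assoc <- simulate_occupancy(preset, duration,
                                  seed = derive_seed(seed, 11))
  n_sites <- ncol(occ_assoc$values)
  values <- rbind(matrix(0L, n_base, n_sites), occ_assoc$values)
  dt <- occ_assoc$dt
  occ <- structure(list(values = values, dt = dt,
                        time_s = (seq_len(nrow(values)) - 1L) * dt),
                   class = "occupancy_matrix")
  sim <- simulate_intensity_trajectory(occ, preset,
                                       seed = derive_seed(seed, 12))
  c_molar <- preset$concentration_nM * 1e-9
  k_obs <- preset$k_on * c_molar + preset$k_off
  sim$truth$onset_index <- n_base + 1L
  sim$truth$onset_time_s <- n_base * dt
  sim$truth$k_obs <- k_obs
  sim$truth$eq_occupancy <- if (k_obs > 0) preset$k_on * c_molar / k_obs else 0
  sim
}

#' Simulate a wash-phase (dissociation) intensity trajectory
#'
#' Sites start bound with the pre-wash equilibrium probability
#' `c / (c + K_d)` and unbind at `k_off` with no rebinding (protein-free
#' wash buffer).
#'
#' @param preset a [sim_preset()]; `concentration_nM` is the pre-wash
#'   concentration.
#' @param duration wash duration (s).
#' @param seed RNG seed.
#' @return List with `trajectory` and `truth` (incl. `initial_occupancy`).
#' @export
simulate_dissociation_trajectory <- function(preset, duration = 40,
                                             seed = preset$seed) {
  stopifnot(inherits(preset, "sim_preset"), duration > 0)
  c_molar <- preset$concentration_nM * 1e-9
  p_eq <- if (preset$k_on * c_molar + preset$k_off > 0) {
    preset$k_on * c_molar / (preset$k_on * c_molar + preset$k_off)
  } else 0
  wash <- preset
  wash$concentration_nM <- 0
  occ <- simulate_occupancy(wash, duration, init = p_eq,
                            seed = derive_seed(seed, 21))
  sim <- simulate_intensity_trajectory(occ, wash,
                                       seed = derive_seed(seed, 22))
  attr(sim$trajectory, "concentration_nM") <- preset$concentration_nM
  sim$truth$initial_occupancy <- p_eq
  sim
}

#' Rate-constant recovery experiment (association + dissociation chain)
#'
#' Simulates per-DNA association trajectories across a concentration series
#' and wash-phase trajectories across a (lower) series, runs each through
#' the full analysis chain — photobleaching correction, association-onset
#' detection, fold normalization, Langmuir association / exponential
#' dissociation fits — and regresses the fitted rates on concentration with
#' [estimate_rate_constants()].
#'
#' @param preset base [sim_preset()] (the concentration field is overridden
#'   per point).
#' @param conc_assoc association concentrations (nM).
#' @param conc_diss pre-wash concentrations for the dissociation series (nM).
#' @param n_dna DNAs per concentration.
#' @param duration_assoc,duration_diss phase durations (s).
#' @param baseline_s protein-free baseline before association (s).
#' @param linear_range_max see [estimate_rate_constants()].
#' @param noise_frac additive Gaussian trajectory noise as a fraction of the
#'   unbound DNA intensity (default 3\%); overrides the preset's `noise_sd`
#'   for the simulated trajectories.
#' @param seed master seed.
#' @return List: `rate_constants` (a `rate_constants` object),
#'   `kobs_summary` / `koff_summary` per-concentration tables (ensemble fit,
#'   per-DNA s.e.m., n), `kobs` / `koff` per-DNA tables, `n_excluded`
#'   (non-detected or non-converged trajectories).
#' @export
experiment_rate_constants <- function(preset = sim_preset_named("r82a"),
                                      conc_assoc = c(25, 50, 100, 150, 200),
                                      conc_diss = c(25, 50, 100),
                                      n_dna = 25,
                                      duration_assoc = 40,
                                      duration_diss = 40,
                                      baseline_s = 5,
                                      linear_range_max = 200,
                                      noise_frac = 0.03,
                                      seed = 1L) {
  preset$noise_sd <- noise_frac * preset$dye_brightness * n_sites_of(preset)
  n_base <- as.integer(round(baseline_s * preset$frame_rate))
  bw <- n_base - 5L
  kobs_rows <- list(); koff_rows <- list(); n_excluded <- 0L
  kobs_sum <- list(); koff_sum <- list()
  for (ci in seq_along(conc_assoc)) {
    p <- preset; p$concentration_nM <- conc_assoc[ci]
    aligned <- list(); per_dna <- numeric(0)
    for (d in seq_len(n_dna)) {
      s <- derive_seed(seed, 1000 * ci + d)
      sim <- simulate_association_trajectory(p, duration_assoc, baseline_s,
                                             seed = s)
      tr <- correct_photobleaching(sim$trajectory, p$t_half_bleach)
      onset <- detect_association_start(tr, baseline_window = bw)
      if (!onset$detected) { n_excluded <- n_excluded + 1L; next }
      fold <- normalize_fold(tr, baseline_window = bw)
      post <- fold[fold$time_s >= onset$time_s, ]
      fit <- fit_association(post)
      if (!fit$converged || fit$at_bound) { n_excluded <- n_excluded + 1L; next }
      aligned[[length(aligned) + 1L]] <- post$value
      per_dna <- c(per_dna, fit$k_obs)
      kobs_rows[[length(kobs_rows) + 1L]] <-
        data.frame(concentration_nM = conc_assoc[ci], dna = d,
                   k_obs = fit$k_obs, f_max = fit$f_max)
    }
    # ensemble-average trajectory over DNAs aligned at their detected onsets
    n_min <- min(lengths(aligned))
    ens_val <- rowMeans(vapply(aligned, function(v) v[seq_len(n_min)],
                               numeric(n_min)))
    ens <- trajectory(seq(0, by = 1 / p$frame_rate, length.out = n_min),
                      ens_val, kind = "intensity",
                      frame_interval = 1 / p$frame_rate)
    ens_fit <- fit_association(ens)
    kobs_sum[[ci]] <- data.frame(
      concentration_nM = conc_assoc[ci], k_obs = ens_fit$k_obs,
      f_max = ens_fit$f_max,
      sem = stats::sd(per_dna) / sqrt(length(per_dna)),
      n = length(per_dna))
  }
  for (ci in seq_along(conc_diss)) {
    p <- preset; p$concentration_nM <- conc_diss[ci]
    aligned <- list(); per_dna <- numeric(0)
    for (d in seq_len(n_dna)) {
      s <- derive_seed(seed, 500000 + 1000 * ci + d)
      sim <- simulate_dissociation_trajectory(p, duration_diss, seed = s)
      tr <- correct_photobleaching(sim$trajectory, p$t_half_bleach)
      norm <- normalize_fold(tr, baseline_window = 5L)
      fit <- fit_dissociation(norm)
      if (!fit$converged || fit$degenerate || fit$at_bound) {
        n_excluded <- n_excluded + 1L; next
      }
      aligned[[length(aligned) + 1L]] <- norm$value
      per_dna <- c(per_dna, fit$k_off)
      koff_rows[[length(koff_rows) + 1L]] <-
        data.frame(concentration_nM = conc_diss[ci], dna = d,
                   k_off = fit$k_off)
    }
    n_min <- min(lengths(aligned))
    ens_val <- rowMeans(vapply(aligned, function(v) v[seq_len(n_min)],
                               numeric(n_min)))
    ens <- trajectory(seq(0, by = 1 / p$frame_rate, length.out = n_min),
                      ens_val, kind = "intensity",
                      frame_interval = 1 / p$frame_rate)
    ens_fit <- fit_dissociation(ens)
    koff_sum[[ci]] <- data.frame(
      concentration_nM = conc_diss[ci], k_off = ens_fit$k_off,
      sem = stats::sd(per_dna) / sqrt(length(per_dna)),
      n = length(per_dna))
  }
  kobs_summary <- do.call(rbind, kobs_sum)
  koff_summary <- do.call(rbind, koff_sum)
  list(rate_constants = estimate_rate_constants(kobs_summary, koff_summary,
                                                linear_range_max),
       kobs_summary = kobs_summary, koff_summary = koff_summary,
       kobs = do.call(rbind, kobs_rows), koff = do.call(rbind, koff_rows),
       n_excluded = n_excluded)
}

#' Compaction lag/rate recovery experiment
#'
#' Simulates length trajectories from a preset and recovers the per-DNA lag
#' time and compaction rate with the changepoint estimator
#' ([estimate_lag_and_rate()]).
#'
#' @param preset a [sim_preset()] (compaction parameters are used).
#' @param n_dna number of trajectories.
#' @param duration trajectory duration (s).
#' @param seed master seed.
#' @return List: `summary` (`lag_mean`, `lag_sem`, `rate_mean`, `rate_sem`,
#'   `n`), `per_dna` table with recovered and true values, `n_excluded`.
#' @export
experiment_compaction <- function(preset = sim_preset_named("spo0j_wt"),
                                  n_dna = 100, duration = 12, seed = 1L) {
  rows <- list(); n_excluded <- 0L
  for (d in seq_len(n_dna)) {
    sim <- simulate_compaction_trajectory(preset, duration,
                                          seed = derive_seed(seed, d))
    fit <- estimate_lag_and_rate(sim$trajectory, t0 = 0)
    if (fit$verdict != "compaction") { n_excluded <- n_excluded + 1L; next }
    rows[[length(rows) + 1L]] <-
      data.frame(dna = d, t_lag = fit$t_lag, rate = fit$rate,
                 true_t_lag = sim$truth$t_lag, true_rate = sim$truth$rate)
  }
  per_dna <- do.call(rbind, rows)
  list(summary = list(
    lag_mean = mean(per_dna$t_lag),
    lag_sem = stats::sd(per_dna$t_lag) / sqrt(nrow(per_dna)),
    rate_mean = mean(per_dna$rate),
    rate_sem = stats::sd(per_dna$rate) / sqrt(nrow(per_dna)),
    n = nrow(per_dna)
  ), per_dna = per_dna, n_excluded = n_excluded)
}

#' Hill-isotherm recovery experiment
#'
#' Repeatedly generates steady-state binding signals from a Hill isotherm
#' ([simulate_hill_steady_state()]) and refits them ([fit_hill()]),
#' summarizing the recovered apparent `K_d` and Hill coefficient across
#' replicate fits.
#'
#' @param conc_grid concentrations (nM); default 8 log-spaced points over
#'   10-1000 nM.
#' @param theta_max,kd,n generator truth (baseline-subtracted saturating
#'   signal, apparent K_d in nM, Hill coefficient).
#' @param n_rep replicate DNAs per concentration per fit.
#' @param noise_frac Gaussian noise s.d. as a fraction of `theta_max`.
#' @param n_fits replicate fits.
#' @param seed master seed.
#' @return List: `summary` (`kd_mean`, `kd_se`, `n_mean`, `n_se`, `n_fits`),
#'   `per_fit` table.
#' @export
experiment_hill <- function(conc_grid = 10^seq(1, 3, length.out = 8),
                            theta_max = 2, kd = 60.5, n = 0.8,
                            n_rep = 25, noise_frac = 0.05, n_fits = 50,
                            seed = 1L) {
  rows <- list()
  for (i in seq_len(n_fits)) {
    dat <- simulate_hill_steady_state(conc_grid, theta_max = theta_max,
                                      kd = kd, n = n, n_rep = n_rep,
                                      noise_frac = noise_frac,
                                      seed = derive_seed(seed, i))
    fit <- fit_hill(dat)
    if (!fit$converged) next
    rows[[length(rows) + 1L]] <-
      data.frame(fit = i, kd = fit$kd_nM, n = fit$n,
                 theta_max = fit$theta_max)
  }
  per_fit <- do.call(rbind, rows)
  m <- nrow(per_fit)
  list(summary = list(
    kd_mean = mean(per_fit$kd), kd_se = stats::sd(per_fit$kd) / sqrt(m),
    n_mean = mean(per_fit$n), n_se = stats::sd(per_fit$n) / sqrt(m),
    n_fits = m
  ), per_fit = per_fit)
}

#' Two-state model recovery experiment
#'
#' Repeatedly generates paired fold-intensity / fold-length steady-state
#' curves from the sequential two-site model and refits them jointly
#' ([fit_twostate()]), summarizing recovered `K1` and `K2` across replicate
#' fits by their medians (robust to the occasional poorly conditioned fit).
#'
#' @param params generator [two_state_params()].
#' @param conc_grid concentrations (nM); default 12 log-spaced points over
#'   1-5000 nM.
#' @param noise_frac fractional noise on both channels.
#' @param n_fits replicate fits.
#' @param n_starts multi-start count per fit.
#' @param seed master seed.
#' @return List: `summary` (`K1_median`, `K1_se`, `K2_median`, `K2_se`,
#'   `n_fits`), `per_fit` table of all six recovered parameters.
#' @export
experiment_twostate <- function(params = sim_preset_named("hbsu")$twostate,
                                conc_grid = 10^seq(0, log10(5000),
                                                   length.out = 12),
                                noise_frac = 0.03, n_fits = 50,
                                n_starts = 20, seed = 1L) {
  rows <- list()
  for (i in seq_len(n_fits)) {
    dat <- simulate_hbsu_steady_state(params, conc_grid,
                                      noise_frac = noise_frac,
                                      seed = derive_seed(seed, i))
    fit <- fit_twostate(dat, n_starts = n_starts,
                        seed = derive_seed(seed, 100000 + i))
    if (!fit$converged) next
    p <- fit$params
    rows[[length(rows) + 1L]] <-
      data.frame(fit = i, K1 = p$K1, K2 = p$K2, I1 = p$I1, I2 = p$I2,
                 L1 = p$L1, L2 = p$L2, sse = fit$sse)
  }
  per_fit <- do.call(rbind, rows)
  m <- nrow(per_fit)
  # s.e. of the median for Gaussian-ish spread: 1.2533 * sd / sqrt(n)
  list(summary = list(
    K1_median = stats::median(per_fit$K1),
    K1_se = 1.2533 * stats::sd(per_fit$K1) / sqrt(m),
    K2_median = stats::median(per_fit$K2),
    K2_se = 1.2533 * stats::sd(per_fit$K2) / sqrt(m),
    n_fits = m
  ), per_fit = per_fit)
}

#' Run a configured end-to-end experiment and write a machine-readable report
#'
#' Dispatches on `config$experiment` (`"rate_constants"`, `"compaction"`,
#' `"hill"` or `"twostate"`), runs the corresponding recovery experiment
#' under the master seed, writes per-DNA/per-fit tables as CSV and a JSON
#' report with parameters, results and provenance (config hash, seed,
#' package version) into `config$out_dir`. Outputs are byte-identical across
#' repeated runs with the same config and seed.
#'
#' @param config a named list (or path to a YAML file) with fields
#'   `experiment`, `seed`, `out_dir`, and optional `params` (overrides passed
#'   to the experiment function).
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("experiment", "seed", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  experiments <- c("rate_constants", "compaction", "hill", "twostate")
  if (!config$experiment %in% experiments) {
    stop("config$experiment must be one of: ",
         paste(experiments, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(config$seed) || config$seed < 0) {
    stop("config$seed must be a nonnegative integer", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config$params %||% list()
  params$seed <- as.integer(config$seed)
  fn <- switch(config$experiment,
               rate_constants = experiment_rate_constants,
               compaction = experiment_compaction,
               hill = experiment_hill,
               twostate = experiment_twostate)
  result <- do.call(fn, params)

  tables <- Filter(is.data.frame, result)
  for (nm in names(tables)) {
    utils::write.csv(format(tables[[nm]], digits = 15, trim = TRUE),
                     file.path(config$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  # hash identifies the scientific configuration; the output location is
  # not part of it
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_for_hash[order(names(cfg_for_hash))], cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  scalar_results <- if (config$experiment == "rate_constants") {
    rc <- result$rate_constants
    list(k_on_per_M_s = rc$k_on, k_on_se = rc$k_on_se,
         k_off_per_s = rc$k_off_mean, k_off_se = rc$k_off_se,
         K_d_nM = rc$K_d_nM, K_d_se_nM = rc$K_d_se_nM)
  } else {
    result$summary
  }
  report <- list(
    experiment = config$experiment,
    parameters = params,
    results = scalar_results,
    excluded = result$n_excluded %||% 0L,
    provenance = list(config_hash = cfg_hash, seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("pifeflow")))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
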