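# Shared fixture builders. All synthetic; nothing is read from disk.

# Small, fast preset: 5-kb DNA (5 dye sites), quiet camera.
tiny_preset <- function(...) {
  sim_preset_named("r82a", dna_length_bp = 5000, noise_sd = 2, ...)
}

# Render a one-DNA movie with a protein-free lead-in followed by binding at
# the preset concentration; returns stack, roi and per-frame truth.
render_assoc_movie <- function(preset, baseline_s = 3, duration = 15,
                               dims = c(32L, 70L), seed = 1) {
  n_base <- round(baseline_s * preset$frame_rate)
  occ_on <- simulate_occupancy(preset, duration, seed = seed)
  occ <- structure(list(
    values = rbind(matrix(0L, n_base, ncol(occ_on$values)), occ_on$values),
    dt = occ_on$dt,
    time_s = (seq_len(n_base + nrow(occ_on$values)) - 1L) * occ_on$dt
  ), class = "occupancy_matrix")
  mv <- render_movie(list(list(occ = occ, length_um = preset$l0_um,
                               tether_row = 16, tether_col = 10)),
                     preset, dims = dims, seed = seed + 1)
  list(stack = mv$stack, roi = mv$truth[[1]]$roi, truth = mv$truth[[1]],
       n_base = n_base)
}

# Exact noiseless fold-intensity association curve.
langmuir_curve <- function(t, c0, c1, k_obs) c0 + c1 * (1 - exp(-k_obs * t))
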