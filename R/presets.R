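#' Simulation preset
#'
#' Bundles every parameter of the synthetic-data generator: binding kinetics,
#' PIFE brightness enhancement, compaction lag/rate distribution, photobleaching,
#' imaging geometry and noise. Four named presets mirror the experimental
#' conditions the generator emulates (see [sim_preset_named()]).
#'
#' @param name identifier for the preset.
#' @param concentration_nM protein concentration (nM).
#' @param k_on association rate constant (per molar per second).
#' @param k_off dissociation rate constant (per second).
#' @param pife_factor fold brightness of a dye whose site is protein-bound
#'   (dimensionless, >= 1).
#' @param lag_mean,lag_sd mean and s.d. of the compaction lag time (s). Draws
#'   are truncated at zero.
#' @param rate_mean,rate_sd mean and s.d. of the compaction rate (um/s).
#'   Draws are truncated at zero.
#' @param twostate optional [two_state_params()] object for the sequential
#'   two-site binding model.
#' @param t_half_bleach photobleaching half-life (s); `Inf` disables bleaching.
#' @param frame_rate imaging frame rate (Hz).
#' @param n_dyes_per_kb mean labelling density (dyes per kilobase).
#' @param dna_length_bp DNA substrate length (bp).
#' @param l0_um extension of the flow-stretched DNA before compaction (um).
#' @param l_floor_um fully-compacted apparent length (um).
#' @param pixel_size camera pixel size in sample space (um).
#' @param psf_sigma_px point-spread-function Gaussian sigma (pixels).
#' @param dye_brightness mean integrated counts per unbound dye per frame.
#' @param noise_sd camera read noise s.d. (counts per pixel); also used as the
#'   additive intensity noise of directly simulated trajectories.
#' @param length_noise_sd additive noise on simulated length trajectories (um).
#' @param seed default master seed for generators driven by this preset.
#'
#' @return An object of class `sim_preset` (a validated list).
#' @export
#' @examples
#' p <- sim_preset_named("r82a", concentration_nM = 100)
#' p$k_on
sim_preset <- function(name = "custom",
                       concentration_nM = 100,
                       k_on = 2.1e6,
                       k_off = 0.16,
                       pife_factor = 4.5,
                       lag_mean = 3.3,
                       lag_sd = 0.7,
                       rate_mean = 0.51,
                       rate_sd = 0.14,
                       twostate = NULL,
                       t_half_bleach = 300,
                       frame_rate = 10,
                       n_dyes_per_kb = 1,
                       dna_length_bp = 20000,
                       l0_um = 6,
                       l_floor_um = 0.5,
                       pixel_size = 0.167,
                       psf_sigma_px = 1.0,
                       dye_brightness = 1000,
                       noise_sd = 10,
                       length_noise_sd = 0.05,
                       seed = 1L) {
  stopifnot(
    is.character(name), length(name) == 1L,
    concentration_nM >= 0, k_on >= 0, k_off >= 0,
    pife_factor >= 1,
    lag_mean >= 0, lag_sd >= 0, rate_mean >= 0, rate_sd >= 0,
    t_half_bleach > 0, frame_rate > 0,
    n_dyes_per_kb >= 0, dna_length_bp > 0,
    l0_um > 0, l_floor_um >= 0, l_floor_um <= l0_um,
    pixel_size > 0, psf_sigma_px > 0, dye_brightness >= 0,
    noise_sd >= 0, length_noise_sd >= 0
  )
  if (!is.null(twostate)) stopifnot(inherits(twostate, "two_state_params"))
  structure(
    list(
      name = name, concentration_nM = concentration_nM,
      k_on = k_on, k_off = k_off, pife_factor = pife_factor,
      lag_mean = lag_mean, lag_sd = lag_sd,
      rate_mean = rate_mean, rate_sd = rate_sd,
      twostate = twostate, t_half_bleach = t_half_bleach,
      frame_rate = frame_rate, n_dyes_per_kb = n_dyes_per_kb,
      dna_length_bp = dna_length_bp, l0_um = l0_um, l_floor_um = l_floor_um,
      pixel_size = pixel_size, psf_sigma_px = psf_sigma_px,
      dye_brightness = dye_brightness, noise_sd = noise_sd,
      length_noise_sd = length_noise_sd, seed = as.integer(seed)
    ),
    class = "sim_preset"
  )
}

#' Named simulation presets
#'
#' Returns one of four presets whose defaults encode the experimental
#' conditions the generator emulates:
#' \describe{
#'   \item{`spo0j_wt`}{wild-type Spo0J: Gaussian-distributed compaction lag
#'     (3.3 s mean) and rate (0.51 um/s mean) on a 20-kb DNA.}
#'   \item{`r82a`}{the bridging-deficient Spo0J R82A mutant: reversible 1:1
#'     site binding with k_on = 2.1e6 /M/s and k_off = 0.16 /s, no compaction.}
#'   \item{`hbsu`}{HBsu: sequential two-dimer-per-segment binding with
#'     K1 = 13 nM (bending, compaction) and K2 = 390 nM (filament,
#'     re-extension).}
#'   \item{`qd`}{quantum-dot motion-capture geometry on XbaI-digested lambda
#'     DNA, four labelled sites, tether-to-free-end tension gradient.}
#' }
#'
#' @param name one of `"spo0j_wt"`, `"r82a"`, `"hbsu"`, `"qd"`.
#' @param ... overrides passed on to [sim_preset()].
#' @return A `sim_preset`.
#' @export
sim_preset_named <- function(name = c("spo0j_wt", "r82a", "hbsu", "qd"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    spo0j_wt = list(
      name = "spo0j_wt", pife_factor = 5,
      lag_mean = 3.3, lag_sd = 0.7, rate_mean = 0.51, rate_sd = 0.14
    ),
    r82a = list(
      name = "r82a", k_on = 2.1e6, k_off = 0.16, pife_factor = 4.5,
      rate_mean = 0, rate_sd = 0
    ),
    hbsu = list(
      name = "hbsu",
      twostate = two_state_params(K1 = 13, K2 = 390,
                                  I1 = 2, I2 = 4, L1 = 0.4, L2 = 0.95)
    ),
    qd = list(
      name = "qd", dna_length_bp = 23994, n_dyes_per_kb = 0
    )
  )
  override <- list(...)
  base[names(override)] <- override
  do.call(sim_preset, base)
}

#' Parameters of the sequential two-site binding model
#'
#' Each DNA segment binds zero, one or two protein dimers with stepwise
#' dissociation constants `K1` and `K2` (nM). The one- and two-bound states
#' carry their own fold change in integrated intensity (`I1`, `I2`) and in
#' DNA length (`L1`, `L2`) relative to the unbound state, whose fold values
#' are identically 1.
#'
#' @param K1,K2 stepwise dissociation constants (nM), both > 0.
#' @param I1,I2 fold intensity of the one- and two-bound states (>= 0).
#' @param L1,L2 fold length of the one- and two-bound states (>= 0).
#' @return An object of class `two_state_params`.
#' @export
#' @examples
#' two_state_params(K1 = 13, K2 = 390, I1 = 2, I2 = 4, L1 = 0.4, L2 = 0.95)
two_state_params <- function(K1, K2, I1, I2, L1, L2) {
  stopifnot(K1 > 0, K2 > 0, I1 >= 0, I2 >= 0, L1 >= 0, L2 >= 0)
  structure(list(K1 = K1, K2 = K2, I1 = I1, I2 = I2, L1 = L1, L2 = L2),
            class = "two_state_params")
}

#' @export
print.sim_preset <- function(x, ...) {
  cat(sprintf("<sim_preset '%s'>\n", x$name))
  cat(sprintf("  [protein] %g nM; k_on %.3g /M/s; k_off %.3g /s; PIFE x%g\n",
              x$concentration_nM, x$k_on, x$k_off, x$pife_factor))
  cat(sprintf("  compaction lag %g +/- %g s; rate %g +/- %g um/s\n",
              x$lag_mean, x$lag_sd, x$rate_mean, x$rate_sd))
  cat(sprintf("  %g kb DNA, %g dyes/kb, %g Hz, bleach t1/2 %g s\n",
              x$dna_length_bp / 1000, x$n_dyes_per_kb, x$frame_rate,
              x$t_half_bleach))
  invisible(x)
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf(
    "<two_state_params> K1 = %g nM, K2 = %g nM; I = (%g, %g); L = (%g, %g)\n",
    x$K1, x$K2, x$I1, x$I2, x$L1, x$L2))
  invisible(x)
}

# Number of dye / binding sites implied by a preset (one site per dye).
n_sites_of <- function(preset) {
  max(1L, as.integer(round(preset$dna_length_bp * preset$n_dyes_per_kb / 1000)))
}
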