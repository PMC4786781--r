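---
title: "Models and methods behind pifeflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pifeflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pifeflow)
```

`pifeflow` analyses single-molecule experiments in which surface-tethered,
flow-stretched DNA is sparsely labelled with a PIFE-responsive dye (Cy3)
and unlabelled DNA-binding protein is flowed in. Protein binding near a dye
enhances its brightness, so the DNA's integrated intensity reads out
occupancy while its apparent length reads out conformation. Because such
raw data come with no ground truth, the package pairs every estimator with
a synthetic-data generator that emulates the measurement; all quantitative
validation in the test suite is parameter recovery against that generator.

## The synthetic-data generator

**Site occupancy.** A DNA of `dna_length_bp` basepairs carries on average
`n_dyes_per_kb` dyes per kilobase (default: 20 kb, 1/kb, hence 20 dyes).
Each dye marks one independent binding site that switches between free and
bound as a two-state Markov chain with per-frame probabilities
`p_on = 1 - exp(-k_on c dt)` and `p_off = 1 - exp(-k_off dt)`. The mean
occupancy therefore relaxes to the Langmuir equilibrium `c/(c + K_d)` with
observed rate `k_obs = k_on c + k_off` — exactly the model the kinetics
module fits. Treating one site per dye with no cooperativity mirrors the
1:1 binding assumption of the analysis; it is a deliberate simplification
(real nonspecific binding has a footprint and the dye only reports binding
within a few nanometres).

**Intensity.** Dye `j` contributes `b0 (1 + (pife_factor - 1) occ[t, j])`
counts, i.e. PIFE is binary per dye: enhanced exactly when its site is
occupied. The 0–4 nm distance dependence of PIFE is collapsed onto site
adjacency because only aggregate DNA intensity is analysed. Photobleaching
is irreversible per dye with per-frame probability `1 - 2^(-dt/t_half)`,
the half-life parameterization that makes the analysis-side correction
`I(t) = I0(t) 2^(t/t_half)` its exact inverse. Gaussian noise of s.d.
`noise_sd` is added to the summed trajectory (or per pixel when rendering
movies).

**Presets.** Four named presets encode the study conditions:
`spo0j_wt` (compacting wild-type protein: lag and rate of compaction drawn
from zero-truncated Gaussians with means 3.3 s and 0.51 um/s), `r82a`
(binding-competent, compaction-deficient mutant: k_on = 2.1e6 /M/s,
k_off = 0.16 /s, K_d = 76.2 nM), `hbsu` (sequential two-dimer binding,
K1 = 13 nM, K2 = 390 nM), and `qd` (quantum-dot motion-capture geometry).
Where the experimental literature states only the means and their standard
errors, the population widths were chosen once as plausible for ~50
molecules — lag s.d. 0.7 s, rate s.d. 0.14 um/s — and recovery targets
compare means, which do not depend on that choice. The per-dye enhancement
`pife_factor` is not directly measurable at the DNA level; the defaults
(4.5 for `r82a`, 5 for `spo0j_wt`) reproduce the observed ~3-fold DNA-level
steady-state enhancement at 100 nM given equilibrium occupancy ~0.57. The
initial extension is 6 um (a 20-kb DNA at moderate flow), pixel size
0.167 um, frame rate 10 Hz, bleach half-life 300 s.

**What the generator does not emulate.** Dye blinking and cis–trans
photophysics beyond a single bleaching exponential; flow fluctuations and
hydrodynamics (tensions are inputs, never derived from flow rate);
footprint overlap or cooperativity between sites; intercalation artifacts.
Recovery tests passing on this generator therefore validate the estimator
chain, not these aspects of real data.

**Reproducibility.** Every generator takes a seed; sub-streams per molecule
are derived with a double-round MINSTD scramble so that nearby master seeds
and molecule indices map to well-separated RNG streams (linearly spaced
seeds produce measurably correlated Mersenne–Twister draws — an effect
large enough to bias ensemble-averaged kinetics, which is why the scramble
exists). Identical `(preset, seed)` reproduce outputs bit for bit.

## Imaging chain

**ROI intensity.** Per frame, background is the median of a 2-pixel ring
around the ROI, times the ROI area; negative net intensities are preserved.
ROIs touching the frame edge fall back to the median of the lowest decile
of the frame (configurable, logged).

**Kymograph and length.** Each ROI is projected onto the flow axis after
background subtraction; summing kymograph columns reproduces the ROI
trajectory exactly (tested invariant). DNA length is the count of
above-threshold pixels times pixel size, with a single per-kymograph
threshold `b + f (q95 - b)` where `b` is the median of the lowest decile
(the background level) and `q95` the 95th percentile. The rule is invariant
to a constant intensity offset. Two numerical choices matter:

- *Profile smoothing* (`smooth_sigma`, default 1.5 px): at ~1 dye/kb the
  dye images are ~1.8 px apart, so an unsmoothed threshold fragments the
  DNA into beads and undercounts length by 5–10 px. Gaussian smoothing
  bridges sub-diffraction gaps; edge-replicating padding keeps the
  offset-invariance exact.
- *Threshold fraction* (`f`, default 0.12): calibrated on noiseless
  rendered movies so that counted length is unbiased (within ~1 px in the
  mean) for sparsely labelled DNA; the residual per-molecule spread of
  ~3 px reflects the random dye placement itself, not the estimator. For
  contiguous profiles the count is exact for any `f`, so the calibration
  only compensates the sparse-labelling geometry.

**Quantum-dot localization.** A four-parameter Gaussian
(offset, amplitude, center, width) is least-squares fitted to the 1-D
projection, initialized at the argmax; profiles without a peak exceeding
background + 3 robust s.d. are rejected, and non-convergence falls back to
the argmax with a flag. At amplitude-to-noise 10 the localization standard
deviation is below 0.1 px and bias below 0.05 px (Monte-Carlo tested).

**Association onset.** Time zero of all kinetic fits is the first frame
where a 5-frame trailing mean exceeds the baseline mean by 4 baseline
standard deviations for 5 consecutive frames. The 4-sigma/5-frame choice
keeps the false-trigger rate under 1% on pure-noise baselines of 100
frames while detecting single-binding-event jumps; on simulated data the
median onset error is within 3 frames. Because the relaxation of a Markov
chain conditioned on its state at the detected onset still proceeds at
`k_obs`, onset-detection jitter shifts the fitted `c0`/`c1` but not the
rate — the property that makes detected-onset alignment safe.

## Kinetics

Association trajectories are bleach-corrected, normalized to their
pre-protein baseline (`F = I / mean(baseline)`), aligned at the detected
onset, and fitted to `F(t) = c0 + c1 (1 - e^(-k_obs t))` with bounds
`k_obs` in (0, 10 x frame rate]; a fit ending on the upper bound means the
rise is unresolvable at the frame rate and is excluded from ensembles.
Dissociation (wash-phase) trajectories are bleach-corrected, normalized to
their first frames, and fitted to `I(t) = A + B e^(-k_off t)`; a decay
amplitude indistinguishable from zero flags `k_off` as unidentifiable.
Although the half-life correction is usually only needed for the slow wash
phase, this package applies it to both phases: over a 40 s association
window a 300 s bleach half-life removes ~9% of signal, which would
otherwise bias the plateau.

Reported per-concentration rates follow the ensemble convention: the value
is the fit to the trajectory averaged over all molecules (aligned at their
onsets), and the per-molecule fits provide the s.e.m. `k_on` is the slope
of the error-weighted line through mean `k_obs` versus concentration
(weights `1/sem^2`; unweighted if any s.e.m. is zero), restricted to the
linear range (default <= 200 nM, above which `k_obs` saturates at the
frame rate). `k_off` is the intercept of the rate-versus-concentration line
of the dissociation fits, whose slope is reported with a significance test
because it should be zero. `K_d = k_off / k_on` exactly, with its error
propagated in quadrature.

Parameter errors of these regressions are propagated from the measured
per-point errors (known-variance weighted least squares), inflated by
`sqrt(chi2/dof)` when the scatter exceeds the stated errors. With only
5 (or 3) concentration points, residual-based errors have 1–3 degrees of
freedom and fluctuate severalfold between replicate experiments; the
error-propagated form tracks the empirical estimator spread much more
closely.

**Estimator spread under the default conditions.** With 25 molecules of 20
sites per concentration, the stochastic site occupancy (correlation time
`1/k_obs`, several seconds at 25 nM) limits the ensemble `k_obs` to ~20%
relative standard deviation at the lowest concentrations — this is
intrinsic to the data volume, not the fit (doubling the trajectory length
does not reduce it). The recovered `k_on` and `K_d` consequently carry
~25–45% standard errors at these conditions; recovery is unbiased, and the
reported standard errors are honest about this spread. Averaging several
replicate experiments per concentration (as a real study would) tightens
the estimates in proportion.

The Hill fit `theta = theta_max c^n / (K_d^n + c^n)` uses baseline-
subtracted steady-state signals, bounds `n` in [0.1, 10] and `K_d` in
(0, 100 max c], and multi-starts `K_d` from 5 log-spaced seeds, keeping the
best SSE. Fixing `n = 1` reduces it exactly to the two-parameter Langmuir
isotherm fit (tested to 1e-10 in SSE).

**Compaction lag and rate.** The length trajectory is fitted with a
continuous two-segment model — flat at `L0` until the changepoint, then
linear decline at rate `r` — by exhaustive search over every frame as
candidate changepoint, solving the conditionally linear `(L0, r)` by least
squares at each. Exhaustive search is robust to the non-smooth objective; a
fitted rate at numerical zero or below yields a "no compaction" verdict
(the phenotype of the bridging-deficient mutant). Frames after the DNA has
fallen below `min_frac` (default 0.2) of its initial length are excluded:
fully compacted DNA sits at the tether in a plateau outside the two-segment
model, and including it biases the rate downward.

## Sequential two-state binding

Each DNA segment binds zero, one or two protein dimers with stepwise
dissociation constants `K1`, `K2` (nM; the statistical weights are
`1 : c/K1 : c^2/(K1 K2)`), and each state has its own fold intensity and
length (`I1, I2, L1, L2`; the unbound state is 1 by definition). Whole-DNA
curves are the population-weighted means — the segments are treated as an
infinite collection of independent, identical units (mean field), with no
inter-segment coupling. The joint fit minimizes the equally weighted sum of
the two channels' SSE (both are fold quantities of order one; the weight
ratio is configurable since nothing in the data dictates it), over
box constraints `K` in [0.1, 1e5] nM, `I` in [0.5, 20], `L` in [0.05, 2],
using L-BFGS-B on `log K` with 20 random starts (log-uniform `K`, near-unit
`I`/`L`). Multi-start matters: the 6-parameter surface has shallow valleys
when `K1` and `K2` are within a decade of each other.

## Tension from differential extension

For labelled sites at contour positions `s_i = L N_i / N_total` (defaults:
the four EcoRI sites of XbaI-digested lambda DNA, `N_total = 23,994` bp,
0.34 nm/bp so `L = 8.158 um`), the differential extension of segment `i` is
`xi_i = (<z_i> - <z_(i-1)>) / (s_i - s_(i-1))` with the tether at
`z_0 = s_0 = 0`. Tension follows from the Marko–Siggia worm-like-chain
interpolation `F = (kBT/P)(1/(4(1-x)^2) - 1/4 + x)` with persistence length
50 nm and `kBT = 4.114 pN nm` (25 C), both configurable; the generator
inverts it by bisection on [0, 1 - 1e-9] to 1e-12. `xi` is clipped into
[0, 1 - 1e-6] so the force stays finite; raw values and clip flags are
preserved, and non-monotone site means are flagged rather than silently
clipped. The first segment's extension is sensitive to tether-point error,
so the tether position is an explicit input (from ROI metadata or
generator truth) rather than something estimated internally.

## Orchestration and problem sizes

`run_pipeline()` runs a named recovery experiment from a config (YAML or
list) under one master seed and writes CSV tables plus a JSON report with
a config hash; identical config and seed give byte-identical outputs. The
packaged experiment sizes — 100 compaction trajectories; 25 molecules per
concentration at five (association) and three (dissociation)
concentrations; 50 replicate Hill and two-state fits — are the package's
default study conditions and complete in a few minutes on one CPU.

## Known limitations

- PIFE is modelled as binary and site-local; graded distance dependence,
  blinking, and spectral effects are out of scope.
- One binding site per dye ignores footprint exclusion and cooperativity;
  the Langmuir chain is exact for the model, approximate for chromatin-like
  crowding.
- The length threshold calibration targets this renderer's point-spread
  and labelling density; other optics warrant re-checking `f` and
  `smooth_sigma` on a known-length control.
- No global multi-concentration fit and no Bayesian uncertainty: estimates
  are least squares with propagated errors.
- Biphasic dissociation of filament-forming proteins is simulated and
  measured descriptively but not model-fitted (no accepted closed form).
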