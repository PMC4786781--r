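# pifeflow

Single-molecule analysis of protein binding and DNA conformation on
flow-stretched DNA, using protein-induced fluorescence enhancement (PIFE)
as a label-free binding readout.

## The problem

Flow-stretching assays extend surface-tethered DNA molecules with
hydrodynamic drag and watch how DNA-binding proteins change their length.
Classically they report only DNA conformation; seeing the protein requires
fluorescent labelling, which is laborious and restricts imaging to low
protein concentrations. When the DNA itself is sparsely labelled with a
cyanine dye such as Cy3 (about one dye per kilobase on a ~20 kb molecule),
an unlabelled protein binding within a few nanometres of a dye raises that
dye's quantum yield — PIFE. The integrated intensity of the DNA then tracks
protein occupancy while the DNA's apparent length tracks conformation, both
from the same movie.

`pifeflow` implements the analysis chain for such experiments, and a
synthetic-data generator that emulates the raw data with known ground
truth, so every estimator can be validated by parameter recovery:

- **simulation** (`sim_preset_named()`, `simulate_occupancy()`,
  `simulate_intensity_trajectory()`, `simulate_compaction_trajectory()`,
  `simulate_hbsu_steady_state()`, `render_movie()`, `simulate_qd_track()`) —
  per-site reversible binding as independent two-state Markov chains, binary
  PIFE brightness enhancement, per-dye exponential photobleaching, camera
  noise, 16-bit TIFF movies, quantum-dot tracks;
- **imaging** (`extract_roi_intensity()`, `build_kymograph()`,
  `measure_length()`, `localize_qd()`, `detect_association_start()`) —
  background-subtracted ROI intensities, kymographs, threshold length
  counting, sub-pixel Gaussian localization, association-onset detection;
- **kinetics** (`normalize_fold()`, `correct_photobleaching()`,
  `fit_association()`, `fit_dissociation()`, `estimate_rate_constants()`,
  `fit_hill()`, `estimate_lag_and_rate()`) — the Langmuir 1:1 model
  `F(t) = c0 + c1 (1 - e^(-k_obs t))`, `I(t) = A + B e^(-k_off t)`,
  `k_obs = k_on [P] + k_off`, the Hill isotherm
  `theta = theta_max [P]^n / (K_d^n + [P]^n)`, and a changepoint estimator
  for compaction lag time and rate;
- **two-state binding** (`occupancy_probs()`, `predict_twostate_curves()`,
  `fit_twostate()`) — sequential binding of up to two protein dimers per
  DNA segment with stepwise constants `K1`, `K2` and per-state fold
  intensity/length, fitted jointly to paired steady-state curves;
- **tension** (`differential_extension()`, `wlc_force()`, `wlc_invert()`,
  `tensions_from_extension()`) — differential extension between labelled
  sites, `xi_i = (<z_i> - <z_(i-1)>) / (s_i - s_(i-1))`, mapped to force
  with the Marko–Siggia worm-like chain
  `F = (kBT/P) [1/(4(1-x)^2) - 1/4 + x]`;
- **orchestration** (`run_pipeline()`, TIFF/CSV/YAML/JSON I/O) —
  deterministic, seeded end-to-end experiments with machine-readable
  reports.

## Worked example

Recover binding rate constants from simulated association and wash
trajectories of a non-compacting DNA-binding protein (k_on = 2.1e6 /M/s,
k_off = 0.16 /s in the generator):

```r
library(pifeflow)

ex <- experiment_rate_constants(preset = sim_preset_named("r82a"),
                                n_dna = 25, seed = 1)
ex$rate_constants
#> <rate_constants>
#>   k_on  = 1.35e+06 +/- 5.9e+05 /M/s
#>   k_off = 0.143 +/- 0.023 /s (slope p = 0.61)
#>   K_d   = 105 +/- 49 nM
```

Each concentration's `k_obs` comes from a Langmuir fit of the
ensemble-averaged fold-intensity trajectory (25 DNAs aligned at their
detected association onsets); `k_on` is the slope of the error-weighted
`k_obs`-versus-concentration line, `k_off` the intercept of the wash-phase
dissociation rates, and `K_d = k_off / k_on` (here 105 ± 49 nM against the
generator's 76.2 nM — within the estimator's error, which is dominated by
stochastic site occupancy at the lower concentrations).

Tension along a flow-stretched DNA from a quantum-dot track:

```r
geom <- motion_capture_geometry()   # four sites on XbaI-cut lambda DNA
trk  <- simulate_qd_track(geom, tensions = c(1.0, 0.6, 0.3, 0.1),
                          loc_sd = 0.02, n_frames = 200, seed = 31)
tensions_from_extension(differential_extension(trk, geom))
#> <tension_profile>
#>       segment     xi xi_raw clipped nonmonotone z_mean_um  s_um    F_pN
#> site1       1 0.8533 0.8533   FALSE       FALSE     1.024 1.200 1.00519
#> site2       2 0.8075 0.8075   FALSE       FALSE     2.618 3.174 0.60104
#> site3       3 0.7195 0.7195   FALSE       FALSE     4.433 5.697 0.30013
#> site4       4 0.4927 0.4927   FALSE       FALSE     5.378 7.615 0.09991
```

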