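# ROI intensity extraction, kymographs, length measurement, QD localization
# and association-onset detection.

make_stack <- function(frames, frame_interval = 0.1, pixel_size = 0.167) {
  px <- array(0, dim = c(length(frames), nrow(frames[[1]]),
                         ncol(frames[[1]])))
  for (t in seq_along(frames)) px[t, , ] <- frames[[t]]
  image_stack(px, frame_interval, pixel_size)
}

test_that("ROI intensity is zero on uniform frames and exact on one dye", {
  fr <- matrix(37, 30, 40)
  st <- make_stack(list(fr, fr))
  r <- roi(10, 20, 10, 30)
  expect_equal(extract_roi_intensity(st, r)$value, c(0, 0))

  # one dye of brightness B on zero background: recovered within PSF
  # truncation error
  B <- 5000
  fr2 <- pifeflow:::add_gaussian_spot(matrix(0, 30, 40), 15, 20, B, 1)
  st2 <- make_stack(list(fr2))
  r2 <- roi(10, 20, 14, 26, tether_col = 14)
  expect_equal(extract_roi_intensity(st2, r2)$value, B, tolerance = 1e-3)
})

test_that("edge-touching ROI falls back to the global background estimate", {
  fr <- matrix(10, 20, 30)
  st <- make_stack(list(fr))
  r_edge <- roi(1, 6, 1, 10)
  expect_message(tr <- extract_roi_intensity(st, r_edge), "edge")
  expect_true(attr(tr, "edge_fallback_used"))
  expect_equal(tr$value, 0)
})

test_that("kymograph is the cross-flow projection and sums back to the ROI", {
  p <- tiny_preset(concentration_nM = 100)
  occ <- simulate_occupancy(p, 3, seed = 2)
  mv <- render_movie(list(list(occ = occ, length_um = 2,
                               tether_row = 16, tether_col = 8)),
                     p, dims = c(32, 40), seed = 3)
  r <- mv$truth[[1]]$roi
  ky <- build_kymograph(mv$stack, r)
  tr <- extract_roi_intensity(mv$stack, r)
  expect_equal(rowSums(ky$values), tr$value, ignore_attr = TRUE)

  # single-frame stack: one kymograph row of column sums
  one <- image_stack(mv$stack$pixels[1, , , drop = FALSE], 0.1, 0.167)
  ky1 <- build_kymograph(one, r)
  expect_equal(dim(ky1$values)[1], 1L)
  expect_equal(ky1$values[1, ], ky$values[1, ])

  # time-constant stack: identical rows
  px <- mv$stack$pixels
  px[2, , ] <- px[1, , ]
  st2 <- image_stack(px[1:2, , , drop = FALSE], 0.1, 0.167)
  ky2 <- build_kymograph(st2, r)
  expect_equal(ky2$values[1, ], ky2$values[2, ])
})

test_that("length counting is exact on contiguous blocks and flags empties", {
  vals <- matrix(0, 3, 30)
  vals[1, 5:14] <- 100   # 10 bright pixels
  vals[2, 5:24] <- 100   # 20 bright pixels
  ky <- structure(list(values = vals, pixel_size = 0.167,
                       frame_interval = 0.1), class = "kymograph")
  len <- measure_length(ky, smooth_sigma = 0, median_filter = FALSE)
  expect_equal(len$value[1:2], c(10, 20) * 0.167)
  expect_equal(len$value[3], 0)
  expect_identical(len$flag_empty, c(FALSE, FALSE, TRUE))

  # all-zero kymograph: all lengths zero, all flagged
  ky0 <- structure(list(values = matrix(0, 2, 30), pixel_size = 0.167,
                        frame_interval = 0.1), class = "kymograph")
  len0 <- measure_length(ky0, smooth_sigma = 0, median_filter = FALSE)
  expect_true(all(len0$value == 0) && all(len0$flag_empty))
})

test_that("length measurement is invariant to a constant intensity offset", {
  set.seed(11)
  vals <- matrix(rnorm(40 * 60, 0, 3), 40, 60)
  for (t in 1:40) vals[t, 5:(44 - t %/% 2)] <- vals[t, 5:(44 - t %/% 2)] + 80
  ky <- structure(list(values = vals, pixel_size = 0.167,
                       frame_interval = 0.1), class = "kymograph")
  ky_off <- ky
  ky_off$values <- ky$values + 500
  expect_equal(measure_length(ky)$value, measure_length(ky_off)$value)
})

test_that("length from rendered sparse-dye movies is unbiased near L0", {
  # per-molecule spread of a few pixels is inherent to random ~1 dye/kb
  # labelling; the ensemble mean should sit within ~1 pixel of truth
  errs <- vapply(1:8, function(i) {
    p <- sim_preset_named("spo0j_wt", concentration_nM = 0, noise_sd = 5)
    occ <- simulate_occupancy(p, 6, seed = 100 + i)
    mv <- render_movie(list(list(occ = occ, length_um = p$l0_um,
                                 tether_row = 16, tether_col = 10)),
                       p, dims = c(32, 70), seed = 200 + i)
    len <- measure_length(build_kymograph(mv$stack, mv$truth[[1]]$roi))
    median(len$value) - p$l0_um
  }, numeric(1))
  expect_lt(abs(mean(errs)) / 0.167, 1.5)
})

test_that("QD localization is exact, shift-equivariant and low-noise", {
  px <- 0.167
  profile_at <- function(mu) 5 + 100 * exp(-((0:40) - mu)^2 / (2 * 1.6^2))
  # noiseless identity at pixel 17
  expect_equal(localize_qd(profile_at(17), px)$position_um, 17 * px,
               tolerance = 1e-6)
  # sub-pixel shift of +0.4 px recovered within 0.02 px
  loc <- localize_qd(profile_at(17.4), px)
  expect_lt(abs(loc$center_px - 17.4), 0.02)
  # whole-pixel shift equivariance
  l0 <- localize_qd(profile_at(14), px)
  l5 <- localize_qd(profile_at(19), px)
  expect_equal(l5$position_um - l0$position_um, 5 * px, tolerance = 1e-6)
  # flat profile: no significant peak
  expect_error(localize_qd(rep(5, 30), px), "no significant peak")
})

test_that("QD localization is precise and unbiased under noise", {
  # QD point source at the camera's sampling (sigma ~0.8 px), SNR 10 white
  # noise, 500 replicates: s.d. < 0.1 px and bias < 0.05 px
  set.seed(42)
  truth <- 17.3
  base <- 5 + 100 * exp(-((0:40) - truth)^2 / (2 * 0.8^2))
  centers <- vapply(1:500, function(i) {
    localize_qd(base + rnorm(41, 0, 10), 0.167)$center_px
  }, numeric(1))
  expect_lt(sd(centers), 0.1)
  expect_lt(abs(mean(centers) - truth), 0.05)
})

test_that("association-onset detection finds steps and rejects constants", {
  tr_const <- trajectory(seq(0, 19.9, by = 0.1), rep(100, 200), "intensity")
  expect_false(detect_association_start(tr_const, 50)$detected)

  v <- c(rep(100, 99), rep(160, 101))
  tr_step <- trajectory(seq(0, 19.9, by = 0.1), v, "intensity")
  on <- detect_association_start(tr_step, 50)
  expect_true(on$detected)
  expect_equal(on$index, 100L)
})

test_that("detected onset tracks the true protein arrival within 3 frames", {
  p <- sim_preset_named("r82a", concentration_nM = 100)
  errs <- vapply(1:50, function(i) {
    sim <- simulate_association_trajectory(p, duration = 10, baseline_s = 5,
                                           seed = 3000 + i)
    on <- detect_association_start(sim$trajectory, baseline_window = 45L)
    if (!on$detected) return(NA_real_)
    on$index - sim$truth$onset_index
  }, numeric(1))
  expect_lte(median(abs(errs), na.rm = TRUE), 3)
})
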