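#' Construct an image stack
#'
#' The raw observable: a time-lapse of 2-D fluorescence frames of tethered,
#' flow-stretched DNAs.
#'
#' @param pixels numeric array `[T, H, W]` of nonnegative pixel values.
#' @param frame_interval frame interval (s), > 0.
#' @param pixel_size pixel size in sample space (um), > 0.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, frame_interval, pixel_size) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3,
            all(dim(pixels) >= 1), frame_interval > 0, pixel_size > 0)
  if (any(pixels < 0)) stop("pixel values must be nonnegative", call. = FALSE)
  structure(list(pixels = pixels, frame_interval = frame_interval,
                 pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d frames of %d x %d px, %g s/frame, %g um/px\n",
              d[1], d[2], d[3], x$frame_interval, x$pixel_size))
  invisible(x)
}

# Add one 2-D Gaussian spot (total integrated brightness B, sigma in px)
# to frame matrix `fr` at continuous (row, col) position, 1-based pixel
# centers. Rendering window is +/- 5 sigma.
add_gaussian_spot <- function(fr, row, col, B, sigma) {
  if (B <= 0) return(fr)
  h <- nrow(fr); w <- ncol(fr)
  r0 <- max(1L, floor(row - 5 * sigma)); r1 <- min(h, ceiling(row + 5 * sigma))
  c0 <- max(1L, floor(col - 5 * sigma)); c1 <- min(w, ceiling(col + 5 * sigma))
  if (r0 > r1 || c0 > c1) return(fr)
  gy <- stats::dnorm(r0:r1, row, sigma)
  gx <- stats::dnorm(c0:c1, col, sigma)
  fr[r0:r1, c0:c1] <- fr[r0:r1, c0:c1] + B * outer(gy, gx)
  fr
}

#' Render a synthetic TIRF movie of tethered DNAs
#'
#' Each DNA is drawn as a horizontal row of dye point-spread functions: dye
#' `j`, placed at a fixed contour fraction `f_j`, projects to column
#' `tether_col + f_j * L(t) / pixel_size` in frame `t`. Per-dye brightness
#' (PIFE enhancement and photobleaching) comes from the occupancy matrix via
#' the same model as [simulate_intensity_trajectory()]. A constant camera
#' baseline plus Gaussian read noise is added and frames are clipped to the
#' 16-bit range.
#'
#' @param dnas list of per-DNA descriptions, each a list with elements
#'   `occ` (an `occupancy_matrix`; all DNAs must share the frame count),
#'   `length_um` (scalar or per-frame vector of DNA extension),
#'   `tether_row`, `tether_col` (1-based pixel position of the tether).
#' @param preset a [sim_preset()]; uses `pixel_size`, `psf_sigma_px`,
#'   `dye_brightness`, `pife_factor`, `t_half_bleach`, `noise_sd`.
#' @param dims frame dimensions `c(H, W)` in pixels.
#' @param background constant camera offset (counts) so read noise is not
#'   clipped at zero.
#' @param seed RNG seed (dye placement, bleaching, read noise).
#' @return List with `stack` (an [image_stack()]) and `truth`: per DNA the
#'   dye contour fractions, per-dye brightness matrix, total intensity and
#'   the suggested [roi()].
#' @export
render_movie <- function(dnas, preset, dims = c(32L, 96L), background = 100,
                         seed = preset$seed) {
  stopifnot(inherits(preset, "sim_preset"), length(dims) == 2)
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  n_frames <- nrow(dnas[[1]]$occ$values)
  sigma <- preset$psf_sigma_px
  px <- preset$pixel_size

  truth <- vector("list", length(dnas))
  frames <- array(0, dim = c(n_frames, H, W))
  for (d in seq_along(dnas)) {
    dna <- dnas[[d]]
    stopifnot(inherits(dna$occ, "occupancy_matrix"),
              nrow(dna$occ$values) == n_frames)
    n_dyes <- ncol(dna$occ$values)
    len <- rep_len(dna$length_um, n_frames)
    if (dna$tether_col + max(len) / px > W - 5 * sigma) {
      stop("DNA extends beyond the frame width", call. = FALSE)
    }
    frac <- sort(with_seed_(derive_seed(seed, 10 * d), stats::runif(n_dyes)))
    bright <- dye_brightness_matrix(dna$occ, preset,
                                    seed = derive_seed(seed, 10 * d + 1))
    for (t in seq_len(n_frames)) {
      fr <- frames[t, , ]
      cols <- dna$tether_col + frac * len[t] / px
      for (j in seq_len(n_dyes)) {
        fr <- add_gaussian_spot(fr, dna$tether_row, cols[j],
                                bright[t, j], sigma)
      }
      frames[t, , ] <- fr
    }
    half_h <- max(3L, ceiling(3 * sigma))
    truth[[d]] <- list(
      dye_fractions = frac,
      per_dye_brightness = bright,
      total_intensity = rowSums(bright),
      length_um = len,
      roi = roi(row0 = max(1L, dna$tether_row - half_h),
                row1 = min(H, dna$tether_row + half_h),
                col0 = max(1L, floor(dna$tether_col - 2)),
                col1 = min(W, ceiling(dna$tether_col + max(len) / px +
                                        5 * sigma)),
                tether_col = dna$tether_col)
    )
  }
  noisy <- with_seed_(derive_seed(seed, 3), {
    frames + background +
      array(stats::rnorm(length(frames), 0, preset$noise_sd), dim(frames))
  })
  noisy <- round(pmin(pmax(noisy, 0), 65535))
  list(stack = image_stack(noisy, frame_interval = 1 / preset$frame_rate,
                           pixel_size = px),
       truth = truth)
}

#' Simulate a quantum-dot motion-capture track
#'
#' Given the tension on each inter-site segment, the fractional extension of
#' segment `i` is the inverse worm-like-chain of `F_i`; the mean position of
#' site `i` from the tether is the cumulative sum of segment extensions times
#' contour spacings. Observed per-frame positions add Gaussian localization
#' noise.
#'
#' @param geom a [motion_capture_geometry()].
#' @param tensions per-segment tensions (pN), one per labelled site, all > 0.
#' @param wlc a [wlc_model()].
#' @param loc_sd localization noise s.d. (um).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return Object of class `qd_track`: list with `positions`
#'   (`n_frames x n_sites` um from the tether), `loc_sd`, and `truth`
#'   (mean positions `z`, segment extensions `x`, input `tensions`).
#' @export
simulate_qd_track <- function(geom, tensions, wlc = wlc_model(),
                              loc_sd = 0.02, n_frames = 100, seed = 1L) {
  stopifnot(inherits(geom, "motion_capture_geometry"),
            length(tensions) == length(geom$s_um))
  if (any(tensions <= 0)) {
    stop("tensions must be positive (WLC force is positive for x > 0)",
         call. = FALSE)
  }
  x <- vapply(tensions, wlc_invert, numeric(1), model = wlc)
  ds <- diff(c(0, geom$s_um))
  z <- cumsum(x * ds)
  positions <- with_seed_(seed, {
    matrix(z, n_frames, length(z), byrow = TRUE) +
      matrix(stats::rnorm(n_frames * length(z), 0, loc_sd),
             n_frames, length(z))
  })
  colnames(positions) <- paste0("site", seq_along(z))
  structure(list(positions = positions, loc_sd = loc_sd,
                 truth = list(z = z, x = x, tensions = tensions)),
            class = "qd_track")
}
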