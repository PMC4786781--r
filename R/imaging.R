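#' Region of interest around a single tethered DNA
#'
#' Row/column ranges are 1-based and inclusive (R convention). The flow axis
#' is the column axis; the tether sits at the low-column side.
#'
#' @param row0,row1 first and last row of the ROI.
#' @param col0,col1 first and last column of the ROI.
#' @param tether_col column of the tether point, inside `[col0, col1]`.
#' @return An object of class `roi`.
#' @export
roi <- function(row0, row1, col0, col1, tether_col = col0) {
  stopifnot(row0 >= 1, col0 >= 1, row1 >= row0, col1 >= col0,
            tether_col >= col0, tether_col <= col1)
  structure(list(row0 = as.integer(row0), row1 = as.integer(row1),
                 col0 = as.integer(col0), col1 = as.integer(col1),
                 tether_col = as.integer(tether_col)),
            class = "roi")
}

check_roi <- function(stack, roi) {
  d <- dim(stack$pixels)
  if (roi$row1 > d[2] || roi$col1 > d[3]) {
    stop("ROI exceeds frame dimensions", call. = FALSE)
  }
}

# Per-frame background estimate (counts per pixel) for an ROI: median of a
# 2-pixel border ring around the ROI. If the ring is incomplete because the
# ROI touches the frame edge, fall back to the median of the lowest decile
# of the whole frame (the default) or to the partial ring.
roi_background <- function(frame, roi, ring = 2L,
                           edge_fallback = c("global_decile", "partial_ring")) {
  edge_fallback <- match.arg(edge_fallback)
  h <- nrow(frame); w <- ncol(frame)
  r0 <- roi$row0 - ring; r1 <- roi$row1 + ring
  c0 <- roi$col0 - ring; c1 <- roi$col1 + ring
  complete <- r0 >= 1 && c0 >= 1 && r1 <= h && c1 <= w
  if (!complete && edge_fallback == "global_decile") {
    v <- sort(as.vector(frame))
    return(stats::median(v[seq_len(max(1L, floor(length(v) / 10)))]))
  }
  rr <- max(1L, r0):min(h, r1)
  cc <- max(1L, c0):min(w, c1)
  outer_box <- frame[rr, cc, drop = FALSE]
  inner <- matrix(FALSE, length(rr), length(cc))
  inner[rr >= roi$row0 & rr <= roi$row1, cc >= roi$col0 & cc <= roi$col1] <- TRUE
  stats::median(outer_box[!inner])
}

#' Integrated ROI intensity trajectory
#'
#' For each frame, sums the pixels inside the ROI and subtracts a per-frame
#' background estimated as the median of a 2-pixel border ring around the ROI
#' times the ROI area. Output may be negative on pure noise (not clipped).
#' ROIs touching the frame edge fall back to a global background estimate
#' (median of the lowest decile of the frame) and are flagged.
#'
#' @param stack an [image_stack()].
#' @param roi an [roi()] valid for the stack.
#' @param edge_fallback background rule when the border ring is incomplete.
#' @return An intensity [trajectory()]; attribute `edge_fallback_used` is
#'   `TRUE` when the global fallback was used.
#' @export
extract_roi_intensity <- function(stack, roi,
                                  edge_fallback = c("global_decile",
                                                    "partial_ring")) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi"))
  edge_fallback <- match.arg(edge_fallback)
  check_roi(stack, roi)
  d <- dim(stack$pixels)
  touches_edge <- roi$row0 - 2L < 1 || roi$col0 - 2L < 1 ||
    roi$row1 + 2L > d[2] || roi$col1 + 2L > d[3]
  if (touches_edge && edge_fallback == "global_decile") {
    message("ROI touches the frame edge; using global lowest-decile background")
  }
  area <- (roi$row1 - roi$row0 + 1) * (roi$col1 - roi$col0 + 1)
  vals <- vapply(seq_len(d[1]), function(t) {
    fr <- stack$pixels[t, , ]
    bg <- roi_background(fr, roi, edge_fallback = edge_fallback)
    sum(fr[roi$row0:roi$row1, roi$col0:roi$col1]) - bg * area
  }, numeric(1))
  out <- trajectory((seq_len(d[1]) - 1) * stack$frame_interval, vals,
                    kind = "intensity", frame_interval = stack$frame_interval)
  attr(out, "edge_fallback_used") <- touches_edge
  out
}

#' Build a kymograph from an ROI
#'
#' Projects each frame's ROI onto the flow (column) axis after background
#' subtraction: each kymograph row is the cross-flow (row-axis) sum of the
#' background-subtracted ROI. Columns run tether to free end.
#'
#' @inheritParams extract_roi_intensity
#' @return Object of class `kymograph`: list with `values` (`T x X` matrix),
#'   `pixel_size`, `frame_interval`.
#' @export
build_kymograph <- function(stack, roi,
                            edge_fallback = c("global_decile",
                                              "partial_ring")) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi"))
  edge_fallback <- match.arg(edge_fallback)
  check_roi(stack, roi)
  d <- dim(stack$pixels)
  n_rows <- roi$row1 - roi$row0 + 1
  values <- t(vapply(seq_len(d[1]), function(t) {
    fr <- stack$pixels[t, , ]
    bg <- roi_background(fr, roi, edge_fallback = edge_fallback)
    colSums(fr[roi$row0:roi$row1, roi$col0:roi$col1, drop = FALSE] - bg)
  }, numeric(roi$col1 - roi$col0 + 1)))
  if (d[1] == 1L) values <- matrix(values, nrow = 1L)
  structure(list(values = values, pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval),
            class = "kymograph")
}

#' Measure DNA length from a kymograph by threshold pixel counting
#'
#' A single intensity threshold is computed from the whole kymograph as
#' `b + f * (q95 - b)` where `b` is the median of the lowest decile of all
#' kymograph pixels (the background level) and `q95` the 95th percentile.
#' Per frame, the length is the number of above-threshold pixels times the
#' pixel size. Before thresholding, each profile is optionally smoothed with
#' a Gaussian kernel along the flow axis (`smooth_sigma`, px) — sparse dye
#' labelling leaves sub-diffraction gaps between dye images that would
#' otherwise fragment the counted length — and a 3-pixel median filter
#' (default on) suppresses isolated bright or dark pixels.
#'
#' @param kym a `kymograph` from [build_kymograph()].
#' @param f threshold fraction of the background-to-95th-percentile range.
#' @param median_filter apply a 3-pixel median filter along the flow axis.
#' @param smooth_sigma Gaussian smoothing sigma along the flow axis (px);
#'   0 disables smoothing.
#' @return A length [trajectory()] with extra column `flag_empty` marking
#'   frames with no above-threshold pixel (length 0).
#' @export
measure_length <- function(kym, f = 0.12, median_filter = TRUE,
                           smooth_sigma = 1.5) {
  stopifnot(inherits(kym, "kymograph"), length(kym$values) >= 1,
            f > 0, f < 1, smooth_sigma >= 0)
  vals <- kym$values
  if (smooth_sigma > 0 && ncol(vals) >= 5) {
    half <- ceiling(3 * smooth_sigma)
    kern <- stats::dnorm(-half:half, 0, smooth_sigma)
    kern <- kern / sum(kern)
    vals <- t(apply(vals, 1, function(row) {
      # pad by edge replication so the smoothing is offset-preserving
      padded <- c(rep(row[1], half), row, rep(row[length(row)], half))
      stats::convolve(padded, rev(kern), type = "filter")
    }))
  }
  v <- as.vector(vals)
  vs <- sort(v)
  b <- stats::median(vs[seq_len(max(1L, floor(length(vs) / 10)))])
  q95 <- stats::quantile(v, 0.95, names = FALSE)
  thr <- b + f * (q95 - b)
  counts <- apply(vals, 1, function(row) {
    if (median_filter && length(row) >= 3) row <- stats::runmed(row, 3)
    sum(row > thr)
  })
  out <- trajectory((seq_len(nrow(kym$values)) - 1) * kym$frame_interval,
                    counts * kym$pixel_size, kind = "length",
                    frame_interval = kym$frame_interval)
  out$flag_empty <- counts == 0L
  attr(out, "threshold") <- thr
  out
}

#' Sub-pixel localization of a quantum dot from a 1-D profile
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - center)^2 / (2 w^2))`
#' to the projected intensity profile, initialized at the argmax. Positions
#' are measured from the first pixel of the profile (pixel 0), so a peak
#' centered on the k-th pixel returns `k * pixel_size`.
#'
#' @param profile numeric vector: 1-D projection along the flow axis.
#' @param pixel_size pixel size (um).
#' @return List with `position_um`, `center_px` (0-based), `sigma_px`,
#'   `amplitude`, `offset`, `converged` (FALSE means the argmax fallback was
#'   used).
#' @export
localize_qd <- function(profile, pixel_size = 0.167) {
  stopifnot(is.numeric(profile), length(profile) >= 5, pixel_size > 0)
  bg <- stats::median(profile)
  noise <- stats::mad(profile)
  if (max(profile) <= bg + 3 * noise) {
    stop("no significant peak in profile (max <= background + 3 sd)",
         call. = FALSE)
  }
  x <- seq_along(profile) - 1  # 0-based pixel coordinates
  i_max <- which.max(profile)
  start <- list(offset = bg, A = max(profile) - bg,
                mu = x[i_max], w = 1.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      profile ~ offset + A * exp(-(x - mu)^2 / (2 * w^2)),
      start = start,
      lower = c(offset = -Inf, A = 0, mu = min(x), w = 0.3),
      upper = c(offset = Inf, A = Inf, mu = max(x), w = length(x)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(position_um = x[i_max] * pixel_size, center_px = x[i_max],
                sigma_px = NA_real_, amplitude = max(profile) - bg,
                offset = bg, converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(position_um = unname(cf["mu"]) * pixel_size,
       center_px = unname(cf["mu"]), sigma_px = unname(cf["w"]),
       amplitude = unname(cf["A"]), offset = unname(cf["offset"]),
       converged = TRUE)
}

#' Detect the start of protein association in an intensity trajectory
#'
#' Time zero of every association fit is the first frame at which a 5-frame
#' trailing running mean of the intensity exceeds the baseline mean by
#' `k_sigma` baseline standard deviations and stays above for `persist`
#' consecutive frames. Baseline statistics come from the first
#' `baseline_window` frames (pre-protein data).
#'
#' @param traj intensity [trajectory()].
#' @param baseline_window number of pre-protein frames (>= 5).
#' @param k_sigma threshold in baseline s.d. units.
#' @param persist required consecutive above-threshold frames.
#' @param smooth trailing running-mean window (frames).
#' @return List with `detected` (logical), `index` (1-based frame) and
#'   `time_s`, or `detected = FALSE` when no sustained crossing exists.
#' @export
detect_association_start <- function(traj, baseline_window = 20L,
                                     k_sigma = 4, persist = 5L, smooth = 5L) {
  stopifnot(nrow(traj) > baseline_window, baseline_window >= 5)
  v <- traj$value
  bm <- mean(v[seq_len(baseline_window)])
  bs <- stats::sd(v[seq_len(baseline_window)])
  rm5 <- as.numeric(stats::filter(v, rep(1 / smooth, smooth), sides = 1))
  above <- !is.na(rm5) & rm5 > bm + k_sigma * bs
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= persist)
  if (!length(hit)) {
    return(list(detected = FALSE, index = NA_integer_, time_s = NA_real_))
  }
  idx <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  list(detected = TRUE, index = idx, time_s = traj$time_s[idx])
}
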