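# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG alone.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-unit sub-seed derived from a master seed. Two rounds of
# the MINSTD Lehmer generator scramble (master, index) so that nearby inputs
# map to well-separated seeds (linearly spaced seeds produce correlated
# Mersenne-Twister streams). All products stay below 2^53, so the double
# arithmetic is exact.
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (48271 * ((as.numeric(master) %% (m - 1)) + 1)) %% m
  s <- (48271 * ((s + as.numeric(index)) %% (m - 1) + 1)) %% m
  s <- (48271 * s) %% m
  as.integer(s)
}

# Truncated-at-zero Gaussian draw (rejection; sd = 0 returns the mean).
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Construct a trajectory table
#'
#' The unit of all fitting: a per-DNA time series of integrated intensity or
#' DNA length with its acquisition metadata.
#'
#' @param time_s time stamps (s).
#' @param value intensity (counts or fold) or length (um).
#' @param kind `"intensity"` or `"length"`.
#' @param dna_id identifier of the molecule.
#' @param concentration_nM protein concentration the trajectory was recorded
#'   at (nM).
#' @param frame_interval frame interval (s); inferred from `time_s` if omitted.
#' @return A `data.frame` of class `pife_trajectory` with columns `time_s`,
#'   `value` and attributes `kind`, `dna_id`, `concentration_nM`,
#'   `frame_interval`.
#' @export
trajectory <- function(time_s, value, kind = c("intensity", "length"),
                       dna_id = "dna1", concentration_nM = NA_real_,
                       frame_interval = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(time_s) == length(value), length(time_s) >= 1)
  if (is.null(frame_interval)) {
    frame_interval <- if (length(time_s) > 1) stats::median(diff(time_s)) else NA_real_
  }
  structure(
    data.frame(time_s = as.numeric(time_s), value = as.numeric(value)),
    kind = kind, dna_id = dna_id, concentration_nM = concentration_nM,
    frame_interval = frame_interval,
    class = c("pife_trajectory", "data.frame")
  )
}

#' @export
print.pife_trajectory <- function(x, ...) {
  cat(sprintf("<pife_trajectory: %s> %d frames, dna '%s', [protein] %s nM\n",
              attr(x, "kind"), nrow(x), attr(x, "dna_id"),
              format(attr(x, "concentration_nM"))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Centered running mean of window w (odd); ends padded with shorter windows.
running_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n < w) return(x)
  cs <- cumsum(c(0, x))
  half <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
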