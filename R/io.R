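#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' Pixel values must lie in `[0, 65535]`; a YAML sidecar
#' (`<path>.yaml`) records `frame_interval` and `pixel_size` so the stack
#' round-trips losslessly through [read_image_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  px <- stack$pixels
  if (max(px) > 65535) stop("pixel values exceed the 16-bit range", call. = FALSE)
  pages <- lapply(seq_len(dim(px)[1]), function(t) round(px[t, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  yaml::write_yaml(list(frame_interval = stack$frame_interval,
                        pixel_size = stack$pixel_size),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Acquisition metadata is taken from the YAML sidecar written by
#' [write_image_stack()] when present, else from the arguments; missing
#' metadata falls back to package defaults with a warning.
#'
#' @param path TIFF path.
#' @param frame_interval frame interval (s), used when no sidecar exists.
#' @param pixel_size pixel size (um), used when no sidecar exists.
#' @return An [image_stack()] with integer pixel values.
#' @export
read_image_stack <- function(path, frame_interval = NULL, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bad <- which(vapply(pages, function(p) length(dim(p)) != 2, logical(1)))
  if (length(bad)) {
    stop(sprintf("page %d is not single-channel grayscale", bad[1]),
         call. = FALSE)
  }
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    frame_interval <- frame_interval %||% meta$frame_interval
    pixel_size <- pixel_size %||% meta$pixel_size
  }
  if (is.null(frame_interval) || is.null(pixel_size)) {
    warning("missing acquisition metadata; using defaults (0.1 s, 0.167 um)",
            call. = FALSE)
    frame_interval <- frame_interval %||% 0.1
    pixel_size <- pixel_size %||% 0.167
  }
  d <- dim(pages[[1]])
  px <- array(0, dim = c(length(pages), d[1], d[2]))
  for (t in seq_along(pages)) px[t, , ] <- pages[[t]]
  image_stack(px, frame_interval = frame_interval, pixel_size = pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write trajectories to a single CSV
#'
#' Long format with unit-bearing headers: `time_s`, `value`, `dna_id`,
#' `concentration_nM`. Values are serialized at full double precision.
#'
#' @param trajs a [trajectory()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "pife_trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    data.frame(time_s = tr$time_s, value = tr$value,
               dna_id = attr(tr, "dna_id"),
               concentration_nM = attr(tr, "concentration_nM"))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories written by [write_trajectories()]
#'
#' @param path CSV path.
#' @param kind `"intensity"` or `"length"`.
#' @return Named list of [trajectory()] objects, one per `dna_id`.
#' @export
read_trajectories <- function(path, kind = c("intensity", "length")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value", "dna_id") %in% names(df)))
  sp <- split(df, df$dna_id)
  lapply(sp, function(d) {
    trajectory(d$time_s, d$value, kind = kind, dna_id = d$dna_id[1],
               concentration_nM = if ("concentration_nM" %in% names(d))
                 d$concentration_nM[1] else NA_real_)
  })
}

#' Write / read a simulation preset as YAML
#'
#' @param preset a [sim_preset()].
#' @param path YAML path.
#' @return `path` invisibly ([write_preset()]); a `sim_preset`
#'   ([read_preset()]).
#' @export
write_preset <- function(preset, path) {
  stopifnot(inherits(preset, "sim_preset"))
  x <- unclass(preset)
  if (!is.null(x$twostate)) x$twostate <- unclass(x$twostate)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_preset
#' @export
read_preset <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$twostate)) x$twostate <- do.call(two_state_params, x$twostate)
  do.call(sim_preset, x)
}
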