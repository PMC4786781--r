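#' Geometry of a motion-capture labelled DNA
#'
#' Positions of the labelled (quantum-dot) sites along the DNA contour. The
#' contour position of site `i` is `s_i = L * N_i / N_total`; the tether
#' point is `s_0 = 0`. Defaults describe the four EcoRI sites of
#' XbaI-digested lambda DNA.
#'
#' @param N_bp sequence positions of the labelled sites from the tether (bp),
#'   strictly increasing and within `N_total`.
#' @param N_total total length of the substrate (bp).
#' @param L_um full contour length (um); computed from `bp_per_um` when
#'   omitted.
#' @param bp_nm contour rise per basepair (nm/bp; default 0.34).
#' @return Object of class `motion_capture_geometry` with element `s_um`
#'   (contour positions of the sites, um).
#' @export
#' @examples
#' motion_capture_geometry()$s_um
motion_capture_geometry <- function(N_bp = c(3530, 9334, 16755, 22398),
                                    N_total = 23994, L_um = NULL,
                                    bp_nm = 0.34) {
  stopifnot(all(diff(c(0, N_bp)) > 0), max(N_bp) <= N_total, N_total > 0)
  if (is.null(L_um)) L_um <- N_total * bp_nm / 1000
  structure(list(N_bp = N_bp, N_total = N_total, L_um = L_um,
                 s_um = L_um * N_bp / N_total),
            class = "motion_capture_geometry")
}

#' Worm-like-chain model parameters
#'
#' @param P_nm persistence length (nm), > 0 (default 50, double-stranded DNA).
#' @param kBT_pNnm thermal energy (pN nm), > 0 (default 4.114, 25 C).
#' @return Object of class `wlc_model`.
#' @export
wlc_model <- function(P_nm = 50, kBT_pNnm = 4.114) {
  stopifnot(P_nm > 0, kBT_pNnm > 0)
  structure(list(P_nm = P_nm, kBT_pNnm = kBT_pNnm), class = "wlc_model")
}

#' Worm-like-chain force at a fractional extension
#'
#' Marko-Siggia interpolation:
#' `F = (kBT / P) * (1 / (4 (1 - x)^2) - 1/4 + x)`, strictly increasing on
#' `[0, 1)`.
#'
#' @param x fractional extension(s), each in `[0, 1)`.
#' @param model a [wlc_model()].
#' @return Force(s) in pN.
#' @export
#' @examples
#' wlc_force(0.5)
wlc_force <- function(x, model = wlc_model()) {
  stopifnot(inherits(model, "wlc_model"))
  if (any(x < 0 | x >= 1)) {
    stop("fractional extension must lie in [0, 1)", call. = FALSE)
  }
  (model$kBT_pNnm / model$P_nm) * (1 / (4 * (1 - x)^2) - 0.25 + x)
}

#' Invert the worm-like-chain force-extension relation
#'
#' Bisection on `[0, 1 - 1e-9]`; the Marko-Siggia force is strictly
#' increasing so the root is unique for any positive force.
#'
#' @param F_pN force (pN), >= 0.
#' @param model a [wlc_model()].
#' @param tol bisection tolerance on the extension.
#' @return Fractional extension in `[0, 1)`.
#' @export
wlc_invert <- function(F_pN, model = wlc_model(), tol = 1e-12) {
  stopifnot(length(F_pN) == 1, F_pN >= 0)
  if (F_pN == 0) return(0)
  lo <- 0; hi <- 1 - 1e-9
  if (wlc_force(hi, model) < F_pN) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (wlc_force(mid, model) < F_pN) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Differential extension along a flow-stretched DNA
#'
#' For quantum-dot sites `i = 1..k` with time-averaged positions `<z_i>`
#' measured from the tether (`z_0 = s_0 = 0`), the differential extension of
#' segment `i` is `xi_i = (<z_i> - <z_{i-1}>) / (s_i - s_{i-1})`. Values are
#' clipped into `[0, 1 - 1e-6]` for the worm-like-chain map (raw values are
#' preserved and clipping is flagged); a negative raw value means the site
#' averages are non-monotone and the segment is flagged.
#'
#' @param track a `qd_track` ([simulate_qd_track()]) or a numeric matrix of
#'   positions (`frames x sites`, um from the tether).
#' @param geom a [motion_capture_geometry()] with one site per track column.
#' @return data.frame with columns `segment`, `xi` (clipped), `xi_raw`,
#'   `clipped`, `nonmonotone`, `z_mean_um`, `s_um`.
#' @export
differential_extension <- function(track, geom) {
  stopifnot(inherits(geom, "motion_capture_geometry"))
  pos <- if (inherits(track, "qd_track")) track$positions else as.matrix(track)
  if (ncol(pos) != length(geom$s_um)) {
    stop("track columns must match the number of labelled sites",
         call. = FALSE)
  }
  if (nrow(pos) < 10) stop("need at least 10 frames", call. = FALSE)
  z <- colMeans(pos)
  xi_raw <- diff(c(0, z)) / diff(c(0, geom$s_um))
  xi <- pmin(pmax(xi_raw, 0), 1 - 1e-6)
  data.frame(segment = seq_along(xi), xi = xi, xi_raw = xi_raw,
             clipped = xi != xi_raw, nonmonotone = xi_raw < 0,
             z_mean_um = z, s_um = geom$s_um)
}

#' Tension profile from differential extensions
#'
#' Maps each segment's differential extension through the worm-like-chain
#' force-extension relation. Clipping/non-monotonicity flags propagate from
#' [differential_extension()].
#'
#' @param xi data.frame from [differential_extension()], or a bare numeric
#'   vector of extensions in `[0, 1)`.
#' @param model a [wlc_model()].
#' @return Object of class `tension_profile`: data.frame with `segment`,
#'   `xi`, `F_pN` and any propagated flags.
#' @export
tensions_from_extension <- function(xi, model = wlc_model()) {
  if (is.numeric(xi)) {
    xi <- data.frame(segment = seq_along(xi), xi = xi,
                     xi_raw = xi, clipped = FALSE, nonmonotone = FALSE)
  }
  out <- xi
  out$F_pN <- wlc_force(xi$xi, model)
  class(out) <- c("tension_profile", "data.frame")
  out
}

#' @export
print.tension_profile <- function(x, ...) {
  cat("<tension_profile>\n")
  print(as.data.frame(x), digits = 4, ...)
  invisible(x)
}
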