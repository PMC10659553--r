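# Phase-resolved Doppler OCT velocimetry.
#
# Axial red-blood-cell motion between consecutive A-scans imprints a phase
# shift on the complex OCT signal (phase subtraction method). With central
# wavelength lambda0, tissue refractive index n, inter-A-scan interval T
# and Doppler angle theta, the velocity is
#     v = lambda0 * dphi / (4 * pi * n * T * cos(theta)).

#' Doppler conversion constants
#'
#' @param lambda0 central wavelength in mm (default 0.00131).
#' @param n refractive index (default 1.38).
#' @param T inter-A-scan interval in seconds (default 0.000167, i.e. a
#'   6k A-lines/s line rate).
#' @param theta Doppler angle in radians (default 0; vessels are assumed
#'   near-axial, a per-vessel override is allowed downstream).
#' @return object of class `doppler_params`.
#' @export
doppler_params <- function(lambda0 = 0.00131, n = 1.38, T = 0.000167,
                           theta = 0) {
  stopifnot(lambda0 > 0, n > 0, T > 0)
  if (abs(cos(theta)) < 1e-12) stop("cos(theta) must be nonzero")
  structure(list(lambda0 = lambda0, n = n, T = T, theta = theta,
                 v_max = lambda0 / (4 * n * T)),
            class = "doppler_params")
}

#' Interferometer optics of the imaging system
#'
#' @param lambda_nm source center wavelength (nm, default 1310).
#' @param dlambda_fwhm_nm source bandwidth FWHM (nm, default 220).
#' @param na objective numerical aperture (default 0.25).
#' @param tissue_index refractive index of the medium (default 1.38).
#' @return object of class `system_optics`.
#' @export
system_optics <- function(lambda_nm = 1310, dlambda_fwhm_nm = 220,
                          na = 0.25, tissue_index = 1.38) {
  stopifnot(lambda_nm > 0, dlambda_fwhm_nm > 0, na > 0, tissue_index > 0)
  structure(list(lambda_nm = lambda_nm, dlambda_fwhm_nm = dlambda_fwhm_nm,
                 na = na, tissue_index = tissue_index),
            class = "system_optics")
}

#' Axial resolution from the source coherence length
#'
#' `L_c = 2 ln(2) lambda^2 / (pi dlambda_FWHM)`; dividing by the tissue
#' index gives the in-tissue axial resolution.
#'
#' @param optics a [system_optics()].
#' @return list with `lc_um` (in air) and `axial_um` (in tissue).
#' @export
axial_resolution <- function(optics) {
  stopifnot(inherits(optics, "system_optics"))
  lc_nm <- 2 * log(2) * optics$lambda_nm^2 / (pi * optics$dlambda_fwhm_nm)
  list(lc_um = lc_nm / 1000, axial_um = lc_nm / 1000 / optics$tissue_index)
}

#' Diffraction-limited transverse resolution
#'
#' The standard Rayleigh estimate `0.61 lambda / NA`.
#'
#' @param optics a [system_optics()].
#' @return transverse resolution in micrometres.
#' @export
transverse_resolution <- function(optics) {
  stopifnot(inherits(optics, "system_optics"))
  0.61 * optics$lambda_nm / optics$na / 1000
}

#' Phase difference between adjacent A-scans
#'
#' The Doppler phase at each voxel is the argument of the conjugate
#' product of adjacent A-scans, wrapped to (-pi, pi]. Consecutive pair
#' phasors are averaged in the complex domain over a running window of
#' `pair_window` pairs to suppress phase noise.
#'
#' @param ascans complex array whose second dimension indexes repeated
#'   A-scans at each lateral position (`[z, a, ...]`).
#' @param pair_window number of adjacent pairs averaged (default 4).
#' @param wrap_threshold magnitude (radians) above which a phase is
#'   flagged as potentially wrapped (default `0.8 * pi`). True wrapping is
#'   not detectable from a single pair product, so this is a conservative
#'   advisory; phases are wrapped, flagged and never unwrapped here.
#' @return array of phase differences with the A-scan dimension reduced by
#'   one; attribute `wrapped` carries the advisory flags.
#' @export
phase_difference <- function(ascans, pair_window = 4,
                             wrap_threshold = 0.8 * pi) {
  stopifnot(is.complex(ascans))
  d <- dim(ascans)
  if (is.null(d)) stop("ascans must be an array with the A-scan axis second")
  if (d[2L] < 2L) stop("need at least 2 adjacent A-scans per position")
  na <- d[2L]
  perm <- c(2L, seq_along(d)[-2L])
  # flatten to [a-scan, everything-else] for the pair products
  arr <- aperm(ascans, perm)
  dim(arr) <- c(na, prod(d[-2L]))
  pr <- arr[2:na, , drop = FALSE] * Conj(arr[1:(na - 1L), , drop = FALSE])
  np <- na - 1L
  w <- max(1L, min(pair_window, np))
  # running complex sum over the pair axis; Arg() ignores the 1/w factor
  cs <- apply(pr, 2L, cumsum)
  if (np == 1L) cs <- matrix(cs, nrow = 1L)
  lo <- pmax(seq_len(np) - w + 1L, 1L)
  run <- cs - rbind(0 + 0i, cs)[lo, , drop = FALSE]
  dphi <- Arg(run)
  dim(dphi) <- c(np, d[-2L])
  dphi <- aperm(dphi, order(perm))
  attr(dphi, "wrapped") <- abs(dphi) >= wrap_threshold
  dphi
}

#' Convert Doppler phase to flow velocity
#'
#' @param dphi phase-difference array (radians, wrapped to (-pi, pi]).
#' @param params a [doppler_params()].
#' @param theta optional angle override (radians).
#' @return object of class `velocity_map`: `v` (mm/s, same shape as
#'   `dphi`), `wrapped` flags, `params`.
#' @export
phase_to_velocity <- function(dphi, params = doppler_params(),
                              theta = NULL) {
  stopifnot(inherits(params, "doppler_params"))
  th <- if (is.null(theta)) params$theta else theta
  ct <- cos(th)
  if (abs(ct) < 1e-12) stop("cos(theta) must be nonzero")
  v <- params$lambda0 * dphi / (4 * pi * params$n * params$T * ct)
  wrapped <- attr(dphi, "wrapped")
  if (is.null(wrapped)) wrapped <- abs(dphi) >= 0.8 * pi
  structure(list(v = v, wrapped = wrapped, params = params),
            class = "velocity_map")
}

#' @export
print.velocity_map <- function(x, ...) {
  cat(sprintf("<velocity_map> %s voxels, |v| <= %.3f mm/s, %d wrapped\n",
              paste(dim(x$v) %||% length(x$v), collapse = " x "),
              max(abs(x$v)), sum(x$wrapped)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-vessel mean blood-flow velocity
#'
#' Multiple ROIs are placed sequentially along each vessel; the vessel's
#' CBFv is the mean of the per-ROI mean velocities. Vessels whose mean
#' absolute velocity falls below `zero_tol` are reported as 0 mm/s with an
#' occlusion-like flag.
#'
#' @param vmap a [phase_to_velocity()] result (or a plain numeric array).
#' @param vessels named list; each element is a list of ROI index vectors
#'   (or logical arrays) into the velocity array.
#' @param orders optional character vector of order labels per vessel.
#' @param stat per-ROI statistic, `"mean"` (default) or `"max"`.
#' @param zero_tol occlusion threshold (mm/s, default 0.01).
#' @return data.frame: vessel_id, order, mean_v, sd, n_rois,
#'   occlusion_flag.
#' @export
vessel_cbfv <- function(vmap, vessels, orders = NULL, stat = c("mean", "max"),
                        zero_tol = 0.01) {
  stat <- match.arg(stat)
  v <- if (inherits(vmap, "velocity_map")) vmap$v else vmap
  if (is.null(orders)) orders <- rep(NA_character_, length(vessels))
  out <- lapply(seq_along(vessels), function(i) {
    rois <- vessels[[i]]
    if (length(rois) == 0L) stop("vessel without ROIs")
    per_roi <- vapply(rois, function(r) {
      vals <- v[r]
      if (length(vals) == 0L) stop("empty ROI")
      if (stat == "mean") mean(vals) else max(vals)
    }, 0)
    mv <- mean(per_roi)
    occl <- abs(mv) < zero_tol
    data.frame(vessel_id = names(vessels)[i] %||% as.character(i),
               order = orders[i], mean_v = if (occl) 0 else mv,
               sd = if (length(per_roi) > 1L) stats::sd(per_roi) else 0,
               n_rois = length(per_roi), occlusion_flag = occl)
  })
  do.call(rbind, out)
}
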