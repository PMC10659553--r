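# OCT phantom: tubes with known diameters and Doppler-encoded flow, plus
# a capillary network of known skeleton density. The phase volume encodes
#     dphi = 4 * pi * n * T * v * cos(theta) / lambda0
# per voxel, wrapped to (-pi, pi]; the angiogram is the structural mask
# with multiplicative speckle.

.wrap_phase <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Specification of an OCT tube/capillary phantom
#'
#' @param shape volume size `c(nz, nx, ny)` in voxels (default
#'   `c(32, 128, 128)`).
#' @param voxel_um isotropic voxel pitch in micrometres (default 3,
#'   matching a ~3 um transverse resolution).
#' @param tubes list of tubes; each a list with `center` (`c(z, y)` voxel
#'   coordinates, or an `nx x 2` matrix of per-slice centers for a curved
#'   centerline), `diameter_um` (> 0), `v_mm_s` (>= 0), `profile`
#'   (`"plug"` or `"parabolic"`, where `v_mm_s` is the centerline maximum),
#'   and `order` (`"1st"` or `"2nd"`). Tubes run along the x axis.
#' @param capillaries `NULL` or a list with `target_fill` (target skeleton
#'   voxel fraction of the volume), `n_steps` (walk length, default 200)
#'   and `tortuosity` (sd of the per-step direction perturbation,
#'   default 0.3).
#' @param phase_noise_sd additive wrapped phase noise sd (radians,
#'   default 0).
#' @param seed integer RNG seed.
#' @return object of class `oct_phantom_spec`.
#' @export
oct_phantom_spec <- function(shape = c(32, 128, 128), voxel_um = 3,
                             tubes = list(), capillaries = NULL,
                             phase_noise_sd = 0, seed = 1) {
  stopifnot(length(shape) == 3L, all(shape >= 1L), voxel_um > 0,
            phase_noise_sd >= 0)
  if (length(tubes) == 0L && is.null(capillaries))
    stop("phantom needs at least one tube or a capillary network")
  for (tb in tubes) {
    stopifnot(tb$diameter_um > 0, tb$v_mm_s >= 0)
    if (!tb$profile %in% c("plug", "parabolic"))
      stop("profile must be 'plug' or 'parabolic'")
  }
  structure(list(shape = shape, voxel_um = voxel_um, tubes = tubes,
                 capillaries = capillaries,
                 phase_noise_sd = phase_noise_sd, seed = as.integer(seed)),
            class = "oct_phantom_spec")
}

# Rasterize one x-axis tube; returns list(mask, v) as [nz, nx, ny] arrays.
.rasterize_tube <- function(tb, shape, voxel_um) {
  nz <- shape[1L]; nx <- shape[2L]; ny <- shape[3L]
  r_vox <- tb$diameter_um / 2 / voxel_um
  ctr <- tb$center
  if (is.null(dim(ctr))) ctr <- matrix(rep(ctr, each = nx), nx, 2L)
  stopifnot(nrow(ctr) == nx)
  mask <- array(FALSE, shape); v <- array(0, shape)
  zg <- matrix(seq_len(nz), nz, ny)
  yg <- matrix(seq_len(ny), nz, ny, byrow = TRUE)
  for (i in seq_len(nx)) {
    r <- sqrt((zg - ctr[i, 1L])^2 + (yg - ctr[i, 2L])^2)
    inside <- r <= r_vox
    mask[, i, ][inside] <- TRUE
    v[, i, ][inside] <- if (tb$profile == "plug") tb$v_mm_s else
      tb$v_mm_s * (1 - (r[inside] / r_vox)^2)
  }
  list(mask = mask, v = v)
}

# Smoothed 3D random walks rasterized at 1-voxel width until the skeleton
# voxel fraction reaches the target (within 10%).
.gen_capillaries <- function(cap, shape) {
  n_steps <- cap$n_steps %||% 200L
  tort <- cap$tortuosity %||% 0.3
  target <- cap$target_fill
  skel <- array(FALSE, shape)
  total <- prod(shape)
  guard <- 0L
  while (sum(skel) / total < target && guard < 10000L) {
    guard <- guard + 1L
    pos <- stats::runif(3L) * (shape - 1L) + 1
    dir <- stats::rnorm(3L); dir <- dir / sqrt(sum(dir^2))
    for (s in seq_len(n_steps)) {
      dir <- dir + tort * stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir
      vox <- round(pos)
      if (any(vox < 1L) || any(vox > shape)) break
      skel[vox[1L], vox[2L], vox[3L]] <- TRUE
      if (sum(skel) / total >= target) break
    }
  }
  skel
}

#' Generate an OCT phantom with Doppler-encoded flow
#'
#' @param spec an [oct_phantom_spec()].
#' @param params a [doppler_params()] giving the phase-encoding constants.
#' @return list with `angiogram` and `dphi` (`[nz, nx, ny]` arrays),
#'   `labels` (tube label array, capillary skeleton array, true velocity
#'   array), `wrapped` (voxels whose encoded |phase| exceeded pi),
#'   `nyquist_ok`, and the spec. A warning is emitted when the encoding
#'   wraps.
#' @export
gen_oct_phantom <- function(spec, params = doppler_params()) {
  stopifnot(inherits(spec, "oct_phantom_spec"),
            inherits(params, "doppler_params"))
  set.seed(spec$seed)
  shape <- spec$shape
  vol_v <- array(0, shape)
  tube_label <- array(0L, shape)
  for (i in seq_along(spec$tubes)) {
    rt <- .rasterize_tube(spec$tubes[[i]], shape, spec$voxel_um)
    if (!any(rt$mask)) stop("tube ", i, " lies outside the volume")
    vol_v[rt$mask] <- rt$v[rt$mask]
    tube_label[rt$mask] <- i
  }
  caps <- if (is.null(spec$capillaries)) array(FALSE, shape) else
    .gen_capillaries(spec$capillaries, shape)
  ct <- cos(params$theta)
  raw_phi <- 4 * pi * params$n * params$T * vol_v * ct / params$lambda0
  wrapped <- abs(raw_phi) > pi + 1e-12
  if (any(wrapped))
    warning("encoded Doppler phase exceeds pi; wrap recorded")
  dphi <- .wrap_phase(raw_phi)
  if (spec$phase_noise_sd > 0)
    dphi <- .wrap_phase(dphi + spec$phase_noise_sd *
                          stats::rnorm(length(dphi)))
  structure_mask <- tube_label > 0L | caps
  ang <- array(0.05, shape)
  ang[structure_mask] <- 1
  ang <- ang * exp(0.1 * stats::rnorm(length(ang)))  # mild speckle
  list(angiogram = ang, dphi = dphi,
       labels = list(tubes = tube_label, capillaries = caps,
                     v_true = vol_v),
       wrapped = wrapped,
       nyquist_ok = !any(wrapped),
       spec = spec)
}

#' Maximum-intensity projection along the depth axis
#'
#' @param vol `[nz, nx, ny]` array.
#' @return `nx x ny` matrix.
#' @export
mip <- function(vol) {
  stopifnot(length(dim(vol)) == 3L)
  apply(vol, c(2L, 3L), max)
}
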