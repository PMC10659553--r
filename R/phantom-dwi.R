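# Forward-model phantom for the dual-wavelength imaging stage.
#
# A cocaine-like vasoconstrictive transient is modelled as a
# gamma-variate dip with an exponential recovery tail: the unit shape
#     h(u; a) = u^a * exp(a * (1 - u)),   u = t / t_nadir,  a = t_nadir / tau
# equals 1 at the nadir and decays with time constant tau for t >> t_nadir.
# Each tissue compartment carries its own dip; reflectance at the two
# wavelengths follows the Beer-Lambert forward model, so the inversion can
# be validated by round trip.

# Unit transient shape; t_rel and t_nadir in the same unit, tau likewise.
.gamma_dip <- function(t_rel, t_nadir, tau) {
  a <- t_nadir / tau
  u <- pmax(t_rel, 0) / t_nadir
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- exp(a * (log(u[pos]) + 1 - u[pos]))
  out
}

#' Specification of a dual-wavelength imaging phantom
#'
#' @param grid image size `c(ny, nx)` in pixels (default 64 x 64).
#' @param frame_interval seconds between two-wavelength frame pairs
#'   (default 1; only relative timing matters to the metrics).
#' @param baseline_min baseline epoch before the stimulus (minutes,
#'   default 10).
#' @param post_min post-stimulus epoch (minutes, default 30).
#' @param compartments named list (`artery`, `vein`, `tissue`), each with
#'   `amp_pct` (dip amplitude, <= 0 for constriction), `t_nadir_min`,
#'   `tau_min`, `hbo2_frac` (fraction of the HbT change carried by HbO2),
#'   `r568`, `r630` (baseline reflectances). Defaults carry the
#'   artery/vein/tissue contrast of the imaging setup.
#' @param masks named list of logical matrices (`artery`, `vein`,
#'   `tissue`), each the union of >= 3 disjoint ROIs; `NULL` uses a
#'   default 9-rectangle layout (3 ROIs per class).
#' @param baseline_hbt baseline total hemoglobin concentration in the
#'   units the extinction coefficients expect (default `1e-4` M, a
#'   physiological ~100 uM cortical HbT for molar extinctions; use 1 with
#'   an order-1 extinction matrix for arbitrary-unit work). Percent traces
#'   are relative to it.
#' @param noise_sd multiplicative reflectance noise sd (fraction of the
#'   baseline reflectance, default 0).
#' @param seed integer RNG seed.
#' @return object of class `dwi_phantom_spec`.
#' @export
dwi_phantom_spec <- function(grid = c(64, 64), frame_interval = 1,
                             baseline_min = 10, post_min = 30,
                             compartments = NULL, masks = NULL,
                             baseline_hbt = 1e-4, noise_sd = 0, seed = 1) {
  stopifnot(baseline_min > 0, post_min > 0, frame_interval > 0,
            baseline_hbt > 0, noise_sd >= 0)
  if (is.null(compartments)) compartments <- list(
    artery = list(amp_pct = -16.37, t_nadir_min = 2, tau_min = 4,
                  hbo2_frac = 0.9, r568 = 0.35, r630 = 0.85),
    vein   = list(amp_pct = -16.97, t_nadir_min = 2.5, tau_min = 5,
                  hbo2_frac = 0.3, r568 = 0.35, r630 = 0.55),
    tissue = list(amp_pct = -9.56, t_nadir_min = 2.5, tau_min = 5,
                  hbo2_frac = 0.5, r568 = 0.75, r630 = 0.92))
  stopifnot(setequal(names(compartments), c("artery", "vein", "tissue")))
  for (cm in compartments)
    if (cm$amp_pct > 0) stop("dip amplitude must be <= 0 (vasoconstriction)")
  if (is.null(masks)) masks <- .default_masks(grid)
  ov <- Reduce(`+`, lapply(masks, function(m) m != 0))
  if (any(ov > 1)) stop("compartment masks overlap")
  structure(list(grid = grid, frame_interval = frame_interval,
                 baseline_min = baseline_min, post_min = post_min,
                 compartments = compartments, masks = masks,
                 baseline_hbt = baseline_hbt, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "dwi_phantom_spec")
}

# 3 ROI rectangles per class, disjoint, scaled to the grid.
.default_masks <- function(grid) {
  ny <- grid[1L]; nx <- grid[2L]
  bands <- round(seq(1, ny, length.out = 7))
  row_rois <- list(bands[1]:bands[2], bands[3]:bands[4], bands[5]:bands[6])
  cols <- round(seq(1, nx, length.out = 7))
  col_of <- list(artery = cols[1]:cols[2], vein = cols[3]:cols[4],
                 tissue = cols[5]:cols[6])
  out <- lapply(col_of, function(cset) {
    m <- matrix(FALSE, ny, nx)
    for (rr in row_rois) m[rr, cset] <- TRUE
    m
  })
  attr(out, "rois") <- lapply(names(col_of), function(cl) {
    lapply(row_rois, function(rr) {
      m <- matrix(FALSE, ny, nx)
      m[rr, col_of[[cl]]] <- TRUE
      m
    })
  })
  names(attr(out, "rois")) <- names(col_of)
  out
}

#' ROI set of a DWI phantom
#'
#' Splits each compartment of the default layout into its 3 ROIs; custom
#' masks yield one ROI per compartment.
#'
#' @param spec a [dwi_phantom_spec()].
#' @return a [roi_set()].
#' @export
phantom_rois <- function(spec) {
  rois <- attr(spec$masks, "rois")
  if (is.null(rois))
    return(roi_set(unname(spec$masks), names(spec$masks)))
  masks <- unlist(unname(rois), recursive = FALSE)
  roi_set(masks, rep(names(rois), vapply(rois, length, 0L)))
}

#' Generate a dual-wavelength reflectance stack with known ground truth
#'
#' Applies the Beer-Lambert forward model per compartment:
#' `R_l(t) = R_l(0) * exp(-(eps_HbO2 * dHbO2(t) + eps_HbR * dHbR(t)) * L_l)`
#' plus multiplicative Gaussian noise. Identical spec and seed give
#' bit-identical output.
#'
#' @param spec a [dwi_phantom_spec()].
#' @param extinction an [extinction_set()].
#' @return list with `stack` (a [spectral_stack()]) and `truth`: per-class
#'   matrices `pct`, `dhbo2`, `dhbr` (`[t, class]`), the timebase,
#'   injection time (s), and the compartment masks.
#' @export
gen_dwi_stack <- function(spec, extinction = extinction_set()) {
  stopifnot(inherits(spec, "dwi_phantom_spec"),
            inherits(extinction, "extinction_set"))
  set.seed(spec$seed)
  t_inject <- spec$baseline_min * 60
  time <- seq(0, (spec$baseline_min + spec$post_min) * 60,
              by = spec$frame_interval)
  cls <- names(spec$compartments)
  pct <- vapply(cls, function(cl) {
    cm <- spec$compartments[[cl]]
    cm$amp_pct * .gamma_dip((time - t_inject) / 60, cm$t_nadir_min,
                            cm$tau_min)
  }, numeric(length(time)))
  dhbt <- spec$baseline_hbt * pct / 100
  frac <- vapply(cls, function(cl) spec$compartments[[cl]]$hbo2_frac, 0)
  dhbo2 <- sweep(dhbt, 2L, frac, `*`)
  dhbr <- dhbt - dhbo2
  ny <- spec$grid[1L]; nx <- spec$grid[2L]; nt <- length(time)
  E <- extinction$E; L <- extinction$L
  r568 <- array(1, c(ny, nx, nt)); r630 <- array(1, c(ny, nx, nt))
  r0_568 <- matrix(1, ny, nx); r0_630 <- matrix(1, ny, nx)
  for (cl in cls) {
    cm <- spec$compartments[[cl]]
    r0_568[spec$masks[[cl]]] <- cm$r568
    r0_630[spec$masks[[cl]]] <- cm$r630
  }
  base568 <- as.vector(r0_568); base630 <- as.vector(r0_630)
  m568 <- matrix(base568, ny * nx, nt)
  m630 <- matrix(base630, ny * nx, nt)
  for (k in seq_along(cls)) {
    cl <- cls[k]
    idx <- which(as.vector(spec$masks[[cl]]))
    a568 <- exp(-(E[1L, 1L] * dhbo2[, k] + E[1L, 2L] * dhbr[, k]) * L[1L])
    a630 <- exp(-(E[2L, 1L] * dhbo2[, k] + E[2L, 2L] * dhbr[, k]) * L[2L])
    m568[idx, ] <- m568[idx, , drop = FALSE] *
      matrix(a568, length(idx), nt, byrow = TRUE)
    m630[idx, ] <- m630[idx, , drop = FALSE] *
      matrix(a630, length(idx), nt, byrow = TRUE)
  }
  if (spec$noise_sd > 0) {
    m568 <- m568 * (1 + spec$noise_sd * stats::rnorm(length(m568)))
    m630 <- m630 * (1 + spec$noise_sd * stats::rnorm(length(m630)))
    eps <- 1e-6
    m568[m568 < eps] <- eps
    m630[m630 < eps] <- eps
  }
  stack <- spectral_stack(array(m568, c(ny, nx, nt)),
                          array(m630, c(ny, nx, nt)), time,
                          baseline_window = c(0, t_inject))
  list(stack = stack,
       truth = list(pct = pct, dhbo2 = dhbo2, dhbr = dhbr, time = time,
                    t_inject = t_inject, masks = spec$masks,
                    baseline_hbt = spec$baseline_hbt))
}
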