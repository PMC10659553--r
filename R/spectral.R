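# Dual-wavelength reflectance -> hemoglobin concentration changes.
#
# The imaging model: diffuse reflectance at two wavelengths (568 nm, where
# HbO2 and HbR absorb comparably strongly, and 630 nm, where HbR dominates)
# is attenuated by the hemoglobin concentration changes along the optical
# path. Under the modified Beer-Lambert assumption the two absorbance time
# courses invert through a 2x2 extinction matrix to per-pixel
# Delta[HbO2](t) and Delta[HbR](t); their sum is Delta[HbT](t).

#' Molar extinction coefficients and pathlengths for the two-wavelength setup
#'
#' Defaults are taken from the standard compiled whole-blood hemoglobin
#' absorption spectra at 568 and 630 nm, in 1/(M*cm). The pathlengths act
#' as differential pathlength factors; with the default `L = c(1, 1)` the
#' recovered concentration changes are in arbitrary units, which is all the
#' percent-based reactivity metrics need.
#'
#' @param eps_hbo2 extinction of HbO2 at (568, 630) nm.
#' @param eps_hbr extinction of HbR at (568, 630) nm.
#' @param L pathlengths (cm) at (568, 630) nm.
#' @return an object of class `extinction_set`.
#' @export
extinction_set <- function(eps_hbo2 = c(44496, 610),
                           eps_hbr = c(42736, 5148.8),
                           L = c(1, 1)) {
  stopifnot(length(eps_hbo2) == 2L, length(eps_hbr) == 2L, length(L) == 2L,
            all(L > 0))
  E <- cbind(HbO2 = eps_hbo2, HbR = eps_hbr)
  rownames(E) <- c("l568", "l630")
  if (!is.finite(rcond <- 1 / kappa(E)) || rcond < 1e-12)
    stop("extinction matrix is singular or near-singular")
  structure(list(E = E, L = L), class = "extinction_set")
}

#' Two-wavelength reflectance stack
#'
#' Container for a time-resolved dual-wavelength acquisition. Channels are
#' stored as `[y, x, t]` arrays on a common timebase.
#'
#' @param r568,r630 numeric arrays `[y, x, t]`, strictly positive.
#' @param time frame timestamps in seconds.
#' @param baseline_window `c(t0, t1)` in seconds; frames with
#'   `t0 <= t <= t1` define the baseline reference R(0).
#' @return an object of class `spectral_stack`.
#' @export
spectral_stack <- function(r568, r630, time, baseline_window) {
  stopifnot(length(dim(r568)) == 3L, identical(dim(r568), dim(r630)),
            dim(r568)[3L] == length(time), length(baseline_window) == 2L,
            baseline_window[1L] < baseline_window[2L])
  for (ch in list(r568 = r568, r630 = r630)) {
    if (any(!is.finite(ch)) || any(ch <= 0)) {
      bad <- which(apply(ch <= 0 | !is.finite(ch), 3L, any))[1L]
      stop("nonpositive reflectance in frame ", bad)
    }
  }
  if (!any(time >= baseline_window[1L] & time <= baseline_window[2L]))
    stop("no frames inside the baseline window")
  structure(list(r568 = r568, r630 = r630, time = as.numeric(time),
                 wavelengths = c(568, 630),
                 baseline_window = as.numeric(baseline_window)),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$r568)
  cat(sprintf(
    "<spectral_stack> %d x %d px, %d frames (%.1f-%.1f s), baseline %.0f-%.0f s\n",
    d[1], d[2], d[3], min(x$time), max(x$time),
    x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

# Baseline reference: temporal mean over the baseline window, per pixel.
.baseline_ref <- function(stack) {
  idx <- which(stack$time >= stack$baseline_window[1L] &
               stack$time <= stack$baseline_window[2L])
  list(r568 = rowMeans(stack$r568[, , idx, drop = FALSE], dims = 2L),
       r630 = rowMeans(stack$r630[, , idx, drop = FALSE], dims = 2L))
}

#' Invert the modified Beer-Lambert model
#'
#' Solves, per pixel and per frame,
#' `[dHbO2; dHbR] = E^{-1} [ln(R568(0)/R568(t))/L1; ln(R630(0)/R630(t))/L2]`
#' where `R(0)` is the temporal mean over the baseline window.
#'
#' @param stack a [spectral_stack()].
#' @param extinction an [extinction_set()].
#' @return list with `[y, x, t]` arrays `dhbo2`, `dhbr`, `dhbt` and the
#'   timebase.
#' @export
invert_beer_lambert <- function(stack, extinction) {
  stopifnot(inherits(stack, "spectral_stack"),
            inherits(extinction, "extinction_set"))
  Ei <- solve(extinction$E)
  ref <- .baseline_ref(stack)
  a1 <- log(as.vector(ref$r568) / matrix(stack$r568,
        prod(dim(stack$r568)[1:2]))) / extinction$L[1L]
  a2 <- log(as.vector(ref$r630) / matrix(stack$r630,
        prod(dim(stack$r630)[1:2]))) / extinction$L[2L]
  d <- dim(stack$r568)
  dhbo2 <- array(Ei[1L, 1L] * a1 + Ei[1L, 2L] * a2, d)
  dhbr  <- array(Ei[2L, 1L] * a1 + Ei[2L, 2L] * a2, d)
  list(dhbo2 = dhbo2, dhbr = dhbr, dhbt = dhbo2 + dhbr,
       time = stack$time, baseline_window = stack$baseline_window)
}

#' ROI label set
#'
#' @param masks list of logical matrices (one per ROI).
#' @param class character vector, one of `"artery"`, `"vein"`, `"tissue"`
#'   per ROI.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(masks, class) {
  stopifnot(length(masks) == length(class),
            all(class %in% c("artery", "vein", "tissue")))
  if (any(vapply(masks, function(m) sum(m != 0), 0L) == 0L))
    stop("empty ROI mask")
  structure(list(masks = masks, class = as.character(class)),
            class = "roi_set")
}

#' Extract per-ROI hemoglobin time courses
#'
#' Unweighted spatial mean of the pixelwise fields over each ROI mask at
#' each frame. Per-class means are the arithmetic means of that class's ROI
#' series.
#'
#' @param fields result of [invert_beer_lambert()].
#' @param rois a [roi_set()].
#' @param baseline_hbt baseline total-hemoglobin level used as the percent
#'   denominator (inversion units; default 1).
#' @return an object of class `hemo_series`: matrices `[t, roi]` of
#'   `dhbo2`, `dhbr`, `dhbt`, `dhbt_pct`, plus `time`, `roi_class`.
#' @export
roi_timeseries <- function(fields, rois, baseline_hbt = 1) {
  stopifnot(inherits(rois, "roi_set"), baseline_hbt > 0)
  nt <- length(fields$time)
  pick <- function(arr, mask) {
    flat <- matrix(arr, ncol = nt)
    colMeans(flat[as.vector(mask != 0), , drop = FALSE])
  }
  dhbo2 <- vapply(rois$masks, function(m) pick(fields$dhbo2, m), numeric(nt))
  dhbr  <- vapply(rois$masks, function(m) pick(fields$dhbr, m), numeric(nt))
  dhbt  <- dhbo2 + dhbr
  structure(list(time = fields$time, roi_class = rois$class,
                 dhbo2 = dhbo2, dhbr = dhbr, dhbt = dhbt,
                 dhbt_pct = 100 * dhbt / baseline_hbt,
                 baseline_window = fields$baseline_window),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("<hemo_series> %d ROIs (%s), %d frames\n",
              length(x$roi_class), paste(x$roi_class, collapse = ", "),
              length(x$time)))
  invisible(x)
}

#' Per-class mean time course
#'
#' @param series a `hemo_series`.
#' @param what which field to average.
#' @return matrix `[t, class]`.
#' @export
class_mean <- function(series, what = "dhbt_pct") {
  cls <- sort(unique(series$roi_class))
  vapply(cls, function(cl)
    rowMeans(series[[what]][, series$roi_class == cl, drop = FALSE]),
    numeric(length(series$time)))
}

#' Express a total-hemoglobin change as percent of baseline
#'
#' @param dhbt numeric vector/matrix of Delta HbT in inversion units.
#' @param baseline_hbt positive scalar baseline total hemoglobin.
#' @return `100 * dhbt / baseline_hbt`.
#' @export
hbt_percent <- function(dhbt, baseline_hbt) {
  if (!is.numeric(baseline_hbt) || length(baseline_hbt) != 1L ||
      baseline_hbt <= 0)
    stop("baseline_hbt must be a positive scalar")
  100 * dhbt / baseline_hbt
}

#' Baseline-normalized ratio images
#'
#' Per-pixel total-hemoglobin ratio images `1 + dHbT(t)/baseline_hbt` at
#' the requested times (nearest frame), with vessel pixels masked to `NA`.
#' During the baseline window the ratio is ~1 (0% change).
#'
#' @param stack a [spectral_stack()].
#' @param extinction an [extinction_set()].
#' @param times times (s) at which to form images.
#' @param vessel_mask optional logical matrix of vessel pixels to blank.
#' @param baseline_hbt percent denominator, as in [roi_timeseries()].
#' @return list of matrices, one per requested time.
#' @export
ratio_images <- function(stack, extinction, times, vessel_mask = NULL,
                         baseline_hbt = 1) {
  if (any(times < min(stack$time) | times > max(stack$time)))
    stop("requested time outside the record")
  fields <- invert_beer_lambert(stack, extinction)
  lapply(times, function(tt) {
    k <- which.min(abs(stack$time - tt))
    img <- 1 + fields$dhbt[, , k] / baseline_hbt
    if (!is.null(vessel_mask)) img[vessel_mask != 0] <- NA_real_
    img
  })
}

#' Artery/vein contrast hint from baseline absorbance
#'
#' At 630 nm HbR absorbs far more strongly than HbO2, so venous (HbR-rich)
#' ROIs show relatively higher 630-nm baseline absorbance. The score is the
#' ratio of baseline absorbances (630 nm over 568 nm), each measured
#' against the image-median reflectance; identical attenuation in both
#' channels gives 1.0, and higher values lean venous. Advisory only:
#' explicit class labels always take precedence.
#'
#' @param stack a [spectral_stack()].
#' @param rois a [roi_set()].
#' @return named numeric vector of scores, one per ROI.
#' @export
vessel_class_hint <- function(stack, rois) {
  ref <- .baseline_ref(stack)
  score_one <- function(mask) {
    a568 <- -log(mean(ref$r568[mask != 0]) / stats::median(ref$r568))
    a630 <- -log(mean(ref$r630[mask != 0]) / stats::median(ref$r630))
    if (a568 <= 0 && a630 <= 0) return(1)
    if (a568 <= 0) return(Inf)
    max(a630, 0) / a568
  }
  out <- vapply(rois$masks, score_one, 0)
  names(out) <- paste0(rois$class, seq_along(out))
  out
}
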