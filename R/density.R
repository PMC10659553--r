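# Microvascular density mapping: skeletonize the angiogram, count
# skeleton pixels in a sliding w x w window (the vascular fill factor FF),
# and smooth the resulting map. FF(x, y) = ||S(x, y, w)|| / w^2, where S
# is the repaired skeleton and the patch is centred at (x, y).

#' Binarize and skeletonize an angiogram
#'
#' Vesselness scoring (small scales by default, aimed at capillaries),
#' thresholding, and thinning-based skeletonization.
#'
#' @param img single-channel angiogram (raw or preprocessed).
#' @param scales Frangi scales (default 1:3 px).
#' @param threshold `"otsu"` (on nonzero response) or a fixed numeric.
#' @param preprocess run [preprocess_angiogram()] first (default FALSE:
#'   the 3x1 median despeckler belongs to the diameter pipeline and would
#'   erase capillaries only one pixel wide).
#' @return object of class `skeleton_map`: `skeleton` 0/1 matrix, `mask`
#'   (pre-thinning binarization), `repaired = FALSE`.
#' @export
binarize_skeletonize <- function(img, scales = 1:3, threshold = "otsu",
                                 preprocess = FALSE) {
  stopifnot(is.matrix(img))
  if (preprocess) img <- preprocess_angiogram(img)
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1L]) / diff(rng)
  if (diff(range(img)) == 0) {
    z <- matrix(0L, nrow(img), ncol(img))
    return(structure(list(skeleton = z, mask = z, repaired = FALSE),
                     class = "skeleton_map"))
  }
  v <- vesselness(img, scales)
  th <- if (identical(threshold, "otsu")) .otsu_nonzero(v)
        else as.numeric(threshold)
  mask <- matrix(as.integer(v > 0 & v >= th), nrow(img), ncol(img))
  structure(list(skeleton = thin_skeleton(mask), mask = mask,
                 repaired = FALSE),
            class = "skeleton_map")
}

#' Repair breakages in a skeleton
#'
#' Morphological closing (dilation then erosion, 3x3 disk by default)
#' bridges small gaps that imaging noise leaves in skeletonized vessels;
#' re-thinning restores the 1-pixel width. Gaps of up to 2 px along a
#' vessel are bridged; structures farther apart than the structuring
#' element's span stay disconnected.
#'
#' @param skel a `skeleton_map` or 0/1 matrix.
#' @param brush_size structuring-element size in pixels (odd, default 3).
#' @return `skeleton_map` with `repaired = TRUE`.
#' @export
repair_skeleton <- function(skel, brush_size = 3) {
  s <- if (inherits(skel, "skeleton_map")) skel$skeleton else
    matrix(as.integer(skel != 0), nrow(skel), ncol(skel))
  if (sum(s) == 0L)
    return(structure(list(skeleton = s, mask = s, repaired = TRUE),
                     class = "skeleton_map"))
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  closed <- matrix(as.integer(EBImage::closing(s, brush) > 0),
                   nrow(s), ncol(s))
  structure(list(skeleton = thin_skeleton(closed), mask = closed,
                 repaired = TRUE),
            class = "skeleton_map")
}

#' Sliding-window vascular fill factor
#'
#' `FF(x, y)` is the number of skeleton pixels inside the `w x w` patch
#' centred at `(x, y)`, divided by `w^2`. The image is zero-padded: an
#' off-image region contributes no vessels, so FF tapers near borders (the
#' subsequent Gaussian step exists to stabilize those artifacts).
#'
#' @param skel a `skeleton_map` or 0/1 matrix.
#' @param w window size in pixels (default 60, minimum 3).
#' @return object of class `density_map`: `ff` matrix, `w`,
#'   `sigma = NULL` (not yet smoothed). The conventional display range is
#'   0.00-0.15; `ff` itself is never clipped.
#' @export
fill_factor_map <- function(skel, w = 60) {
  s <- if (inherits(skel, "skeleton_map")) skel$skeleton else
    matrix(as.integer(skel != 0), nrow(skel), ncol(skel))
  if (w < 3) stop("w must be >= 3")
  if (w > min(dim(s))) stop("w larger than the image")
  ff <- .box_count(s, w) / w^2
  structure(list(ff = ff, w = w, sigma = NULL), class = "density_map")
}

#' Gaussian smoothing of a density map
#'
#' Reflective-boundary Gaussian filter (sigma = 3 by default); total FF
#' mass away from the borders is conserved.
#'
#' @param dmap a `density_map` (or plain matrix).
#' @param sigma Gaussian standard deviation in pixels (default 3).
#' @return smoothed `density_map`.
#' @export
smooth_density <- function(dmap, sigma = 3) {
  stopifnot(sigma > 0)
  ff <- if (inherits(dmap, "density_map")) dmap$ff else dmap
  out <- gauss_smooth(ff, sigma)
  structure(list(ff = out,
                 w = if (inherits(dmap, "density_map")) dmap$w else NA,
                 sigma = sigma),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d, w = %s, FF in [%.4f, %.4f]%s\n",
              nrow(x$ff), ncol(x$ff), x$w, min(x$ff), max(x$ff),
              if (is.null(x$sigma)) "" else sprintf(", sigma = %g", x$sigma)))
  invisible(x)
}

#' Per-ROI density statistics
#'
#' Maximum and mean fill factor inside each ROI. ROIs must avoid large and
#' medium vessels: if a diameter map is supplied, any ROI containing a
#' pixel with diameter above `max_phi_um` is rejected.
#'
#' @param dmap a `density_map`.
#' @param rois list of logical matrices (ROI masks).
#' @param diameter optional [diameter_from_edt()] result (or phi matrix in
#'   micrometres) used to validate the ROIs.
#' @param max_phi_um vessel-diameter exclusion limit (micrometres,
#'   default 50).
#' @return data.frame: roi_id, ff_max, ff_mean.
#' @export
roi_density_stats <- function(dmap, rois, diameter = NULL,
                              max_phi_um = 50) {
  ff <- if (inherits(dmap, "density_map")) dmap$ff else dmap
  phi <- if (inherits(diameter, "diameter_map")) diameter$phi_um
         else diameter
  out <- lapply(seq_along(rois), function(i) {
    m <- rois[[i]] != 0
    if (!any(m)) stop("empty ROI ", i)
    if (!is.null(phi) && any(phi[m] > max_phi_um))
      stop("ROI ", i, " overlaps a vessel wider than ", max_phi_um,
           " um; choose a capillary-only region")
    data.frame(roi_id = i, ff_max = max(ff[m]), ff_mean = mean(ff[m]))
  })
  do.call(rbind, out)
}
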