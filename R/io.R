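# File exchange: multi-page TIFF for stacks and volumes, JSON sidecars
# for metadata/ground truth, CSV for metric tables.

#' Write a 3D array as a multi-page TIFF
#'
#' Pages are the slices along the last dimension. TIFF samples are stored
#' in [0, 1] at 32 bits; the original value range is kept in a small JSON
#' sidecar (`<path>.json`) and restored by [read_volume_tiff()].
#'
#' @param arr numeric 3D array.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_volume_tiff <- function(arr, path) {
  stopifnot(length(dim(arr)) == 3L, all(is.finite(arr)))
  rng <- range(arr)
  scaled <- if (diff(rng) > 0) (arr - rng[1L]) / diff(rng) else arr * 0
  pages <- lapply(seq_len(dim(arr)[3L]), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(min = rng[1L], max = rng[2L]),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into a 3D array
#'
#' Applies the range stored by [write_volume_tiff()]'s sidecar when
#' present.
#'
#' @param path TIFF file.
#' @return numeric array `[y, x, page]`.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), c(dim(pages[[1L]])[1:2], length(pages)))
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    rng <- jsonlite::read_json(sc)
    arr <- arr * (rng$max - rng$min) + rng$min
  }
  arr
}

#' Write a hemoglobin time-course table as CSV
#'
#' Long-format columns: time_s, roi, roi_class, dHbO2, dHbR, dHbT,
#' dHbT_pct.
#'
#' @param series a `hemo_series`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hemo_csv <- function(series, path) {
  stopifnot(inherits(series, "hemo_series"))
  n_roi <- length(series$roi_class)
  df <- do.call(rbind, lapply(seq_len(n_roi), function(j) data.frame(
    time_s = series$time, roi = j, roi_class = series$roi_class[j],
    dHbO2 = series$dhbo2[, j], dHbR = series$dhbr[, j],
    dHbT = series$dhbt[, j], dHbT_pct = series$dhbt_pct[, j])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a hemoglobin time-course CSV back into a `hemo_series`
#'
#' @param path CSV written by [write_hemo_csv()].
#' @param baseline_window optional `c(t0, t1)` (s).
#' @return a `hemo_series`.
#' @export
read_hemo_csv <- function(path, baseline_window = NULL) {
  df <- utils::read.csv(path)
  rois <- sort(unique(df$roi))
  grab <- function(col) vapply(rois, function(j)
    df[[col]][df$roi == j], numeric(sum(df$roi == rois[1L])))
  structure(list(time = df$time_s[df$roi == rois[1L]],
                 roi_class = vapply(rois, function(j)
                   df$roi_class[df$roi == j][1L], ""),
                 dhbo2 = grab("dHbO2"), dhbr = grab("dHbR"),
                 dhbt = grab("dHbT"), dhbt_pct = grab("dHbT_pct"),
                 baseline_window = baseline_window),
            class = "hemo_series")
}

#' Write a ground-truth or metadata sidecar as JSON
#'
#' @param x list to serialize.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sidecar_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
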