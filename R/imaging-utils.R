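# Low-level raster helpers shared by the morphology and density stages.

#' Separable Gaussian smoothing with reflective boundaries
#'
#' Convolves a 2D image with an isotropic Gaussian kernel, one axis at a
#' time. The image is padded by reflection before each pass so that the
#' total intensity away from the borders is conserved (the property the
#' density stage relies on).
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param radius kernel half-width; defaults to `ceiling(3 * sigma)`.
#' @return smoothed matrix of the same dimension.
#' @export
gauss_smooth <- function(img, sigma, radius = ceiling(3 * sigma)) {
  stopifnot(is.matrix(img), sigma > 0)
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  img <- .conv1_reflect(img, k)          # along rows (dim 1)
  t(.conv1_reflect(t(img), k))           # along columns
}

# 1D convolution along dim 1 with reflect padding, shift-accumulate form.
.conv1_reflect <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(img)
  # reflect indices: 2,3,... mirrored about the first/last row (no repeat)
  top <- pmin(r, n - 1L)
  idx <- c(rev(seq_len(top) + 1L), seq_len(n), n - seq_len(top))
  if (top < r) { # image smaller than kernel half-width: clamp remainder
    idx <- c(rep(idx[1L], r - top), idx, rep(idx[length(idx)], r - top))
  }
  pad <- img[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(img))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# 8-neighbourhood of a binary matrix as shifted copies (zero outside).
.shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0L, n, p)
  rs <- seq_len(n) - dr; cs <- seq_len(p) - dc
  ok_r <- rs >= 1L & rs <= n; ok_c <- cs >= 1L & cs <= p
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Thinning-based skeletonization
#'
#' Iteratively peels a binary mask down to a 1-pixel-wide skeleton using the
#' two-subiteration Zhang-Suen thinning scheme. Connectivity and line
#' endpoints are preserved; a mask that is already 1 pixel wide is returned
#' unchanged.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer 0/1 matrix of the skeleton.
#' @export
thin_skeleton <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours in Zhang-Suen order p2..p9 (clockwise from north)
      p2 <- .shift_mat(m, -1L,  0L); p3 <- .shift_mat(m, -1L,  1L)
      p4 <- .shift_mat(m,  0L,  1L); p5 <- .shift_mat(m,  1L,  1L)
      p6 <- .shift_mat(m,  1L,  0L); p7 <- .shift_mat(m,  1L, -1L)
      p8 <- .shift_mat(m,  0L, -1L); p9 <- .shift_mat(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (j in 1:8) a <- a + (seqs[[j]] == 0L & seqs[[j + 1L]] == 1L)
      if (sub == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- m == 1L & b >= 2L & b <= 6L & a == 1L & cond
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Otsu threshold of the nonzero response values (EBImage's histogram Otsu).
.otsu_nonzero <- function(v) {
  x <- v[v > 0]
  if (length(x) < 2L || diff(range(x)) == 0) return(Inf)
  EBImage::otsu(matrix(x, ncol = 1L), range = range(x))
}

# Exact w x w box counts by summed-area table, zero padding outside the
# image. The patch centred at (i, j) covers rows i - floor((w-1)/2) ..
# i + ceiling((w-1)/2) (and likewise columns), so even w leans one pixel
# towards the bottom/right.
.box_count <- function(m, w) {
  n <- nrow(m); p <- ncol(m)
  lo <- floor((w - 1) / 2); hi <- ceiling((w - 1) / 2)
  sat <- matrix(0, n + 1L, p + 1L)
  sat[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(n) - lo, 1L); r2 <- pmin(seq_len(n) + hi, n)
  c1 <- pmax(seq_len(p) - lo, 1L); c2 <- pmin(seq_len(p) + hi, p)
  sat[r2 + 1L, c2 + 1L] - sat[r1, c2 + 1L] - sat[r2 + 1L, c1] + sat[r1, c1]
}
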