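# Small builders shared across the test files.

iou <- function(a, b) sum(a & b) / sum(a | b)

# Short-record DWI phantom spec (keeps stacks small).
small_dwi_spec <- function(...) {
  dwi_phantom_spec(grid = c(24, 24), frame_interval = 5, baseline_min = 2,
                   post_min = 6, ...)
}

# Two-bar angiogram (8 px and 80 px wide) with ground truth.
two_bar_image <- function(noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  img <- matrix(0, 200, 220)
  img[40:47, 20:200] <- 1
  img[100:179, 20:200] <- 1
  list(gt = img,
       img = img + noise_sd * matrix(stats::rnorm(length(img)), nrow(img)),
       small_rows = 30:57, large_rows = 90:190)
}

# Straight complex A-scan block with an imposed per-step phase ramp.
phase_ramp_ascans <- function(nz = 4, na = 6, ny = 3, step = 0.3) {
  A <- array(complex(modulus = 1, argument = 0), c(nz, na, ny))
  for (j in seq_len(na))
    A[, j, ] <- complex(modulus = 1, argument = step * (j - 1))
  A
}
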