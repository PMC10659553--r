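# Beer-Lambert inversion and ROI extraction.

test_that("constant reflectance inverts to zero concentration change", {
  sp <- small_dwi_spec(compartments = list(
    artery = list(amp_pct = 0, t_nadir_min = 1, tau_min = 1,
                  hbo2_frac = 0.9, r568 = 0.4, r630 = 0.8),
    vein = list(amp_pct = 0, t_nadir_min = 1, tau_min = 1,
                hbo2_frac = 0.3, r568 = 0.4, r630 = 0.5),
    tissue = list(amp_pct = 0, t_nadir_min = 1, tau_min = 1,
                  hbo2_frac = 0.5, r568 = 0.8, r630 = 0.9)))
  g <- gen_dwi_stack(sp)
  # zero-amplitude transients, zero noise: stack constant in time
  expect_equal(g$stack$r568[, , 5], g$stack$r568[, , 1])
  f <- invert_beer_lambert(g$stack, extinction_set())
  expect_equal(max(abs(f$dhbo2)), 0)
  expect_equal(max(abs(f$dhbr)), 0)
})

test_that("noiseless forward model round-trips through the inversion", {
  sp <- small_dwi_spec()
  ext <- extinction_set()
  g <- gen_dwi_stack(sp, ext)
  f <- invert_beer_lambert(g$stack, ext)
  hs <- roi_timeseries(f, phantom_rois(sp),
                       baseline_hbt = g$truth$baseline_hbt)
  cm <- class_mean(hs, "dhbt_pct")
  for (cl in c("artery", "vein", "tissue")) {
    rel <- max(abs(cm[, cl] - g$truth$pct[, cl])) /
      max(abs(g$truth$pct[, cl]))
    expect_lt(rel, 1e-9)
  }
  # additivity to machine precision
  expect_equal(hs$dhbt, hs$dhbo2 + hs$dhbr, tolerance = 1e-14)
})

test_that("inversion recovers imposed (dHbO2, dHbR) and is linear", {
  # constant fields dHbO2 = +5, dHbR = -2 in a.u. with L = 1
  ext <- extinction_set(eps_hbo2 = c(2, 0.5), eps_hbr = c(1.5, 3))
  time <- 0:9
  E <- ext$E
  att <- function(o, r) exp(-(E[, 1] * o + E[, 2] * r))
  r568 <- array(1, c(4, 4, 10)); r630 <- array(1, c(4, 4, 10))
  for (k in 6:10) {
    a <- att(5, -2)
    r568[, , k] <- a[1]; r630[, , k] <- a[2]
  }
  st <- spectral_stack(r568, r630, time, baseline_window = c(0, 4))
  f <- invert_beer_lambert(st, ext)
  expect_equal(f$dhbo2[2, 2, 8], 5, tolerance = 1e-9)
  expect_equal(f$dhbr[2, 2, 8], -2, tolerance = 1e-9)
  # doubling the imposed changes doubles the recovery
  for (k in 6:10) {
    a <- att(10, -4)
    r568[, , k] <- a[1]; r630[, , k] <- a[2]
  }
  f2 <- invert_beer_lambert(spectral_stack(r568, r630, time, c(0, 4)), ext)
  expect_equal(f2$dhbo2[1, 1, 8], 10, tolerance = 1e-9)
  expect_equal(f2$dhbr[1, 1, 8], -4, tolerance = 1e-9)
})

test_that("inversion agrees with an independent per-pixel 2x2 solve", {
  sp <- small_dwi_spec(noise_sd = 0.01, seed = 42)
  ext <- extinction_set()
  g <- gen_dwi_stack(sp, ext)
  f <- invert_beer_lambert(g$stack, ext)
  ref <- vasoreact:::.baseline_ref(g$stack)
  set.seed(7)
  for (rep in 1:100) {
    i <- sample(24, 1); j <- sample(24, 1); k <- sample(dim(g$stack$r568)[3], 1)
    y <- c(log(ref$r568[i, j] / g$stack$r568[i, j, k]) / ext$L[1],
           log(ref$r630[i, j] / g$stack$r630[i, j, k]) / ext$L[2])
    sol <- solve(ext$E, y)
    expect_equal(f$dhbo2[i, j, k], sol[[1]], tolerance = 1e-10)
    expect_equal(f$dhbr[i, j, k], sol[[2]], tolerance = 1e-10)
  }
})

test_that("singular extinction matrix and bad reflectance are rejected", {
  expect_error(extinction_set(eps_hbo2 = c(2, 4), eps_hbr = c(1, 2)),
               "singular")
  r <- array(1, c(2, 2, 3)); r2 <- r; r2[1, 1, 2] <- -1
  expect_error(spectral_stack(r2, r, 0:2, c(0, 1)), "frame 2")
})

test_that("roi_timeseries averages masks correctly", {
  time <- 0:5
  f <- list(dhbo2 = array(0, c(4, 4, 6)), dhbr = array(0, c(4, 4, 6)),
            time = time, baseline_window = c(0, 2))
  f$dhbo2[1, 1, ] <- 1:6        # pixel trace
  f$dhbo2[3, 3, ] <- 3 * (1:6)
  m1 <- matrix(FALSE, 4, 4); m1[1, 1] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[3, 3] <- TRUE
  f$dhbt <- f$dhbo2
  hs <- roi_timeseries(f, roi_set(list(m1, m2), c("artery", "artery")))
  # one-pixel mask returns the pixel trace
  expect_equal(hs$dhbo2[, 1], as.numeric(1:6))
  # class mean is the pointwise mean of the two ROI series
  expect_equal(class_mean(hs, "dhbo2")[, "artery"], (1:6 + 3 * (1:6)) / 2)
  expect_error(roi_set(list(matrix(FALSE, 4, 4)), "vein"), "empty")
})

test_that("hbt_percent scales and validates", {
  expect_equal(hbt_percent(numeric(10), 2), numeric(10))
  expect_equal(hbt_percent(rep(-0.1 * 7, 4), 7), rep(-10, 4))
  expect_error(hbt_percent(1, 0), "positive")
})

test_that("ratio images are ~1 at baseline and mask vessels", {
  sp <- small_dwi_spec()
  ext <- extinction_set()
  g <- gen_dwi_stack(sp, ext)
  base_img <- ratio_images(g$stack, ext, times = 30,
                           baseline_hbt = g$truth$baseline_hbt)[[1]]
  expect_equal(max(abs(base_img - 1)), 0, tolerance = 1e-9)
  vm <- matrix(TRUE, 24, 24)
  masked <- ratio_images(g$stack, ext, times = 30, vessel_mask = vm)[[1]]
  expect_true(all(is.na(masked)))
  expect_error(ratio_images(g$stack, ext, times = 1e6), "outside")
  # at the tissue nadir the tissue pixels match the configured dip
  t_nadir <- g$truth$t_inject + sp$compartments$tissue$t_nadir_min * 60
  img <- ratio_images(g$stack, ext, times = t_nadir,
                      baseline_hbt = g$truth$baseline_hbt)[[1]]
  tis <- 100 * (mean(img[sp$masks$tissue]) - 1)
  expect_equal(tis, sp$compartments$tissue$amp_pct, tolerance = 0.2)
})

test_that("baseline absorbance ratio separates arteries from veins", {
  sp <- small_dwi_spec()
  g <- gen_dwi_stack(sp)
  rois <- roi_set(unname(sp$masks), names(sp$masks))
  sc <- vessel_class_hint(g$stack, rois)
  expect_gt(sc[["vein2"]], sc[["artery1"]])
})

test_that("appending baseline frames does not change the metrics", {
  sp <- small_dwi_spec()
  ext <- extinction_set()
  g <- gen_dwi_stack(sp, ext)
  hs <- roi_timeseries(invert_beer_lambert(g$stack, ext), phantom_rois(sp),
                       baseline_hbt = g$truth$baseline_hbt)
  tr <- class_mean(hs, "dhbt_pct")[, "artery"]
  m1 <- cvr_metrics(tr, g$stack$time, g$truth$t_inject, smooth_window = 0,
                    baseline_stats = list(mean = 0, sd = 0.25))
  # prepend 60 s of constant baseline, shift times accordingly
  nadd <- 12
  tr2 <- c(rep(0, nadd), tr)
  t2 <- c(seq(-60, -5, by = 5), g$stack$time)
  m2 <- cvr_metrics(tr2, t2, g$truth$t_inject, smooth_window = 0,
                    baseline_stats = list(mean = 0, sd = 0.25))
  expect_equal(m1$peak_pct, m2$peak_pct)
  expect_equal(m1$rt_min, m2$rt_min)
  expect_equal(m1$ir_pct_min, m2$ir_pct_min)
})
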