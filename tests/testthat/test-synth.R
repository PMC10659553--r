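# Generators: determinism, ground-truth fidelity, noise behaviour.

test_that("generators are seed-deterministic", {
  sp <- small_dwi_spec(noise_sd = 0.01, seed = 11)
  g1 <- gen_dwi_stack(sp); g2 <- gen_dwi_stack(sp)
  expect_identical(g1$stack$r568, g2$stack$r568)
  expect_identical(g1$stack$r630, g2$stack$r630)
  so <- oct_phantom_spec(shape = c(12, 24, 24), tubes = list(
    list(center = c(6, 12), diameter_um = 24, v_mm_s = 0.5,
         profile = "plug", order = "1st")), phase_noise_sd = 0.05,
    seed = 3)
  p1 <- gen_oct_phantom(so); p2 <- gen_oct_phantom(so)
  expect_identical(p1$dphi, p2$dphi)
  expect_identical(p1$angiogram, p2$angiogram)
  cs <- cohort_spec(seed = 5)
  c1 <- gen_cohort(cs); c2 <- gen_cohort(cs)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$traces, c2$traces)
})

test_that("phantom spec invariants are enforced", {
  expect_error(dwi_phantom_spec(baseline_min = 0), "positive|> 0")
  bad <- list(artery = list(amp_pct = 5, t_nadir_min = 1, tau_min = 1,
                            hbo2_frac = 0.9, r568 = 0.4, r630 = 0.8),
              vein = list(amp_pct = 0, t_nadir_min = 1, tau_min = 1,
                          hbo2_frac = 0.3, r568 = 0.4, r630 = 0.5),
              tissue = list(amp_pct = 0, t_nadir_min = 1, tau_min = 1,
                            hbo2_frac = 0.5, r568 = 0.8, r630 = 0.9))
  expect_error(small_dwi_spec(compartments = bad), "vasoconstriction")
  m <- matrix(TRUE, 24, 24)
  expect_error(small_dwi_spec(masks = list(artery = m, vein = m,
                                           tissue = m)), "overlap")
  expect_error(oct_phantom_spec(tubes = list()), "at least one")
  expect_error(oct_phantom_spec(tubes = list(
    list(center = c(1, 1), diameter_um = -3, v_mm_s = 1,
         profile = "plug", order = "1st"))), "diameter|> 0")
})

test_that("phase encoding matches the hand-evaluated constants", {
  # plug flow at 1.421 mm/s encodes dphi = pi at every tube voxel
  v_pi <- 0.00131 / (4 * 1.38 * 0.000167)
  sp <- oct_phantom_spec(shape = c(16, 24, 24), tubes = list(
    list(center = c(8, 12), diameter_um = 24, v_mm_s = v_pi,
         profile = "plug", order = "1st")))
  ph <- gen_oct_phantom(sp)
  inside <- ph$labels$tubes == 1
  expect_equal(range(ph$dphi[inside]), c(pi, pi), tolerance = 1e-12)
  # above the Nyquist velocity the generator warns and records the wrap
  sp2 <- oct_phantom_spec(shape = c(16, 24, 24), tubes = list(
    list(center = c(8, 12), diameter_um = 24, v_mm_s = 1.1 * v_pi,
         profile = "plug", order = "1st")))
  expect_warning(ph2 <- gen_oct_phantom(sp2), "wrap")
  expect_true(all(ph2$wrapped[ph2$labels$tubes == 1]))
  expect_false(ph2$nyquist_ok)
})

test_that("capillary fill fraction hits its target within 10%", {
  for (target in c(0.002, 0.006)) {
    sp <- oct_phantom_spec(shape = c(20, 100, 100),
                           capillaries = list(target_fill = target),
                           seed = 2)
    ph <- gen_oct_phantom(sp)
    frac <- sum(ph$labels$capillaries) / prod(sp$shape)
    expect_lt(abs(frac - target) / target, 0.1)
  }
})

test_that("zero-sd cohorts reproduce the group means exactly", {
  cs <- cohort_spec(seed = 1)
  # zero out every sd
  for (g in names(cs$cvr)) for (cl in names(cs$cvr[[g]]))
    for (m in names(cs$cvr[[g]][[cl]])) cs$cvr[[g]][[cl]][[m]][2] <- 0
  for (g in names(cs$flow)) for (o in names(cs$flow[[g]]))
    for (m in names(cs$flow[[g]][[o]])) cs$flow[[g]][[o]][[m]][2] <- 0
  for (g in names(cs$density)) for (m in names(cs$density[[g]]))
    cs$density[[g]][[m]][2] <- 0
  cs$roi_density_sd <- 0
  co <- gen_cohort(cs)
  wt_art <- co$truth[co$truth$group == "WT" & co$truth$class == "artery", ]
  expect_equal(unique(wt_art$value[wt_art$metric == "peak_pct"]), -16.37)
  expect_equal(unique(wt_art$value[wt_art$metric == "ir_pct_min"]), -147.97)
  expect_equal(unique(wt_art$value[wt_art$metric == "rt_min"]), 14.96)
  expect_equal(unique(co$vessels$v[co$vessels$group == "WT" &
                                   co$vessels$order == "1st"]), 0.787)
  expect_equal(unique(co$density$ff_max[co$density$group == "WT"]), 0.1045)
})

test_that("large cohorts concentrate on the published artery peak", {
  cs <- cohort_spec(n_cvr = list(WT = c(M = 2500, F = 2500),
                                 AD = c(M = 1, F = 1)), seed = 9)
  co <- gen_cohort(cs)
  sel <- co$truth$group == "WT" & co$truth$class == "artery" &
    co$truth$metric == "peak_pct"
  expect_equal(mean(co$truth$value[sel]), -16.37, tolerance = 0.1)
})

test_that("recovered-trace error grows with trace noise", {
  # RMSE of estimated artery IR vs truth, averaged over seeds, should not
  # decrease when the trace noise doubles
  rmse_at <- function(noise_sd, seeds) {
    errs <- vapply(seeds, function(s) {
      cs <- cohort_spec(n_cvr = list(WT = c(M = 2, F = 2),
                                     AD = c(M = 2, F = 2)),
                        trace_noise_sd = noise_sd, seed = s)
      co <- gen_cohort(cs)
      est <- cohort_cvr_metrics(co)
      tr <- co$truth
      sel <- tr$class == "artery" & tr$metric == "ir_pct_min"
      sq <- (est$value[est$class == "artery" &
                       est$metric == "ir_pct_min"] - tr$value[sel])^2
      mean(sq)
    }, 0)
    sqrt(mean(errs))
  }
  seeds <- 1:12
  expect_lte(rmse_at(0.25, seeds), rmse_at(1, seeds))
})

test_that("the dip shape solver reproduces drawn metric triples", {
  thr <- 0.5
  cases <- list(c(-16.37, -147.97, 14.96), c(-13.21, -57.17, 7.61),
                c(-9.56, -96.37, 15.93), c(-16.97, -142.49, 16.40))
  tm <- seq(0, 2400, 0.5); tin <- 600
  for (cs in cases) {
    sh <- vasoreact:::.solve_shape(cs[1], cs[2], cs[3], thr)
    x <- cs[1] * vasoreact:::.dip_shape((tm - tin) / 60, sh$t_rise,
                                        sh$t_hold, sh$tau, sh$alpha)
    m <- cvr_metrics(x, tm, tin, smooth_window = 0,
                     baseline_stats = list(mean = 0, sd = thr))
    expect_equal(m$peak_pct, cs[1], tolerance = 1e-6)
    expect_equal(m$rt_min, cs[3], tolerance = 0.05)
    expect_equal(m$ir_pct_min, cs[2], tolerance = abs(cs[2]) * 0.01)
  }
})
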