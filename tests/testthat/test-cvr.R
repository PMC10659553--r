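# Reactivity metrics and group statistics.

test_that("flat traces yield null metrics", {
  tm <- seq(0, 1200); x <- numeric(length(tm))
  expect_equal(peak_response(x, tm, 300), 0)
  rt <- recovery_time(x, tm, 300, baseline_stats = list(mean = 0, sd = 0.1))
  expect_equal(rt$rt_min, 0)
  expect_true(rt$recovered)
  expect_equal(rt$note, "no response")
  expect_equal(integrated_reactivity(x, tm, 300, rt$rt_min), 0)
})

test_that("peak equals the brute-force minimum of the smoothed samples", {
  set.seed(11)
  tm <- seq(0, 1800)
  x <- -8 * exp(-((tm - 700) / 180)^2) + 0.4 * rnorm(length(tm))
  w <- 30
  p <- peak_response(x, tm, 300, smooth_window = w)
  sm <- vapply(seq_along(tm), function(i)
    mean(x[abs(tm - tm[i]) <= w / 2]), 0)
  expect_equal(p, min(sm[tm > 300]))
})

test_that("step dip recovers at the constructed crossing", {
  tm <- seq(0, 1800); tin <- 300
  x <- ifelse(tm > tin & tm <= tin + 300, -10, 0)  # returns at tin + 5 min
  rt <- recovery_time(x, tm, tin, baseline_stats = list(mean = 0, sd = 0.5),
                      smooth_window = 0)
  expect_equal(rt$rt_min, 5, tolerance = 1 / 60 + 1e-9)
  expect_true(rt$recovered)
})

test_that("exponential recovery crosses at the closed-form time", {
  tm <- seq(0, 2400); tin <- 600; tn <- 900
  for (tau in c(90, 150)) for (s in c(0.3, 0.8)) {
    A <- 12
    x <- ifelse(tm <= tn,
                ifelse(tm > tin, -A * (tm - tin) / (tn - tin), 0),
                -A * exp(-(tm - tn) / tau))
    rt <- recovery_time(x, tm, tin, k = 1, smooth_window = 0,
                        baseline_stats = list(mean = 0, sd = s))
    expected <- ((tn - tin) + tau * log(A / s)) / 60
    expect_equal(rt$rt_min, expected, tolerance = 2 / 60)  # one sample
  }
})

test_that("never-recovering trace reports record length and is flagged", {
  tm <- seq(0, 1200); tin <- 300
  x <- ifelse(tm > tin, -10, 0)
  rt <- recovery_time(x, tm, tin, baseline_stats = list(mean = 0, sd = 0.5),
                      smooth_window = 0)
  expect_false(rt$recovered)
  expect_equal(rt$rt_min, (max(tm) - tin) / 60)
})

test_that("IR matches closed-form areas of rectangular and triangular dips", {
  tm <- seq(0, 1500, by = 0.5); tin <- 120
  rect <- ifelse(tm > tin & tm <= tin + 300, -10, 0)
  expect_equal(integrated_reactivity(rect, tm, tin, rt_min = 5,
                                     smooth_window = 0), -50,
               tolerance = 0.1)
  tri <- ifelse(tm > tin & tm <= tin + 600,
                -10 * (1 - abs(tm - tin - 300) / 300), 0)
  expect_equal(integrated_reactivity(tri, tm, tin, rt_min = 10,
                                     smooth_window = 0), -50,
               tolerance = 0.01)
  # zero-length recovery gives zero area
  expect_equal(integrated_reactivity(rect, tm, tin, rt_min = 0), 0)
})

test_that("metrics are scale-equivariant and time-shift invariant", {
  set.seed(3)
  tm <- seq(0, 2400); tin <- 600
  x <- -10 * vasoreact:::.dip_shape((tm - tin) / 60, 1.5, 4, 2) +
    0.3 * rnorm(length(tm))
  bs <- list(mean = 0, sd = 0.3)
  m <- cvr_metrics(x, tm, tin, baseline_stats = bs)
  # scaling the trace (and the band consistently) scales peak and IR
  cc <- 2.5
  m_sc <- cvr_metrics(cc * x, tm, tin,
                      baseline_stats = list(mean = 0, sd = cc * 0.3))
  expect_equal(m_sc$peak_pct, cc * m$peak_pct, tolerance = 1e-9)
  expect_equal(m_sc$ir_pct_min, cc * m$ir_pct_min, tolerance = 1e-9)
  expect_equal(m_sc$rt_min, m$rt_min)
  # shifting injection and trace together changes nothing
  m_sh <- cvr_metrics(x, tm + 500, tin + 500, baseline_stats = bs)
  expect_equal(m_sh$peak_pct, m$peak_pct)
  expect_equal(m_sh$ir_pct_min, m$ir_pct_min, tolerance = 1e-9)
  expect_equal(m_sh$rt_min, m$rt_min)
  # a zero tail appended after recovery changes nothing
  m_tail <- cvr_metrics(c(x, numeric(600)), c(tm, max(tm) + 1:600), tin,
                        baseline_stats = bs)
  expect_equal(m_tail$peak_pct, m$peak_pct)
  expect_equal(m_tail$ir_pct_min, m$ir_pct_min, tolerance = 1e-9)
  expect_equal(m_tail$rt_min, m$rt_min)
})

test_that("pooled t-test matches the hand computation", {
  tt <- group_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0213, tolerance = 1e-3)
  same <- group_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(group_ttest(c(1, 1), c(2, 2)), "zero pooled variance")
})

test_that("two-way ANOVA matches a manual sums-of-squares decomposition", {
  # balanced 2x2, two replicates per cell
  v <- c(10, 12, 20, 22, 30, 32, 44, 46)
  sx <- rep(c("M", "F"), each = 4)
  gr <- rep(c("WT", "AD", "WT", "AD"), each = 2)
  res <- sex_by_group_anova(v, sx, gr)
  # manual: cell means 11, 21, 31, 45; grand 27
  # SS_sex = 968, SS_group = 288, SS_int = 8, SS_res = 8, df_res = 4
  f <- function(eff) res$anova$F[res$anova$effect == eff]
  expect_equal(f("sex"), (968 / 1) / (8 / 4), tolerance = 1e-10)
  expect_equal(f("group"), (288 / 1) / (8 / 4), tolerance = 1e-10)
  expect_equal(f("sex:group"), (8 / 1) / (8 / 4), tolerance = 1e-10)
  # swapping the factor labels leaves the interaction unchanged
  res2 <- sex_by_group_anova(v, gr, sx)
  expect_equal(f("sex:group"),
               res2$anova$F[res2$anova$effect == "sex:group"])
  # equal cell means with noise: all F ~ 0 is not required, but p = 1
  v0 <- c(5, 7, 5, 7, 5, 7, 5, 7)
  res0 <- sex_by_group_anova(v0, sx, gr)
  expect_true(all(res0$anova$F < 1e-20))
  expect_true(all(res0$anova$p > 0.999))
  expect_error(sex_by_group_anova(v[1:6], sx[1:6], gr[1:6]), "empty")
})

test_that("Bonferroni post-hoc multiplies p by the family size, capped", {
  set.seed(5)
  v <- c(rnorm(6), rnorm(6) + 5, rnorm(6), rnorm(6) + 5)
  sx <- rep(c("M", "F"), each = 12)
  gr <- rep(rep(c("WT", "AD"), each = 6), 2)
  res <- sex_by_group_anova(v, sx, gr)
  raw <- group_ttest(v[sx == "F" & gr == "WT"], v[sx == "F" & gr == "AD"])$p
  got <- res$posthoc$p_adj[res$posthoc$comparison == "WT vs AD | sex 1"]
  expect_equal(got, min(1, raw * 4))
  expect_true(all(res$posthoc$p_adj <= 1))
})

test_that("the RT estimator is unbiased at the published WT artery value", {
  cs <- cohort_spec(n_cvr = list(WT = c(M = 500, F = 500),
                                 AD = c(M = 1, F = 1)), seed = 21)
  co <- gen_cohort(cs)
  est <- cohort_cvr_metrics(co)
  sel <- est$group == "WT" & est$class == "artery" & est$metric == "rt_min"
  expect_equal(mean(est$value[sel]), 14.96, tolerance = 0.5 / 14.96)
})
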