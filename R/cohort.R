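# Synthetic WT/AD cohorts parameterized by the published group
# statistics, with per-animal ground truth. CVR metrics are realized as
# actual Delta[HbT]% traces (so the full metric-extraction chain is
# exercised); flow, diameter and density entries are per-animal
# measurement records, since those group statistics summarize per-animal
# numbers rather than images.

# ---- dip shape machinery ----------------------------------------------
# A rise-plateau-exponential dip: unit depth is reached over a rise time
# t_r (power-law rise u^alpha), held for a plateau Th, then released with
# an exponential tail of time constant tau. With q = threshold / |peak|,
# the drawn triple (peak P, integrated reactivity I, recovery time R)
# fixes (Th, tau) in closed form:
#     R = t_r + Th + tau * ln(1/q)
#     |I|/|P| = t_r / (alpha + 1) + Th + tau * (1 - q)
# (A one-parameter gamma-variate tail cannot reach the mean/peak ratios
# the published triples imply, which is why the plateau exists.)

.dip_shape <- function(t_rel, t_rise, t_hold, tau, alpha = 2) {
  h <- numeric(length(t_rel))
  rise <- t_rel > 0 & t_rel < t_rise
  h[rise] <- (t_rel[rise] / t_rise)^alpha
  h[t_rel >= t_rise & t_rel <= t_rise + t_hold] <- 1
  tail_i <- t_rel > t_rise + t_hold
  h[tail_i] <- exp(-(t_rel[tail_i] - t_rise - t_hold) / tau)
  h
}

# Solve (t_hold, tau) for one (P, I, R) draw; all times in minutes.
# Infeasible draws are clamped to the nearest feasible shape.
.solve_shape <- function(peak, ir, rt, threshold_pct, t_rise = 1.5,
                         alpha = 2) {
  q <- min(max(threshold_pct / abs(peak), 1e-6), 0.9)
  t_rise <- min(t_rise, rt / 2)
  ia <- abs(ir) / abs(peak)                    # target area of unit shape
  lq <- log(1 / q)
  denom <- lq - (1 - q)                        # > 0 for q < 1
  tau <- (rt - ia - t_rise * alpha / (alpha + 1)) / denom
  tau <- max(tau, 1e-3)
  t_hold <- rt - t_rise - tau * lq
  if (t_hold < 0) {                            # IR too large for this RT
    t_hold <- 0
    tau <- max((rt - t_rise) / lq, 1e-3)
  }
  list(t_rise = t_rise, t_hold = t_hold, tau = tau, alpha = alpha)
}

#' Specification of a synthetic WT/AD cohort
#'
#' All distribution defaults are the published group values: per-animal
#' draws are normal with the printed mean and the printed dispersion.
#' Three sub-cohorts mirror the study design: the reactivity cohort
#' (WT 4M + 4F, AD 6M + 6F), the flow/diameter cohort (6 animals per
#' group), and the density cohort (9 WT, 6 AD).
#'
#' @param n_cvr named list `list(WT = c(M =, F =), AD = c(M =, F =))`.
#' @param n_flow animals per group in the flow/diameter sub-cohort.
#' @param n_density `c(WT =, AD =)` animals in the density sub-cohort.
#' @param cvr nested list `cvr[[group]][[class]]` with `peak = c(mean, sd)`
#'   (%), `ir = c(mean, sd)` (%*min), `rt = c(mean, sd)` (min), for
#'   classes `vein`, `artery`, `tissue`.
#' @param flow list `flow[[group]][[order]]` with `v = c(mean, sd)` (mm/s)
#'   and `phi = c(mean, sd)` (um) for orders `1st`, `2nd`.
#' @param density list `density[[group]]` with `max = c(mean, sd)` and
#'   `mean = c(mean, sd)` (fill-factor units).
#' @param n_rois ROI traces per class per animal (default 3).
#' @param trace_noise_sd baseline noise sd of the per-class mean trace
#'   (% units, default 0.5); each ROI trace gets `sqrt(n_rois)` times
#'   this so the class mean has the stated noise level.
#' @param roi_density_sd ROI-to-ROI jitter of the density readings
#'   (default 0.002).
#' @param frame_interval trace sampling interval (s, default 1).
#' @param baseline_min,post_min epoch durations (min, defaults 10 / 30).
#' @param k recovery-band width in baseline sds (default 1; must match
#'   the analysis setting for the drawn RT to be the true crossing time).
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cvr = list(WT = c(M = 4, F = 4),
                                     AD = c(M = 6, F = 6)),
                        n_flow = c(WT = 6, AD = 6),
                        n_density = c(WT = 9, AD = 6),
                        cvr = NULL, flow = NULL, density = NULL,
                        n_rois = 3, trace_noise_sd = 0.5,
                        roi_density_sd = 0.002, frame_interval = 1,
                        baseline_min = 10, post_min = 30, k = 1,
                        seed = 1) {
  if (is.null(cvr)) cvr <- list(
    WT = list(vein   = list(peak = c(-16.97, 1.22), ir = c(-142.49, 22.29),
                            rt = c(16.40, 1.60)),
              artery = list(peak = c(-16.37, 1.04), ir = c(-147.97, 26.09),
                            rt = c(14.96, 1.38)),
              tissue = list(peak = c(-9.56, 1.00), ir = c(-96.37, 20.59),
                            rt = c(15.93, 1.51))),
    AD = list(vein   = list(peak = c(-16.09, 1.61), ir = c(-91.92, 13.40),
                            rt = c(11.41, 1.44)),
              artery = list(peak = c(-13.21, 1.13), ir = c(-57.17, 7.41),
                            rt = c(7.61, 1.03)),
              tissue = list(peak = c(-7.45, 0.47), ir = c(-31.48, 4.21),
                            rt = c(7.46, 0.91))))
  if (is.null(flow)) flow <- list(
    WT = list(`1st` = list(v = c(0.787, 0.014), phi = c(79.28, 2.54)),
              `2nd` = list(v = c(0.746, 0.025), phi = c(72.20, 2.94))),
    AD = list(`1st` = list(v = c(0.624, 0.075), phi = c(78.61, 3.09)),
              `2nd` = list(v = c(0.537, 0.043), phi = c(63.77, 3.12))))
  if (is.null(density)) density <- list(
    WT = list(max = c(0.1045, 0.0034), mean = c(0.0801, 0.0034)),
    AD = list(max = c(0.0839, 0.0049), mean = c(0.0600, 0.0054)))
  for (g in names(cvr)) for (cl in names(cvr[[g]]))
    for (m in names(cvr[[g]][[cl]]))
      if (cvr[[g]][[cl]][[m]][2L] < 0) stop("negative sd in cvr spec")
  stopifnot(all(unlist(n_cvr) >= 1), all(n_flow >= 1), all(n_density >= 1),
            n_rois >= 1, trace_noise_sd >= 0)
  structure(list(n_cvr = n_cvr, n_flow = n_flow, n_density = n_density,
                 cvr = cvr, flow = flow, density = density,
                 n_rois = n_rois, trace_noise_sd = trace_noise_sd,
                 roi_density_sd = roi_density_sd,
                 frame_interval = frame_interval,
                 baseline_min = baseline_min, post_min = post_min,
                 k = k, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with ground truth
#'
#' Per-animal true metrics are drawn from the configured normal
#' distributions; the reactivity metrics are then realized as noisy
#' Delta[HbT]% ROI traces whose noiseless metrics equal the drawn values
#' (the gamma-variate shape is solved exactly per animal and class).
#'
#' @param spec a [cohort_spec()].
#' @return list with `animals` (data.frame: animal_id, group, sex),
#'   `truth` (long data.frame: animal_id, group, sex, class, metric,
#'   value), `traces` (per animal: per class `[t, roi]` matrices), `time`,
#'   `t_inject` (s), `vessels` (data.frame: animal_id, group, order, v,
#'   phi), `density` (data.frame: animal_id, group, roi_id, ff_max,
#'   ff_mean), and the spec.
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  t_inject <- spec$baseline_min * 60
  time <- seq(0, (spec$baseline_min + spec$post_min) * 60,
              by = spec$frame_interval)
  thr_pct <- spec$k * spec$trace_noise_sd
  classes <- c("vein", "artery", "tissue")
  animals <- do.call(rbind, lapply(names(spec$n_cvr), function(g) {
    do.call(rbind, lapply(names(spec$n_cvr[[g]]), function(sx) {
      n <- spec$n_cvr[[g]][[sx]]
      if (n < 1) return(NULL)
      data.frame(group = g, sex = sx, idx = seq_len(n))
    }))
  }))
  animals$animal_id <- sprintf("%s_%s_%02d", animals$group, animals$sex,
                               animals$idx)
  animals$idx <- NULL
  truth <- list(); traces <- list()
  rec_len_min <- spec$post_min
  for (i in seq_len(nrow(animals))) {
    g <- animals$group[i]; id <- animals$animal_id[i]
    tr_animal <- list()
    for (cl in classes) {
      par <- spec$cvr[[g]][[cl]]
      peak <- stats::rnorm(1L, par$peak[1L], par$peak[2L])
      ir   <- stats::rnorm(1L, par$ir[1L], par$ir[2L])
      rt   <- stats::rnorm(1L, par$rt[1L], par$rt[2L])
      peak <- min(peak, -1e-3)
      rt <- min(max(rt, 0.5), rec_len_min - 1)
      ir <- min(ir, -1e-3)
      sh <- .solve_shape(peak, ir, rt, thr_pct)
      clean <- peak * .dip_shape((time - t_inject) / 60, sh$t_rise,
                                 sh$t_hold, sh$tau, sh$alpha)
      roi_sd <- spec$trace_noise_sd * sqrt(spec$n_rois)
      tr <- vapply(seq_len(spec$n_rois), function(j)
        clean + roi_sd * stats::rnorm(length(time)),
        numeric(length(time)))
      tr_animal[[cl]] <- tr
      truth[[length(truth) + 1L]] <- data.frame(
        animal_id = id, group = g, sex = animals$sex[i], class = cl,
        metric = c("peak_pct", "ir_pct_min", "rt_min"),
        value = c(peak, ir, rt))
    }
    traces[[id]] <- tr_animal
  }
  vessels <- do.call(rbind, lapply(names(spec$flow), function(g) {
    do.call(rbind, lapply(seq_len(spec$n_flow[[g]]), function(j) {
      do.call(rbind, lapply(names(spec$flow[[g]]), function(ord) {
        fl <- spec$flow[[g]][[ord]]
        data.frame(animal_id = sprintf("%s_flow_%02d", g, j), group = g,
                   order = ord,
                   v = max(stats::rnorm(1L, fl$v[1L], fl$v[2L]), 0),
                   phi = max(stats::rnorm(1L, fl$phi[1L], fl$phi[2L]), 1))
      }))
    }))
  }))
  density <- do.call(rbind, lapply(names(spec$density), function(g) {
    de <- spec$density[[g]]
    do.call(rbind, lapply(seq_len(spec$n_density[[g]]), function(j) {
      tmax <- stats::rnorm(1L, de$max[1L], de$max[2L])
      tmean <- stats::rnorm(1L, de$mean[1L], de$mean[2L])
      data.frame(animal_id = sprintf("%s_dens_%02d", g, j), group = g,
                 roi_id = 1:3,
                 ff_max = pmax(tmax + spec$roi_density_sd *
                                 stats::rnorm(3L), 0),
                 ff_mean = pmax(tmean + spec$roi_density_sd *
                                  stats::rnorm(3L), 0))
    }))
  }))
  list(animals = animals[, c("animal_id", "group", "sex")],
       truth = do.call(rbind, truth), traces = traces, time = time,
       t_inject = t_inject, vessels = vessels, density = density,
       spec = spec)
}
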