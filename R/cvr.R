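# Cerebrovascular reactivity metrics from Delta[HbT]% time courses, and
# the group comparisons applied to them.
#
# Three statistics summarize the vasoconstrictive transient:
#   peak response  - most negative smoothed Delta[HbT]% after the stimulus;
#   integrated reactivity (IR) - signed trapezoidal area of the transient
#       from the stimulus until recovery, in %*min;
#   recovery time (RT) - time from the stimulus until the trace re-enters
#       the baseline band (mean - k*sd, sustained for a dwell period).

# Centered moving average over a time window (seconds) on the actual
# timestamps; window 0 disables smoothing. Irregular sampling is allowed.
.smooth_trace <- function(x, time, window) {
  if (window <= 0) return(x)
  half <- window / 2
  lo <- findInterval(time - half, time, left.open = TRUE) + 1L
  hi <- findInterval(time + half, time)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Baseline mean/sd of the raw trace over the pre-injection window.
.baseline_stats <- function(x, time, t_inject, baseline_window = NULL) {
  if (is.null(baseline_window)) baseline_window <- c(min(time), t_inject)
  idx <- time >= baseline_window[1L] & time <= baseline_window[2L]
  if (!any(idx)) stop("no samples in the baseline window")
  list(mean = mean(x[idx]), sd = stats::sd(x[idx]))
}

#' Peak vasoconstrictive response
#'
#' Minimum of the smoothed Delta[HbT]% trace after the injection time.
#'
#' @param x Delta[HbT]% trace.
#' @param time timestamps (s).
#' @param t_inject injection time (s).
#' @param smooth_window moving-average window (s); default 30.
#' @return peak response in percent (<= 0 for a constriction).
#' @export
peak_response <- function(x, time, t_inject, smooth_window = 30) {
  post <- time > t_inject
  if (!any(post)) stop("no post-injection samples")
  s <- .smooth_trace(x, time, smooth_window)
  min(s[post])
}

#' Recovery time
#'
#' Time (minutes from injection) at which the smoothed trace first rises
#' above the baseline band `mean - k*sd` after the nadir and stays above it
#' for at least `dwell` seconds. A trace that never departs the band has
#' `rt = 0` with a `"no response"` note; a trace that never recovers
#' reports the record length with `recovered = FALSE`.
#'
#' @inheritParams peak_response
#' @param k band half-width in baseline standard deviations (default 1).
#' @param dwell sustained time above the band required (s, default 60).
#' @param baseline_window optional `c(t0, t1)` (s) for the baseline stats;
#'   defaults to everything before `t_inject`.
#' @param baseline_stats optional `list(mean =, sd =)` overriding the
#'   estimated baseline statistics.
#' @return list with `rt_min`, `recovered`, `note`, `threshold`,
#'   `t_nadir`.
#' @export
recovery_time <- function(x, time, t_inject, k = 1, dwell = 60,
                          smooth_window = 30, baseline_window = NULL,
                          baseline_stats = NULL) {
  if (is.null(baseline_stats))
    baseline_stats <- .baseline_stats(x, time, t_inject, baseline_window)
  thr <- baseline_stats$mean - k * baseline_stats$sd
  s <- .smooth_trace(x, time, smooth_window)
  post <- which(time > t_inject)
  if (length(post) == 0L) stop("no post-injection samples")
  below <- s[post] < thr
  if (!any(below)) {
    return(list(rt_min = 0, recovered = TRUE, note = "no response",
                threshold = thr, t_nadir = NA_real_))
  }
  i_nadir <- post[which.min(s[post])]
  t_nadir <- time[i_nadir]
  after <- post[time[post] >= t_nadir]
  above <- s[after] >= thr
  t_aft <- time[after]
  # first index above the band whose subsequent dwell window stays above
  cand <- which(above)
  for (i in cand) {
    win <- t_aft >= t_aft[i] & t_aft <= t_aft[i] + dwell
    if (all(above[win])) {
      if (t_aft[i] + dwell > max(time) && !all(above[t_aft >= t_aft[i]]))
        next
      return(list(rt_min = (t_aft[i] - t_inject) / 60, recovered = TRUE,
                  note = NA_character_, threshold = thr, t_nadir = t_nadir))
    }
  }
  list(rt_min = (max(time) - t_inject) / 60, recovered = FALSE,
       note = "did not recover within the record", threshold = thr,
       t_nadir = t_nadir)
}

#' Integrated reactivity
#'
#' Signed trapezoidal integral of the smoothed Delta[HbT]% trace over
#' `[t_inject, t_inject + rt]`, in percent-minutes (negative for a
#' constriction). The endpoint value is linearly interpolated.
#'
#' @inheritParams peak_response
#' @param rt_min recovery time in minutes (from [recovery_time()]).
#' @return integrated reactivity in %*min.
#' @export
integrated_reactivity <- function(x, time, t_inject, rt_min,
                                  smooth_window = 30) {
  if (is.na(rt_min) || rt_min <= 0) return(0)
  s <- .smooth_trace(x, time, smooth_window)
  t_end <- min(t_inject + rt_min * 60, max(time))
  idx <- which(time >= t_inject & time <= t_end)
  tt <- time[idx]; ss <- s[idx]
  if (t_inject < tt[1L] && t_inject >= min(time)) {
    tt <- c(t_inject, tt)
    ss <- c(stats::approx(time, s, t_inject)$y, ss)
  }
  if (t_end > tt[length(tt)]) {
    tt <- c(tt, t_end)
    ss <- c(ss, stats::approx(time, s, t_end)$y)
  }
  sum(diff(tt) * (head(ss, -1L) + tail(ss, -1L)) / 2) / 60
}

#' All three CVR metrics of one trace
#'
#' @inheritParams recovery_time
#' @return list with `peak_pct`, `ir_pct_min`, `rt_min`, `recovered`,
#'   `note`.
#' @export
cvr_metrics <- function(x, time, t_inject, k = 1, dwell = 60,
                        smooth_window = 30, baseline_window = NULL,
                        baseline_stats = NULL) {
  rt <- recovery_time(x, time, t_inject, k = k, dwell = dwell,
                      smooth_window = smooth_window,
                      baseline_window = baseline_window,
                      baseline_stats = baseline_stats)
  list(peak_pct = peak_response(x, time, t_inject, smooth_window),
       ir_pct_min = integrated_reactivity(x, time, t_inject, rt$rt_min,
                                          smooth_window),
       rt_min = rt$rt_min, recovered = rt$recovered, note = rt$note)
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed Student's t-test with pooled variance, as used for the
#' WT-vs-AD group comparisons.
#'
#' @param a,b numeric vectors (each `n >= 2`).
#' @return list with `t`, `df`, `p`.
#' @export
group_ttest <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (sp2 <= .Machine$double.eps * max(abs(c(a, b, 1)))^2) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-way sex-by-group ANOVA with Bonferroni post-hoc tests
#'
#' Type-II sums of squares for the `sex`, `group` main effects and their
#' interaction (identical to the sequential decomposition when the design
#' is balanced), plus the four pairwise sex-by-group comparisons
#' (WT vs AD within each sex, M vs F within each group) as pooled t-tests
#' with Bonferroni-adjusted p-values (multiplied by 4, capped at 1).
#'
#' @param value numeric response, one entry per animal.
#' @param sex,group factors (2 levels each).
#' @return list with `anova` (data.frame: effect, F, df, p) and
#'   `posthoc` (data.frame: comparison, t, p_adj).
#' @export
sex_by_group_anova <- function(value, sex, group) {
  sex <- factor(sex); group <- factor(group)
  tab <- table(sex, group)
  if (any(tab == 0L)) stop("empty sex-by-group cell")
  cellvar <- tapply(value, interaction(sex, group), stats::var)
  if (all(!is.na(cellvar)) && all(cellvar == 0))
    stop("zero within-cell variance")
  fit <- stats::lm(value ~ sex * group)
  aov2 <- car::Anova(fit, type = 2)
  eff <- rownames(aov2)
  keep <- eff != "Residuals"
  an <- data.frame(effect = eff[keep], F = aov2$`F value`[keep],
                   df = aov2$Df[keep], p = aov2$`Pr(>F)`[keep])
  cmp <- list(
    list(name = "WT vs AD | sex 1", i = sex == levels(sex)[1L], f = group),
    list(name = "WT vs AD | sex 2", i = sex == levels(sex)[2L], f = group),
    list(name = "sex | group 1", i = group == levels(group)[1L], f = sex),
    list(name = "sex | group 2", i = group == levels(group)[2L], f = sex))
  ph <- do.call(rbind, lapply(cmp, function(cc) {
    v <- value[cc$i]; f <- droplevels(cc$f[cc$i])
    tt <- group_ttest(v[f == levels(f)[1L]], v[f == levels(f)[2L]])
    data.frame(comparison = cc$name, t = tt$t,
               p_adj = min(1, tt$p * length(cmp)))
  }))
  list(anova = an, posthoc = ph)
}
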