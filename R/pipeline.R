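# End-to-end orchestration: simulate a cohort, push every animal through
# the metric-extraction chain, tabulate group statistics (mean +/- SEM,
# pooled t-tests), and render a small report.

.known_config_keys <- c(
  "seed", "out_dir", "stages", "smooth_window", "k", "dwell",
  "baseline_hbt", "fill_window", "gauss_sigma", "frangi_small",
  "frangi_large", "doppler", "cohort", "log_level")

#' Build and validate a pipeline configuration
#'
#' Every parameter has a default equal to the pipeline's documented
#' values; unknown keys raise a validation error naming the key. The
#' configuration round-trips losslessly through JSON.
#'
#' @param ... named overrides of the defaults (see
#'   `vasoreact:::.known_config_keys`). `cohort` takes a [cohort_spec()];
#'   `doppler` a [doppler_params()].
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all config entries must be named")
  unknown <- setdiff(names(over), .known_config_keys)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  cfg <- list(seed = 1L, out_dir = NULL, stages = c("simulate", "cvr",
              "cohort-stats"), smooth_window = 30, k = 1, dwell = 60,
              baseline_hbt = 1, fill_window = 60, gauss_sigma = 3,
              frangi_small = 1:5, frangi_large = seq(5, 25, by = 5),
              doppler = doppler_params(), cohort = NULL,
              log_level = "info")
  cfg[names(over)] <- over
  if (is.null(cfg$cohort)) cfg$cohort <- cohort_spec(seed = cfg$seed)
  structure(cfg, class = "run_config")
}

#' Estimate CVR metrics for every animal of a cohort
#'
#' The per-class mean trace (mean of the ROI traces) is pushed through
#' [cvr_metrics()].
#'
#' @param cohort a [gen_cohort()] result.
#' @param smooth_window,k,dwell analysis settings (defaults 30 s, 1, 60 s).
#' @return long data.frame: animal_id, group, sex, class, metric, value.
#' @export
cohort_cvr_metrics <- function(cohort, smooth_window = 30, k = 1,
                               dwell = 60) {
  out <- list()
  for (i in seq_len(nrow(cohort$animals))) {
    id <- cohort$animals$animal_id[i]
    for (cl in names(cohort$traces[[id]])) {
      tr <- rowMeans(cohort$traces[[id]][[cl]])
      m <- cvr_metrics(tr, cohort$time, cohort$t_inject, k = k,
                       dwell = dwell, smooth_window = smooth_window)
      out[[length(out) + 1L]] <- data.frame(
        animal_id = id, group = cohort$animals$group[i],
        sex = cohort$animals$sex[i], class = cl,
        metric = c("peak_pct", "ir_pct_min", "rt_min"),
        value = c(m$peak_pct, m$ir_pct_min, m$rt_min))
    }
  }
  do.call(rbind, out)
}

# Group-level mean/SEM/n + WT-vs-AD pooled t per (class, metric) cell.
.summarize_groups <- function(df, cell_cols) {
  cells <- unique(df[cell_cols])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(df))
    for (cc in cell_cols) sel <- sel & df[[cc]] == cells[[cc]][i]
    sub <- df[sel, ]
    groups <- unique(sub$group)
    p <- if (length(groups) == 2L &&
             all(table(sub$group) >= 2L))
      group_ttest(sub$value[sub$group == groups[1L]],
                  sub$value[sub$group == groups[2L]])$p
      else NA_real_
    do.call(rbind, lapply(groups, function(g) {
      v <- sub$value[sub$group == g]
      out <- cells[i, , drop = FALSE]
      rownames(out) <- NULL
      cbind(out, data.frame(group = g, mean = mean(v),
            sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
            n = length(v), p_vs_other = p))
    }))
  })
  do.call(rbind, rows)
}

#' Run the full synthetic-cohort pipeline
#'
#' Deterministic given config and seed: generates the cohort, estimates
#' CVR metrics from the traces, aggregates the flow/diameter and density
#' records, and tabulates group statistics. When `out_dir` is set, writes
#' the summary table, the per-animal metrics and a provenance log.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_result`: `summary` (long data.frame:
#'   class/order, metric, group, mean, sem, n, p_vs_other), `per_animal`,
#'   `cohort`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- gen_cohort(config$cohort)
  est <- cohort_cvr_metrics(cohort, smooth_window = config$smooth_window,
                            k = config$k, dwell = config$dwell)
  cvr_sum <- .summarize_groups(est, c("class", "metric"))
  vs <- cohort$vessels
  vdf <- rbind(
    data.frame(class = vs$order, metric = "cbfv_mm_s", group = vs$group,
               animal_id = vs$animal_id, value = vs$v),
    data.frame(class = vs$order, metric = "phi_um", group = vs$group,
               animal_id = vs$animal_id, value = vs$phi))
  vessel_sum <- .summarize_groups(vdf, c("class", "metric"))
  de <- cohort$density
  an_de <- do.call(rbind, lapply(split(de, de$animal_id), function(dd)
    data.frame(group = dd$group[1L], animal_id = dd$animal_id[1L],
               ff_max = mean(dd$ff_max), ff_mean = mean(dd$ff_mean))))
  ddf <- rbind(
    data.frame(class = "capillary", metric = "ff_max", group = an_de$group,
               animal_id = an_de$animal_id, value = an_de$ff_max),
    data.frame(class = "capillary", metric = "ff_mean",
               group = an_de$group, animal_id = an_de$animal_id,
               value = an_de$ff_mean))
  dens_sum <- .summarize_groups(ddf, c("class", "metric"))
  summary <- rbind(cvr_sum, vessel_sum, dens_sum)
  res <- structure(list(summary = summary, per_animal = est,
                        cohort = cohort, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_artifacts(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

.write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$per_animal, file.path(out_dir, "per_animal.csv"),
                   row.names = FALSE)
  cfg <- res$config
  cfg$cohort <- unclass(cfg$cohort)
  cfg$doppler <- unclass(cfg$doppler)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  prov <- list(config_hash = unname(tools::md5sum(tmp)),
               r_version = R.version.string,
               package_version = as.character(
                 utils::packageVersion("vasoreact")),
               timestamp = format(Sys.time(), tz = "UTC"))
  file.copy(tmp, file.path(out_dir, "config.json"), overwrite = TRUE)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Significance annotation for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise
#' `"NS"`.
#'
#' @param p p-value(s).
#' @return character vector of annotations.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "NS",
    ifelse(p < 0.001, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "NS"))))
}

#' Render bar-chart panels and a markdown summary of a pipeline run
#'
#' One panel per (class, metric) cell: group means with SEM whiskers and
#' the significance annotation of the WT-vs-AD comparison. Empty metric
#' cells are skipped with a warning.
#'
#' @param summary the `summary` table of a [run_pipeline()] result.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
render_report <- function(summary, out_dir) {
  stopifnot(nrow(summary) > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  cells <- unique(summary[c("class", "metric")])
  for (i in seq_len(nrow(cells))) {
    sub <- summary[summary$class == cells$class[i] &
                   summary$metric == cells$metric[i], ]
    if (nrow(sub) == 0L || all(!is.finite(sub$mean))) {
      warning("empty panel skipped: ", cells$class[i], "/",
              cells$metric[i])
      next
    }
    f <- file.path(out_dir, sprintf("panel_%s_%s.png", cells$class[i],
                                    cells$metric[i]))
    grDevices::png(f, width = 480, height = 480)
    ylim <- range(0, sub$mean - sub$sem, sub$mean + sub$sem)
    bp <- graphics::barplot(sub$mean, names.arg = sub$group,
                            ylim = ylim * 1.15,
                            main = paste(cells$class[i], cells$metric[i]),
                            ylab = cells$metric[i])
    graphics::arrows(bp, sub$mean - sub$sem, bp, sub$mean + sub$sem,
                     angle = 90, code = 3, length = 0.06)
    graphics::mtext(significance_stars(sub$p_vs_other[1L]), side = 3)
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  md <- file.path(out_dir, "report.md")
  lines <- c("# Cohort summary", "",
             "| class | metric | group | mean | SEM | n | p | sig |",
             "|---|---|---|---|---|---|---|---|")
  for (j in seq_len(nrow(summary))) {
    s <- summary[j, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %.4g | %.4g | %d | %s | %s |",
      s$class, s$metric, s$group, s$mean, s$sem, s$n,
      ifelse(is.na(s$p_vs_other), "-", sprintf("%.3g", s$p_vs_other)),
      significance_stars(s$p_vs_other)))
  }
  writeLines(lines, md)
  invisible(c(paths, md))
}
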