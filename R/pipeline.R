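#' Analyze a single participant from files
#'
#' Reads the RR and breath recordings, runs the full estimation chain, and
#' optionally writes a JSON report (configuration echo, segment bounds,
#' regression coefficients, both threshold estimates, quality flags) plus a
#' one-row CSV suitable for cohort assembly.
#'
#' @param rr_file RR recording (plain ms-per-line or timestamped CSV).
#' @param breath_file breath-by-breath CSV.
#' @param id participant identifier.
#' @param weight_kg body mass.
#' @param sex `"M"` or `"F"`.
#' @param slope_w_per_min ramp slope.
#' @param ramp_start_s ramp onset in seconds; defaults to the standard
#'   protocol's 840 s (override when the recording used different phase
#'   durations, e.g. from a cohort manifest).
#' @param out optional output directory; when given, `<id>_<slope>w.json`
#'   and `<id>_<slope>w.csv` are written there.
#' @param rr_dialect dialect passed to [read_rr()].
#' @param cfg,detrend,segment passed to [estimate_hrvt()].
#' @return the [estimate_hrvt()] result, with a `row` element holding the
#'   one-row summary data frame.
#' @export
run_analyze <- function(rr_file, breath_file, id, weight_kg, sex = "M",
                        slope_w_per_min = 30, ramp_start_s = NULL,
                        out = NULL, rr_dialect = "plain_ms",
                        cfg = dfa_config(), detrend = detrend_config(),
                        segment = NULL) {
  if (!file.exists(rr_file)) stop("run_analyze: RR file not found: ", rr_file)
  if (!file.exists(breath_file))
    stop("run_analyze: breath file not found: ", breath_file)
  rr <- read_rr(rr_file, dialect = rr_dialect)
  br <- read_breaths(breath_file)
  proto <- ramp_protocol(slope_w_per_min = slope_w_per_min,
                         moderate_w = if (sex == "F") 60 else 80)
  if (!is.null(ramp_start_s)) proto$ramp_start_s <- ramp_start_s
  p <- participant(id, weight_kg, sex, proto)
  res <- estimate_hrvt(rr, br, p, cfg = cfg, detrend = detrend,
                       segment = segment)
  e1 <- res$estimates$hrvt1; e2 <- res$estimates$hrvt2
  res$row <- data.frame(
    participant = id, slope = slope_w_per_min,
    hrvt1_t = e1$t_cross_s, hrvt1_vo2 = e1$vo2_ml_kg_min, hrvt1_hr = e1$hr_bpm,
    hrvt2_t = e2$t_cross_s, hrvt2_vo2 = e2$vo2_ml_kg_min, hrvt2_hr = e2$hr_bpm,
    segment_t0 = res$segment$t_start, segment_t1 = res$segment$t_end,
    r_squared = res$segment$r_squared,
    artifact_fraction = res$segment$artifact_fraction,
    low_r2 = e1$low_r2, artifact_exceeded = e1$artifact_exceeded,
    extrapolated = e1$extrapolated || e2$extrapolated)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stem <- sprintf("%s_%02dw", id, slope_w_per_min)
    report <- list(
      package_version = as.character(utils::packageVersion("hrvt")),
      config = list(dfa = unclass(cfg), detrend = unclass(detrend),
                    segment_override = segment,
                    rr_file = rr_file, breath_file = breath_file,
                    weight_kg = weight_kg, sex = sex,
                    slope_w_per_min = slope_w_per_min),
      segment = unclass(res$segment)[c("t_start", "t_end", "slope",
                                       "intercept", "r_squared", "n_points",
                                       "low_r2", "artifact_fraction")],
      hr_vs_a1 = {
        sub <- as.data.frame(res$trace)[res$segment$indices, ]
        as.list(stats::coef(stats::lm(mean_hr_bpm ~ a1, data = sub)))
      },
      estimates = lapply(res$estimates, function(e)
        list(level = e$level, t_cross_s = round(e$t_cross_s, 1),
             vo2_ml_kg_min = round(e$vo2_ml_kg_min, 1),
             hr_bpm = round(e$hr_bpm, 1),
             extrapolated = e$extrapolated, low_r2 = e$low_r2,
             artifact_exceeded = e$artifact_exceeded)))
    jsonlite::write_json(report, file.path(out, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = 6, null = "null")
    utils::write.csv(res$row, file.path(out, paste0(stem, ".csv")),
                     row.names = FALSE)
  }
  res
}

#' Analyze a cohort from a manifest
#'
#' The manifest CSV has columns `participant_id, weight_kg, sex,
#' slope_w_per_min, rr_file, breath_file, ramp_start_s` (file paths
#' relative to the manifest's directory).  Every row is analyzed with
#' [run_analyze()]; participants missing any slope, or whose analysis
#' fails, are excluded with a logged message.  The agreement battery is
#' then run and the three report tables are written: `table1.csv` (group
#' mean and SD per metric and slope), `table2.csv` (pairwise r, SEE, bias,
#' SD, limits of agreement, paired t) and `icc_anova.csv`.
#'
#' @param manifest path to the manifest CSV.
#' @param out output directory for the report tables (default: next to the
#'   manifest).
#' @param cfg,detrend passed to the per-participant analysis.
#' @return a list with `estimates` (per participant-slope rows), `report`
#'   (the [cohort_report()]), and `tables` (list of the three data frames).
#' @export
run_cohort <- function(manifest, out = NULL, cfg = dfa_config(),
                       detrend = detrend_config()) {
  if (!file.exists(manifest)) stop("run_cohort: manifest not found: ", manifest)
  mdir <- dirname(manifest)
  mf <- utils::read.csv(manifest)
  rows <- list()
  for (i in seq_len(nrow(mf))) {
    r <- mf[i, ]
    res <- tryCatch(
      run_analyze(file.path(mdir, r$rr_file), file.path(mdir, r$breath_file),
                  id = r$participant_id, weight_kg = r$weight_kg,
                  sex = r$sex, slope_w_per_min = r$slope_w_per_min,
                  ramp_start_s = r$ramp_start_s, cfg = cfg,
                  detrend = detrend),
      error = function(e) {
        message(sprintf("run_cohort: %s @ %s W/min failed: %s",
                        r$participant_id, r$slope_w_per_min,
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res$row
  }
  if (!length(rows)) stop("run_cohort: no participant analyses succeeded")
  est <- do.call(rbind, rows)
  report <- cohort_report(est)

  metrics <- c("hrvt1_vo2", "hrvt1_hr", "hrvt2_vo2", "hrvt2_hr")
  units <- c(hrvt1_vo2 = "mL.kg-1.min-1", hrvt1_hr = "bpm",
             hrvt2_vo2 = "mL.kg-1.min-1", hrvt2_hr = "bpm")
  t1 <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(sort(unique(est$slope)), function(s) {
      v <- est[[m]][est$slope == s]
      data.frame(metric = m, unit = units[[m]], slope_w_per_min = s,
                 mean = mean(v), sd = stats::sd(v), n = length(v))
    }))
  }))
  t2 <- report$pairwise
  t2$unit <- units[t2$metric]
  t3 <- report$overall
  t3$unit <- units[t3$metric]
  tables <- list(table1 = t1, table2 = t2, icc_anova = t3)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(t1, file.path(out, "table1.csv"), row.names = FALSE)
    utils::write.csv(t2, file.path(out, "table2.csv"), row.names = FALSE)
    utils::write.csv(t3, file.path(out, "icc_anova.csv"), row.names = FALSE)
    utils::write.csv(est, file.path(out, "estimates.csv"), row.names = FALSE)
  }
  list(estimates = est, report = report, tables = tables)
}

#' Simulate a cohort to disk
#'
#' Thin wrapper over [generate_cohort()] for the command-line interface.
#'
#' @param n participants.
#' @param slopes ramp slopes, W/min.
#' @param seed master seed.
#' @param outdir output directory.
#' @return the [generate_cohort()] result.
#' @export
run_simulate <- function(n = 17, slopes = c(15, 30, 45), seed = 1L,
                         outdir = "cohort") {
  generate_cohort(n = n, slopes = slopes, seed = seed, outdir = outdir)
}
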