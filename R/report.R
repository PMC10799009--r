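# Confounder-stratified analyses and full study-report orchestration.

#' Stratification specification
#'
#' Duration bins follow the published layout: a partition
#' `[0,10) [10,30) [30,60) [60,120) [120,Inf)` seconds plus two overlapping
#' catch-all bins (`<10 s` and `>10 s`) that are reported alongside but are
#' never used for count-conservation checks. Binning uses the duration
#' reported by the reference system, left-closed/right-open. Strata with
#' fewer walking bouts than `min_wbs` are flagged underpowered (the study's
#' power analysis asked for at least 101 bouts per stratum).
#'
#' @param duration_breaks Inner break points of the partition (s).
#' @param min_wbs Minimum bouts per stratum for a powered estimate.
#' @return A list of class `stratum_spec`.
#' @export
stratum_spec <- function(duration_breaks = c(10, 30, 60, 120),
                         min_wbs = 101) {
  stopifnot(!is.unsorted(duration_breaks, strictly = TRUE), min_wbs >= 1)
  structure(list(duration_breaks = duration_breaks, min_wbs = min_wbs),
            class = "stratum_spec")
}

duration_bin_labels <- function(breaks) {
  lo <- c(0, breaks); hi <- c(breaks, Inf)
  ifelse(is.infinite(hi), sprintf(">%g s", lo),
         sprintf("%g-%g s", lo, hi))
}

summary_row_or_na <- function(ref, dev, label, bootstrap, min_n = 3) {
  n <- sum(!is.na(ref) & !is.na(dev))
  if (n >= min_n) {
    s <- agreement_summary(ref, dev, label = label, bootstrap = bootstrap)
    attr(s, "errors") <- NULL
    class(s) <- "data.frame"
    return(s)
  }
  empty <- agreement_summary(c(1, 2, 3), c(1, 2, 3), bootstrap = NULL)
  attr(empty, "errors") <- NULL
  class(empty) <- "data.frame"
  empty[1, ] <- NA
  empty$label <- label
  empty$n <- n
  empty
}

#' Agreement stratified by bout duration
#'
#' Summarizes the true-positive pairs within each reference-duration bin:
#' the partition bins plus the `<10 s` / `>10 s` catch-alls. Each row
#' carries the per-system bout counts falling in the bin (all bouts, not
#' only matched ones, when `ref_wbs`/`dev_wbs` are supplied) and an
#' `underpowered` flag.
#'
#' @param pairs Pair data frame from [match_bouts()] (may span sessions).
#' @param spec A [stratum_spec()].
#' @param ref_wbs,dev_wbs Optional full bout tables for the per-system
#'   counts; defaults to the bouts inside `pairs`.
#' @param bootstrap A [bootstrap_config()] or `NULL`.
#' @return Data frame: `label`, `partition_bin`, `n_ref_wbs`, `n_dev_wbs`,
#'   `underpowered` plus the [agreement_summary()] columns.
#' @export
stratify_by_duration <- function(pairs, spec = stratum_spec(),
                                 ref_wbs = NULL, dev_wbs = NULL,
                                 bootstrap = bootstrap_config()) {
  breaks <- spec$duration_breaks
  labels <- duration_bin_labels(breaks)
  lo <- c(0, breaks); hi <- c(breaks, Inf)
  bins <- rbind(data.frame(label = labels, lo = lo, hi = hi,
                           partition_bin = TRUE, stringsAsFactors = FALSE),
                data.frame(label = c(sprintf("<%g s", breaks[1]),
                                     sprintf(">%g s", breaks[1])),
                           lo = c(0, breaks[1]), hi = c(breaks[1], Inf),
                           partition_bin = FALSE, stringsAsFactors = FALSE))
  bins <- bins[!duplicated(bins$label), , drop = FALSE]
  count_in <- function(d, l, h) sum(d >= l & d < h)
  out <- lapply(seq_len(nrow(bins)), function(i) {
    sel <- pairs$ref_duration_s >= bins$lo[i] &
      pairs$ref_duration_s < bins$hi[i]
    row <- summary_row_or_na(pairs$ref_mean_speed_mps[sel],
                             pairs$dev_mean_speed_mps[sel],
                             bins$label[i], bootstrap)
    row$partition_bin <- bins$partition_bin[i]
    row$n_ref_wbs <- count_in(
      if (is.null(ref_wbs)) pairs$ref_duration_s else ref_wbs$duration_s,
      bins$lo[i], bins$hi[i])
    row$n_dev_wbs <- count_in(
      if (is.null(dev_wbs)) pairs$dev_duration_s else dev_wbs$duration_s,
      bins$lo[i], bins$hi[i])
    row$underpowered <- row$n < spec$min_wbs
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Linear speed-error relationship
#'
#' Ordinary least squares of the signed speed error on the reference
#' walking speed, with seeded percentile-bootstrap confidence intervals for
#' slope and intercept. A negative slope reproduces the reported pattern:
#' slow bouts overestimated, fast bouts underestimated.
#'
#' @param pairs Pair data frame from [match_bouts()], n >= 3.
#' @param bootstrap A [bootstrap_config()] or `NULL`.
#' @return List: `slope`, `intercept`, `slope_ci`, `intercept_ci`, `n`,
#'   `data` (x = reference speed, y = error) for residual plotting.
#' @export
speed_error_regression <- function(pairs, bootstrap = bootstrap_config()) {
  x <- pairs$ref_mean_speed_mps
  y <- pairs$speed_error
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate regression: reference speeds have zero variance",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  coefs <- unname(fit$coefficients)
  slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  if (!is.null(bootstrap)) {
    alpha <- 1 - bootstrap$conf
    bs <- with_local_seed(bootstrap$seed, {
      t(vapply(seq_len(bootstrap$B), function(b) {
        idx <- sample.int(length(x), replace = TRUE)
        if (stats::var(x[idx]) == 0) return(c(NA_real_, NA_real_))
        unname(stats::lm.fit(cbind(1, x[idx]), y[idx])$coefficients)
      }, numeric(2)))
    })
    intercept_ci <- unname(stats::quantile(bs[, 1],
                                           c(alpha / 2, 1 - alpha / 2),
                                           na.rm = TRUE, type = 7))
    slope_ci <- unname(stats::quantile(bs[, 2],
                                       c(alpha / 2, 1 - alpha / 2),
                                       na.rm = TRUE, type = 7))
  }
  list(slope = coefs[2], intercept = coefs[1], slope_ci = slope_ci,
       intercept_ci = intercept_ci, n = length(x),
       data = data.frame(ref_speed_mps = x, error_mps = y))
}

#' Agreement stratified by gait complexity
#'
#' Per-class (and optionally per-cohort) agreement summaries, classes taken
#' from the reference bout's turn-coverage classification (or any label
#' column present in the pairs). Class-by-cohort cells below the
#' underpowered threshold are flagged; empty classes are omitted.
#'
#' @param pairs Pair data frame; must carry the class column and, when
#'   `by_cohort`, a `cohort` column.
#' @param class_col Column holding the class labels, default
#'   `"ref_complexity"`.
#' @param by_cohort Also split by cohort (default `FALSE`).
#' @param spec A [stratum_spec()] (for the underpowered flag).
#' @param bootstrap A [bootstrap_config()] or `NULL`.
#' @return Data frame of [agreement_summary()] rows with `complexity`
#'   (and `cohort`) columns.
#' @export
stratify_by_complexity <- function(pairs, class_col = "ref_complexity",
                                   by_cohort = FALSE, spec = stratum_spec(),
                                   bootstrap = bootstrap_config()) {
  classes <- unique(pairs[[class_col]])
  groups <- if (by_cohort) {
    expand.grid(complexity = classes, cohort = unique(pairs$cohort),
                stringsAsFactors = FALSE)
  } else data.frame(complexity = classes, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- pairs[[class_col]] == groups$complexity[i]
    if (by_cohort) sel <- sel & pairs$cohort == groups$cohort[i]
    if (!any(sel)) return(NULL)
    row <- summary_row_or_na(pairs$ref_mean_speed_mps[sel],
                             pairs$dev_mean_speed_mps[sel],
                             groups$complexity[i], bootstrap)
    row$complexity <- groups$complexity[i]
    if (by_cohort) row$cohort <- groups$cohort[i]
    row$underpowered <- row$n < spec$min_wbs
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the full validation report for a study
#'
#' Orchestrates the whole two-tier validation on a set of paired sessions:
#' runs the bout pipeline on both systems of every session, matches bouts,
#' computes per-participant sample-wise detection metrics aggregated per
#' cohort, true-positive agreement per cohort and overall, combined
#' (per-recording median) agreement, duration-bin and complexity
#' stratifications, and the speed-error regression. Deterministic given the
#' bootstrap seed.
#'
#' @param study A `synthetic_study`, or a plain list of `gait_session`s.
#' @param pipeline A [pipeline_config()].
#' @param match A [match_config()].
#' @param strata A [stratum_spec()].
#' @param bootstrap A [bootstrap_config()] (or `NULL` to skip intervals).
#' @return Object of class `study_report`: list of tables `detection`,
#'   `tp_agreement`, `combined`, `duration`, `complexity`, `regression`,
#'   plus `wbs`, `pairs` and a `settings` echo.
#' @export
build_study_report <- function(study, pipeline = pipeline_config(),
                               match = match_config(),
                               strata = stratum_spec(),
                               bootstrap = bootstrap_config()) {
  sessions <- if (inherits(study, "synthetic_study")) study$sessions
  else study
  all_wbs <- NULL; all_pairs <- NULL; confusions <- NULL
  for (s in sessions) {
    key <- data.frame(recording_id = s$recording_id,
                      participant_id = s$reference$participant_id,
                      cohort = s$reference$cohort, stringsAsFactors = FALSE)
    ref_wbs <- process_stream(s$reference, pipeline)
    dev_wbs <- process_stream(s$device, pipeline)
    wbs <- rbind(ref_wbs, dev_wbs)
    if (nrow(wbs))
      all_wbs <- rbind(all_wbs, cbind(key[rep(1, nrow(wbs)), , drop = FALSE],
                                      wbs))
    m <- match_bouts(ref_wbs, dev_wbs, match)
    if (nrow(m$pairs))
      all_pairs <- rbind(all_pairs,
                         cbind(key[rep(1, nrow(m$pairs)), , drop = FALSE],
                               m$pairs))
    confusions <- rbind(confusions,
                        cbind(key, samplewise_confusion(
                          ref_wbs, dev_wbs, s$reference$duration_s,
                          s$sample_rate_hz)))
  }
  if (is.null(all_pairs)) stop("no true-positive pairs in study",
                               call. = FALSE)
  rownames(all_wbs) <- rownames(all_pairs) <- rownames(confusions) <- NULL
  detection <- rbind(aggregate_detection(confusions, "cohort", bootstrap),
                     aggregate_detection(confusions, NULL, bootstrap))
  tp_rows <- lapply(c(unique(all_pairs$cohort), "All"), function(g) {
    sel <- if (g == "All") rep(TRUE, nrow(all_pairs))
    else all_pairs$cohort == g
    summary_row_or_na(all_pairs$ref_mean_speed_mps[sel],
                      all_pairs$dev_mean_speed_mps[sel], g, bootstrap)
  })
  tp_agreement <- do.call(rbind, tp_rows)
  combined <- combined_rows(all_wbs, bootstrap)
  duration <- stratify_by_duration(
    all_pairs, strata,
    ref_wbs = all_wbs[all_wbs$system == "reference", , drop = FALSE],
    dev_wbs = all_wbs[all_wbs$system == "device", , drop = FALSE],
    bootstrap = bootstrap)
  complexity <- stratify_by_complexity(all_pairs, spec = strata,
                                       bootstrap = bootstrap)
  regression <- speed_error_regression(all_pairs, bootstrap)
  structure(list(detection = detection, tp_agreement = tp_agreement,
                 combined = combined, duration = duration,
                 complexity = complexity, regression = regression,
                 wbs = all_wbs, pairs = all_pairs, confusions = confusions,
                 settings = list(pipeline = unclass(pipeline),
                                 match = unclass(match),
                                 strata = unclass(strata),
                                 bootstrap = if (is.null(bootstrap)) NULL
                                 else unclass(bootstrap))),
            class = "study_report")
}

combined_rows <- function(all_wbs, bootstrap) {
  per_unit <- function(sel, label) {
    sub <- all_wbs[sel, , drop = FALSE]
    med <- function(sys) {
      s2 <- sub[sub$system == sys, , drop = FALSE]
      v <- tapply(s2$mean_speed_mps, s2$recording_id, stats::median)
      data.frame(unit = names(v), value = as.numeric(v),
                 stringsAsFactors = FALSE)
    }
    units <- merge(med("reference"), med("device"), by = "unit",
                   suffixes = c("_ref", "_dev"))
    summary_row_or_na(units$value_ref, units$value_dev, label, bootstrap)
  }
  rows <- lapply(c(unique(all_wbs$cohort), "All"), function(g) {
    sel <- if (g == "All") rep(TRUE, nrow(all_wbs))
    else all_wbs$cohort == g
    per_unit(sel, g)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  n_sess <- nrow(x$confusions)
  all_det <- x$detection[x$detection$group == "All", ]
  all_tp <- x$tp_agreement[x$tp_agreement$label == "All", ]
  all_cb <- x$combined[x$combined$label == "All", ]
  cat(sprintf("<study_report> %d sessions, %d true-positive pairs\n",
              n_sess, nrow(x$pairs)))
  cat(sprintf("  detection: sensitivity %s, specificity %s, PPV %s\n",
              f(all_det$sensitivity), f(all_det$specificity), f(all_det$ppv)))
  cat(sprintf("  true-positive: ME %s m/s, MAE %s m/s, ICC %s (%s)\n",
              f(all_tp$me), f(all_tp$mae), f(all_tp$icc),
              all_tp$icc_category))
  cat(sprintf("  combined:      ME %s m/s, MAE %s m/s, ICC %s (%s)\n",
              f(all_cb$me), f(all_cb$mae), f(all_cb$icc),
              all_cb$icc_category))
  cat(sprintf("  speed-error slope %s m/s per m/s (intercept %s)\n",
              f(x$regression$slope), f(x$regression$intercept)))
  invisible(x)
}

#' Write a study report to disk
#'
#' `report.json` holds every table; `tables/*.csv` mirror them for
#' spreadsheet use. Byte-identical across runs with identical inputs and
#' seeds.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study_report <- function(report, dir) {
  dir.create(file.path(dir, "tables"), showWarnings = FALSE, recursive = TRUE)
  tables <- list(detection = report$detection,
                 tp_agreement = report$tp_agreement,
                 combined = report$combined,
                 duration = report$duration,
                 complexity = report$complexity)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(dir, "tables",
                                             paste0(nm, ".csv")),
                     row.names = FALSE, na = "NA")
  doc <- c(tables,
           list(regression = report$regression[c("slope", "intercept",
                                                 "slope_ci", "intercept_ci",
                                                 "n")],
                settings = report$settings))
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), na = "null",
                       pretty = TRUE)
  invisible(dir)
}
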