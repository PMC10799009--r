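# Walking-bout pipeline: stride interpolation -> stride selection ->
# bout assembly -> per-bout DMO aggregation -> complexity classification.

#' Pipeline configuration
#'
#' Thresholds implementing the consensus walking-bout definition: a bout is
#' a continuous sequence of alternating left/right strides with at least two
#' strides per foot; a break of more than `max_intra_bout_gap_s` seconds
#' splits consecutive bouts; an individual stride is retained only if its
#' duration lies within `stride_duration_range_s` (inclusive) and its length
#' strictly exceeds `min_stride_length_m`. Turn coverage below
#' `simple_turn_fraction_max` marks a bout as simple straight gait, coverage
#' at or above `complex_turn_fraction_min` as complex gait.
#'
#' @param max_intra_bout_gap_s Maximal tolerated break between consecutive
#'   strides within one bout (s).
#' @param stride_duration_range_s Inclusive admissible stride duration (s).
#' @param min_stride_length_m Strict lower bound on stride length (m).
#' @param min_strides_per_foot Minimum strides of each foot per bout.
#' @param simple_turn_fraction_max,complex_turn_fraction_min Turn-coverage
#'   cut points for the simple/intermediate/complex classes.
#' @param bout_speed_method `"stride_mean"` (default) averages per-stride
#'   speeds; `"dmo_means"` applies the speed formula to the bout's mean
#'   cadence and mean stride length instead.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_intra_bout_gap_s = 3.0,
                            stride_duration_range_s = c(0.2, 3.0),
                            min_stride_length_m = 0.15,
                            min_strides_per_foot = 2,
                            simple_turn_fraction_max = 0.20,
                            complex_turn_fraction_min = 0.60,
                            bout_speed_method = c("stride_mean", "dmo_means")) {
  stopifnot(stride_duration_range_s[1] < stride_duration_range_s[2],
            simple_turn_fraction_max >= 0, complex_turn_fraction_min <= 1,
            simple_turn_fraction_max < complex_turn_fraction_min,
            max_intra_bout_gap_s > 0, min_strides_per_foot >= 1)
  structure(list(max_intra_bout_gap_s = max_intra_bout_gap_s,
                 stride_duration_range_s = stride_duration_range_s,
                 min_stride_length_m = min_stride_length_m,
                 min_strides_per_foot = min_strides_per_foot,
                 simple_turn_fraction_max = simple_turn_fraction_max,
                 complex_turn_fraction_min = complex_turn_fraction_min,
                 bout_speed_method = match.arg(bout_speed_method)),
            class = "pipeline_config")
}

#' Walking speed from cadence and stride length
#'
#' `speed [m/s] = (cadence [steps/min] / (2 * 60)) * stride length [m]`:
#' cadence/120 converts the stepping rate to strides per second, and one
#' stride advances the body by one stride length.
#'
#' @param cadence_spm Cadence in steps per minute (> 0).
#' @param stride_length_m Stride length in meters (>= 0).
#' @return Walking speed in m/s. Vectorized; `NA` propagates.
#' @examples
#' stride_speed(120, 1.0)  # 1 m/s
#' @export
stride_speed <- function(cadence_spm, stride_length_m) {
  if (any(!is.na(cadence_spm) & cadence_spm <= 0))
    stop("cadence_spm must be > 0", call. = FALSE)
  if (any(!is.na(stride_length_m) & stride_length_m < 0))
    stop("stride_length_m must be >= 0", call. = FALSE)
  (cadence_spm / 120) * stride_length_m
}

#' Interpolate per-second traces to stride level
#'
#' The upstream cadence and stride-length algorithms report one value per
#' second; bout construction needs per-stride values. Each stride receives
#' the time-weighted mean of the per-second values over its `[start_s,
#' end_s]` span, weighting each second by the length of its overlap with the
#' stride; seconds with missing (`NA`) values are dropped from the weights.
#' A stride overlapping only missing (or absent) seconds is flagged
#' unvalued (`valued = FALSE`, `NA` DMOs) and is removed by stride
#' selection.
#'
#' @param secondly Data frame with `second_index`, `cadence_spm`,
#'   `stride_length_m`; second `i` covers `[i, i+1)`.
#' @param strides Data frame with at least `start_s`, `end_s`, `laterality`.
#' @return `strides` with `cadence_spm`, `stride_length_m`, `speed_mps` and
#'   a logical `valued` column filled.
#' @export
interpolate_to_strides <- function(secondly, strides) {
  strides <- as.data.frame(strides, stringsAsFactors = FALSE)
  n <- nrow(strides)
  cad <- len <- rep(NA_real_, n)
  if (n) {
    sec_map_c <- sec_map_l <- numeric(0)
    if (nrow(secondly)) {
      sec_map_c <- stats::setNames(secondly$cadence_spm,
                                   secondly$second_index)
      sec_map_l <- stats::setNames(secondly$stride_length_m,
                                   secondly$second_index)
    }
    for (i in seq_len(n)) {
      a <- strides$start_s[i]; b <- strides$end_s[i]
      secs <- seq.int(floor(a), ceiling(b) - 1)
      w <- pmin(b, secs + 1) - pmax(a, secs)
      keep <- w > 1e-12
      secs <- secs[keep]; w <- w[keep]
      cv <- sec_map_c[as.character(secs)]
      lv <- sec_map_l[as.character(secs)]
      okc <- !is.na(cv); okl <- !is.na(lv)
      if (any(okc)) cad[i] <- sum(w[okc] * cv[okc]) / sum(w[okc])
      if (any(okl)) len[i] <- sum(w[okl] * lv[okl]) / sum(w[okl])
    }
  }
  strides$cadence_spm <- cad
  strides$stride_length_m <- len
  strides$speed_mps <- ifelse(is.na(cad) | is.na(len), NA_real_,
                              stride_speed(cad, len))
  strides$valued <- !is.na(cad) & !is.na(len)
  strides
}

#' Stride selection
#'
#' Retains strides whose duration lies in the configured inclusive range
#' and whose stride length strictly exceeds the minimum; unvalued strides
#' (no length available) are dropped. Order is preserved.
#'
#' @param strides Data frame with `start_s`, `end_s`, `stride_length_m`
#'   (and optionally `valued`).
#' @param config A [pipeline_config()].
#' @return The retained subset of `strides`.
#' @export
select_strides <- function(strides, config = pipeline_config()) {
  if (!nrow(strides)) return(strides)
  dur <- strides$end_s - strides$start_s
  keep <- dur >= config$stride_duration_range_s[1] &
    dur <= config$stride_duration_range_s[2] &
    !is.na(strides$stride_length_m) &
    strides$stride_length_m > config$min_stride_length_m
  if (!is.null(strides$valued)) keep <- keep & strides$valued
  out <- strides[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Walking-bout assembly
#'
#' Groups time-sorted selected strides into maximal runs in which the break
#' between consecutive strides — `next start - previous end` over the
#' interleaved both-feet sequence, with negative values (double-support
#' overlap) treated as zero — never exceeds the configured gap. Runs are
#' additionally split wherever two consecutive strides share a foot, so
#' each run has a strictly alternating L/R initial-contact pattern. A run
#' qualifies as a walking bout only if it holds at least
#' `min_strides_per_foot` strides of each foot.
#'
#' @param strides Selected, time-sorted strides with `laterality`.
#' @param config A [pipeline_config()].
#' @return A list of data frames, one per walking bout (possibly empty).
#' @export
assemble_walking_bouts <- function(strides, config = pipeline_config()) {
  n <- nrow(strides)
  if (n == 0) return(list())
  if (is.unsorted(strides$start_s))
    stop("strides must be sorted by start_s", call. = FALSE)
  gap <- pmax(0, strides$start_s[-1] - strides$end_s[-n])
  new_run <- c(TRUE, gap > config$max_intra_bout_gap_s |
                 strides$laterality[-1] == strides$laterality[-n])
  run_id <- cumsum(new_run)
  runs <- split(strides, run_id)
  # an alternation split can leave the previous run's last (interleaved)
  # stride reaching past the next run's start; trim those strides so bout
  # spans never overlap
  if (length(runs) > 1) {
    for (i in seq_len(length(runs) - 1)) {
      nxt <- runs[[i + 1]]$start_s[1]
      keep_st <- runs[[i]]$end_s <= nxt + 1e-9
      runs[[i]] <- runs[[i]][keep_st, , drop = FALSE]
    }
    runs <- runs[vapply(runs, nrow, 1L) > 0]
  }
  keep <- vapply(runs, function(r) {
    tab <- table(factor(r$laterality, levels = c("L", "R")))
    all(tab >= config$min_strides_per_foot)
  }, TRUE)
  out <- unname(runs[keep])
  lapply(out, function(r) { rownames(r) <- NULL; r })
}

#' Per-bout DMO aggregation
#'
#' Final bout-level digital mobility outcomes are the unweighted arithmetic
#' means of the per-stride values. With `bout_speed_method = "dmo_means"`
#' the bout speed is instead recomputed from the bout's mean cadence and
#' mean stride length via [stride_speed()].
#'
#' @param bout_strides Data frame of one bout's strides, all valued.
#' @param config A [pipeline_config()].
#' @return One-row data frame: `start_s`, `end_s`, `duration_s`,
#'   `n_strides`, `mean_cadence_spm`, `mean_stride_length_m`,
#'   `mean_speed_mps`.
#' @export
aggregate_bout_dmos <- function(bout_strides, config = pipeline_config()) {
  if (any(is.na(bout_strides$cadence_spm)) ||
      any(is.na(bout_strides$stride_length_m)))
    stop("unvalued stride in bout; filter upstream", call. = FALSE)
  speed <- if (config$bout_speed_method == "stride_mean")
    mean(bout_strides$speed_mps)
  else
    stride_speed(mean(bout_strides$cadence_spm),
                 mean(bout_strides$stride_length_m))
  data.frame(start_s = min(bout_strides$start_s),
             end_s = max(bout_strides$end_s),
             duration_s = max(bout_strides$end_s) - min(bout_strides$start_s),
             n_strides = nrow(bout_strides),
             mean_cadence_spm = mean(bout_strides$cadence_spm),
             mean_stride_length_m = mean(bout_strides$stride_length_m),
             mean_speed_mps = speed)
}

interval_overlap_len <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}

merge_intervals <- function(starts, ends) {
  if (!length(starts)) return(list(start = numeric(0), end = numeric(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- starts[i]; me <- ends[i] }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Turn-coverage complexity classification
#'
#' The turn fraction of a bout is the total duration of the intersection of
#' the (merged) turn intervals with the bout span, divided by the bout
#' duration. Bouts with turn coverage below the simple cut point are
#' `simple`, those at or above the complex cut point are `complex`, the rest
#' `intermediate`.
#'
#' @param start_s,end_s Bout span in seconds.
#' @param turns Data frame of turn intervals (`start_s`, `end_s`).
#' @param config A [pipeline_config()].
#' @return List with `turn_fraction` and `complexity`.
#' @export
classify_complexity <- function(start_s, end_s, turns,
                                config = pipeline_config()) {
  merged <- merge_intervals(turns$start_s, turns$end_s)
  ov <- sum(interval_overlap_len(start_s, end_s, merged$start, merged$end))
  frac <- ov / (end_s - start_s)
  cls <- if (frac < config$simple_turn_fraction_max) "simple"
  else if (frac >= config$complex_turn_fraction_min) "complex"
  else "intermediate"
  list(turn_fraction = frac, complexity = cls)
}

#' Run the full bout pipeline on one stream
#'
#' Interpolates the per-second traces to stride level, applies stride
#' selection, assembles walking bouts, aggregates per-bout DMOs and
#' classifies turn complexity.
#'
#' @param stream A `stride_stream`.
#' @param config A [pipeline_config()].
#' @return Data frame of walking bouts with columns `bout_id`, `system`,
#'   `start_s`, `end_s`, `duration_s`, `n_strides`, `mean_cadence_spm`,
#'   `mean_stride_length_m`, `mean_speed_mps`, `turn_fraction`,
#'   `complexity`.
#' @examples
#' \donttest{
#' s <- generate_reference_stream(cohort_profile("HA"), duration_s = 600,
#'                                seed = 1)
#' process_stream(s)
#' }
#' @export
process_stream <- function(stream, config = pipeline_config()) {
  st <- interpolate_to_strides(stream$secondly, stream$strides)
  st <- select_strides(st, config)
  bouts <- assemble_walking_bouts(st, config)
  if (!length(bouts)) return(empty_wb_df(stream$system))
  rows <- lapply(seq_along(bouts), function(i) {
    agg <- aggregate_bout_dmos(bouts[[i]], config)
    cc <- classify_complexity(agg$start_s, agg$end_s, stream$turns, config)
    cbind(data.frame(bout_id = i, system = stream$system,
                     stringsAsFactors = FALSE),
          agg,
          data.frame(turn_fraction = cc$turn_fraction,
                     complexity = cc$complexity, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_wb_df <- function(system = character(0)) {
  data.frame(bout_id = integer(0), system = character(0),
             start_s = numeric(0), end_s = numeric(0),
             duration_s = numeric(0), n_strides = integer(0),
             mean_cadence_spm = numeric(0), mean_stride_length_m = numeric(0),
             mean_speed_mps = numeric(0), turn_fraction = numeric(0),
             complexity = character(0), stringsAsFactors = FALSE)
}
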