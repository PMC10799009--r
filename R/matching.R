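# True-positive bout matching and sample-wise walking-detection metrics.

#' Matching configuration
#'
#' A reference and a device walking bout form a true-positive pair when
#' their temporal overlap is large enough. The published criterion —
#' "overlap of more than 80%" — does not name the denominator, so the rule
#' is explicit here:
#' \describe{
#'   \item{both}{(default, strictest symmetric reading) the intersection
#'     must exceed the threshold fraction of \emph{both} bouts' durations;}
#'   \item{reference}{of the reference bout's duration only;}
#'   \item{union}{of the union of the two spans (Jaccard index).}
#' }
#' The comparison is strict (`>`). Candidates are assigned one-to-one
#' greedily by descending overlap seconds, ties broken by earlier reference
#' start.
#'
#' @param overlap_threshold Fraction in (0, 1]; default 0.80.
#' @param denominator_rule `"both"`, `"reference"` or `"union"`.
#' @return A list of class `match_config`.
#' @export
match_config <- function(overlap_threshold = 0.80,
                         denominator_rule = c("both", "reference", "union")) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  structure(list(overlap_threshold = overlap_threshold,
                 denominator_rule = match.arg(denominator_rule)),
            class = "match_config")
}

overlap_fraction <- function(ov, dur_ref, dur_dev, rule) {
  switch(rule,
         both = pmin(ov / dur_ref, ov / dur_dev),
         reference = ov / dur_ref,
         union = ov / (dur_ref + dur_dev - ov))
}

assert_non_overlapping <- function(wbs, label) {
  if (nrow(wbs) < 2) return(invisible())
  o <- order(wbs$start_s)
  if (any(wbs$start_s[o][-1] < wbs$end_s[o][-nrow(wbs)] - 1e-9))
    stop("overlapping bouts within the ", label, " list", call. = FALSE)
}

#' Match walking bouts between systems
#'
#' Identifies true-positive pairs: all (reference, device) bout pairs with
#' positive temporal intersection are scored by their overlap fraction
#' under the configured denominator rule, pairs exceeding the threshold are
#' assigned one-to-one greedily by descending overlap seconds (ties: earlier
#' reference start, then earlier device start).
#'
#' @param ref_wbs,dev_wbs Walking-bout data frames (see [process_stream()]);
#'   each list must be internally non-overlapping.
#' @param config A [match_config()].
#' @return A list with `pairs` (data frame: `ref_idx`, `dev_idx`,
#'   `overlap_s`, `overlap_fraction`, plus `ref_`/`dev_`-prefixed bout
#'   columns and `speed_error`, `relative_error_pct`), `unmatched_ref` and
#'   `unmatched_dev` (row indices).
#' @export
match_bouts <- function(ref_wbs, dev_wbs, config = match_config()) {
  assert_non_overlapping(ref_wbs, "reference")
  assert_non_overlapping(dev_wbs, "device")
  nr <- nrow(ref_wbs); nd <- nrow(dev_wbs)
  cand <- NULL
  if (nr && nd) {
    grid <- expand.grid(ref_idx = seq_len(nr), dev_idx = seq_len(nd))
    ov <- interval_overlap_len(ref_wbs$start_s[grid$ref_idx],
                               ref_wbs$end_s[grid$ref_idx],
                               dev_wbs$start_s[grid$dev_idx],
                               dev_wbs$end_s[grid$dev_idx])
    frac <- overlap_fraction(ov,
                             ref_wbs$duration_s[grid$ref_idx],
                             dev_wbs$duration_s[grid$dev_idx],
                             config$denominator_rule)
    # strict ">" per the published criterion; a perfect overlap (fraction
    # exactly 1) matches at any admissible threshold, including 1.0
    keep <- ov > 0 & (frac > config$overlap_threshold | frac >= 1)
    cand <- cbind(grid[keep, , drop = FALSE],
                  overlap_s = ov[keep], overlap_fraction = frac[keep])
  }
  sel <- integer(0)
  if (!is.null(cand) && nrow(cand)) {
    ord <- order(-cand$overlap_s, ref_wbs$start_s[cand$ref_idx],
                 dev_wbs$start_s[cand$dev_idx])
    cand <- cand[ord, , drop = FALSE]
    used_r <- logical(nr); used_d <- logical(nd)
    for (i in seq_len(nrow(cand))) {
      r <- cand$ref_idx[i]; d <- cand$dev_idx[i]
      if (!used_r[r] && !used_d[d]) {
        used_r[r] <- TRUE; used_d[d] <- TRUE
        sel <- c(sel, i)
      }
    }
  }
  pairs <- if (length(sel)) {
    p <- cand[sel, , drop = FALSE]
    pref <- ref_wbs[p$ref_idx, , drop = FALSE]
    pdev <- dev_wbs[p$dev_idx, , drop = FALSE]
    names(pref) <- paste0("ref_", names(pref))
    names(pdev) <- paste0("dev_", names(pdev))
    out <- cbind(p, pref, pdev)
    out$speed_error <- out$dev_mean_speed_mps - out$ref_mean_speed_mps
    out$relative_error_pct <-
      ifelse(out$ref_mean_speed_mps > 0,
             100 * out$speed_error / out$ref_mean_speed_mps, NA_real_)
    out <- out[order(out$ref_idx), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else empty_pairs_df(ref_wbs, dev_wbs)
  list(pairs = pairs,
       unmatched_ref = setdiff(seq_len(nr), pairs$ref_idx),
       unmatched_dev = setdiff(seq_len(nd), pairs$dev_idx))
}

empty_pairs_df <- function(ref_wbs, dev_wbs) {
  pref <- ref_wbs[0, , drop = FALSE]
  pdev <- dev_wbs[0, , drop = FALSE]
  names(pref) <- paste0("ref_", names(pref))
  names(pdev) <- paste0("dev_", names(pdev))
  out <- cbind(data.frame(ref_idx = integer(0), dev_idx = integer(0),
                          overlap_s = numeric(0),
                          overlap_fraction = numeric(0)),
               pref, pdev)
  out$speed_error <- numeric(0)
  out$relative_error_pct <- numeric(0)
  out
}

#' Rasterize walking bouts onto the sample grid
#'
#' Sample `k` (0-based) represents time `(k + 0.5) / rate`; it is marked as
#' walking when that midpoint falls inside any bout span (closed on both
#' ends, so abutting fragments cover the same samples as their union).
#'
#' @param wbs Walking-bout data frame.
#' @param duration_s Recording duration (s).
#' @param sample_rate_hz Grid rate (Hz).
#' @return Logical vector of length `round(duration_s * sample_rate_hz)`.
#' @export
rasterize_bouts <- function(wbs, duration_s, sample_rate_hz = 100) {
  n <- round(duration_s * sample_rate_hz)
  mask <- logical(n)
  for (i in seq_len(nrow(wbs))) {
    k0 <- ceiling(wbs$start_s[i] * sample_rate_hz - 0.5)
    k1 <- floor(wbs$end_s[i] * sample_rate_hz - 0.5)
    if (k1 >= k0)
      mask[max(0, k0):min(n - 1, k1) + 1] <- TRUE
  }
  mask
}

#' Sample-wise detection confusion
#'
#' Compares device-detected against reference walking regions sample by
#' sample on the recording grid and reports the confusion counts plus the
#' derived metrics: accuracy, sensitivity, specificity and positive
#' predictive value. A metric whose denominator is zero is `NA` (flagged
#' undefined), never silently zero.
#'
#' @param ref_wbs,dev_wbs Walking-bout data frames, within
#'   `[0, duration_s]`.
#' @param duration_s Recording duration (s).
#' @param sample_rate_hz Grid rate (Hz), default 100.
#' @return One-row data frame: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`.
#' @export
samplewise_confusion <- function(ref_wbs, dev_wbs, duration_s,
                                 sample_rate_hz = 100) {
  ref <- rasterize_bouts(ref_wbs, duration_s, sample_rate_hz)
  dev <- rasterize_bouts(dev_wbs, duration_s, sample_rate_hz)
  confusion_from_masks(ref, dev)
}

#' Confusion metrics from binary masks
#'
#' @param ref,dev Logical vectors of equal length (reference and device
#'   walking masks).
#' @return One-row data frame as in [samplewise_confusion()].
#' @export
confusion_from_masks <- function(ref, dev) {
  stopifnot(length(ref) == length(dev))
  tp <- sum(ref & dev); fp <- sum(!ref & dev)
  fn <- sum(ref & !dev); tn <- sum(!ref & !dev)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             accuracy = ratio(tp + tn, tp + fp + fn + tn),
             sensitivity = ratio(tp, tp + fn),
             specificity = ratio(tn, tn + fp),
             ppv = ratio(tp, tp + fp))
}

#' Aggregate per-participant detection metrics
#'
#' Detection performance is computed per participant and then aggregated
#' per cohort as the unweighted mean, with seeded percentile-bootstrap
#' intervals over participants (undefined per-participant metrics are
#' dropped from both mean and bootstrap).
#'
#' @param confusions Data frame of per-participant rows (as from
#'   [samplewise_confusion()]) with added `participant_id` and `cohort`
#'   columns.
#' @param by Grouping column, default `"cohort"`; use `NULL` for a single
#'   overall group labelled `"All"`.
#' @param bootstrap A [bootstrap_config()].
#' @return Data frame: group, `n_participants`, and for each metric its
#'   mean, `*_lo`, `*_hi`.
#' @export
aggregate_detection <- function(confusions, by = "cohort",
                                bootstrap = bootstrap_config()) {
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv")
  groups <- if (is.null(by)) rep("All", nrow(confusions))
  else confusions[[by]]
  out <- lapply(unique(groups), function(g) {
    sub <- confusions[groups == g, , drop = FALSE]
    row <- data.frame(group = g, n_participants = nrow(sub),
                      stringsAsFactors = FALSE)
    for (m in metrics) {
      x <- sub[[m]][!is.na(sub[[m]])]
      row[[m]] <- if (length(x)) mean(x) else NA_real_
      ci <- bootstrap_ci(x, mean, bootstrap)
      row[[paste0(m, "_lo")]] <- ci[1]
      row[[paste0(m, "_hi")]] <- ci[2]
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
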