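#' @keywords internal
"_PACKAGE"

# Domain containers -----------------------------------------------------------

COHORTS <- c("HA", "CHF", "COPD", "MS", "PD", "PFF")
SYSTEMS <- c("device", "reference")
SCHEMA_VERSION <- "wbgait-stream-1"

empty_stride_df <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             laterality = character(0), cadence_spm = numeric(0),
             stride_length_m = numeric(0), speed_mps = numeric(0),
             stringsAsFactors = FALSE)
}

empty_secondly_df <- function() {
  data.frame(second_index = integer(0), cadence_spm = numeric(0),
             stride_length_m = numeric(0), stringsAsFactors = FALSE)
}

empty_turns_df <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0), stringsAsFactors = FALSE)
}

#' Construct a stride stream
#'
#' A stride stream is one system's complete gait output for one recording:
#' the ordered stride events (initial-contact timing plus laterality), the
#' per-second cadence and stride-length traces produced by the upstream
#' estimation algorithms, and the detected turn intervals. It is the common
#' currency of the whole package: the bout pipeline consumes it, the
#' synthetic generator produces it, and the readers/writers serialize it.
#'
#' Strides of opposite feet may overlap in time (double support); strides of
#' the same foot may not. Per-second values may be `NA`, which marks a
#' missing measurement within a gait sequence, as opposed to an absent row,
#' which means no walking was detected in that second.
#'
#' @param system `"device"` or `"reference"`.
#' @param recording_id,participant_id Character identifiers.
#' @param cohort One of `"HA"`, `"CHF"`, `"COPD"`, `"MS"`, `"PD"`, `"PFF"`.
#' @param context Recording context, e.g. `"real_world"` or
#'   `"laboratory_task:straight_slow"`.
#' @param duration_s Recording duration in seconds.
#' @param strides Data frame with columns `start_s`, `end_s`, `laterality`
#'   and optionally `cadence_spm`, `stride_length_m`, `speed_mps`.
#' @param secondly Data frame with columns `second_index`, `cadence_spm`,
#'   `stride_length_m`.
#' @param turns Data frame with columns `start_s`, `end_s`.
#' @param validate If `TRUE` (default), stop on any invariant violation.
#' @return An object of class `stride_stream`.
#' @seealso [validate_stream()], [read_stride_stream()], [process_stream()]
#' @export
stride_stream <- function(system, recording_id, participant_id,
                          cohort = "HA", context = "real_world",
                          duration_s = NULL,
                          strides = empty_stride_df(),
                          secondly = empty_secondly_df(),
                          turns = empty_turns_df(),
                          validate = TRUE) {
  strides <- as.data.frame(strides, stringsAsFactors = FALSE)
  for (col in c("cadence_spm", "stride_length_m", "speed_mps"))
    if (is.null(strides[[col]])) strides[[col]] <- rep(NA_real_, nrow(strides))
  if (nrow(strides)) {
    strides <- strides[order(strides$start_s, strides$end_s), , drop = FALSE]
    rownames(strides) <- NULL
  }
  secondly <- as.data.frame(secondly, stringsAsFactors = FALSE)
  if (nrow(secondly)) {
    secondly <- secondly[order(secondly$second_index), , drop = FALSE]
    rownames(secondly) <- NULL
  }
  turns <- as.data.frame(turns, stringsAsFactors = FALSE)
  if (nrow(turns)) {
    turns <- turns[order(turns$start_s, turns$end_s), , drop = FALSE]
    rownames(turns) <- NULL
  }
  if (is.null(duration_s))
    duration_s <- max(0, strides$end_s, turns$end_s,
                      if (nrow(secondly)) secondly$second_index + 1)
  x <- structure(list(system = system, recording_id = recording_id,
                      participant_id = participant_id, cohort = cohort,
                      context = context, duration_s = as.numeric(duration_s),
                      strides = strides, secondly = secondly, turns = turns),
                 class = "stride_stream")
  if (validate) {
    v <- validate_stream(x)
    if (length(v))
      stop("invalid stride_stream:\n", paste("-", v, collapse = "\n"),
           call. = FALSE)
  }
  x
}

#' Construct a paired recording session
#'
#' Bundles the reference-system and device stride streams of one recording.
#' The two streams must agree on identifiers and duration; the sample grid
#' used for sample-wise detection metrics is derived from `sample_rate_hz`.
#'
#' @param reference,device `stride_stream` objects for the two systems.
#' @param sample_rate_hz Sampling rate of the underlying devices (Hz).
#' @param validate If `TRUE`, stop when [validate_session()] reports
#'   violations.
#' @return An object of class `gait_session`.
#' @export
gait_session <- function(reference, device, sample_rate_hz = 100,
                         validate = TRUE) {
  x <- structure(list(recording_id = reference$recording_id,
                      reference = reference, device = device,
                      sample_rate_hz = sample_rate_hz),
                 class = "gait_session")
  if (validate) {
    v <- validate_session(x)
    if (length(v))
      stop("invalid gait_session:\n", paste("-", v, collapse = "\n"),
           call. = FALSE)
  }
  x
}

# Validation ------------------------------------------------------------------

#' Validate a stride stream
#'
#' Checks every container invariant and returns a character vector of
#' human-readable violation descriptors (empty when the stream is valid).
#' Violations are data, not exceptions, so callers can collect and report
#' them all at once.
#'
#' @param stream A `stride_stream`.
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_stream <- function(stream) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!stream$system %in% SYSTEMS)
    add(sprintf("system '%s' not one of %s", stream$system,
                paste(SYSTEMS, collapse = "/")))
  if (!stream$cohort %in% COHORTS)
    add(sprintf("cohort '%s' not one of %s", stream$cohort,
                paste(COHORTS, collapse = "/")))
  s <- stream$strides
  if (nrow(s)) {
    bad <- which(!(s$end_s > s$start_s))
    for (i in bad) add(sprintf("stride %d: end_s (%g) <= start_s (%g)",
                               i, s$end_s[i], s$start_s[i]))
    bad <- which(!s$laterality %in% c("L", "R"))
    for (i in bad) add(sprintf("stride %d: laterality '%s' not L/R",
                               i, s$laterality[i]))
    if (is.unsorted(s$start_s)) add("strides not sorted by start_s")
    for (col in c("cadence_spm", "stride_length_m", "speed_mps")) {
      bad <- which(!is.na(s[[col]]) & s[[col]] < 0)
      for (i in bad) add(sprintf("stride %d: %s negative", i, col))
    }
    bad <- which(!is.na(s$cadence_spm) & s$cadence_spm == 0)
    for (i in bad) add(sprintf("stride %d: cadence_spm must be > 0", i))
    # same-foot strides must not overlap; opposite feet may (double support)
    for (foot in c("L", "R")) {
      f <- s[s$laterality == foot & s$laterality %in% c("L", "R"), ,
             drop = FALSE]
      if (nrow(f) > 1) {
        f <- f[order(f$start_s), , drop = FALSE]
        ov <- which(f$start_s[-1] < f$end_s[-nrow(f)] - 1e-9)
        for (i in ov)
          add(sprintf("same-foot (%s) strides overlap: [%g,%g] and [%g,%g]",
                      foot, f$start_s[i], f$end_s[i],
                      f$start_s[i + 1], f$end_s[i + 1]))
      }
    }
    if (stream$duration_s < max(s$end_s) - 1e-9)
      add(sprintf("duration_s (%g) < last stride end (%g)",
                  stream$duration_s, max(s$end_s)))
  }
  sec <- stream$secondly
  if (nrow(sec)) {
    if (any(sec$second_index < 0)) add("secondly: negative second_index")
    if (anyDuplicated(sec$second_index))
      add("secondly: duplicated second_index")
    for (col in c("cadence_spm", "stride_length_m")) {
      if (any(!is.na(sec[[col]]) & sec[[col]] < 0))
        add(sprintf("secondly: negative %s", col))
    }
  }
  tu <- stream$turns
  if (nrow(tu)) {
    bad <- which(!(tu$end_s > tu$start_s))
    for (i in bad) add(sprintf("turn %d: end_s <= start_s", i))
    if (any(tu$start_s < 0) || any(tu$end_s > stream$duration_s + 1e-9))
      add("turns extend outside recording span")
  }
  v
}

#' Validate a paired session
#'
#' Runs [validate_stream()] on both streams and checks co-registration:
#' matching recording and participant identifiers, equal duration, correct
#' system labels and a positive sample rate.
#'
#' @param session A `gait_session`.
#' @return Character vector of violations; `character(0)` if coherent.
#' @export
validate_session <- function(session) {
  v <- character(0)
  for (sys in c("reference", "device")) {
    sv <- validate_stream(session[[sys]])
    if (length(sv)) v <- c(v, paste0(sys, ": ", sv))
  }
  r <- session$reference; d <- session$device
  if (r$system != "reference") v <- c(v, "reference stream mislabelled")
  if (d$system != "device") v <- c(v, "device stream mislabelled")
  if (!identical(r$recording_id, d$recording_id))
    v <- c(v, "recording_id differs between systems")
  if (!identical(r$participant_id, d$participant_id))
    v <- c(v, "participant_id differs between systems")
  if (!isTRUE(all.equal(r$duration_s, d$duration_s)))
    v <- c(v, sprintf("duration_s differs: reference %g vs device %g",
                      r$duration_s, d$duration_s))
  if (!is.numeric(session$sample_rate_hz) || session$sample_rate_hz <= 0)
    v <- c(v, "sample_rate_hz must be > 0")
  v
}

#' @export
print.stride_stream <- function(x, ...) {
  cat(sprintf("<stride_stream> %s / %s (%s, %s, %s)\n",
              x$recording_id, x$system, x$participant_id, x$cohort, x$context))
  cat(sprintf("  duration %.1f s, %d strides, %d secondly samples, %d turns\n",
              x$duration_s, nrow(x$strides), nrow(x$secondly), nrow(x$turns)))
  invisible(x)
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> %s @ %g Hz\n", x$recording_id, x$sample_rate_hz))
  cat(sprintf("  reference: %d strides | device: %d strides\n",
              nrow(x$reference$strides), nrow(x$device$strides)))
  invisible(x)
}
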