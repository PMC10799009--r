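# Seeded generator of paired reference/device gait-event streams.
#
# The reference stream plays the role of a multi-sensor ground-truth system:
# walking bouts drawn from a cohort-specific speed distribution and a
# log-normal duration distribution skewed toward short bouts, each bout a
# strictly alternating L/R stride train with self-consistent per-second
# cadence/stride-length traces. The device stream is the reference degraded
# by the error phenomenology reported for single lower-back sensors: whole
# bouts missed (low sensitivity), long bouts fragmented into separate
# segments, initial-contact jitter, occasional laterality misclassification,
# a speed-dependent bias applied through stride length (overestimation of
# slow and underestimation of fast walking), and rare spurious walking.

#' Cohort profile for the synthetic generator
#'
#' Defaults encode the real-world reference walking-speed means of the six
#' study cohorts (healthy adults 0.72, congestive heart failure 0.95, COPD
#' 0.65, multiple sclerosis 0.67, Parkinson's 0.76, proximal femoral
#' fracture 0.66 m/s), a bout-duration distribution with roughly two thirds
#' of bouts shorter than 30 s, and about 20 bouts per hour of recording.
#'
#' @param cohort Cohort label (`"HA"`, `"CHF"`, `"COPD"`, `"MS"`, `"PD"`,
#'   `"PFF"`).
#' @param mean_speed_mps,speed_sd_mps Per-bout walking-speed distribution
#'   (normal, truncated above `min_speed_mps`).
#' @param min_speed_mps Truncation point of the speed distribution (m/s).
#' @param bout_duration_meanlog,bout_duration_sdlog Log-normal bout-duration
#'   parameters (log seconds).
#' @param bouts_per_hour Expected walking-bout rate.
#' @param turn_rate_per_min Expected turns per minute of walking.
#' @return A list of class `cohort_profile`.
#' @export
cohort_profile <- function(cohort,
                           mean_speed_mps = c(HA = 0.72, CHF = 0.95,
                                              COPD = 0.65, MS = 0.67,
                                              PD = 0.76, PFF = 0.66)[[cohort]],
                           speed_sd_mps = 0.25,
                           min_speed_mps = 0.1,
                           bout_duration_meanlog = log(20),
                           bout_duration_sdlog = 1.0,
                           bouts_per_hour = 20,
                           turn_rate_per_min = 2) {
  stopifnot(cohort %in% COHORTS, mean_speed_mps > 0, speed_sd_mps > 0,
            bout_duration_sdlog > 0, bouts_per_hour >= 0,
            turn_rate_per_min >= 0)
  structure(list(cohort = cohort, mean_speed_mps = mean_speed_mps,
                 speed_sd_mps = speed_sd_mps, min_speed_mps = min_speed_mps,
                 bout_duration_meanlog = bout_duration_meanlog,
                 bout_duration_sdlog = bout_duration_sdlog,
                 bouts_per_hour = bouts_per_hour,
                 turn_rate_per_min = turn_rate_per_min),
            class = "cohort_profile")
}

#' Default profiles for all six cohorts
#' @return Named list of [cohort_profile()] objects.
#' @export
default_cohort_profiles <- function() {
  stats::setNames(lapply(COHORTS, cohort_profile), COHORTS)
}

#' Device error model
#'
#' Controls how the device stream is degraded from the reference stream.
#' Defaults are calibrated to the aggregate detection performance reported
#' for the single lower-back device (sample-wise sensitivity about 0.65,
#' specificity about 0.99) and to the observed speed-dependent bias: the
#' per-bout speed error is `e = a + b * v_ref + noise`, with `b < 0` so
#' slow bouts are overestimated and fast bouts underestimated (zero
#' crossing at 1 m/s with the defaults).
#'
#' @param miss_bout_prob Probability a reference bout is missed entirely
#'   (default 0.35, i.e. bout-level sensitivity 0.65).
#' @param slow_miss_extra Additional miss probability for bouts slower than
#'   `slow_speed_mps` (default 0: misses independent of speed).
#' @param slow_speed_mps Speed below which `slow_miss_extra` applies.
#' @param false_walk_rate_per_h Expected spurious device bouts per hour
#'   (kept small; the default reproduces specificity near 0.99).
#' @param fragmentation_prob Probability a sufficiently long bout is split
#'   into two fragments.
#' @param fragment_gap_s Silent gap inserted when fragmenting; must exceed
#'   3 s so the fragments remain separate bouts under assembly.
#' @param ic_jitter_sd_s SD of the per-stride timing jitter (s).
#' @param laterality_flip_prob Probability a stride's foot label is flipped.
#' @param speed_bias_intercept_a,speed_bias_slope_b Linear speed-error
#'   model coefficients (m/s and dimensionless).
#' @param speed_noise_sd SD of the per-bout speed error noise (m/s).
#' @param per_second_noise_sd SD of additive per-second stride-length noise
#'   (m).
#' @return A list of class `device_error_model`.
#' @export
device_error_model <- function(miss_bout_prob = 0.35,
                               slow_miss_extra = 0,
                               slow_speed_mps = 0.5,
                               false_walk_rate_per_h = 4,
                               fragmentation_prob = 0.15,
                               fragment_gap_s = 4,
                               ic_jitter_sd_s = 0.02,
                               laterality_flip_prob = 0.005,
                               speed_bias_intercept_a = 0.25,
                               speed_bias_slope_b = -0.25,
                               speed_noise_sd = 0.15,
                               per_second_noise_sd = 0.02) {
  stopifnot(miss_bout_prob >= 0, miss_bout_prob <= 1,
            slow_miss_extra >= 0, fragmentation_prob >= 0,
            fragmentation_prob <= 1, fragment_gap_s > 3,
            ic_jitter_sd_s >= 0, laterality_flip_prob >= 0,
            laterality_flip_prob <= 1, speed_noise_sd >= 0,
            per_second_noise_sd >= 0, false_walk_rate_per_h >= 0)
  structure(list(miss_bout_prob = miss_bout_prob,
                 slow_miss_extra = slow_miss_extra,
                 slow_speed_mps = slow_speed_mps,
                 false_walk_rate_per_h = false_walk_rate_per_h,
                 fragmentation_prob = fragmentation_prob,
                 fragment_gap_s = fragment_gap_s,
                 ic_jitter_sd_s = ic_jitter_sd_s,
                 laterality_flip_prob = laterality_flip_prob,
                 speed_bias_intercept_a = speed_bias_intercept_a,
                 speed_bias_slope_b = speed_bias_slope_b,
                 speed_noise_sd = speed_noise_sd,
                 per_second_noise_sd = per_second_noise_sd),
            class = "device_error_model")
}

#' Error-free device model (device = reference)
#' @return A [device_error_model()] with every degradation disabled.
#' @export
zero_error_model <- function() {
  device_error_model(miss_bout_prob = 0, slow_miss_extra = 0,
                     false_walk_rate_per_h = 0, fragmentation_prob = 0,
                     ic_jitter_sd_s = 0, laterality_flip_prob = 0,
                     speed_bias_intercept_a = 0, speed_bias_slope_b = 0,
                     speed_noise_sd = 0, per_second_noise_sd = 0)
}

#' Study generator configuration
#'
#' Defaults mirror the study conditions: six cohorts with their real-world
#' sample sizes (17/9/17/13/15/11 participants for HA/CHF/COPD/MS/PD/PFF),
#' one 2.5-hour real-world recording per participant, and the default
#' [device_error_model()].
#'
#' @param profiles Named list of [cohort_profile()]s.
#' @param error_model A [device_error_model()].
#' @param duration_s Recording duration (s), default 9000 (2.5 h).
#' @param n_participants Named integer vector of participants per cohort
#'   (names must match `profiles`).
#' @param sample_rate_hz Device sampling rate (Hz).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(profiles = default_cohort_profiles(),
                             error_model = device_error_model(),
                             duration_s = 9000,
                             n_participants = c(HA = 17, CHF = 9, COPD = 17,
                                                MS = 13, PD = 15, PFF = 11),
                             sample_rate_hz = 100,
                             seed = 1) {
  n_participants <- n_participants[names(n_participants) %in% names(profiles)]
  stopifnot(length(n_participants) > 0, all(n_participants >= 1),
            duration_s > 0)
  structure(list(profiles = profiles, error_model = error_model,
                 duration_s = duration_s, n_participants = n_participants,
                 sample_rate_hz = sample_rate_hz, seed = as.integer(seed)),
            class = "generator_config")
}

rtruncnorm1 <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0
  while (length(bad) && guard < 1000) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= lower)
    guard <- guard + 1
  }
  out[out <= lower] <- lower + sd / 10
  out
}

# place n bout durations in [0, duration] with >= min_sep between bouts and
# at the edges; drops the longest bouts if they cannot fit
place_bouts <- function(durations, duration_s, min_sep = 5) {
  durations <- durations[order(durations)]  # drop longest first if needed
  while (length(durations) &&
         sum(durations) + (length(durations) + 1) * min_sep > duration_s)
    durations <- durations[-length(durations)]
  n <- length(durations)
  if (!n) return(data.frame(start = numeric(0), dur = numeric(0)))
  durations <- durations[sample.int(n)]     # random order along the recording
  free <- duration_s - sum(durations) - (n + 1) * min_sep
  cuts <- sort(stats::runif(n))
  extra <- free * diff(c(0, cuts))
  starts <- min_sep + cumsum(extra) +
    cumsum(c(0, durations[-n] + min_sep))
  data.frame(start = starts, dur = durations)
}

# one bout's stride train + constant per-second trace parameters
make_bout_strides <- function(t0, dur, v) {
  cad_lo <- max(48, 60 * v)
  cad_hi <- min(130, 600 * v)
  cad <- min(cad_hi, max(cad_lo, stats::rnorm(1, 105, 10)))
  len <- 120 * v / cad
  step <- 60 / cad
  n_steps <- max(4, round(dur / step) - 1)
  starts <- t0 + (seq_len(n_steps) - 1) * step
  data.frame(start_s = starts, end_s = starts + 2 * step,
             laterality = rep_len(c("L", "R"), n_steps),
             cadence_spm = cad, stride_length_m = len,
             speed_mps = NA_real_, stringsAsFactors = FALSE)
}

#' Generate a reference (ground-truth) stride stream
#'
#' Draws a Poisson number of bouts at the profile's hourly rate, places
#' them without overlap (at least 5 s apart so bouts remain distinct under
#' the 3 s break rule), fills each with a strictly alternating L/R stride
#' train whose cadence and stride length reproduce the bout's target speed,
#' derives consistent per-second traces, and inserts turn intervals at the
#' profile's turn rate. Stride rows carry timing and laterality only
#' (per-stride DMOs are the interpolation stage's job); the constant
#' within-bout traces make interpolation exact.
#'
#' @param profile A [cohort_profile()].
#' @param duration_s Recording length (s).
#' @param recording_id,participant_id Identifiers.
#' @param seed Optional integer; when given, the stream is generated under
#'   a local RNG state seeded with it.
#' @return A `stride_stream` (system `"reference"`) with a `"bouts"`
#'   attribute recording each placed bout's span and target speed.
#' @export
generate_reference_stream <- function(profile, duration_s,
                                      recording_id = "rec1",
                                      participant_id = "p1",
                                      seed = NULL) {
  if (!is.null(seed))
    return(with_local_seed(seed,
      generate_reference_stream(profile, duration_s, recording_id,
                                participant_id)))
  n_target <- stats::rpois(1, profile$bouts_per_hour * duration_s / 3600)
  durations <- stats::rlnorm(n_target, profile$bout_duration_meanlog,
                             profile$bout_duration_sdlog)
  durations <- pmin(pmax(durations, 4), min(600, duration_s / 2))
  placed <- place_bouts(durations, duration_s)
  strides <- empty_stride_df()
  secondly <- empty_secondly_df()
  turns <- empty_turns_df()
  bouts <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      speed_mps = numeric(0))
  for (i in seq_len(nrow(placed))) {
    v <- rtruncnorm1(1, profile$mean_speed_mps, profile$speed_sd_mps,
                     profile$min_speed_mps)
    st <- make_bout_strides(placed$start[i], placed$dur[i], v)
    span <- c(min(st$start_s), max(st$end_s))
    secs <- seq.int(floor(span[1]), ceiling(span[2]) - 1)
    secondly <- rbind(secondly,
                      data.frame(second_index = secs,
                                 cadence_spm = st$cadence_spm[1],
                                 stride_length_m = st$stride_length_m[1]))
    n_turns <- stats::rpois(1, profile$turn_rate_per_min *
                              (span[2] - span[1]) / 60)
    if (n_turns) {
      ts <- stats::runif(n_turns, span[1], span[2])
      te <- pmin(ts + stats::runif(n_turns, 1, 3), span[2])
      keep <- te > ts
      turns <- rbind(turns, data.frame(start_s = ts[keep],
                                       end_s = te[keep]))
    }
    st$cadence_spm <- NA_real_
    st$stride_length_m <- NA_real_
    strides <- rbind(strides, st)
    bouts <- rbind(bouts, data.frame(start_s = span[1], end_s = span[2],
                                     speed_mps = v))
  }
  secondly <- secondly[!duplicated(secondly$second_index), , drop = FALSE]
  secondly <- secondly[order(secondly$second_index), , drop = FALSE]
  if (nrow(turns)) turns <- turns[order(turns$start_s), , drop = FALSE]
  out <- stride_stream(system = "reference", recording_id = recording_id,
                       participant_id = participant_id,
                       cohort = profile$cohort, context = "real_world",
                       duration_s = duration_s, strides = strides,
                       secondly = secondly, turns = turns)
  attr(out, "bouts") <- bouts
  out
}

group_strides_by_gap <- function(strides, max_gap = 3) {
  n <- nrow(strides)
  if (!n) return(integer(0))
  gap <- pmax(0, strides$start_s[-1] - strides$end_s[-n])
  cumsum(c(TRUE, gap > max_gap))
}

#' Degrade a reference stream into a device stream
#'
#' Applies the device error model bout by bout: whole-bout misses (with an
#' optional extra miss probability for slow bouts), fragmentation of long
#' bouts by a silent gap wider than the 3 s break threshold, per-stride
#' timing jitter, laterality flips (same-foot overlaps created by a flip
#' are resolved by truncating the earlier stride), a per-bout speed error
#' `e = a + b * v_ref + N(0, sd)` applied through the per-second stride
#' length, additive per-second noise, and spurious walking bouts in
#' non-walking time.
#'
#' @param reference A reference `stride_stream`.
#' @param model A [device_error_model()].
#' @param seed Optional integer for a locally seeded run.
#' @return A device `stride_stream` with an `"injected"` attribute: one row
#'   per reference bout (`start_s`, `end_s`, `v_ref`, `missed`,
#'   `fragmented`, `speed_error`) for parameter-recovery checks.
#' @export
degrade_to_device_stream <- function(reference, model = device_error_model(),
                                     seed = NULL) {
  if (!is.null(seed))
    return(with_local_seed(seed,
      degrade_to_device_stream(reference, model)))
  st <- reference$strides
  sec <- reference$secondly
  bid <- group_strides_by_gap(st, 3)
  sec_speed <- stride_speed(ifelse(is.na(sec$cadence_spm), NA, sec$cadence_spm),
                            sec$stride_length_m)
  dev_strides <- empty_stride_df()
  dev_sec <- empty_secondly_df()
  injected <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         v_ref = numeric(0), missed = logical(0),
                         fragmented = logical(0), speed_error = numeric(0))
  for (b in unique(bid)) {
    bs <- st[bid == b, , drop = FALSE]
    span <- c(min(bs$start_s), max(bs$end_s))
    insec <- sec$second_index >= floor(span[1]) &
      sec$second_index < ceiling(span[2])
    v <- mean(sec_speed[insec], na.rm = TRUE)
    p_miss <- min(1, model$miss_bout_prob +
                    if (v < model$slow_speed_mps) model$slow_miss_extra else 0)
    missed <- stats::runif(1) < p_miss
    if (missed) {
      injected <- rbind(injected,
                        data.frame(start_s = span[1], end_s = span[2],
                                   v_ref = v, missed = TRUE,
                                   fragmented = FALSE,
                                   speed_error = NA_real_))
      next
    }
    fragmented <- FALSE
    min_frag <- 6   # each fragment keeps >= ~6 s so it survives assembly
    if (stats::runif(1) < model$fragmentation_prob &&
        diff(span) > 2 * min_frag + model$fragment_gap_s) {
      centre <- stats::runif(1, span[1] + min_frag + model$fragment_gap_s / 2,
                             span[2] - min_frag - model$fragment_gap_s / 2)
      w <- c(centre - model$fragment_gap_s / 2,
             centre + model$fragment_gap_s / 2)
      keep <- bs$end_s <= w[1] | bs$start_s >= w[2]
      fragmented <- sum(keep) < nrow(bs)
      bs <- bs[keep, , drop = FALSE]
    }
    if (model$ic_jitter_sd_s > 0 && nrow(bs)) {
      d <- stats::rnorm(nrow(bs), 0, model$ic_jitter_sd_s)
      bs$start_s <- bs$start_s + d
      bs$end_s <- bs$end_s + d
      bs <- bs[order(bs$start_s), , drop = FALSE]
    }
    if (model$laterality_flip_prob > 0 && nrow(bs)) {
      flip <- stats::runif(nrow(bs)) < model$laterality_flip_prob
      bs$laterality[flip] <- ifelse(bs$laterality[flip] == "L", "R", "L")
    }
    bs <- resolve_same_foot_overlaps(bs)
    e <- model$speed_bias_intercept_a + model$speed_bias_slope_b * v +
      (if (model$speed_noise_sd > 0) stats::rnorm(1, 0, model$speed_noise_sd)
       else 0)
    f <- max(0.05, (v + e) / v)
    if (nrow(bs)) {
      bsec <- sec[insec, , drop = FALSE]
      covered <- vapply(bsec$second_index, function(k)
        any(bs$start_s < k + 1 & bs$end_s > k), TRUE)
      bsec <- bsec[covered, , drop = FALSE]
      bsec$stride_length_m <- pmax(0, bsec$stride_length_m * f +
        (if (model$per_second_noise_sd > 0)
          stats::rnorm(nrow(bsec), 0, model$per_second_noise_sd) else 0))
      dev_sec <- rbind(dev_sec, bsec)
      dev_strides <- rbind(dev_strides, bs)
    }
    injected <- rbind(injected,
                      data.frame(start_s = span[1], end_s = span[2],
                                 v_ref = v, missed = FALSE,
                                 fragmented = fragmented, speed_error = e))
  }
  # spurious walking in non-walking time
  n_false <- if (model$false_walk_rate_per_h > 0)
    stats::rpois(1, model$false_walk_rate_per_h * reference$duration_s / 3600)
  else 0
  if (n_false > 0) {
    occupied <- merge_intervals(
      c(st$start_s, dev_strides$start_s) - 6,
      c(st$end_s, dev_strides$end_s) + 6)
    for (j in seq_len(n_false)) {
      fdur <- stats::runif(1, 5, 10)
      for (try in 1:20) {
        t0 <- stats::runif(1, 1, reference$duration_s - fdur - 1)
        clash <- any(interval_overlap_len(t0 - 6, t0 + fdur + 6,
                                          occupied$start, occupied$end) > 0)
        if (!clash) {
          fv <- rtruncnorm1(1, 0.8, 0.2, 0.3)
          fs <- make_bout_strides(t0, fdur, fv)
          span <- c(min(fs$start_s), max(fs$end_s))
          secs <- seq.int(floor(span[1]), ceiling(span[2]) - 1)
          dev_sec <- rbind(dev_sec,
                           data.frame(second_index = secs,
                                      cadence_spm = fs$cadence_spm[1],
                                      stride_length_m = fs$stride_length_m[1]))
          fs$cadence_spm <- NA_real_
          fs$stride_length_m <- NA_real_
          dev_strides <- rbind(dev_strides, fs)
          occupied <- merge_intervals(c(occupied$start, span[1] - 6),
                                      c(occupied$end, span[2] + 6))
          break
        }
      }
    }
  }
  dev_sec <- dev_sec[!duplicated(dev_sec$second_index), , drop = FALSE]
  dev_sec <- dev_sec[order(dev_sec$second_index), , drop = FALSE]
  out <- stride_stream(system = "device",
                       recording_id = reference$recording_id,
                       participant_id = reference$participant_id,
                       cohort = reference$cohort,
                       context = reference$context,
                       duration_s = reference$duration_s,
                       strides = dev_strides, secondly = dev_sec,
                       turns = reference$turns)
  attr(out, "injected") <- injected
  out
}

# truncate the earlier of two overlapping same-foot strides; drop degenerates
resolve_same_foot_overlaps <- function(bs) {
  if (nrow(bs) < 2) return(bs)
  for (foot in c("L", "R")) {
    idx <- which(bs$laterality == foot)
    if (length(idx) > 1) {
      for (j in seq_along(idx)[-1]) {
        a <- idx[j - 1]; b <- idx[j]
        if (bs$end_s[a] > bs$start_s[b] + 1e-9)
          bs$end_s[a] <- bs$start_s[b]
      }
    }
  }
  bs <- bs[bs$end_s > bs$start_s + 0.05, , drop = FALSE]
  rownames(bs) <- NULL
  bs
}

#' Generate a full synthetic validation study
#'
#' One real-world recording per synthetic participant, per cohort: a
#' reference stream from the cohort profile and a device stream degraded by
#' the error model. All randomness derives from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_study`: `sessions` (list of
#'   `gait_session`s), `manifest` (per-reference-bout injected truths with
#'   recording/cohort keys), and `config`.
#' @export
generate_study <- function(config = generator_config()) {
  with_local_seed(config$seed, {
    sessions <- list()
    manifest <- NULL
    for (cohort in names(config$n_participants)) {
      profile <- config$profiles[[cohort]]
      for (p in seq_len(config$n_participants[[cohort]])) {
        pid <- sprintf("%s%02d", cohort, p)
        rid <- paste0(pid, "_rw")
        ref <- generate_reference_stream(profile, config$duration_s,
                                         recording_id = rid,
                                         participant_id = pid)
        dev <- degrade_to_device_stream(ref, config$error_model)
        sessions[[rid]] <- gait_session(ref, dev,
                                        sample_rate_hz = config$sample_rate_hz)
        inj <- attr(dev, "injected")
        if (nrow(inj)) {
          inj <- cbind(data.frame(recording_id = rid, participant_id = pid,
                                  cohort = cohort, stringsAsFactors = FALSE),
                       inj)
          manifest <- rbind(manifest, inj)
        }
      }
    }
    if (is.null(manifest))
      manifest <- data.frame(recording_id = character(0),
                             participant_id = character(0),
                             cohort = character(0), start_s = numeric(0),
                             end_s = numeric(0), v_ref = numeric(0),
                             missed = logical(0), fragmented = logical(0),
                             speed_error = numeric(0))
    rownames(manifest) <- NULL
    structure(list(sessions = sessions, manifest = manifest,
                   config = config), class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d sessions, %d reference bouts (seed %d)\n",
              length(x$sessions), nrow(x$manifest), x$config$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Serializes every stream of every session into one CSV directory (per the
#' stream schema) plus `manifest.json` holding the injected ground truths
#' and the generator settings. Byte-identical for identical config + seed.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  streams <- unlist(lapply(study$sessions, function(s)
    list(s$reference, s$device)), recursive = FALSE)
  write_stride_streams(streams, dir)
  cfg <- study$config
  doc <- list(schema = SCHEMA_VERSION,
              seed = cfg$seed, duration_s = cfg$duration_s,
              sample_rate_hz = cfg$sample_rate_hz,
              n_participants = as.list(cfg$n_participants),
              error_model = unclass(cfg$error_model),
              profiles = lapply(cfg$profiles, unclass),
              injected = study$manifest)
  jsonlite::write_json(doc, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(dir)
}
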