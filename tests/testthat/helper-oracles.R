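# Shared fixture builders and independent oracles.

# n alternating strides starting at t0; non-overlapping feet, small gaps
make_alt_strides <- function(n, t0 = 0, stride_dur = 1.0, gap = 0.1,
                             lat0 = c("L", "R"), speed = 1.0,
                             cadence = 110) {
  lat0 <- match.arg(lat0)
  starts <- t0 + (seq_len(n) - 1) * (stride_dur + gap)
  lats <- rep_len(if (lat0 == "L") c("L", "R") else c("R", "L"), n)
  data.frame(start_s = starts, end_s = starts + stride_dur,
             laterality = lats, cadence_spm = cadence,
             stride_length_m = 120 * speed / cadence,
             speed_mps = speed, valued = TRUE, stringsAsFactors = FALSE)
}

# minimal walking-bout table for matcher tests
make_wb <- function(start, end, speed = 1.0) {
  n <- length(start)
  data.frame(bout_id = seq_len(n), system = rep_len("x", n),
             start_s = start, end_s = end, duration_s = end - start,
             n_strides = rep_len(8L, n),
             mean_cadence_spm = rep_len(110, n),
             mean_stride_length_m = rep_len(1, n),
             mean_speed_mps = rep_len(speed, n),
             turn_fraction = rep_len(0, n),
             complexity = rep_len("simple", n),
             stringsAsFactors = FALSE)
}

# random internally non-overlapping bout list on [0, span]
random_wb_list <- function(n_max, span = 100) {
  n <- sample.int(n_max, 1)
  cuts <- sort(runif(2 * n, 0, span))
  start <- cuts[seq(1, 2 * n, 2)]
  end <- cuts[seq(2, 2 * n, 2)]
  keep <- end - start > 0.5
  make_wb(start[keep], end[keep], speed = runif(sum(keep), 0.4, 1.4))
}

# ICC(2,1) oracle: mean squares from R's own two-way ANOVA fit (aov),
# a code path independent of the closed-form implementation
oracle_icc21 <- function(ref, dev) {
  n <- length(ref); k <- 2
  d <- data.frame(y = c(ref, dev),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# exhaustive one-to-one assignment maximizing total overlap seconds subject
# to the threshold rule; returns the maximal total and one optimal pair set
oracle_match <- function(ref_wbs, dev_wbs, config = match_config()) {
  nr <- nrow(ref_wbs); nd <- nrow(dev_wbs)
  cand <- list()
  for (r in seq_len(nr)) for (d in seq_len(nd)) {
    ov <- max(0, min(ref_wbs$end_s[r], dev_wbs$end_s[d]) -
                max(ref_wbs$start_s[r], dev_wbs$start_s[d]))
    if (ov <= 0) next
    fr <- switch(config$denominator_rule,
                 both = min(ov / ref_wbs$duration_s[r],
                            ov / dev_wbs$duration_s[d]),
                 reference = ov / ref_wbs$duration_s[r],
                 union = ov / (ref_wbs$duration_s[r] +
                                 dev_wbs$duration_s[d] - ov))
    if (fr > config$overlap_threshold || fr >= 1)
      cand[[length(cand) + 1]] <- c(r, d, ov)
  }
  best <- list(total = 0, pairs = matrix(numeric(0), ncol = 2))
  ovs <- vapply(cand, function(p) p[3], 0)
  suffix <- rev(cumsum(rev(c(ovs, 0))))  # suffix[i] = sum of ov from i on
  recurse <- function(i, used_r, used_d, total, pairs) {
    if (i > length(cand)) {
      if (total > best$total)
        best <<- list(total = total, pairs = pairs)
      return()
    }
    if (total + suffix[i] <= best$total) return()
    p <- cand[[i]]
    if (!(p[1] %in% used_r) && !(p[2] %in% used_d))
      recurse(i + 1, c(used_r, p[1]), c(used_d, p[2]), total + p[3],
              rbind(pairs, p[1:2]))
    recurse(i + 1, used_r, used_d, total, pairs)
  }
  recurse(1, integer(0), integer(0), 0, matrix(numeric(0), ncol = 2))
  best
}

pair_key <- function(r, d) paste(r, d, sep = ":")

# small error-free paired study for end-to-end identity checks
tiny_zero_error_study <- function(n_participants = c(HA = 2, PD = 2),
                                  duration_s = 1500, seed = 11) {
  generate_study(generator_config(
    error_model = zero_error_model(),
    duration_s = duration_s,
    n_participants = n_participants,
    seed = seed))
}

temp_dir <- function() {
  d <- tempfile("wbgait")
  dir.create(d)
  d
}
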