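# Agreement statistics for method comparison: error characterization,
# Bland-Altman limits of agreement, ICC(2,1), combined (median-based)
# evaluation.

#' Bootstrap configuration
#'
#' Percentile bootstrap used for all interval estimates that have no
#' closed-form convention in this package (cohort-aggregated detection
#' metrics, limits-of-agreement bounds, regression slopes).
#'
#' @param B Number of resamples (>= 100), default 1000.
#' @param seed Integer seed; every bootstrap is locally seeded so results
#'   are reproducible and independent of the caller's RNG state.
#' @param conf Confidence level, default 0.95.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 1000, seed = 1, conf = 0.95) {
  stopifnot(B >= 100, conf > 0, conf < 1)
  structure(list(B = as.integer(B), seed = as.integer(seed), conf = conf),
            class = "bootstrap_config")
}

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

bootstrap_ci <- function(x, statfun, config = bootstrap_config()) {
  x <- x[!is.na(x)]
  if (is.null(config) || length(x) < 2) return(c(NA_real_, NA_real_))
  alpha <- 1 - config$conf
  with_local_seed(config$seed, {
    stats_b <- vapply(seq_len(config$B), function(b)
      statfun(x[sample.int(length(x), replace = TRUE)]), numeric(1))
    unname(stats::quantile(stats_b, c(alpha / 2, 1 - alpha / 2), type = 7))
  })
}

#' Per-pair error table
#'
#' For each true-positive pair, the signed error (device minus reference),
#' the relative error as a percentage of the reference value, and their
#' absolute versions. Pairs whose reference value is zero are excluded from
#' the relative errors (`NA`) and counted in the `n_zero_reference`
#' attribute.
#'
#' @param pairs Pair data frame from [match_bouts()].
#' @param dmo Which outcome to compare: `"speed"`, `"cadence"` or
#'   `"stride_length"`.
#' @return Data frame with `ref`, `dev`, `error`, `abs_error`,
#'   `rel_error_pct`, `abs_rel_error_pct`.
#' @export
pair_errors <- function(pairs, dmo = c("speed", "cadence", "stride_length")) {
  dmo <- match.arg(dmo)
  col <- switch(dmo, speed = "mean_speed_mps", cadence = "mean_cadence_spm",
                stride_length = "mean_stride_length_m")
  ref <- pairs[[paste0("ref_", col)]]
  dev <- pairs[[paste0("dev_", col)]]
  err <- dev - ref
  rel <- ifelse(ref > 0, 100 * err / ref, NA_real_)
  out <- data.frame(ref = ref, dev = dev, error = err,
                    abs_error = abs(err), rel_error_pct = rel,
                    abs_rel_error_pct = abs(rel))
  attr(out, "n_zero_reference") <- sum(!is.na(ref) & ref == 0)
  out
}

#' Error summary statistics
#'
#' Mean error (bias), mean absolute error (accuracy), mean relative and
#' mean absolute relative error (percent of the reference value), with 5%
#' and 95% quantiles of the absolute errors. Quantiles use R's default
#' linear-interpolation convention (type 7).
#'
#' @param errors Error table from [pair_errors()].
#' @return One-row data frame: `n`, `me`, `mae`, `mae_q05`, `mae_q95`,
#'   `mre_pct`, `mare_pct`, `mare_q05`, `mare_q95`.
#' @export
error_summary <- function(errors) {
  if (!nrow(errors)) stop("empty error table", call. = FALSE)
  q <- function(x, p) if (sum(!is.na(x)) >= 2)
    unname(stats::quantile(x, p, na.rm = TRUE, type = 7)) else NA_real_
  data.frame(n = nrow(errors),
             me = mean(errors$error),
             mae = mean(errors$abs_error),
             mae_q05 = q(errors$abs_error, 0.05),
             mae_q95 = q(errors$abs_error, 0.95),
             mre_pct = mean(errors$rel_error_pct, na.rm = TRUE),
             mare_pct = mean(errors$abs_rel_error_pct, na.rm = TRUE),
             mare_q05 = q(errors$abs_rel_error_pct, 0.05),
             mare_q95 = q(errors$abs_rel_error_pct, 0.95))
}

#' Bland-Altman limits of agreement
#'
#' `LoA = mean(e) +/- 1.96 * sd(e)` with the sample (n-1) standard
#' deviation; the multiplier is configurable. Confidence intervals for the
#' mean and for each limit come from a seeded percentile bootstrap.
#'
#' @param errors Numeric vector of signed errors (n >= 3).
#' @param bootstrap A [bootstrap_config()], or `NULL` to skip the CIs.
#' @param multiplier LoA multiplier, default 1.96.
#' @return One-row data frame: `mean`, `loa_lower`, `loa_upper` and
#'   `*_lo`/`*_hi` bootstrap bounds for each.
#' @export
limits_of_agreement <- function(errors, bootstrap = bootstrap_config(),
                                multiplier = 1.96) {
  errors <- errors[!is.na(errors)]
  if (length(errors) < 3) stop("need at least 3 errors", call. = FALSE)
  s <- stats::sd(errors)
  out <- data.frame(mean = mean(errors),
                    loa_lower = mean(errors) - multiplier * s,
                    loa_upper = mean(errors) + multiplier * s)
  if (!is.null(bootstrap)) {
    ci_m <- bootstrap_ci(errors, mean, bootstrap)
    ci_l <- bootstrap_ci(errors, function(x)
      mean(x) - multiplier * stats::sd(x), bootstrap)
    ci_u <- bootstrap_ci(errors, function(x)
      mean(x) + multiplier * stats::sd(x), bootstrap)
    out$mean_lo <- ci_m[1]; out$mean_hi <- ci_m[2]
    out$loa_lower_lo <- ci_l[1]; out$loa_lower_hi <- ci_l[2]
    out$loa_upper_lo <- ci_u[1]; out$loa_upper_hi <- ci_u[2]
  }
  out
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computed from the two-way ANOVA mean squares of the n-by-2 table
#' (subjects = pairs, raters = systems):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The confidence interval uses the F-distribution method with
#' Satterthwaite degrees of freedom. A table with zero variance in both
#' raters is perfect agreement and returns 1 with a warning.
#'
#' @param ref,dev Paired numeric vectors (n >= 3).
#' @param conf Confidence level, default 0.95.
#' @return One-row data frame: `icc`, `icc_lo`, `icc_hi`, `category`.
#' @export
icc_2_1 <- function(ref, dev, conf = 0.95) {
  stopifnot(length(ref) == length(dev))
  ok <- !is.na(ref) & !is.na(dev)
  x <- cbind(ref[ok], dev[ok])
  n <- nrow(x); k <- 2
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x[, 1]) == 0 && stats::var(x[, 2]) == 0) {
    warning("zero variance in both systems; ICC defined as 1")
    return(data.frame(icc = 1, icc_lo = NA_real_, icc_hi = NA_real_,
                      category = interpret_icc(1), stringsAsFactors = FALSE))
  }
  rm_ <- rowMeans(x); cm <- colMeans(x); g <- mean(x)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  data.frame(icc = icc, icc_lo = lo, icc_hi = hi,
             category = interpret_icc(icc), stringsAsFactors = FALSE)
}

#' Qualitative ICC band
#'
#' Reliability bands: below 0.5 poor, 0.5 to below 0.75 moderate, 0.75 to
#' 0.9 good, above 0.9 excellent (both band edges 0.75 and 0.90 fall in
#' the better-known lower band, i.e. `good` needs `>= 0.75` and
#' `excellent` a strict `> 0.90`).
#'
#' @param icc Numeric, at most 1 (strong disagreement can push the
#'   absolute-agreement coefficient below -1; any negative value is poor).
#'   Vectorized.
#' @return Character vector of `"poor"`, `"moderate"`, `"good"`,
#'   `"excellent"`.
#' @export
interpret_icc <- function(icc) {
  stopifnot(all(icc <= 1, na.rm = TRUE))
  out <- ifelse(icc < 0.5, "poor",
                ifelse(icc < 0.75, "moderate",
                       ifelse(icc <= 0.90, "good", "excellent")))
  out[is.na(icc)] <- NA_character_
  out
}

#' Full agreement summary (one table row)
#'
#' Bundles everything a validation table row reports for one stratum: the
#' number of pairs, the reference and device means with 5%/95% quantiles,
#' mean error with limits of agreement, mean relative error with limits of
#' agreement, mean absolute (relative) error with quantiles, and the
#' ICC(2,1) with its confidence interval and qualitative band.
#'
#' @param ref,dev Paired numeric vectors (e.g. bout or unit-median walking
#'   speeds from the two systems).
#' @param label Optional stratum label carried in the output.
#' @param bootstrap A [bootstrap_config()], or `NULL` to skip bootstrap
#'   intervals.
#' @return Object of class `agreement_summary` (a one-row data frame).
#' @examples
#' set.seed(42)
#' v <- runif(50, 0.4, 1.3)
#' agreement_summary(v, v + rnorm(50, 0.05, 0.1), bootstrap = NULL)
#' @export
agreement_summary <- function(ref, dev, label = "All",
                              bootstrap = bootstrap_config()) {
  ok <- !is.na(ref) & !is.na(dev)
  ref <- ref[ok]; dev <- dev[ok]
  if (length(ref) < 3) stop("need at least 3 pairs", call. = FALSE)
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  err <- dev - ref
  rel <- ifelse(ref > 0, 100 * err / ref, NA_real_)
  es <- error_summary(data.frame(ref = ref, dev = dev, error = err,
                                 abs_error = abs(err), rel_error_pct = rel,
                                 abs_rel_error_pct = abs(rel)))
  loa <- limits_of_agreement(err, bootstrap)
  can_rel <- sum(!is.na(rel)) >= 3
  loa_rel <- if (can_rel) limits_of_agreement(rel[!is.na(rel)], bootstrap)
  else data.frame(mean = NA_real_, loa_lower = NA_real_,
                  loa_upper = NA_real_)
  icc <- icc_2_1(ref, dev)
  out <- data.frame(label = label, n = length(ref),
                    ref_mean = mean(ref), ref_q05 = q(ref, 0.05),
                    ref_q95 = q(ref, 0.95),
                    dev_mean = mean(dev), dev_q05 = q(dev, 0.05),
                    dev_q95 = q(dev, 0.95),
                    me = es$me, loa_lower = loa$loa_lower,
                    loa_upper = loa$loa_upper,
                    mre_pct = es$mre_pct,
                    rel_loa_lower = loa_rel$loa_lower,
                    rel_loa_upper = loa_rel$loa_upper,
                    mae = es$mae, mae_q05 = es$mae_q05, mae_q95 = es$mae_q95,
                    mare_pct = es$mare_pct, mare_q05 = es$mare_q05,
                    mare_q95 = es$mare_q95,
                    icc = icc$icc, icc_lo = icc$icc_lo, icc_hi = icc$icc_hi,
                    icc_category = icc$category,
                    stringsAsFactors = FALSE)
  attr(out, "errors") <- data.frame(ref = ref, dev = dev, error = err)
  class(out) <- c("agreement_summary", "data.frame")
  out
}

#' @export
print.agreement_summary <- function(x, digits = 2, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  cat(sprintf("<agreement_summary> %s (n = %d)\n", x$label, x$n))
  cat(sprintf("  reference   %s [%s, %s] m/s | device %s [%s, %s] m/s\n",
              f(x$ref_mean), f(x$ref_q05), f(x$ref_q95),
              f(x$dev_mean), f(x$dev_q05), f(x$dev_q95)))
  cat(sprintf("  ME  %s LoA [%s, %s] | MRE %s%% LoA [%s, %s]\n",
              f(x$me), f(x$loa_lower), f(x$loa_upper),
              f(x$mre_pct), f(x$rel_loa_lower), f(x$rel_loa_upper)))
  cat(sprintf("  MAE %s [%s, %s] | MARE %s%% [%s, %s]\n",
              f(x$mae), f(x$mae_q05), f(x$mae_q95),
              f(x$mare_pct), f(x$mare_q05), f(x$mare_q95)))
  cat(sprintf("  ICC(2,1) %s [%s, %s] (%s)\n",
              f(x$icc), f(x$icc_lo), f(x$icc_hi), x$icc_category))
  invisible(x)
}

#' Bland-Altman style plot of an agreement summary
#'
#' Signed error against the reference value, with the mean error (solid)
#' and limits of agreement (dashed).
#'
#' @param x An `agreement_summary`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.agreement_summary <- function(x, ...) {
  e <- attr(x, "errors")
  graphics::plot(e$ref, e$error, xlab = "reference walking speed (m/s)",
                 ylab = "error, device - reference (m/s)",
                 main = sprintf("%s (n = %d)", x$label, x$n), ...)
  graphics::abline(h = x$me, lwd = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Combined (median-based) evaluation
#'
#' The traditional analysis route: instead of restricting to true-positive
#' pairs, each system's own bouts are reduced to one median value per unit
#' (a laboratory task, or a whole real-world recording per participant),
#' and the unit medians are compared between systems. Units missing either
#' system are excluded and counted.
#'
#' @param wbs Walking-bout data frame holding both systems, with a unit
#'   identifier column.
#' @param unit_col Name of the unit column (e.g. `"recording_id"` or a
#'   participant-by-task key).
#' @param value_col Outcome column, default `"mean_speed_mps"`.
#' @param label Label for the resulting summary.
#' @param bootstrap A [bootstrap_config()] or `NULL`.
#' @return List: `units` (per-unit medians for both systems),
#'   `n_excluded_units`, and `summary` (an [agreement_summary()]).
#' @export
combined_evaluation <- function(wbs, unit_col, value_col = "mean_speed_mps",
                                label = "combined",
                                bootstrap = bootstrap_config()) {
  med <- function(sys) {
    sub <- wbs[wbs$system == sys, , drop = FALSE]
    vals <- tapply(sub[[value_col]], sub[[unit_col]], stats::median)
    data.frame(unit = names(vals), value = as.numeric(vals),
               stringsAsFactors = FALSE)
  }
  r <- med("reference"); d <- med("device")
  units <- merge(r, d, by = "unit", suffixes = c("_ref", "_dev"))
  n_excluded <- length(union(r$unit, d$unit)) - nrow(units)
  list(units = units, n_excluded_units = n_excluded,
       summary = agreement_summary(units$value_ref, units$value_dev,
                                   label = label, bootstrap = bootstrap))
}
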