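# build a pair table directly (bypassing the pipeline) with known errors
synthetic_pairs <- function(n, ref_speed, error, ref_duration,
                            complexity = "simple", cohort = "HA") {
  data.frame(cohort = rep_len(cohort, n),
             ref_mean_speed_mps = rep_len(ref_speed, n),
             dev_mean_speed_mps = rep_len(ref_speed + error, n),
             speed_error = rep_len(error, n),
             ref_duration_s = rep_len(ref_duration, n),
             dev_duration_s = rep_len(ref_duration, n),
             ref_complexity = rep_len(complexity, n),
             stringsAsFactors = FALSE)
}

test_that("duration binning partitions counts and respects boundaries", {
  set.seed(61)
  d <- c(9.9, 10.1, runif(120, 2, 200))
  pairs <- synthetic_pairs(length(d), runif(length(d), 0.4, 1.2),
                           rnorm(length(d), 0, 0.05), d)
  out <- stratify_by_duration(pairs, stratum_spec(), bootstrap = NULL)
  part <- out[out$partition_bin, ]
  expect_equal(sum(part$n), nrow(pairs))
  expect_equal(sum(part$n_ref_wbs), nrow(pairs))
  b10 <- out[out$label == "<10 s", ]
  expect_gte(b10$n, 1)
  expect_true(9.9 < 10 && b10$n == sum(d < 10))
  over10 <- out[out$label == ">10 s", ]
  expect_equal(over10$n, sum(d >= 10))
  expect_true(all(out$underpowered == (out$n < 101)))
})

test_that("all-15s bouts populate only the 10-30 s and >10 s bins", {
  pairs <- synthetic_pairs(40, runif(40, 0.5, 1.0), rnorm(40, 0, 0.02),
                           rep(15, 40))
  out <- stratify_by_duration(pairs, stratum_spec(), bootstrap = NULL)
  populated <- out$label[out$n > 0]
  expect_setequal(populated, c("10-30 s", ">10 s"))
})

test_that("removing short bouts leaves the other bins unchanged", {
  set.seed(62)
  d <- runif(150, 2, 200)
  pairs <- synthetic_pairs(150, runif(150, 0.4, 1.2),
                           rnorm(150, 0, 0.05), d)
  full <- stratify_by_duration(pairs, stratum_spec(), bootstrap = NULL)
  trimmed <- stratify_by_duration(pairs[pairs$ref_duration_s >= 10, ],
                                  stratum_spec(), bootstrap = NULL)
  for (lab in c("10-30 s", "30-60 s", "60-120 s", ">120 s")) {
    a <- full[full$label == lab, c("n", "me", "mae", "icc")]
    b <- trimmed[trimmed$label == lab, c("n", "me", "mae", "icc")]
    expect_equal(a, b, ignore_attr = TRUE, info = lab)
  }
})

test_that("speed-error regression recovers exact and zero relationships", {
  set.seed(63)
  v <- runif(50, 0.3, 1.5)
  zero <- synthetic_pairs(50, v, rep(0, 50), runif(50, 5, 60))
  r0 <- speed_error_regression(zero, bootstrap = NULL)
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_equal(r0$intercept, 0, tolerance = 1e-12)

  exact <- synthetic_pairs(50, v, 0.15 - 0.25 * v, runif(50, 5, 60))
  r1 <- speed_error_regression(exact, bootstrap = NULL)
  expect_equal(r1$slope, -0.25, tolerance = 1e-10)
  expect_equal(r1$intercept, 0.15, tolerance = 1e-10)

  degen <- synthetic_pairs(10, rep(1, 10), rnorm(10, 0, 0.1), rep(20, 10))
  expect_error(speed_error_regression(degen, bootstrap = NULL), "degenerate")
})

test_that("complexity strata recover class-specific error scales", {
  set.seed(64)
  n <- 300
  simple <- synthetic_pairs(n, runif(n, 0.5, 1.2), rnorm(n, 0, 0.08 * sqrt(pi / 2)),
                            runif(n, 5, 60), complexity = "simple")
  complexp <- synthetic_pairs(n, runif(n, 0.5, 1.2), rnorm(n, 0, 0.17 * sqrt(pi / 2)),
                              runif(n, 5, 60), complexity = "complex")
  out <- stratify_by_complexity(rbind(simple, complexp), bootstrap = NULL)
  mae_s <- out$mae[out$complexity == "simple"]
  mae_c <- out$mae[out$complexity == "complex"]
  # E|N(0, s*sqrt(pi/2))| = s: injected MAE 0.08 vs 0.17
  expect_lt(abs(mae_s - 0.08), 0.015)
  expect_lt(abs(mae_c - 0.17), 0.03)
  expect_false("intermediate" %in% out$complexity)  # empty class omitted
})

test_that("the full report is deterministic and traceable", {
  study <- tiny_zero_error_study(c(HA = 2, MS = 1), duration_s = 1500,
                                 seed = 19)
  bs <- bootstrap_config(B = 150, seed = 3)
  rep1 <- build_study_report(study, bootstrap = bs)
  rep2 <- build_study_report(study, bootstrap = bs)
  d1 <- temp_dir(); d2 <- temp_dir()
  write_study_report(rep1, d1)
  write_study_report(rep2, d2)
  for (f in c("report.json", file.path("tables", "detection.csv"),
              file.path("tables", "tp_agreement.csv")))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  # zero-error study: every populated error cell is exactly zero, ICC 1
  all_row <- rep1$tp_agreement[rep1$tp_agreement$label == "All", ]
  expect_equal(all_row$me, 0)
  expect_equal(all_row$icc, 1)
  det <- rep1$detection[rep1$detection$group == "All", ]
  expect_equal(c(det$accuracy, det$sensitivity, det$specificity, det$ppv),
               rep(1, 4))
})
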