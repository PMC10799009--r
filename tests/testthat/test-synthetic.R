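test_that("degenerate generator settings behave as documented", {
  p0 <- cohort_profile("HA", bouts_per_hour = 0)
  s <- generate_reference_stream(p0, 3600, seed = 1)
  expect_equal(nrow(s$strides), 0)

  a <- generate_reference_stream(cohort_profile("PFF"), 1800, seed = 42)
  b <- generate_reference_stream(cohort_profile("PFF"), 1800, seed = 42)
  expect_identical(a$strides, b$strides)
  expect_identical(a$secondly, b$secondly)
  expect_identical(a$turns, b$turns)
})

test_that("generated bout speeds follow the truncated cohort distribution", {
  p <- cohort_profile("HA")
  speeds <- numeric(0)
  for (i in 1:30) {
    ref <- generate_reference_stream(p, 9000, seed = 1000 + i)
    speeds <- c(speeds, attr(ref, "bouts")$speed_mps)
  }
  expect_gt(length(speeds), 1000)
  # oracle: closed-form mean of the truncated normal
  alpha <- (p$min_speed_mps - p$mean_speed_mps) / p$speed_sd_mps
  mu_trunc <- p$mean_speed_mps +
    p$speed_sd_mps * dnorm(alpha) / (1 - pnorm(alpha))
  se <- sd(speeds) / sqrt(length(speeds))
  expect_lt(abs(mean(speeds) - mu_trunc), 3 * se)
  expect_true(all(speeds > p$min_speed_mps))
})

test_that("per-second traces are consistent with stride-level values", {
  ref <- generate_reference_stream(cohort_profile("CHF"), 2000, seed = 9)
  st <- interpolate_to_strides(ref$secondly, ref$strides)
  intended <- attr(ref, "bouts")
  # every stride's interpolated speed equals its bout's target speed
  bout_of <- findInterval(st$start_s, intended$start_s)
  expect_true(all(st$valued))
  expect_equal(st$speed_mps, intended$speed_mps[bout_of], tolerance = 1e-9)
})

test_that("zero-error degradation is the identity; miss prob 1 empties", {
  ref <- generate_reference_stream(cohort_profile("MS"), 1500, seed = 3)
  dev <- degrade_to_device_stream(ref, zero_error_model(), seed = 4)
  expect_identical(dev$strides, ref$strides)
  expect_identical(dev$secondly, ref$secondly)
  expect_identical(dev$turns, ref$turns)
  expect_equal(dev$system, "device")

  gone <- degrade_to_device_stream(
    ref, device_error_model(miss_bout_prob = 1, false_walk_rate_per_h = 0),
    seed = 5)
  expect_equal(nrow(gone$strides), 0)
  expect_true(all(attr(gone, "injected")$missed))
})

test_that("a pure additive speed bias is injected exactly", {
  ref <- generate_reference_stream(cohort_profile("HA"), 3000, seed = 6)
  model <- device_error_model(miss_bout_prob = 0, false_walk_rate_per_h = 0,
                              fragmentation_prob = 0, ic_jitter_sd_s = 0,
                              laterality_flip_prob = 0,
                              speed_bias_intercept_a = 0.06,
                              speed_bias_slope_b = 0, speed_noise_sd = 0,
                              per_second_noise_sd = 0)
  dev <- degrade_to_device_stream(ref, model, seed = 7)
  rw <- process_stream(ref)
  dw <- process_stream(dev)
  m <- match_bouts(rw, dw)
  expect_equal(nrow(m$pairs), nrow(rw))
  expect_equal(m$pairs$speed_error, rep(0.06, nrow(rw)), tolerance = 1e-9)
})

test_that("study generation is deterministic and fully manifested", {
  cfg <- generator_config(n_participants = c(HA = 1, COPD = 1),
                          duration_s = 1200, seed = 77)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$sessions[[1]]$device$strides,
                   s2$sessions[[1]]$device$strides)
  expect_equal(length(s1$sessions), 2)
  expect_setequal(unique(s1$manifest$cohort), c("HA", "COPD"))
  # every reference bout appears in the manifest
  ref_bouts <- sum(vapply(s1$sessions, function(ss)
    nrow(attr(ss$reference, "bouts")), 1L))
  expect_equal(nrow(s1$manifest), ref_bouts)

  d1 <- temp_dir(); d2 <- temp_dir()
  write_study(s1, d1)
  write_study(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("zero-error study yields exact zero downstream errors", {
  study <- tiny_zero_error_study(c(CHF = 1), duration_s = 1500, seed = 13)
  rep <- build_study_report(study, bootstrap = NULL)
  expect_equal(rep$tp_agreement$me, rep(0, nrow(rep$tp_agreement)))
  expect_equal(rep$tp_agreement$mae, rep(0, nrow(rep$tp_agreement)))
})
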