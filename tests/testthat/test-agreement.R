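test_that("pair error tables follow the definitions", {
  pairs <- make_wb(c(0, 20), c(10, 30), speed = c(1.0, 0.8))
  m <- match_bouts(pairs, pairs)
  e <- pair_errors(m$pairs, "speed")
  expect_equal(e$error, c(0, 0))

  p <- m$pairs
  p$dev_mean_speed_mps <- c(1.1, 0.9)
  e2 <- pair_errors(p, "speed")
  expect_equal(e2$error, c(0.1, 0.1))
  expect_equal(e2$rel_error_pct, c(10, 12.5))
  expect_equal(e2$abs_error, c(0.1, 0.1))

  set.seed(8)
  ref <- runif(40, 0.3, 1.4); dev <- ref + rnorm(40, 0, 0.1)
  p3 <- data.frame(ref_mean_speed_mps = ref, dev_mean_speed_mps = dev,
                   ref_mean_cadence_spm = 1, dev_mean_cadence_spm = 1,
                   ref_mean_stride_length_m = 1, dev_mean_stride_length_m = 1)
  e3 <- pair_errors(p3, "speed")
  expect_equal(e3$error, dev - ref, tolerance = 1e-12)
  expect_equal(e3$rel_error_pct, 100 * (dev - ref) / ref, tolerance = 1e-12)
  expect_equal(e3$abs_rel_error_pct, abs(100 * (dev - ref) / ref),
               tolerance = 1e-12)
})

test_that("error summaries: bias, accuracy and their relative forms", {
  es <- error_summary(data.frame(ref = c(1, 1), dev = c(0.9, 1.1),
                                 error = c(-0.1, 0.1),
                                 abs_error = c(0.1, 0.1),
                                 rel_error_pct = c(-10, 10),
                                 abs_rel_error_pct = c(10, 10)))
  expect_equal(es$me, 0)
  expect_equal(es$mae, 0.1)
  expect_equal(es$mre_pct, 0)
  expect_equal(es$mare_pct, 10)

  b <- 0.07
  const <- data.frame(ref = rep(1, 5), dev = 1 + b, error = b,
                      abs_error = abs(b), rel_error_pct = 100 * b,
                      abs_rel_error_pct = 100 * abs(b))
  es2 <- error_summary(const)
  expect_equal(es2$me, b)
  expect_equal(es2$mae, abs(b))
  expect_equal(es2$mae_q05, es2$mae_q95)
  expect_error(error_summary(data.frame()), "empty")
})

test_that("limits of agreement: closed forms and degenerate cases", {
  three <- limits_of_agreement(c(-1, 0, 1), bootstrap = NULL)
  expect_equal(three$mean, 0)
  expect_equal(three$loa_lower, -1.96)
  expect_equal(three$loa_upper, 1.96)

  const <- limits_of_agreement(rep(0.2, 10), bootstrap = NULL)
  expect_equal(const$loa_lower, const$loa_upper)
  expect_equal(const$loa_lower, 0.2)

  set.seed(5)
  e <- rnorm(1000, 0, 0.1)
  loa <- limits_of_agreement(e, bootstrap_config(B = 300, seed = 2))
  expect_lt(abs(loa$loa_upper - 0.196), 0.02)
  expect_lt(abs(loa$loa_lower + 0.196), 0.02)
  expect_true(loa$loa_lower_lo <= loa$loa_lower &
                loa$loa_lower <= loa$loa_lower_hi)
  expect_error(limits_of_agreement(c(1, 2)), "at least 3")
})

test_that("ICC(2,1) equals the ANOVA oracle and behaves at the edges", {
  v <- c(0.5, 0.7, 0.9, 1.1, 1.3)
  perfect <- icc_2_1(v, v)
  expect_equal(perfect$icc, 1)

  # anticorrelated data must give a negative coefficient
  x <- c(-2, -1, 0, 1, 2)
  neg <- suppressWarnings(icc_2_1(x, -x + 0.1))  # CI quantile is extreme here
  expect_lt(neg$icc, 0)
  expect_equal(neg$icc, oracle_icc21(x, -x + 0.1), tolerance = 1e-10)

  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    ref <- runif(n, 0.3, 1.5)
    dev <- ref * runif(1, 0.7, 1.3) + rnorm(n, 0, 0.15)
    got <- icc_2_1(ref, dev)
    expect_equal(got$icc, oracle_icc21(ref, dev), tolerance = 1e-10)
    expect_true(got$icc_lo <= got$icc & got$icc <= got$icc_hi)
  }

  expect_warning(z <- icc_2_1(rep(1, 5), rep(1, 5)), "zero variance")
  expect_equal(z$icc, 1)
})

test_that("ICC bands follow the published interpretation", {
  expect_equal(interpret_icc(0.84), "good")
  expect_equal(interpret_icc(0.57), "moderate")
  expect_equal(interpret_icc(-0.15), "poor")
  expect_equal(interpret_icc(c(0.49, 0.5, 0.75, 0.9, 0.901)),
               c("poor", "moderate", "good", "good", "excellent"))
})

test_that("agreement summary invariants: MAE >= |ME|, LoA bracket ME", {
  set.seed(23)
  for (i in 1:15) {
    ref <- runif(30, 0.3, 1.4)
    dev <- ref + rnorm(30, runif(1, -0.1, 0.1), 0.1)
    s <- agreement_summary(ref, dev, bootstrap = NULL)
    expect_gte(s$mae, abs(s$me))
    expect_gte(s$mare_pct, abs(s$mre_pct))
    expect_lte(s$loa_lower, s$me)
    expect_gte(s$loa_upper, s$me)
    expect_true(s$icc >= -1 & s$icc <= 1)
  }
})

test_that("combined evaluation takes per-unit medians of each system", {
  wbs <- rbind(
    data.frame(system = "device", recording_id = "u1",
               mean_speed_mps = c(0.5, 0.7, 0.9)),
    data.frame(system = "reference", recording_id = "u1",
               mean_speed_mps = c(0.6, 0.8)),
    data.frame(system = "device", recording_id = "u2", mean_speed_mps = 1.0),
    data.frame(system = "reference", recording_id = "u2",
               mean_speed_mps = 1.2),
    data.frame(system = "device", recording_id = "u3", mean_speed_mps = 1.0),
    data.frame(system = "reference", recording_id = "u3",
               mean_speed_mps = 0.9),
    data.frame(system = "device", recording_id = "only_dev",
               mean_speed_mps = 0.4))
  ce <- combined_evaluation(wbs, "recording_id", bootstrap = NULL)
  expect_equal(ce$n_excluded_units, 1)
  u1 <- ce$units[ce$units$unit == "u1", ]
  expect_equal(u1$value_dev, 0.7)
  expect_equal(u1$value_ref, 0.7)

  same <- wbs[wbs$system == "reference", ]
  same2 <- same; same2$system <- "device"
  ce2 <- combined_evaluation(rbind(same, same2), "recording_id",
                             bootstrap = NULL)
  expect_equal(ce2$summary$me, 0)
  expect_equal(ce2$summary$mae, 0)
  expect_equal(ce2$summary$icc, 1)
})
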