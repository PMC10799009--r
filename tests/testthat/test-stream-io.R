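test_that("CSV fixture reads to a sorted, validated stream", {
  dir <- temp_dir()
  s <- stride_stream(
    system = "reference", recording_id = "r1", participant_id = "p1",
    duration_s = 5,
    strides = data.frame(start_s = c(2.0, 0.0, 1.0),
                         end_s = c(3.1, 1.1, 2.1),
                         laterality = c("L", "L", "R"),
                         stringsAsFactors = FALSE))
  expect_equal(nrow(s$strides), 3)
  expect_false(is.unsorted(s$strides$start_s))
  write_stride_stream(s, dir, "csv")
  back <- read_stride_stream(dir, "csv")
  expect_identical(back$strides, s$strides)
  expect_identical(back$duration_s, s$duration_s)
})

test_that("invariant violations are reported, not silently accepted", {
  s <- stride_stream(
    system = "reference", recording_id = "r1", participant_id = "p1",
    duration_s = 5,
    strides = data.frame(start_s = 1, end_s = 0.5, laterality = "L"),
    validate = FALSE)
  v <- validate_stream(s)
  expect_true(any(grepl("end_s", v)))
  expect_error(
    stride_stream(system = "reference", recording_id = "r",
                  participant_id = "p", duration_s = 5,
                  strides = data.frame(start_s = 1, end_s = 0.5,
                                       laterality = "L")),
    "end_s")
})

test_that("JSON and CSV encodings round-trip to the same stream", {
  d <- temp_dir()
  s <- stride_stream(
    system = "device", recording_id = "rec9", participant_id = "p9",
    cohort = "PD", context = "laboratory_task:l_test", duration_s = 30,
    strides = data.frame(start_s = c(0, 0.6, 1.2), end_s = c(1.2, 1.8, 2.4),
                         laterality = c("L", "R", "L"),
                         cadence_spm = c(100, NA, 101.5),
                         stride_length_m = c(1.1, 1.2, NA),
                         speed_mps = c(0.9167, NA, NA)),
    secondly = data.frame(second_index = 0:2,
                          cadence_spm = c(100, NA, 103),
                          stride_length_m = c(1.1, 1.2, NA)),
    turns = data.frame(start_s = 0.5, end_s = 1.7))
  write_stride_stream(s, file.path(d, "csvdir"), "csv")
  write_stride_stream(s, file.path(d, "s.json"), "json")
  from_csv <- read_stride_stream(file.path(d, "csvdir"), "csv")
  from_json <- read_stride_stream(file.path(d, "s.json"), "json")
  for (f in c("system", "recording_id", "participant_id", "cohort",
              "context", "duration_s", "strides", "secondly", "turns")) {
    expect_identical(from_csv[[f]], s[[f]], info = paste("csv", f))
    expect_identical(from_json[[f]], s[[f]], info = paste("json", f))
  }
})

test_that("empty stream round-trips; missing secondly values keep sentinel", {
  d <- temp_dir()
  s <- stride_stream(system = "reference", recording_id = "e",
                     participant_id = "p", duration_s = 10)
  write_stride_stream(s, d, "csv")
  back <- read_stride_stream(d, "csv")
  expect_equal(nrow(back$strides), 0)
  expect_equal(back$duration_s, 10)
})

test_that("round-trip identity holds for randomized streams", {
  set.seed(401)
  for (i in 1:20) {
    ref <- generate_reference_stream(cohort_profile(sample(
      c("HA", "CHF", "COPD", "MS", "PD", "PFF"), 1)),
      duration_s = runif(1, 200, 600),
      recording_id = paste0("r", i), participant_id = paste0("p", i))
    d <- temp_dir()
    write_stride_stream(ref, d, "csv")
    back <- read_stride_stream(d, "csv")
    for (f in c("duration_s", "strides", "secondly", "turns"))
      expect_identical(back[[f]], ref[[f]], info = paste("seeded run", i, f))
    jf <- file.path(d, "s.json")
    write_stride_stream(ref, jf, "json")
    backj <- read_stride_stream(jf, "json")
    for (f in c("duration_s", "strides", "secondly", "turns"))
      expect_identical(backj[[f]], ref[[f]],
                       info = paste("json seeded run", i, f))
  }
})

test_that("session validation detects incoherence and same-foot overlaps", {
  study <- tiny_zero_error_study(c(HA = 1), duration_s = 800, seed = 5)
  ses <- study$sessions[[1]]
  expect_length(validate_session(ses), 0)

  bad <- ses
  bad$device$duration_s <- bad$device$duration_s + 5
  expect_true(any(grepl("duration_s differs", validate_session(bad))))

  s2 <- ses$reference
  s2$strides$laterality[2] <- s2$strides$laterality[1]  # force same foot
  s2$strides$laterality[3] <- s2$strides$laterality[1]
  v <- validate_stream(s2)
  expect_gte(sum(grepl("same-foot", v)), 2)
})

test_that("fuzzed corruptions always produce at least one violation", {
  set.seed(77)
  base <- generate_reference_stream(cohort_profile("MS"), 400)
  corruptions <- list(
    function(s) { s$strides$end_s[1] <- s$strides$start_s[1] - 0.1; s },
    function(s) { s$strides$laterality[2] <- "X"; s },
    function(s) { s$secondly$cadence_spm[1] <- -5; s },
    function(s) { s$duration_s <- max(s$strides$end_s) / 2; s },
    function(s) { s$turns <- data.frame(start_s = 2, end_s = 1); s },
    function(s) { s$cohort <- "XYZ"; s })
  for (k in seq_along(corruptions)) {
    s <- corruptions[[k]](base)
    expect_gt(length(validate_stream(s)), 0, label = paste("corruption", k))
  }
})
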