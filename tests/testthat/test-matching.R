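test_that("overlap rules decide the worked examples", {
  ref <- make_wb(0, 10)
  m <- match_bouts(ref, make_wb(1, 10))        # 90% of ref, 100% of dev
  expect_equal(nrow(m$pairs), 1)
  m2 <- match_bouts(ref, make_wb(0, 7))        # 70% of ref
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_ref, 1L)
  expect_equal(m2$unmatched_dev, 1L)
  # under the reference rule the 70% case still fails, 90% passes
  m3 <- match_bouts(ref, make_wb(1, 10), match_config(0.8, "reference"))
  expect_equal(nrow(m3$pairs), 1)

  ident <- make_wb(c(0, 20, 40), c(10, 30, 55), speed = c(0.7, 0.9, 1.1))
  m4 <- match_bouts(ident, ident)
  expect_equal(nrow(m4$pairs), 3)
  expect_equal(m4$pairs$overlap_fraction, rep(1, 3))
  expect_equal(m4$pairs$speed_error, rep(0, 3))

  expect_error(match_bouts(make_wb(c(0, 5), c(6, 12)), ident), "overlapping")
})

test_that("sample-wise confusion matches hand counts", {
  ref <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0) == 1
  dev <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1) == 1
  cm <- confusion_from_masks(ref, dev)
  expect_equal(cm$tp, 3); expect_equal(cm$fn, 1)
  expect_equal(cm$fp, 1); expect_equal(cm$tn, 5)
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 5 / 6)
  expect_equal(cm$ppv, 0.75)

  same <- samplewise_confusion(make_wb(c(1, 8), c(5, 9.5)),
                               make_wb(c(1, 8), c(5, 9.5)), 12, 100)
  expect_equal(c(same$accuracy, same$sensitivity, same$specificity,
                 same$ppv), rep(1, 4))

  degen <- samplewise_confusion(make_wb(1, 5), make_wb(numeric(0),
                                                       numeric(0)), 10, 100)
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$specificity, 1)
  expect_true(is.na(degen$ppv))
})

test_that("sample-wise metrics ignore bout order and abutting splits", {
  dur <- 60
  ref <- make_wb(c(5, 30), c(20, 50))
  whole <- make_wb(6, 19)
  split <- make_wb(c(12, 6), c(19, 12))     # same span, two abutting, shuffled
  a <- samplewise_confusion(ref, whole, dur, 100)
  b <- samplewise_confusion(ref, split, dur, 100)
  expect_equal(a, b)
})

test_that("cohort aggregation of detection metrics", {
  conf <- data.frame(cohort = c("HA", "HA"), participant_id = c("a", "b"),
                     tp = 1, fp = 1, fn = 1, tn = 1,
                     accuracy = c(0.9, 0.9), sensitivity = c(0.6, 0.8),
                     specificity = c(1, 1), ppv = c(0.9, NA))
  agg <- aggregate_detection(conf, "cohort", bootstrap = NULL)
  expect_equal(agg$sensitivity, 0.7)
  expect_equal(agg$ppv, 0.9)               # undefined participant dropped
  expect_equal(agg$specificity, 1)

  one <- aggregate_detection(conf[c(1, 1), ], "cohort",
                             bootstrap = bootstrap_config(B = 200, seed = 4))
  expect_equal(one$sensitivity, 0.6)
  expect_equal(one$sensitivity_lo, 0.6)    # identical participants
  expect_equal(one$sensitivity_hi, 0.6)
})

test_that("matcher invariants hold on random instances", {
  set.seed(91)
  for (i in 1:60) {
    ref <- random_wb_list(8)
    dev <- random_wb_list(8)
    m8 <- match_bouts(ref, dev, match_config(0.8))
    expect_lte(nrow(m8$pairs), min(nrow(ref), nrow(dev)))
    # lowering the threshold never loses pairs
    m5 <- match_bouts(ref, dev, match_config(0.5))
    m2 <- match_bouts(ref, dev, match_config(0.2))
    expect_gte(nrow(m5$pairs), nrow(m8$pairs))
    expect_gte(nrow(m2$pairs), nrow(m5$pairs))
    # one-to-one
    expect_equal(anyDuplicated(m2$pairs$ref_idx), 0)
    expect_equal(anyDuplicated(m2$pairs$dev_idx), 0)
  }
})
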