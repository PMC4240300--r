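test_that("the worked error examples classify as published", {
  # ZNH -> Z names a flanker
  expect_identical(as.character(classify_error("N", "Z", "H", "Z")), "B")
  # YMT -> V and 3T6 -> C name letters absent from the array
  expect_identical(as.character(classify_error("M", "Y", "T", "V")), "C")
  expect_identical(as.character(classify_error("T", "3", "6", "C")), "C")
  expect_identical(as.character(classify_error("T", "3", "6", NO_RESPONSE)),
                   "A")
  expect_identical(as.character(classify_error("N", "Z", "H", "N")),
                   "correct")
})

test_that("error classes partition every flanked table and ignore flanker order", {
  set.seed(33)
  tr <- simulate_cohort(small_pca_config(seed = 33, n_participants = 6,
                                         tasks = 2:4))
  fl <- tr[tr$task != 1, ]
  cls <- classify_error(fl$target, fl$flanker_left, fl$flanker_right,
                        fl$response)
  expect_equal(sum(table(cls)), nrow(fl))
  expect_false(any(is.na(cls)))
  swapped <- classify_error(fl$target, fl$flanker_right, fl$flanker_left,
                            fl$response)
  expect_identical(cls, swapped)
  expect_error(classify_error("N", "", "", "N"), "flanked trials")
  expect_error(classify_error("N", "Z", "H", "?"), "invalid response")
})

test_that("error summaries count planted errors exactly", {
  tr <- make_trials(
    participant_id = "p1",
    target = rep("N", 10),
    flanker_left = "Z", flanker_right = "H",
    response = c(rep("N", 8), "Z", "V"))
  s <- error_summary(tr)
  expect_equal(s$error_rate, 0.2)
  expect_equal(unname(s$proportions), c(0, 0.5, 0.5))
  # planted composition 6 A, 8 B, 6 C in 100 trials
  tr2 <- make_trials(
    participant_id = "p1", target = rep("N", 100),
    flanker_left = "Z", flanker_right = "H",
    response = c(rep("N", 80), rep(NO_RESPONSE, 6), rep("Z", 8),
                 rep("V", 6)))
  s2 <- error_summary(tr2)
  expect_equal(s2$error_rate, 0.20)
  expect_equal(unname(s2$proportions), c(0.30, 0.40, 0.30))
  # no errors: rate 0, undefined proportions
  s3 <- error_summary(tr2[1:80, ])
  expect_equal(s3$error_rate, 0)
  expect_true(all(is.na(s3$proportions)))
})

test_that("the 2-SD rule removes exactly the planted 5000 ms outlier", {
  tr <- make_trials(
    participant_id = "p1", target = rep("N", 11),
    flanker_left = "Z", flanker_right = "H", response = "N",
    latency_ms = c(rep(500, 10), 5000))
  # direct-computation oracle: mean 909.1, sd 1357, 5000 > mean + 2 sd
  expect_gt(5000, mean(tr$latency_ms) + 2 * sd(tr$latency_ms))
  expect_lt(500, mean(tr$latency_ms) + 2 * sd(tr$latency_ms))
  out <- trim_latencies(tr)
  expect_equal(out$ledger$removed_stage1, 0)
  expect_equal(out$ledger$removed_stage2, 1)
  expect_false(5000 %in% out$retained$latency_ms)
  expect_equal(nrow(out$retained), 10)
})

test_that("stage 1 removes errors, prompts and distraction regardless of latency", {
  tr <- make_trials(
    participant_id = "p1", target = rep("N", 6),
    flanker_left = "Z", flanker_right = "H",
    response = c("N", "Z", "N", "N", "N", "N"),
    prompted = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    distracted = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    latency_ms = c(600, 600, 600, 600, NA, 600))
  out <- trim_latencies(tr)
  expect_equal(out$ledger$removed_stage1, 4)
  expect_equal(nrow(out$retained), 2)
  # all equal latencies: SD 0, nothing removed at stage 2
  expect_equal(out$ledger$removed_stage2, 0)
})

test_that("trimming conserves counts on random fixtures", {
  set.seed(404)
  for (k in 1:100) {
    n <- sample(3:40, 1)
    tr <- make_trials(
      participant_id = sample(paste0("p", 1:3), n, replace = TRUE),
      target = rep("N", n), flanker_left = "Z", flanker_right = "H",
      response = sample(c("N", "Z", "V", NO_RESPONSE), n, replace = TRUE,
                        prob = c(0.7, 0.1, 0.1, 0.1)),
      prompted = runif(n) < 0.15, distracted = runif(n) < 0.1,
      latency_ms = ifelse(runif(n) < 0.05, NA,
                          round(rlnorm(n, log(700), 0.6))))
    out <- trim_latencies(tr)
    l <- out$ledger
    expect_true(l$conserved)
    expect_equal(l$removed_stage1 + l$removed_stage2 + l$retained, l$total)
    expect_equal(l$total, n)
  }
})

test_that("participants with fewer than two survivors skip stage 2", {
  tr <- make_trials(participant_id = c("p1", "p2", "p2", "p2"),
                    target = "N", flanker_left = "Z", flanker_right = "H",
                    response = "N", latency_ms = c(800, 500, 520, 540))
  out <- trim_latencies(tr)
  expect_identical(out$ledger$stage2_skipped_participants, "p1")
  expect_true("p1" %in% out$retained$participant_id)
})

test_that("inverse transform is the reciprocal rate in 1/s", {
  expect_equal(inverse_transform(800), 1.25)
  expect_equal(inverse_transform(1000), 1.0)
  lat <- sort(rlnorm(50, log(800), 0.4))
  expect_true(all(diff(inverse_transform(lat)) < 0))
  expect_error(inverse_transform(0), "invalid latency")
  expect_error(inverse_transform(-100), "invalid latency")
})

test_that("score standardization maps the patient range onto 0-100", {
  raw <- c(3, 7, 11, 15)
  s <- standardize_scores(raw)
  expect_equal(s, c(0, 100 / 3, 200 / 3, 100))
  expect_equal(standardize_scores(c(10, 15, 20))[2], 50)  # midpoint
  # affine invariance
  expect_equal(standardize_scores(2.5 * raw + 7), s)
  expect_error(standardize_scores(c(5, 5, 5)), "degenerate range")
  expect_error(standardize_scores(5), "at least two")
})

test_that("crowding indices are raw correct-count differences", {
  mk <- function(task, spacing, n_correct, n_wrong, polarity = "same") {
    make_trials(participant_id = "p1", task = task,
                spacing_condition = spacing,
                polarity_condition = polarity,
                target = "N", flanker_left = "Z", flanker_right = "H",
                response = c(rep("N", n_correct), rep("V", n_wrong)))
  }
  tr <- rbind(mk(3, "spaced", 20, 0), mk(3, "condensed", 14, 6),
              mk(4, "spaced", 18, 2), mk(4, "condensed", 13, 7),
              mk(5, "condensed", 8, 4), mk(5, "spaced", 10, 2),
              mk(6, "condensed", 11, 1, "reverse"),
              mk(6, "spaced", 11, 1, "reverse"))
  idx <- crowding_indices(tr)$per_participant
  expect_equal(idx$spacing_shape, 6)
  expect_equal(idx$spacing_number, 5)
  expect_equal(idx$spacing_shapes_numbers, 11)
  expect_equal(idx$polarity, 22 - 18)
  expect_equal(idx$polarity_condensed, 11 - 8)
})

test_that("missing tasks yield missing indices and prompts do not count", {
  tr <- make_trials(participant_id = "p1", task = 3,
                    spacing_condition = rep(c("spaced", "condensed"),
                                            each = 4),
                    target = "N", flanker_left = "Z", flanker_right = "H",
                    response = "N",
                    prompted = c(TRUE, FALSE, FALSE, FALSE, rep(FALSE, 4)))
  idx <- crowding_indices(tr)$per_participant
  expect_equal(idx$spacing_shape, 3 - 4)  # prompted correct not counted
  expect_true(is.na(idx$spacing_number))
  expect_true(is.na(idx$polarity))
  # identical accuracy across conditions -> zero index
  tr2 <- make_trials(participant_id = "p1", task = 4,
                     spacing_condition = rep(c("spaced", "condensed"), 4),
                     target = "N", flanker_left = "2", flanker_right = "9",
                     response = "N")
  expect_equal(crowding_indices(tr2)$per_participant$spacing_number, 0)
})

test_that("trial tables round-trip through TSV with NR and empty fields", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tr <- simulate_cohort(small_pca_config(seed = 5, n_participants = 2,
                                         tasks = c(1, 2)))
  tr$latency_ms[3] <- NA
  write_trials(tr, tmp)
  raw <- readLines(tmp)
  expect_match(raw[1], "^participant_id\t")
  back <- read_trials(tmp)
  expect_equal(back, tr, ignore_attr = TRUE)
  # validation errors name the offending column/symbol
  bad <- tr
  bad$response[1] <- "?"
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_trials(bad, tmp2)
  expect_error(read_trials(tmp2), "invalid response")
  expect_error(validate_trials(tr[, -3]), "missing column")
})
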