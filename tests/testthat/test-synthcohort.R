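test_that("mechanism parameters enforce their invariants", {
  expect_error(mechanism_params(w_avg = 0.6, w_subst = 0.5), "is not TRUE")
  expect_error(mechanism_params(rho = 1.2), "is not TRUE")
  expect_error(mechanism_params(critical_spacing_deg = 0), "is not TRUE")
  p <- mechanism_params(w_avg = 0.3, rho = 0.4)
  expect_equal(crowding_strength(0, p), 1)
  expect_equal(crowding_strength(1.2, p), 0)  # at critical spacing
  expect_equal(crowding_strength(2.0, p), 0)  # beyond
  expect_equal(crowding_strength(0.6, p), 0.5)
  expect_equal(crowding_strength(0.6, p, polarity_condition = "reverse"),
               0.5 * 0.4)
  # monotone in gap
  gaps <- seq(0, 1.2, by = 0.1)
  expect_true(all(diff(crowding_strength(gaps, p)) <= 0))
})

test_that("a seed is mandatory and reproduces bit-identical tables", {
  expect_error(cohort_config(), "seed")
  cc <- small_pca_config(seed = 77)
  t1 <- simulate_cohort(cc)
  t2 <- simulate_cohort(small_pca_config(seed = 77))
  expect_identical(t1, t2)
  t3 <- simulate_cohort(small_pca_config(seed = 78))
  expect_false(identical(t1, t3))
})

test_that("the default cohort has the study's structure", {
  tr <- cached("default_cohort", simulate_cohort(cohort_config(seed = 1)))
  expect_equal(length(unique(tr$participant_id[tr$group == "PCA"])), 26)
  expect_equal(length(unique(tr$participant_id[tr$group == "tAD"])), 17)
  expect_equal(length(unique(tr$participant_id[tr$group == "control"])),
               14)
  one <- tr[tr$participant_id == "PCA01", ]
  expect_equal(sum(one$task == 1), 20)
  for (t in 2:6) expect_equal(sum(one$task == t), 24)
  # three flanker tasks x 24 items = 72 items (tasks 2-4)
  expect_equal(sum(one$task %in% 2:4), 72)
  expect_equal(sum(one$task %in% 2:4 &
                     one$spacing_condition == "condensed"), 36)
  # same flanker combination for each target under both spacing conditions
  t2 <- one[one$task == 2, ]
  key <- paste(t2$target, t2$flanker_left, t2$flanker_right)
  expect_true(all(table(key, t2$spacing_condition) == 1))
  # task 6 is reverse polarity, task 5 same
  expect_true(all(one$polarity_condition[one$task == 6] == "reverse"))
  expect_true(all(one$polarity_condition[one$task == 5] == "same"))
  # six-item ABBA blocks by spacing
  sp <- one$spacing_condition[one$task == 3]
  expect_identical(sp, rep(rep(c("condensed", "spaced", "spaced",
                                 "condensed"), each = 6)))
})

test_that("controls are error-free and PCA-like accuracy orders condensed < spaced", {
  tr <- cached("default_cohort", simulate_cohort(cohort_config(seed = 1)))
  fl <- tr[tr$task != 1, ]
  ctrl <- fl[fl$group == "control", ]
  expect_true(all(ctrl$response == ctrl$target))
  pca <- fl[fl$group == "PCA", ]
  acc <- tapply(pca$response == pca$target, pca$spacing_condition, mean)
  expect_lt(acc["condensed"], acc["spaced"])
  tad <- fl[fl$group == "tAD", ]
  expect_gt(mean(tad$response == tad$target), 0.98)
})

test_that("error-type composition follows the mechanism weights", {
  # flankers outside the candidate alphabet and beta 0 ensure averaging
  # rarely lands on target or flankers; planted mask:subst:avg =
  # 0.30:0.36:0.34
  set.seed(99)
  p <- mechanism_params(w_avg = 0.34, w_subst = 0.36, w_mask = 0.30,
                        beta_avg = 0)
  prof <- stats::setNames(rep(0.3, 20), alphabet_spec()$permitted_targets)
  n <- 10000
  resp <- vapply(seq_len(n), function(i) {
    crowding:::.draw_response("N", "I", "J", 1, p, prof, "I", "J")
  }, character(1))
  cls <- classify_error(rep("N", n), rep("I", n), rep("J", n), resp)
  err <- cls[cls != "correct"]
  props <- table(err) / length(err)
  expect_equal(unname(props[["A"]]), 0.30, tolerance = 0.05)
  expect_equal(unname(props[["B"]]), 0.36, tolerance = 0.05)
  expect_equal(unname(props[["C"]]), 0.34, tolerance = 0.05)
})

test_that("accuracy is monotone in gap and nulled at the critical spacing", {
  set.seed(15)
  p <- mechanism_params(w_avg = 0.4, w_subst = 0.3, w_mask = 0.3,
                        critical_spacing_deg = 1.2)
  prof <- stats::setNames(runif(20, 0.2, 0.5),
                          alphabet_spec()$permitted_targets)
  acc_at <- function(gap) {
    s <- crowding_strength(gap, p)
    mean(vapply(1:2000, function(i) {
      crowding:::.draw_response("N", "Z", "H", s, p, prof, "Z", "H") == "N"
    }, logical(1)))
  }
  accs <- vapply(c(0, 0.4, 0.8, 1.2), acc_at, numeric(1))
  expect_true(all(diff(accs) > 0))
  expect_equal(accs[4], 1)  # gap >= critical spacing: no crowding errors
})

test_that("reverse polarity with rho 0 abolishes the spacing effect", {
  p <- mechanism_params(w_avg = 0.5, rho = 0)
  expect_equal(crowding_strength(0.1, p, polarity_condition = "reverse"), 0)
  expect_equal(crowding_strength(1.0, p, polarity_condition = "reverse"), 0)
})

test_that("pure averaging at extreme beta names the most similar candidate", {
  set.seed(8)
  p <- mechanism_params(w_avg = 1, beta_avg = 1e4)
  prof <- stats::setNames(runif(20, 0, 0.6),
                          alphabet_spec()$permitted_targets)
  best <- names(which.max(prof))
  resp <- vapply(1:50, function(i) {
    crowding:::.draw_response("N", "Z", "H", 1, p, prof, "Z", "H")
  }, character(1))
  expect_true(all(resp == best))
})

test_that("planted truth echoes the configuration and survives JSON", {
  cc <- recovery_config("averaging", seed = 3)
  tt <- planted_truth(cc)
  expect_identical(tt$groups$PCA$mechanism, "averaging")
  expect_equal(tt$groups$PCA$w_avg, 0.30)
  expect_equal(tt$groups$PCA$w_subst, 0)
  cc2 <- cohort_config(seed = 4)
  expect_identical(planted_truth(cc2)$groups$PCA$mechanism, "mixed")
  expect_identical(planted_truth(cc2)$groups$control$mechanism, "none")
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(tt, tmp, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$groups$PCA$w_avg, tt$groups$PCA$w_avg)
  expect_equal(back$seed, tt$seed)
  expect_identical(back$groups$PCA$mechanism, "averaging")
})

test_that("latency trimming recovers roughly the planted contamination", {
  tr <- cached("default_cohort", simulate_cohort(cohort_config(seed = 1)))
  ctrl <- tr[tr$group == "control", ]
  out <- trim_latencies(ctrl)
  frac2 <- out$ledger$removed_stage2 /
    (out$ledger$total - out$ledger$removed_stage1)
  # planted 2% scale-5 outliers plus the log-normal tail beyond 2 SD
  expect_gte(frac2, 0.02)
  expect_lte(frac2, 0.10)
})

test_that("simulate_trial draws a coherent record from a stimulus array", {
  set.seed(12)
  geom <- viewing_geometry(pixel_pitch_mm = 0.5)
  arr <- build_array(render_glyph("G", geometry = geom),
                     render_glyph("T", role = "flanker", geometry = geom),
                     render_glyph("H", role = "flanker", geometry = geom),
                     "condensed", geometry = geom)
  p <- mechanism_params(w_avg = 0.3, w_subst = 0.3, w_mask = 0.3)
  recs <- do.call(rbind, lapply(1:40, function(i) {
    simulate_trial(arr, p)
  }))
  expect_true(all(recs$latency_ms > 0))
  expect_true(all(recs$response %in% c(LETTERS, NO_RESPONSE)))
  expect_true(any(recs$response != "G"))  # strong crowding produces errors
  expect_true(all(recs$prompted == (recs$response %in% c("T", "H"))))
  # at or beyond the critical spacing the target is always named
  arr_far <- build_array(render_glyph("G", geometry = geom),
                         render_glyph("T", role = "flanker",
                                      geometry = geom),
                         render_glyph("H", role = "flanker",
                                      geometry = geom),
                         "spaced", geometry = geom)
  p_narrow <- mechanism_params(w_avg = 0.3, w_subst = 0.3, w_mask = 0.3,
                               critical_spacing_deg = 0.9)
  recs_far <- do.call(rbind, lapply(1:30, function(i) {
    simulate_trial(arr_far, p_narrow)
  }))
  expect_true(all(recs_far$response == "G"))
})
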