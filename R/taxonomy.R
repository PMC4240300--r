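#' Token recording a trial with no naming response
#' @export
NO_RESPONSE <- "NR"

.trial_cols <- c("participant_id", "group", "task", "spacing_condition",
                 "polarity_condition", "target", "flanker_left",
                 "flanker_right", "response", "prompted", "distracted",
                 "latency_ms")

#' Read / write trial tables
#'
#' Trial tables are UTF-8 tab-delimited files with a mandatory header and
#' the columns `participant_id, group, task, spacing_condition,
#' polarity_condition, target, flanker_left, flanker_right, response,
#' prompted, distracted, latency_ms`. A missing naming response is encoded
#' as the literal token `NR`; a missing latency as an empty field. Flanker
#' fields are empty for the unflanked task (Task 1).
#'
#' @param path File path.
#' @return `read_trials()` returns a validated data frame.
#' @export
read_trials <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "", colClasses = "character")
  missing <- setdiff(.trial_cols, names(d))
  if (length(missing) > 0) {
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  d$task <- as.integer(d$task)
  d$prompted <- as.logical(d$prompted)
  d$distracted <- as.logical(d$distracted)
  d$latency_ms <- as.numeric(d$latency_ms)
  d$flanker_left[is.na(d$flanker_left)] <- ""
  d$flanker_right[is.na(d$flanker_right)] <- ""
  validate_trials(d)
}

#' @param trials A trial data frame.
#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  out <- trials[, .trial_cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a trial table
#'
#' Checks column presence, target membership in the permitted alphabet,
#' response symbols, positive latencies and the absence of flankers on
#' Task 1.
#'
#' @param trials A trial data frame.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(.trial_cols, names(trials))
  if (length(missing) > 0) {
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ab <- alphabet_spec()
  bad_t <- !trials$target %in% ab$permitted_targets
  if (any(bad_t)) {
    stop("invalid target symbol(s): ",
         paste(unique(trials$target[bad_t]), collapse = ", "), call. = FALSE)
  }
  bad_r <- !(trials$response %in% c(ab$letters, NO_RESPONSE))
  if (any(bad_r)) {
    stop("invalid response symbol(s): ",
         paste(unique(trials$response[bad_r]), collapse = ", "),
         call. = FALSE)
  }
  if (any(trials$task == 1L &
          (nzchar(trials$flanker_left) | nzchar(trials$flanker_right)))) {
    stop("Task 1 trials must not carry flankers", call. = FALSE)
  }
  lat <- trials$latency_ms
  if (any(!is.na(lat) & lat <= 0)) {
    stop("invalid latency: latencies must be positive", call. = FALSE)
  }
  trials
}

#' Classify flanked-trial responses into the A/B/C error taxonomy
#'
#' Correct responses name the target. Errors fall into three classes:
#' Type A (no response, the target unidentified), Type B (a flanker is
#' named instead of the target, e.g. ZNH -> Z) and Type C (a letter absent
#' from the target/flanker array, e.g. YMT -> V or 3T6 -> C, suggestive of
#' perceptual integration of target and flanker features).
#'
#' @param target,flanker_left,flanker_right,response Character vectors of
#'   equal length (recycled); `response` may be [NO_RESPONSE].
#' @return Factor with levels `correct`, `A`, `B`, `C`.
#' @export
classify_error <- function(target, flanker_left, flanker_right, response) {
  n <- max(length(target), length(response))
  target <- rep_len(target, n); response <- rep_len(response, n)
  flanker_left <- rep_len(flanker_left, n)
  flanker_right <- rep_len(flanker_right, n)
  if (any(!nzchar(flanker_left) | !nzchar(flanker_right))) {
    stop("classify_error applies to flanked trials only", call. = FALSE)
  }
  ok <- response %in% c(LETTERS, NO_RESPONSE)
  if (any(!ok)) {
    stop("invalid response symbol(s): ",
         paste(unique(response[!ok]), collapse = ", "), call. = FALSE)
  }
  out <- ifelse(response == target, "correct",
         ifelse(response == NO_RESPONSE, "A",
         ifelse(response == flanker_left | response == flanker_right,
                "B", "C")))
  factor(out, levels = c("correct", "A", "B", "C"))
}

#' @param trials A flanked trial table (Tasks 2--6).
#' @return `classify_trials()` returns the table with an `error_class`
#'   column appended.
#' @rdname classify_error
#' @export
classify_trials <- function(trials) {
  trials$error_class <- classify_error(trials$target, trials$flanker_left,
                                       trials$flanker_right,
                                       trials$response)
  trials
}

#' Summarise error rate and error-type composition
#'
#' @param trials Flanked trial table.
#' @return List with `n_valid`, `n_errors`, `error_rate` and `proportions`
#'   (shares of Types A/B/C among error trials; all `NA` when there are no
#'   errors).
#' @export
error_summary <- function(trials) {
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  cls <- classify_error(trials$target, trials$flanker_left,
                        trials$flanker_right, trials$response)
  n <- length(cls)
  err <- cls != "correct"
  counts <- table(factor(cls[err], levels = c("A", "B", "C")))
  props <- if (sum(err) == 0) {
    c(A = NA_real_, B = NA_real_, C = NA_real_)
  } else {
    as.numeric(counts) / sum(err)
  }
  names(props) <- c("A", "B", "C")
  list(n_valid = n, n_errors = sum(err), error_rate = sum(err) / n,
       proportions = props)
}

#' Two-stage latency trimming
#'
#' Stage 1 removes the latencies of erroneous, prompted or overtly
#' distracted responses (and trials with no recorded latency). Stage 2
#' computes each participant's mean and sample standard deviation on the
#' stage-1 survivors in a single pass and removes latencies more than two
#' standard deviations from that mean. Participants with fewer than two
#' surviving latencies are skipped at stage 2 and flagged.
#'
#' @param trials Trial table.
#' @return List with `retained` (trial table) and `ledger`: counts per
#'   stage, skipped participants, and the conservation identity
#'   `removed_stage1 + removed_stage2 + retained == total`.
#' @export
trim_latencies <- function(trials) {
  total <- nrow(trials)
  err <- trials$response != trials$target
  stage1_drop <- err | trials$prompted | trials$distracted |
    is.na(trials$latency_ms)
  s1 <- trials[!stage1_drop, , drop = FALSE]

  keep2 <- rep(TRUE, nrow(s1))
  skipped <- character(0)
  for (p in unique(s1$participant_id)) {
    ix <- which(s1$participant_id == p)
    if (length(ix) < 2L) {
      skipped <- c(skipped, p)
      next
    }
    m <- mean(s1$latency_ms[ix])
    s <- stats::sd(s1$latency_ms[ix])
    if (s > 0) {
      keep2[ix] <- abs(s1$latency_ms[ix] - m) <= 2 * s
    }
  }
  retained <- s1[keep2, , drop = FALSE]
  ledger <- list(
    total = total,
    removed_stage1 = sum(stage1_drop),
    removed_stage2 = sum(!keep2),
    retained = nrow(retained),
    stage2_skipped_participants = skipped,
    conserved = sum(stage1_drop) + sum(!keep2) + nrow(retained) == total
  )
  list(retained = retained, ledger = ledger)
}

#' Inverse (reciprocal) latency transform
#'
#' Maps a latency in milliseconds to a naming rate in 1/s, the
#' transformation applied before linear modelling of latencies because raw
#' latencies leave non-normal residuals.
#'
#' @param latency_ms Positive latencies in milliseconds.
#' @return Rates in s^-1 (e.g. 800 ms -> 1.25).
#' @export
inverse_transform <- function(latency_ms) {
  if (any(!is.finite(latency_ms)) || any(latency_ms <= 0)) {
    stop("invalid latency: latencies must be positive and finite",
         call. = FALSE)
  }
  1000 / latency_ms
}

#' Standardize raw scores to a 0--100 range
#'
#' Linear map in which 0 and 100 correspond to the minimum and maximum
#' score achieved by any patient. Composite domain scores are means of
#' standardized member tests.
#'
#' @param raw Numeric vector of raw scores over patients (length >= 2).
#' @return Scores in `[0, 100]`.
#' @export
standardize_scores <- function(raw) {
  x <- raw[!is.na(raw)]
  if (length(x) < 2L) stop("need at least two patient scores", call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0) {
    stop("degenerate range: all raw scores are equal", call. = FALSE)
  }
  (raw - rng[1]) / diff(rng) * 100
}

#' Per-participant crowding indices
#'
#' Raw correct-count differences between conditions:
#' \describe{
#'   \item{spacing_shape}{spaced - condensed correct counts, Task 3.}
#'   \item{spacing_number}{spaced - condensed, Task 4.}
#'   \item{spacing_shapes_numbers}{spaced - condensed, Tasks 3 and 4
#'     combined.}
#'   \item{polarity}{Task 6 (reverse) - Task 5 (same), all trials.}
#'   \item{polarity_condensed}{Task 6 - Task 5, condensed trials only.}
#' }
#' A response counts as correct only when it names the target without a
#' prompt. A missing task yields `NA`, not zero.
#'
#' @param trials Trial table.
#' @return List with `per_participant` (one row per participant) and
#'   `group_means`.
#' @export
crowding_indices <- function(trials) {
  trials$ok <- (trials$response == trials$target) & !trials$prompted
  cnt <- function(d, tasks, spacing = NULL) {
    keep <- d$task %in% tasks
    if (!is.null(spacing)) keep <- keep & d$spacing_condition == spacing
    if (!any(keep)) return(NA_real_)
    sum(d$ok[keep])
  }
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(p) {
    d <- trials[trials$participant_id == p, , drop = FALSE]
    data.frame(
      participant_id = p,
      group = d$group[1],
      spacing_shape = cnt(d, 3, "spaced") - cnt(d, 3, "condensed"),
      spacing_number = cnt(d, 4, "spaced") - cnt(d, 4, "condensed"),
      spacing_shapes_numbers =
        cnt(d, c(3, 4), "spaced") - cnt(d, c(3, 4), "condensed"),
      polarity = cnt(d, 6) - cnt(d, 5),
      polarity_condensed =
        cnt(d, 6, "condensed") - cnt(d, 5, "condensed"),
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, rows)
  idx_cols <- setdiff(names(per), c("participant_id", "group"))
  gm <- stats::aggregate(per[idx_cols], by = list(group = per$group),
                         FUN = function(x) mean(x, na.rm = TRUE))
  list(per_participant = per, group_means = gm)
}
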