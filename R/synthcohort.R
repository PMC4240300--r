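#' Mechanism parameters for synthetic crowding behaviour
#'
#' Governs how a simulated participant responds to a flanked stimulus.
#' With probability `crowding_strength * (w_mask + w_subst + w_avg)` one of
#' three error mechanisms engages, chosen proportionally to its weight:
#' \describe{
#'   \item{masking (`w_mask`)}{the target is not identified: no response
#'     (Type A errors);}
#'   \item{substitution (`w_subst`)}{a flanker is named in place of the
#'     target (Type B); digit or triangle flankers yield the most-similar
#'     letter instead, since participants respond with letters;}
#'   \item{averaging (`w_avg`)}{a candidate letter is sampled with
#'     probability proportional to `exp(beta_avg * similarity)` to the
#'     averaged target/flanker composite (mostly Type C).}
#' }
#' Otherwise the target is named (up to a small `lapse_rate`). Crowding
#' strength ramps linearly from 1 at zero gap to 0 at the participant's
#' critical spacing (configurable `exponent`), and is multiplied by
#' `rho` when the flankers have reverse polarity. In peripheral vision the
#' critical spacing is roughly the Bouma fraction (0.5) times target
#' eccentricity; the centrally presented stimuli modelled here instead take
#' a pathological central critical spacing directly, drawn per participant
#' from a log-normal distribution.
#'
#' @param w_avg,w_subst,w_mask Nonnegative mechanism weights with sum
#'   at most 1; the remainder is the floor probability of a correct
#'   response while crowded.
#' @param beta_avg Softmax inverse temperature on composite similarity.
#' @param critical_spacing_deg Median critical spacing in degrees.
#' @param critical_spacing_sd Log-scale SD of critical spacing across
#'   participants.
#' @param rho Multiplier in `[0, 1]` applied under reverse polarity.
#' @param exponent Exponent of the crowding-strength ramp.
#' @param critical_spacing_fraction Bouma fraction (eccentricity-based
#'   peripheral reference, default 0.5; informational for central
#'   presentation).
#' @param lapse_rate Stimulus-independent error probability.
#' @return An object of class `mechanism_params`.
#' @export
mechanism_params <- function(w_avg = 0, w_subst = 0, w_mask = 0,
                             beta_avg = 4,
                             critical_spacing_deg = 1.2,
                             critical_spacing_sd = 0,
                             rho = 1, exponent = 1,
                             critical_spacing_fraction = 0.5,
                             lapse_rate = 0) {
  stopifnot(w_avg >= 0, w_subst >= 0, w_mask >= 0,
            w_avg + w_subst + w_mask <= 1,
            rho >= 0, rho <= 1, critical_spacing_deg > 0,
            critical_spacing_sd >= 0, exponent > 0,
            lapse_rate >= 0, lapse_rate < 1)
  structure(as.list(environment()), class = "mechanism_params")
}

#' Crowding strength as a function of gap and polarity
#'
#' Linear (or power) ramp from 1 at zero edge-to-edge gap down to 0 at the
#' critical spacing, multiplied by `rho` under reverse polarity.
#'
#' @param gap_deg Edge-to-edge gap in degrees.
#' @param params A [mechanism_params()] object.
#' @param critical_spacing_deg Participant-level critical spacing override.
#' @param polarity_condition `"same"` or `"reverse"` (or `"none"`).
#' @return Strength in `[0, 1]`; 0 whenever `gap_deg >= critical spacing`.
#' @export
crowding_strength <- function(gap_deg, params,
                              critical_spacing_deg =
                                params$critical_spacing_deg,
                              polarity_condition = "same") {
  s <- pmax(0, 1 - gap_deg / critical_spacing_deg)^params$exponent
  if (identical(polarity_condition, "reverse")) s <- s * params$rho
  s
}

#' Cohort configuration for the synthetic crowding study
#'
#' Defaults reproduce the structure of the study cohort: 26 PCA-like,
#' 17 typical-AD-like and 14 control participants; Task 1 presents the 20
#' permitted letters unflanked; Tasks 2--6 present `items_per_condition`
#' target/flanker triplets per task, each under both the condensed (0.1
#' deg) and spaced (1.0 deg) condition, in six-item blocks ordered ABBA by
#' spacing. PCA-like defaults produce prominent crowding (condensed well
#' below spaced accuracy, overall flanked error rate near 18%, a mixture of
#' no-response, flanker-naming and integration errors); tAD-like defaults
#' are near ceiling with latency-only crowding costs; controls make no
#' flanked errors.
#'
#' @param group_sizes Named integer vector (`PCA`, `tAD`, `control`).
#' @param params Named list of [mechanism_params()] per group.
#' @param latency Named list per group with elements `base_ms`,
#'   `crowd_cost_ms`, `sigma` (log-normal), `participant_sd` (log-scale),
#'   `outlier_prob`, `outlier_scale`.
#' @param items_per_condition Unique triplets per flanked task (each is
#'   shown condensed and spaced, so trials per task = 2x this; default 12,
#'   giving the 24-item tasks and 72-item Tasks 2--4 total).
#' @param tasks Tasks to simulate (default 1:6); focused designs (e.g.
#'   letter flankers only) are used for replicate studies.
#' @param p_distract Probability a trial is marked overtly distracted.
#' @param height_deg Glyph height (degrees).
#' @param geometry A [viewing_geometry()].
#' @param seed Mandatory integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(PCA = 26, tAD = 17, control = 14),
                          params = list(
                            PCA = mechanism_params(
                              w_avg = 0.09, w_subst = 0.14, w_mask = 0.10,
                              beta_avg = 4, critical_spacing_deg = 1.4,
                              critical_spacing_sd = 0.25, rho = 0.35,
                              lapse_rate = 0.002),
                            tAD = mechanism_params(
                              w_avg = 0.003, w_subst = 0.003, w_mask = 0.002,
                              beta_avg = 4, critical_spacing_deg = 1.2,
                              critical_spacing_sd = 0.2, rho = 0.5),
                            control = mechanism_params()
                          ),
                          latency = list(
                            PCA = list(base_ms = 800, crowd_cost_ms = 1500,
                                       sigma = 0.45, participant_sd = 0.30,
                                       outlier_prob = 0.02,
                                       outlier_scale = 5),
                            tAD = list(base_ms = 560, crowd_cost_ms = 80,
                                       sigma = 0.20, participant_sd = 0.12,
                                       outlier_prob = 0.02,
                                       outlier_scale = 5),
                            control = list(base_ms = 500, crowd_cost_ms = 60,
                                           sigma = 0.18,
                                           participant_sd = 0.08,
                                           outlier_prob = 0.02,
                                           outlier_scale = 5)
                          ),
                          items_per_condition = 12,
                          tasks = 1:6,
                          p_distract = 0.02,
                          height_deg = 1.2,
                          geometry = viewing_geometry(),
                          seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is mandatory for reproducibility", call. = FALSE)
  }
  stopifnot(all(group_sizes >= 1),
            all(names(group_sizes) %in% c("PCA", "tAD", "control")),
            length(group_sizes) >= 1,
            items_per_condition >= 1, all(tasks %in% 1:6))
  structure(
    list(group_sizes = group_sizes, params = params, latency = latency,
         items_per_condition = items_per_condition, tasks = tasks,
         p_distract = p_distract, height_deg = height_deg,
         geometry = geometry, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Task definitions: flanker category and polarity condition.
.task_defs <- data.frame(
  task = 1:6,
  flanker_category = c("none", "letter", "shape", "digit", "letter",
                       "letter"),
  polarity_condition = c("none", "same", "same", "same", "same", "reverse"),
  stringsAsFactors = FALSE
)

# Build the shared stimulus catalogue: triplets for tasks 2-6 plus the
# similarity structures the response mechanisms need.
.build_catalogue <- function(config) {
  ab <- alphabet_spec()
  cand <- candidate_glyphs(ab$permitted_targets, config$height_deg,
                           config$geometry)
  glyph_cache <- new.env(parent = emptyenv())
  get_glyph <- function(sym) {
    if (!exists(sym, envir = glyph_cache)) {
      assign(sym, .symbol_glyph(sym, config$height_deg, config$geometry),
             envir = glyph_cache)
    }
    get(sym, envir = glyph_cache)
  }
  sim_to_letters <- function(raster) {
    vapply(cand, function(g) pixel_overlap(raster, g), numeric(1))
  }
  catalogue <- list()
  for (t in intersect(2:6, config$tasks)) {
    def <- .task_defs[.task_defs$task == t, ]
    n <- config$items_per_condition
    targets <- sample(ab$permitted_targets,
                      n, replace = n > length(ab$permitted_targets))
    # letter flankers are drawn from the permitted target alphabet so that
    # every flanker-naming (Type B) error is expressible in the candidate
    # space of the error-identity models
    fl <- switch(def$flanker_category,
      letter = replicate(n, sample(ab$permitted_targets, 2)),
      digit = replicate(n, sample(as.character(2:9), 2)),
      shape = replicate(n, paste0(
        "triangle", sample(alphabet_spec()$triangle_orientations, 2))))
    items <- data.frame(target = targets, flanker_left = fl[1, ],
                        flanker_right = fl[2, ],
                        stringsAsFactors = FALSE)
    # drop accidental flanker == target
    if (def$flanker_category == "letter") {
      for (i in seq_len(n)) {
        while (items$flanker_left[i] == items$target[i]) {
          items$flanker_left[i] <- sample(ab$permitted_targets, 1)
        }
        while (items$flanker_right[i] == items$target[i]) {
          items$flanker_right[i] <- sample(ab$permitted_targets, 1)
        }
      }
    }
    items$avg_profile <- vector("list", n)
    items$subst_left <- items$flanker_left
    items$subst_right <- items$flanker_right
    for (i in seq_len(n)) {
      gl <- get_glyph(items$flanker_left[i])
      gr <- get_glyph(items$flanker_right[i])
      if (def$polarity_condition == "reverse") {
        gl <- .flip_polarity(gl); gr <- .flip_polarity(gr)
      }
      comp <- composite_average(get_glyph(items$target[i]), list(gl, gr))
      items$avg_profile[[i]] <- sim_to_letters(comp)
      if (def$flanker_category != "letter") {
        items$subst_left[i] <- names(which.max(
          sim_to_letters(get_glyph(items$flanker_left[i])$raster)))
        items$subst_right[i] <- names(which.max(
          sim_to_letters(get_glyph(items$flanker_right[i])$raster)))
      }
    }
    catalogue[[as.character(t)]] <-
      list(items = items, polarity_condition = def$polarity_condition)
  }
  catalogue
}

# Core response mechanism shared by simulate_trial and simulate_cohort.
# avg_profile: named similarity vector of candidate letters vs composite;
# subst_left/right: letter named when the corresponding flanker is
# substituted.
.draw_response <- function(target, flanker_left, flanker_right, strength,
                           params, avg_profile, subst_left, subst_right) {
  if (stats::runif(1) < params$lapse_rate) {
    return(sample(setdiff(alphabet_spec()$permitted_targets, target), 1))
  }
  W <- params$w_mask + params$w_subst + params$w_avg
  if (W > 0 && stats::runif(1) < strength * W) {
    mech <- sample(c("mask", "subst", "avg"), 1,
                   prob = c(params$w_mask, params$w_subst, params$w_avg))
    if (mech == "mask") return(NO_RESPONSE)
    if (mech == "subst") {
      return(if (stats::runif(1) < 0.5) subst_left else subst_right)
    }
    pr <- exp(params$beta_avg * (avg_profile - max(avg_profile)))
    return(sample(names(avg_profile), 1, prob = pr))
  }
  target
}

.draw_latency <- function(strength, lat, participant_mult) {
  x <- (lat$base_ms + lat$crowd_cost_ms * strength) * participant_mult *
    exp(stats::rnorm(1, 0, lat$sigma))
  if (stats::runif(1) < lat$outlier_prob) x <- x * lat$outlier_scale
  round(x)
}

# Vectorized counterparts used by the cohort generator.
.draw_latencies <- function(strength, lat, participant_mult) {
  n <- length(strength)
  x <- (lat$base_ms + lat$crowd_cost_ms * strength) * participant_mult *
    exp(stats::rnorm(n, 0, lat$sigma))
  out <- stats::runif(n) < lat$outlier_prob
  x[out] <- x[out] * lat$outlier_scale
  round(x)
}

.draw_responses <- function(items, strength, pars) {
  n <- nrow(items)
  resp <- items$target
  W <- pars$w_mask + pars$w_subst + pars$w_avg
  engaged <- if (W > 0) stats::runif(n) < strength * W else rep(FALSE, n)
  mech <- character(n)
  if (any(engaged)) {
    mech[engaged] <- sample(c("mask", "subst", "avg"), sum(engaged),
                            replace = TRUE,
                            prob = c(pars$w_mask, pars$w_subst,
                                     pars$w_avg))
  }
  resp[mech == "mask"] <- NO_RESPONSE
  sb <- which(mech == "subst")
  if (length(sb) > 0) {
    left <- stats::runif(length(sb)) < 0.5
    resp[sb] <- ifelse(left, items$subst_left[sb], items$subst_right[sb])
  }
  for (i in which(mech == "avg")) {
    prof <- items$avg_profile[[i]]
    pr <- exp(pars$beta_avg * (prof - max(prof)))
    resp[i] <- sample(names(prof), 1, prob = pr)
  }
  lapsed <- which(stats::runif(n) < pars$lapse_rate)
  for (i in lapsed) {
    resp[i] <- sample(setdiff(alphabet_spec()$permitted_targets,
                              items$target[i]), 1)
  }
  resp
}

#' Simulate one naming trial for a stimulus array
#'
#' Draws a response and latency from the mechanism mixture for a composed
#' [build_array()] stimulus. The similarity profile of the averaged
#' composite is computed on the fly (the cohort generator caches it).
#' Randomness uses R's current RNG stream; seed it for reproducibility.
#'
#' @param array A [build_array()] stimulus.
#' @param params A [mechanism_params()].
#' @param participant List with `critical_spacing_deg` and `latency_mult`
#'   (default 1).
#' @param latency Latency model list (see [cohort_config()]).
#' @return One-row trial data frame (without participant/group labels).
#' @export
simulate_trial <- function(array, params,
                           participant = list(
                             critical_spacing_deg =
                               params$critical_spacing_deg,
                             latency_mult = 1),
                           latency = cohort_config(seed = 0)$latency$PCA) {
  stopifnot(inherits(array, "stimulus_array"),
            inherits(params, "mechanism_params"))
  strength <- crowding_strength(array$gap_deg, params,
                                participant$critical_spacing_deg,
                                array$polarity_condition)
  comp <- composite_average(array$target,
                            list(array$left_flanker, array$right_flanker))
  prof <- similarity_profile(comp)
  avg_profile <- stats::setNames(prof$value, prof$candidate)
  subst <- function(g) {
    if (g$symbol %in% LETTERS) return(g$symbol)
    p <- similarity_profile(abs(g$raster))
    attr(p, "argmax")
  }
  response <- .draw_response(array$target$symbol,
                             array$left_flanker$symbol,
                             array$right_flanker$symbol,
                             strength, params, avg_profile,
                             subst(array$left_flanker),
                             subst(array$right_flanker))
  data.frame(
    task = NA_integer_,
    spacing_condition = array$spacing_condition,
    polarity_condition = array$polarity_condition,
    target = array$target$symbol,
    flanker_left = array$left_flanker$symbol,
    flanker_right = array$right_flanker$symbol,
    response = response,
    prompted = response %in% c(array$left_flanker$symbol,
                               array$right_flanker$symbol),
    distracted = FALSE,
    latency_ms = .draw_latency(strength, latency,
                               participant$latency_mult),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic cohort
#'
#' Generates the complete Tasks 1--6 trial table for every participant in
#' the configured groups. The stimulus catalogue (triplets and their
#' similarity structures) is drawn once per cohort and shared across
#' participants, mirroring a fixed test battery. Trials within each
#' flanked task run in six-item blocks with spacing conditions ordered
#' ABBA (condensed, spaced, spaced, condensed). A trial is marked
#' `prompted` when the named response is a flanker (the examiner's "Is
#' that the letter in the middle?" prompt), and `distracted` with
#' probability `p_distract`. The same seed yields a bit-identical table.
#'
#' @param config A [cohort_config()].
#' @param catalogue Optional pre-built stimulus catalogue (for replicate
#'   simulations reusing the same stimuli); by default built from the
#'   config's seed.
#' @return A trial data frame in the standard trial-table schema.
#' @export
simulate_cohort <- function(config, catalogue = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  if (is.null(catalogue)) catalogue <- .build_catalogue(config)
  ab <- alphabet_spec()
  n_cond <- config$items_per_condition
  # six-item ABBA blocks when the counts divide evenly, else interleaved
  block_sp <- if ((2L * n_cond) %% 24L == 0L) {
    rep(rep(c("condensed", "spaced", "spaced", "condensed"), each = 6L),
        length.out = 2L * n_cond)
  } else {
    rep(c("condensed", "spaced"), n_cond)
  }

  out <- vector("list", sum(config$group_sizes))
  latents <- vector("list", sum(config$group_sizes))
  k <- 0L
  for (grp in names(config$group_sizes)) {
    pars <- config$params[[grp]]
    lat <- config$latency[[grp]]
    for (s in seq_len(config$group_sizes[[grp]])) {
      pid <- sprintf("%s%02d", grp, s)
      cs <- stats::rlnorm(1, log(pars$critical_spacing_deg),
                          pars$critical_spacing_sd)
      lmult <- exp(stats::rnorm(1, 0, lat$participant_sd))
      rows <- list()
      # Task 1: the 20 permitted letters, unflanked, in random order
      if (1L %in% config$tasks) {
        tg <- sample(ab$permitted_targets)
        n1 <- length(tg)
        resp <- tg
        for (i in which(stats::runif(n1) < pars$lapse_rate)) {
          resp[i] <- sample(setdiff(ab$permitted_targets, tg[i]), 1)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, group = grp, task = 1L,
          spacing_condition = "none", polarity_condition = "none",
          target = tg, flanker_left = "", flanker_right = "",
          response = resp, prompted = FALSE,
          distracted = stats::runif(n1) < config$p_distract,
          latency_ms = .draw_latencies(rep(0, n1), lat, lmult),
          stringsAsFactors = FALSE)
      }
      for (t in intersect(2:6, config$tasks)) {
        cat_t <- catalogue[[as.character(t)]]
        items <- cat_t$items
        # each triplet appears once per spacing condition
        order_cond <- sample(n_cond); order_spa <- sample(n_cond)
        idx <- integer(2L * n_cond)
        idx[block_sp == "condensed"] <- order_cond
        idx[block_sp == "spaced"] <- order_spa
        it <- items[idx, ]
        gap <- ifelse(block_sp == "condensed", 0.1, 1.0)
        strength <- crowding_strength(gap, pars, cs,
                                      cat_t$polarity_condition)
        resp <- .draw_responses(it, strength, pars)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, group = grp, task = t,
          spacing_condition = block_sp,
          polarity_condition = cat_t$polarity_condition,
          target = it$target, flanker_left = it$flanker_left,
          flanker_right = it$flanker_right, response = resp,
          prompted = resp == it$flanker_left | resp == it$flanker_right,
          distracted = stats::runif(length(resp)) < config$p_distract,
          latency_ms = .draw_latencies(strength, lat, lmult),
          stringsAsFactors = FALSE)
      }
      k <- k + 1L
      out[[k]] <- do.call(rbind, rows)
      latents[[k]] <- data.frame(participant_id = pid, group = grp,
                                 critical_spacing_deg = cs,
                                 latency_mult = lmult,
                                 stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  # per-participant latent draws, exposed for recovery analyses
  attr(trials, "participants") <- do.call(rbind, latents)
  trials
}

#' Ground-truth record of the generating mechanisms
#'
#' Emits the mechanism weights, softmax temperature, critical spacing and
#' polarity attenuation planted in each group, plus a mechanism label, so
#' recovery analyses can be scored against truth. The record survives a
#' JSON round trip unchanged.
#'
#' @param config A [cohort_config()].
#' @return List, one entry per group, plus the seed.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lab <- function(p) {
    w <- c(averaging = p$w_avg, substitution = p$w_subst,
           masking = p$w_mask)
    if (sum(w) == 0) return("none")
    if (sum(w > 0) == 1L) return(names(w)[w > 0])
    "mixed"
  }
  groups <- lapply(config$params, function(p) {
    list(mechanism = lab(p), w_avg = p$w_avg, w_subst = p$w_subst,
         w_mask = p$w_mask, beta_avg = p$beta_avg,
         critical_spacing_deg = p$critical_spacing_deg,
         critical_spacing_sd = p$critical_spacing_sd, rho = p$rho,
         exponent = p$exponent, lapse_rate = p$lapse_rate)
  })
  list(seed = config$seed, group_sizes = as.list(config$group_sizes),
       groups = groups)
}
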