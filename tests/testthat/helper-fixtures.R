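# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

# Minimal hand-built trial table.
make_trials <- function(participant_id, target, flanker_left,
                        flanker_right, response, task = 2L,
                        spacing_condition = "condensed",
                        polarity_condition = "same",
                        group = "PCA", prompted = FALSE,
                        distracted = FALSE, latency_ms = 800) {
  data.frame(participant_id = participant_id, group = group, task = task,
             spacing_condition = spacing_condition,
             polarity_condition = polarity_condition, target = target,
             flanker_left = flanker_left, flanker_right = flanker_right,
             response = response, prompted = prompted,
             distracted = distracted, latency_ms = latency_ms,
             stringsAsFactors = FALSE)
}

# Small single-group cohort configuration used by fast pipeline tests;
# coarse pixel pitch keeps glyph rendering cheap.
small_pca_config <- function(seed, n_participants = 4,
                             items_per_condition = 6, tasks = 2,
                             params = NULL) {
  if (is.null(params)) {
    params <- mechanism_params(w_avg = 0.2, w_subst = 0.2, w_mask = 0.1,
                               beta_avg = 4, critical_spacing_deg = 1.4,
                               critical_spacing_sd = 0.15, rho = 0.35)
  }
  cohort_config(
    group_sizes = c(PCA = n_participants),
    params = list(PCA = params),
    latency = list(PCA = list(base_ms = 800, crowd_cost_ms = 1500,
                              sigma = 0.45, participant_sd = 0.30,
                              outlier_prob = 0.02, outlier_scale = 5)),
    items_per_condition = items_per_condition, tasks = tasks,
    geometry = viewing_geometry(pixel_pitch_mm = 0.5),
    seed = seed)
}

# Pure-mechanism recovery configuration: 20 PCA-like participants, full
# flanked battery, a single engaged mechanism at weight 0.30 so each
# participant accrues roughly 15-20 Type B/C errors.
recovery_config <- function(mechanism = c("averaging", "substitution",
                                          "null"),
                            seed, n_participants = 20, tasks = 2:6) {
  mechanism <- match.arg(mechanism)
  p <- switch(mechanism,
    averaging = mechanism_params(w_avg = 0.30, beta_avg = 4,
                                 critical_spacing_deg = 1.4,
                                 critical_spacing_sd = 0.15, rho = 0.35),
    substitution = mechanism_params(w_subst = 0.30,
                                    critical_spacing_deg = 1.4,
                                    critical_spacing_sd = 0.15,
                                    rho = 0.35),
    # similarity-independent errors: averaging at beta 0 samples
    # candidates uniformly
    null = mechanism_params(w_avg = 0.30, beta_avg = 0,
                            critical_spacing_deg = 1.4,
                            critical_spacing_sd = 0.15, rho = 0.35))
  cohort_config(
    group_sizes = c(PCA = n_participants),
    params = list(PCA = p),
    latency = list(PCA = list(base_ms = 800, crowd_cost_ms = 1500,
                              sigma = 0.45, participant_sd = 0.30,
                              outlier_prob = 0.02, outlier_scale = 5)),
    tasks = tasks, seed = seed)
}

# Fit Models 1-3 to the Type B/C errors of a trial table; returns the fits
# plus error counts. Model 2 reuses the Model 3 design with a feature
# subset (same rows by construction).
fit_three_models <- function(trials) {
  fl <- classify_trials(trials[trials$task != 1, , drop = FALSE])
  err <- fl[fl$error_class %in% c("B", "C"), , drop = FALSE]
  d1 <- build_design(err, 1)
  d3 <- build_design(err, 3)
  list(
    model1 = fit_logistic_mixed(d1),
    model2 = fit_logistic_mixed(d3, features = c("sim_left", "sim_right")),
    model3 = fit_logistic_mixed(d3),
    n_errors = nrow(err),
    errors_per_participant = table(err$participant_id)
  )
}

zstat <- function(fit, term) {
  fit$coefficients$z[fit$coefficients$term == term]
}
pval <- function(fit, term) {
  fit$coefficients$p[fit$coefficients$term == term]
}

# Memoised store for simulation studies shared between test files.
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}
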