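# Memoised similarity vectors shared across build_design calls.
.overlap_memo <- new.env(parent = emptyenv())

# Glyph lookup for any symbol appearing in a trial table: letters, digits
# 2-9, or "triangle<orientation>".
.symbol_glyph <- function(symbol, height_deg = 1.2,
                          geometry = viewing_geometry()) {
  if (symbol %in% LETTERS) {
    render_glyph(symbol, "letter", height_deg = height_deg,
                 geometry = geometry, role = "flanker")
  } else if (symbol %in% as.character(2:9)) {
    render_glyph(symbol, "digit", height_deg = height_deg,
                 geometry = geometry)
  } else if (grepl("^triangle", symbol)) {
    render_glyph("triangle", "shape", height_deg = height_deg,
                 geometry = geometry,
                 orientation = as.numeric(sub("^triangle", "", symbol)))
  } else {
    stop("unknown stimulus symbol: ", symbol, call. = FALSE)
  }
}

#' Build the candidate-expansion design for the error-identity models
#'
#' Each Type B or C error trial is expanded to one row per candidate letter
#' (the permitted target alphabet minus the trial's own target, since a
#' target response would have been correct, not an error). The binary
#' outcome `chosen` marks the candidate actually named. Features are
#' pixel-overlap similarities of the candidate's glyph against:
#' \describe{
#'   \item{Model 1 (target/flanker averaging)}{the averaged target/flanker
#'     composite (`sim_avg`);}
#'   \item{Model 2 (individual flankers)}{each flanker separately
#'     (`sim_left`, `sim_right`);}
#'   \item{Model 3 (individual flankers and target)}{as Model 2 plus the
#'     target (`sim_target`).}
#' }
#' Digit and triangle flanker trials enter with their digit/triangle
#' rasters, so letter-digit integration errors (e.g. 3T6 -> C) are scored
#' on the same footing as letter flankers. Reverse-polarity trials
#' contribute sign-flipped flanker rasters to the Model 1 composite;
#' similarity itself is computed on contrast magnitude.
#'
#' @param trials Error trials (Tasks 2--6) classified Type B or C; trials
#'   that are correct or Type A raise an error.
#' @param model_id 1, 2 or 3.
#' @param height_deg,geometry Rendering geometry for the similarity
#'   computation.
#' @param align,metric Passed to [pixel_overlap()].
#' @return Data frame with columns `trial_id`, `participant_id`,
#'   `candidate`, `chosen` and the model's feature columns.
#' @export
build_design <- function(trials, model_id = 1, height_deg = 1.2,
                         geometry = viewing_geometry(), align = TRUE,
                         metric = "jaccard") {
  stopifnot(model_id %in% 1:3, nrow(trials) > 0)
  cls <- classify_error(trials$target, trials$flanker_left,
                        trials$flanker_right, trials$response)
  if (any(!cls %in% c("B", "C"))) {
    stop("wrong error class: design rows require Type B or C error trials",
         call. = FALSE)
  }
  ab <- alphabet_spec()
  cand_glyphs <- candidate_glyphs(ab$permitted_targets, height_deg, geometry)
  if (is.null(trials$trial_id)) {
    trials$trial_id <- seq_len(nrow(trials))
  }

  # cache glyphs and per-reference similarity vectors over unique symbols;
  # rendering is deterministic, so similarity vectors are memoised across
  # calls (replicate simulation studies reuse the same stimuli)
  ckey <- function(kind, key) {
    paste(kind, key, height_deg, geometry$distance_mm,
          geometry$pixel_pitch_mm, align, metric, sep = "@")
  }
  syms <- unique(c(trials$target, trials$flanker_left, trials$flanker_right))
  glyphs <- lapply(syms, .symbol_glyph, height_deg = height_deg,
                   geometry = geometry)
  names(glyphs) <- syms
  sim_to <- function(ref_raster) {
    vapply(cand_glyphs, function(g) {
      pixel_overlap(ref_raster, g, align = align, metric = metric)
    }, numeric(1))
  }
  memo <- function(kind, key, value_fn) {
    k <- ckey(kind, key)
    if (!exists(k, envir = .overlap_memo)) {
      assign(k, value_fn(), envir = .overlap_memo)
    }
    get(k, envir = .overlap_memo)
  }
  item_sim <- lapply(syms, function(s) {
    memo("item", s, function() sim_to(glyphs[[s]]$raster))
  })
  names(item_sim) <- syms

  comp_sim <- NULL
  if (model_id == 1) {
    key <- paste(trials$target, trials$flanker_left, trials$flanker_right,
                 trials$polarity_condition, sep = "|")
    comp_sim <- new.env(parent = emptyenv())
    for (k in unique(key)) {
      assign(k, memo("composite", k, function() {
        parts <- strsplit(k, "|", fixed = TRUE)[[1]]
        fl <- glyphs[[parts[2]]]; fr <- glyphs[[parts[3]]]
        if (identical(parts[4], "reverse")) {
          fl <- .flip_polarity(fl); fr <- .flip_polarity(fr)
        }
        sim_to(composite_average(glyphs[[parts[1]]], list(fl, fr)))
      }), envir = comp_sim)
    }
    trials$.key <- key
  }

  resp_ok <- trials$response %in% ab$permitted_targets &
    trials$response != trials$target
  if (any(!resp_ok)) {
    stop("invalid response: ",
         paste(unique(trials$response[!resp_ok]), collapse = ", "),
         " outside the candidate alphabet; such trials cannot enter the ",
         "error-identity models", call. = FALSE)
  }
  nt <- nrow(trials)
  nc <- length(ab$permitted_targets) - 1L
  cand_mat <- vapply(trials$target, function(tg) {
    ab$permitted_targets[ab$permitted_targets != tg]
  }, character(nc))
  feature_mat <- function(lookup) {
    vapply(seq_len(nt), function(i) lookup(i)[cand_mat[, i]],
           numeric(nc))
  }
  design <- data.frame(
    trial_id = rep(trials$trial_id, each = nc),
    participant_id = rep(trials$participant_id, each = nc),
    candidate = as.vector(cand_mat),
    chosen = as.integer(as.vector(cand_mat) ==
                          rep(trials$response, each = nc)),
    stringsAsFactors = FALSE)
  if (model_id == 1) {
    design$sim_avg <- as.vector(feature_mat(function(i) {
      get(trials$.key[i], envir = comp_sim)
    }))
  } else {
    design$sim_left <- as.vector(feature_mat(function(i) {
      item_sim[[trials$flanker_left[i]]]
    }))
    design$sim_right <- as.vector(feature_mat(function(i) {
      item_sim[[trials$flanker_right[i]]]
    }))
    if (model_id == 3) {
      design$sim_target <- as.vector(feature_mat(function(i) {
        item_sim[[trials$target[i]]]
      }))
    }
  }
  design
}

#' Fit a crossed random-intercepts logistic model
#'
#' Fits `chosen ~ features + (1 | participant) + (1 | candidate)` by maximum
#' marginal likelihood with the Laplace approximation (via
#' \code{lme4::glmer}): a logistic mixed-effects model with crossed random
#' effects of participant and error-response letter and fixed effects of
#' the similarity values. Wald z statistics and p-values are reported for
#' the fixed effects.
#'
#' If the fixed-effects structure shows signs of complete separation
#' (diverging coefficients), the function warns and refits the
#' fixed-effects part with a Jeffreys-prior (Firth) penalty, flagging the
#' result.
#'
#' @param design A [build_design()] data frame.
#' @param features Character vector of feature columns (defaults to every
#'   `sim_*` column present).
#' @return Object of class `crowding_mixed_fit`: coefficient table,
#'   random-intercept variances, log-likelihood, convergence flag, `n_obs`.
#' @export
fit_logistic_mixed <- function(design, features = NULL) {
  if (is.null(features)) {
    features <- grep("^sim_", names(design), value = TRUE)
  }
  stopifnot(length(features) > 0, all(features %in% names(design)))
  if (length(unique(design$participant_id)) < 2L) {
    stop("need at least two participants", call. = FALSE)
  }
  if (length(unique(design$candidate[design$chosen == 1])) < 2L) {
    stop("need at least two distinct response letters", call. = FALSE)
  }
  if (any(vapply(design[features], function(x) stats::sd(x) == 0,
                 logical(1)))) {
    stop("constant similarity feature", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "chosen ~", paste(features, collapse = " + "),
    "+ (1 | participant_id) + (1 | candidate)"))
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                             optCtrl = list(maxfun = 20000),
                             check.conv.singular = "ignore")
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = design, family = stats::binomial(),
                nAGQ = 1, control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  co <- summary(fit)$coefficients
  penalized <- FALSE
  if (any(abs(co[, "Estimate"]) > 15) || any(co[, "Std. Error"] > 50)) {
    warning("possible separation in fixed effects; ",
            "refitting with a Firth-penalized logistic model",
            call. = FALSE)
    fo <- .firth_logistic(as.matrix(cbind(1, design[features])),
                          design$chosen)
    co <- cbind(Estimate = fo$coef, `Std. Error` = fo$se,
                `z value` = fo$coef / fo$se,
                `Pr(>|z|)` = 2 * stats::pnorm(-abs(fo$coef / fo$se)))
    rownames(co) <- c("(Intercept)", features)
    penalized <- TRUE
  }
  vc <- lme4::VarCorr(fit)
  coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      z = co[, 3], p = co[, 4], row.names = NULL)
  structure(
    list(coefficients = coefs,
         re_variances = c(participant = as.numeric(vc$participant_id),
                          candidate = as.numeric(vc$candidate)),
         loglik = as.numeric(stats::logLik(fit)),
         converged = length(fit@optinfo$conv$lme4$messages) == 0 &&
           !any(grepl("failed to converge", msgs)),
         penalized = penalized,
         n_obs = nrow(design),
         features = features,
         fit = fit),
    class = "crowding_mixed_fit"
  )
}

# Firth (Jeffreys-prior) penalized logistic regression by modified IRLS;
# fixed effects only, used as the separation fallback.
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    XtWX <- crossprod(X, XW)
    H <- XW %*% solve(XtWX, t(X))  # hat matrix (weighted)
    h <- diag(H)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- solve(XtWX, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(XtWX)))
  list(coef = drop(beta), se = se, iterations = it)
}

#' @export
print.crowding_mixed_fit <- function(x, ...) {
  cat("Crossed random-intercepts logistic fit (Laplace)\n")
  cat(sprintf("  n_obs: %d   logLik: %.3f   converged: %s%s\n", x$n_obs,
              x$loglik, x$converged,
              if (x$penalized) "   [Firth fallback]" else ""))
  print(x$coefficients, digits = 4)
  cat(sprintf("  RE variances: participant %.4f, candidate %.4f\n",
              x$re_variances["participant"], x$re_variances["candidate"]))
  invisible(x)
}

#' Compare the averaging and substitution error models
#'
#' Fits (or accepts pre-fitted) Models 1--3 on the same Type B/C error
#' trials and tabulates their similarity coefficients. The averaging
#' account is flagged as supported when the Model 1 composite-similarity
#' coefficient is significantly positive at `alpha`; the substitution
#' account when an individual-flanker coefficient in Model 2 is.
#'
#' @param fits Named list of three `crowding_mixed_fit` objects
#'   (`model1`, `model2`, `model3`) fitted to the same trial set.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `crowding_model_comparison`: coefficient table
#'   across models and the supported-account flags.
#' @export
compare_models <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) == 3L)
  if (is.null(names(fits))) names(fits) <- paste0("model", 1:3)
  n <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n)) != 1L) {
    stop("inconsistent design: models were fitted to different trial sets",
         call. = FALSE)
  }
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    co <- fits[[nm]]$coefficients
    co <- co[co$term != "(Intercept)", , drop = FALSE]
    cbind(model = nm, co)
  }))
  rownames(tab) <- NULL
  m1 <- fits[[1]]$coefficients
  m2 <- fits[[2]]$coefficients
  avg_sig <- m1$p[m1$term == "sim_avg"] < alpha &&
    m1$estimate[m1$term == "sim_avg"] > 0
  fl <- m2[m2$term %in% c("sim_left", "sim_right"), ]
  subst_sig <- any(fl$p < alpha & fl$estimate > 0)
  verdict <- if (avg_sig && !subst_sig) "averaging"
    else if (subst_sig && !avg_sig) "substitution"
    else if (avg_sig && subst_sig) "both"
    else "neither"
  structure(
    list(table = tab, alpha = alpha, n_obs = unname(n[1]),
         averaging_supported = avg_sig,
         substitution_supported = subst_sig,
         supported_account = verdict),
    class = "crowding_model_comparison"
  )
}

#' @export
print.crowding_model_comparison <- function(x, ...) {
  cat("Averaging vs. substitution model comparison (alpha =",
      x$alpha, ")\n")
  print(x$table, digits = 4)
  cat("Supported account:", x$supported_account, "\n")
  invisible(x)
}
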