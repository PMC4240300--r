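#' Cluster-robust regression of accuracy or latency
#'
#' Fits an ordinary logistic (accuracy) or linear (inverse latency) model
#' and replaces the conventional standard errors with a cluster-robust
#' sandwich estimator with participants as clusters. The default flavour
#' is CR0 (no small-sample correction); `type = "CR2"` applies the HC2-type
#' leverage adjustment.
#'
#' @param data Model data frame.
#' @param formula Model formula; for latency analyses the response should
#'   already be on the inverse (1/s) scale via [inverse_transform()] and
#'   accuracy included as a covariate.
#' @param cluster Name of the clustering column (default
#'   `"participant_id"`).
#' @param family `"binomial"` for accuracy, `"gaussian"` for (inverse)
#'   latency.
#' @param type `"CR0"` or `"CR2"`.
#' @return Object of class `cluster_robust_fit` with the coefficient table
#'   (`estimate`, `se`, `z`, `p`), the underlying fit and the cluster
#'   count. For near-ceiling logistic fits with separation the
#'   coefficients come from a Firth-penalized refit and are flagged.
#' @export
fit_cluster_robust <- function(data, formula,
                               cluster = "participant_id",
                               family = c("binomial", "gaussian"),
                               type = c("CR0", "CR2")) {
  family <- match.arg(family)
  type <- match.arg(type)
  stopifnot(cluster %in% names(data))
  cl <- data[[cluster]]
  if (length(unique(cl)) < 2L) {
    stop("robust SE undefined with a single cluster", call. = FALSE)
  }
  fit <- stats::glm(formula, data = data,
                    family = if (family == "binomial") {
                      stats::binomial()
                    } else {
                      stats::gaussian()
                    })
  penalized <- FALSE
  if (family == "binomial" && any(abs(stats::coef(fit)) > 15,
                                  na.rm = TRUE)) {
    warning("possible separation; using Firth-penalized estimates",
            call. = FALSE)
    mm <- stats::model.matrix(fit)
    y <- fit$y
    fo <- .firth_logistic(mm, y)
    fit$coefficients[] <- fo$coef
    penalized <- TRUE
  }
  vc <- sandwich::vcovCL(fit, cluster = cl,
                         type = if (type == "CR0") "HC0" else "HC2",
                         cadjust = FALSE)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                      z = ct[, 3], p = ct[, 4], row.names = NULL)
  structure(
    list(coefficients = coefs, vcov = vc, fit = fit, family = family,
         type = type, n_clusters = length(unique(cl)),
         penalized = penalized),
    class = "cluster_robust_fit"
  )
}

#' @export
print.cluster_robust_fit <- function(x, ...) {
  cat(sprintf("Cluster-robust %s fit (%s, %d clusters)%s\n",
              x$family, x$type, x$n_clusters,
              if (x$penalized) " [Firth fallback]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Standard spacing-by-flanker group contrasts
#'
#' Convenience wrapper fitting the canonical contrast models on the
#' flanked-letter tasks 2--4: accuracy by cluster-robust logistic
#' regression on spacing, flanker type, their interaction and group
#' interactions; latency by cluster-robust linear regression of inverse
#' latency on the same terms plus accuracy as a covariate, after
#' [trim_latencies()].
#'
#' @param trials Trial table.
#' @param outcome `"accuracy"` or `"latency"`.
#' @param groups Groups to include (default all present).
#' @param type Sandwich flavour, see [fit_cluster_robust()].
#' @return A `cluster_robust_fit`.
#' @export
crowding_contrasts <- function(trials, outcome = c("accuracy", "latency"),
                               groups = unique(trials$group),
                               type = "CR0") {
  outcome <- match.arg(outcome)
  d <- trials[trials$task %in% 2:4 & trials$group %in% groups, ,
              drop = FALSE]
  d$correct <- as.integer(d$response == d$target)
  d$flanker_type <- factor(c("2" = "letter", "3" = "shape",
                             "4" = "number")[as.character(d$task)])
  d$spacing_condition <- factor(d$spacing_condition,
                                levels = c("spaced", "condensed"))
  d$group <- factor(d$group, levels = intersect(
    c("control", "tAD", "PCA"), unique(d$group)))
  one_group <- length(unique(d$group)) == 1L
  if (outcome == "accuracy") {
    fml <- if (one_group) {
      correct ~ spacing_condition * flanker_type
    } else {
      correct ~ spacing_condition * flanker_type +
        spacing_condition * group + flanker_type * group
    }
    fit_cluster_robust(d, fml, family = "binomial", type = type)
  } else {
    tr <- trim_latencies(d)
    dd <- tr$retained
    dd$inv_latency <- inverse_transform(dd$latency_ms)
    dd$correct <- as.integer(dd$response == dd$target)
    fml <- if (one_group) {
      inv_latency ~ spacing_condition * flanker_type + correct
    } else {
      inv_latency ~ spacing_condition * flanker_type +
        spacing_condition * group + flanker_type * group + correct
    }
    fit_cluster_robust(dd, fml, family = "gaussian", type = type)
  }
}

#' Does any covariate absorb an effect of interest?
#'
#' Refits a cluster-robust contrast model once per covariate, adding that
#' covariate (standardized to 0--100 per [standardize_scores()]) as a
#' participant-level term, and reports whether the effect of interest
#' retains significance at `alpha`.
#'
#' @param trials Trial table (flanked tasks).
#' @param covariates Data frame with `participant_id` and one column per
#'   standardized covariate; an empty covariate set reproduces the
#'   unadjusted fit.
#' @param term Coefficient of interest (default the spacing main effect).
#' @param outcome,alpha See [crowding_contrasts()].
#' @return Data frame: covariate, adjusted estimate, z, p and whether the
#'   effect survives adjustment.
#' @export
covariate_adjustment <- function(trials, covariates = NULL,
                                 term = "spacing_conditioncondensed",
                                 outcome = "accuracy", alpha = 0.05) {
  base_fit <- crowding_contrasts(trials, outcome)
  pick <- function(fit) {
    co <- fit$coefficients
    if (!term %in% co$term) {
      stop("term not found in model: ", term, call. = FALSE)
    }
    co[co$term == term, ]
  }
  rows <- list()
  b <- pick(base_fit)
  rows[["(unadjusted)"]] <- data.frame(
    covariate = "(unadjusted)", estimate = b$estimate, z = b$z, p = b$p,
    retained = b$p < alpha)
  cov_names <- if (is.null(covariates)) {
    character(0)
  } else {
    setdiff(names(covariates), "participant_id")
  }
  for (cv in cov_names) {
    if (stats::sd(covariates[[cv]], na.rm = TRUE) == 0) {
      stop("degenerate covariate: ", cv, call. = FALSE)
    }
    d <- trials[trials$task %in% 2:4, , drop = FALSE]
    d$correct <- as.integer(d$response == d$target)
    d$flanker_type <- factor(c("2" = "letter", "3" = "shape",
                               "4" = "number")[as.character(d$task)])
    d$spacing_condition <- factor(d$spacing_condition,
                                  levels = c("spaced", "condensed"))
    d$group <- factor(d$group, levels = intersect(
      c("control", "tAD", "PCA"), unique(d$group)))
    d$covariate <- covariates[[cv]][match(d$participant_id,
                                          covariates$participant_id)]
    one_group <- length(unique(d$group)) == 1L
    fml <- if (one_group) {
      correct ~ spacing_condition * flanker_type + covariate
    } else {
      correct ~ spacing_condition * flanker_type +
        spacing_condition * group + flanker_type * group + covariate
    }
    fit <- fit_cluster_robust(d, fml, family = "binomial")
    a <- pick(fit)
    rows[[cv]] <- data.frame(covariate = cv, estimate = a$estimate,
                             z = a$z, p = a$p, retained = a$p < alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon utilities for group comparisons
#'
#' Thin wrappers around [stats::wilcox.test()]: rank-sum for between-group
#' comparisons, signed-rank for within-group paired comparisons (exact for
#' small untied samples, normal approximation with continuity/tie
#' correction otherwise).
#'
#' @param x,y Numeric score vectors.
#' @return The `htest` object.
#' @export
wilcoxon_between <- function(x, y) {
  stats::wilcox.test(x, y, exact = NULL)
}

#' @rdname wilcoxon_between
#' @export
wilcoxon_within <- function(x, y) {
  stats::wilcox.test(x, y, paired = TRUE, exact = NULL)
}

#' Holm adjustment helper
#'
#' The primary analyses report unadjusted p-values; this helper applies a
#' Holm correction when a family-wise bound is wanted.
#'
#' @param p Numeric p-values.
#' @return Holm-adjusted p-values.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
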