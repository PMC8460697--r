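#' Fit the structural equation system for mediation
#'
#' Fits, by least squares with a shared confounder encoding, the recursive
#' linear system linking ART status, maternal fasting glucose (FG),
#' pregnancy systolic blood pressure (SBP), gestational age (GA), the
#' methylation residual, and the child outcome. Two orderings are supported:
#' \itemize{
#'   \item `fetal_cpg_last_mediator`: FG, SBP, GA, CPG, Y — fetal cord
#'     methylation is the last mediator before the outcome.
#'   \item `maternal_cpg_first_mediator`: CPG_M, FG, SBP, GA, Y — the
#'     negative-control ordering with maternal mid-pregnancy methylation
#'     first.
#' }
#' Each equation regresses its variable on ART, all preceding mediators, and
#' the confounders.
#'
#' @param data Data.frame with columns `art`, `FG`, `SBP_preg`, `GA`, the
#'   methylation column, the outcome column, and the confounders.
#' @param cpg_col Methylation column name (a fetal `cpg_*` or maternal
#'   `cpgm_*` residual; a mean-of-residuals pseudo-CpG column is equally
#'   valid).
#' @param outcome_col Outcome column name.
#' @param confounders Confounder column names (default: the structural set
#'   used throughout the package).
#' @param ordering Equation ordering tag (see above).
#' @return A `structural_fit`: per-equation coefficients and residual SDs,
#'   the ordering, and the mediator-of-interest name.
#' @export
fit_structural_system <- function(data, cpg_col, outcome_col,
                                  confounders = STRUCTURAL_CONFOUNDERS,
                                  ordering = c("fetal_cpg_last_mediator",
                                               "maternal_cpg_first_mediator")) {
  ordering <- match.arg(ordering)
  if (length(unique(data$art)) < 2) {
    stop("fit_structural_system: ART column is constant; treatment ",
         "coefficients are inestimable")
  }
  chain <- if (ordering == "fetal_cpg_last_mediator") {
    c("FG", "SBP_preg", "GA", cpg_col, outcome_col)
  } else {
    c(cpg_col, "FG", "SBP_preg", "GA", outcome_col)
  }
  mediator <- cpg_col
  C <- as.matrix(data[confounders])
  cc <- stats::complete.cases(data[c("art", chain)], C)
  d <- data[cc, , drop = FALSE]
  C <- C[cc, , drop = FALSE]
  fit_equation <- function(lhs, mediators_before, rows = seq_len(nrow(d))) {
    X <- cbind(`(Intercept)` = 1, art = d$art[rows])
    if (length(mediators_before) > 0) {
      X <- cbind(X, as.matrix(d[rows, mediators_before, drop = FALSE]))
    }
    X <- cbind(X, C[rows, , drop = FALSE])
    f <- stats::lm.fit(X, d[[lhs]][rows])
    if (any(is.na(f.coef <- f$coefficients))) {
      stop("fit_structural_system: singular design for '", lhs,
           "'; aliased: ",
           paste(names(f.coef)[is.na(f.coef)], collapse = ", "))
    }
    list(lhs = lhs, mediators = mediators_before, coef = f$coefficients,
         sigma = sqrt(sum(f$residuals^2) / max(1, length(rows) - ncol(X))))
  }
  eqs <- lapply(seq_along(chain), function(i) {
    fit_equation(chain[i], chain[seq_len(i - 1)])
  })
  names(eqs) <- chain
  structure(list(equations = eqs, chain = chain, mediator = mediator,
                 outcome = outcome_col, confounders = confounders,
                 ordering = ordering, n = nrow(d), data = d,
                 conf_matrix = C),
            class = "structural_fit")
}

# mean-propagation of counterfactual values through the fitted chain;
# force_mediator, if given, overrides the mediator-of-interest values
propagate <- function(fit, art_value, C, force_mediator = NULL) {
  vals <- list()
  for (eq in fit$equations) {
    v <- eq$coef[["(Intercept)"]] + eq$coef[["art"]] * art_value +
      as.vector(C %*% eq$coef[colnames(C)])
    for (mname in eq$mediators) {
      v <- v + eq$coef[[mname]] * vals[[mname]]
    }
    if (!is.null(force_mediator) && eq$lhs == fit$mediator) {
      v <- force_mediator
    }
    vals[[eq$lhs]] <- v
  }
  vals
}

# TE/NDE/NIE for one fitted system on one confounder matrix
contrast_effects <- function(fit, C) {
  v1 <- propagate(fit, 1, C)
  v0 <- propagate(fit, 0, C)
  # NDE: ART = 1 with the mediator of interest held at its ART = 0 level
  # (upstream mediators at their ART = 0 values feed that level)
  vnde <- propagate(fit, 1, C, force_mediator = v0[[fit$mediator]])
  te <- mean(v1[[fit$outcome]] - v0[[fit$outcome]])
  nde <- mean(vnde[[fit$outcome]] - v0[[fit$outcome]])
  c(te = te, nde = nde, nie = te - nde)
}

#' Proportion of the total effect mediated
#' @param nie Natural indirect effect.
#' @param te Total effect.
#' @return 100 * nie / te (percent).
#' @export
prop_mediated <- function(nie, te) 100 * nie / te

#' Parametric g-computation of total, direct and indirect effects
#'
#' Point estimates propagate each subject's observed confounders through the
#' fitted equation chain under ART = 1 versus ART = 0 (total effect), and
#' under ART = 1 with the methylation mediator held at its ART = 0 predicted
#' level (natural direct effect); the natural indirect effect is TE - NDE.
#' Standard errors are the standard deviation of each quantity across
#' bootstrap resamples (rows resampled with replacement, the whole system
#' refit per replicate); confidence intervals are normal-based. For this
#' all-linear system mean propagation equals the expectation of
#' residual-draw simulation without its Monte-Carlo noise; a draw-based mode
#' is available via `draw_residuals = TRUE`.
#'
#' @param fit A [fit_structural_system()] result.
#' @param n_boot Bootstrap replicates (default 100; must be >= 2).
#' @param seed RNG seed for resampling.
#' @param draw_residuals If TRUE, propagation adds Gaussian residual draws
#'   per equation (point estimates then carry simulation noise).
#' @param conf_level Confidence level.
#' @return One-row data.frame: te, nde, nie with bootstrap SEs and CIs,
#'   prop_mediated (%), n, n_boot, and the count of dropped singular
#'   replicates.
#' @export
gcompute_effects <- function(fit, n_boot = 100, seed = 1L,
                             draw_residuals = FALSE, conf_level = 0.95) {
  stopifnot(inherits(fit, "structural_fit"))
  if (n_boot < 2) stop("gcompute_effects: n_boot must be >= 2")
  C <- fit$conf_matrix
  point <- if (draw_residuals) {
    contrast_effects_draws(fit, C, seed)
  } else {
    contrast_effects(fit, C)
  }
  set.seed(seed)
  n <- fit$n
  boots <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("te", "nde", "nie")))
  dropped <- 0
  for (r in seq_len(n_boot)) {
    rows <- sample.int(n, n, replace = TRUE)
    bfit <- tryCatch(
      fit_structural_system(fit$data[rows, , drop = FALSE], fit$mediator,
                            fit$outcome, fit$confounders, fit$ordering),
      error = function(e) NULL)
    if (is.null(bfit)) { dropped <- dropped + 1; next }
    boots[r, ] <- contrast_effects(bfit, bfit$conf_matrix)
  }
  if (dropped > 0) {
    message("gcompute_effects: dropped ", dropped, " singular replicate(s)")
  }
  ses <- apply(boots, 2, stats::sd, na.rm = TRUE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    outcome = fit$outcome, mediator = fit$mediator, ordering = fit$ordering,
    te = point[["te"]], te_se = ses[["te"]],
    te_lo = point[["te"]] - z * ses[["te"]],
    te_hi = point[["te"]] + z * ses[["te"]],
    nde = point[["nde"]], nde_se = ses[["nde"]],
    nde_lo = point[["nde"]] - z * ses[["nde"]],
    nde_hi = point[["nde"]] + z * ses[["nde"]],
    nie = point[["nie"]], nie_se = ses[["nie"]],
    nie_lo = point[["nie"]] - z * ses[["nie"]],
    nie_hi = point[["nie"]] + z * ses[["nie"]],
    prop_mediated = prop_mediated(point[["nie"]], point[["te"]]),
    n = fit$n, n_boot = n_boot, dropped_replicates = dropped,
    stringsAsFactors = FALSE
  )
}

# residual-draw variant of contrast_effects (non-default)
contrast_effects_draws <- function(fit, C, seed) {
  set.seed(seed)
  draw_propagate <- function(art_value, force_mediator = NULL) {
    vals <- list()
    for (eq in fit$equations) {
      v <- eq$coef[["(Intercept)"]] + eq$coef[["art"]] * art_value +
        as.vector(C %*% eq$coef[colnames(C)]) +
        stats::rnorm(nrow(C), 0, eq$sigma)
      for (mname in eq$mediators) v <- v + eq$coef[[mname]] * vals[[mname]]
      if (!is.null(force_mediator) && eq$lhs == fit$mediator) {
        v <- force_mediator
      }
      vals[[eq$lhs]] <- v
    }
    vals
  }
  v1 <- draw_propagate(1)
  v0 <- draw_propagate(0)
  vnde <- draw_propagate(1, force_mediator = v0[[fit$mediator]])
  te <- mean(v1[[fit$outcome]] - v0[[fit$outcome]])
  nde <- mean(vnde[[fit$outcome]] - v0[[fit$outcome]])
  c(te = te, nde = nde, nie = te - nde)
}

#' Closed-form path effects of a fitted linear system
#'
#' For the all-linear chain the counterfactual contrasts have closed forms:
#' each variable's treated-minus-untreated difference is its ART coefficient
#' plus the mediator coefficients times the upstream differences, and the
#' natural indirect effect is the outcome's mediator-of-interest coefficient
#' times that mediator's contrast. Used as an algebraic cross-check of the
#' g-computation engine.
#'
#' @param fit A [fit_structural_system()] result.
#' @return Named vector: per-variable contrasts, te, nde, nie.
#' @export
linear_path_effects <- function(fit) {
  deltas <- list()
  for (eq in fit$equations) {
    d <- eq$coef[["art"]]
    for (mname in eq$mediators) d <- d + eq$coef[[mname]] * deltas[[mname]]
    deltas[[eq$lhs]] <- d
  }
  te <- deltas[[fit$outcome]]
  y_eq <- fit$equations[[fit$outcome]]
  nie <- y_eq$coef[[fit$mediator]] * deltas[[fit$mediator]]
  out <- unlist(deltas)
  c(out, te = te, nde = te - nie, nie = nie)
}

#' Negative-control mediation with maternal methylation
#'
#' Re-runs the g-computation engine with maternal mid-pregnancy methylation
#' residuals in place of the fetal cord measure, under the reordered system
#' in which the maternal CpG precedes the pregnancy mediators. Under the
#' fetal-imprinting hypothesis and no unmeasured confounding the natural
#' indirect effect through the maternal CpG should be approximately zero; a
#' systematically nonzero estimate flags residual confounding or a direct
#' maternal epigenetic effect.
#'
#' @param data As for [fit_structural_system()].
#' @param maternal_cpg_col Maternal methylation residual column (`cpgm_*`).
#' @inheritParams fit_structural_system
#' @inheritParams gcompute_effects
#' @return As [gcompute_effects()].
#' @export
negative_control_mediation <- function(data, maternal_cpg_col, outcome_col,
                                       confounders = STRUCTURAL_CONFOUNDERS,
                                       n_boot = 100, seed = 1L) {
  fit <- fit_structural_system(data, maternal_cpg_col, outcome_col,
                               confounders,
                               ordering = "maternal_cpg_first_mediator")
  gcompute_effects(fit, n_boot = n_boot, seed = seed)
}

#' Mediation effects across the visit schedule
#'
#' Runs the g-computation engine per visit for one outcome and one CpG,
#' optionally restricted to the emulated-trial arms, producing the
#' trajectory of total, direct and indirect effects over age.
#'
#' @param subjects Subject table.
#' @param visits Long visit table.
#' @param cpg_col Methylation residual column in `subjects`.
#' @param outcome Visit measure name.
#' @param visit_list Months to analyze.
#' @param rule Optional [arm_rule()] restricting to the emulated trial.
#' @inheritParams fit_structural_system
#' @inheritParams gcompute_effects
#' @return Data.frame with one row per analyzable visit (column
#'   `visit_month`); visits without treated observations are skipped with a
#'   message.
#' @export
mediation_over_visits <- function(subjects, visits, cpg_col, outcome,
                                  visit_list, rule = NULL,
                                  confounders = STRUCTURAL_CONFOUNDERS,
                                  n_boot = 100, seed = 1L) {
  cohort <- emulated_trial_cohort(subjects, rule)
  need_conf <- setdiff(confounders, names(cohort))
  if (length(need_conf) > 0) {
    cm <- confounder_matrix(cohort)
    cohort <- cbind(cohort, cm[, need_conf, drop = FALSE])
  }
  rows <- lapply(visit_list, function(v) {
    d <- cohort
    d$..y <- outcome_at_visit(d, visits, outcome, v)
    if (!any(!is.na(d$..y) & d$art == 1)) {
      message("mediation_over_visits: no treated observations at month ", v,
              "; skipped")
      return(NULL)
    }
    fit <- fit_structural_system(d, cpg_col, "..y", confounders)
    res <- gcompute_effects(fit, n_boot = n_boot, seed = seed)
    res$outcome <- outcome
    res$visit_month <- v
    res
  })
  do.call(rbind, rows)
}
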