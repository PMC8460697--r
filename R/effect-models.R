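#' Confounder adjustment sets
#'
#' `pre_pregnancy`: time-invariant confounders preceding conception —
#' maternal age, education, ethnicity, household income, height,
#' pre-pregnancy BMI, parity, household smoke exposure; paternal age, height,
#' weight, diabetes and hypertension history; child sex and polygenic risk
#' score. `pre_plus_pregnancy` further adjusts for pregnancy factors that may
#' sit on the causal pathway: maternal fasting and 2-h post-OGTT glucose,
#' pregnancy systolic blood pressure, and gestational age at delivery.
#' `none` gives the crude (unadjusted) contrast.
#'
#' @param name One of "none", "pre_pregnancy", "pre_plus_pregnancy".
#' @return A `covariate_set` list with the ordered variable names.
#' @export
covariate_set <- function(name = c("pre_pregnancy", "pre_plus_pregnancy",
                                   "none")) {
  name <- match.arg(name)
  pre <- c("maternal_age", "education", "ethnicity", "income",
           "maternal_height", "ppBMI", "parity", "smoke_home",
           "paternal_age", "paternal_height", "paternal_weight",
           "paternal_diabetes", "paternal_htn", "child_sex", "prs")
  vars <- switch(name,
    none = character(0),
    pre_pregnancy = pre,
    pre_plus_pregnancy = c(pre, "FG", "OGTT2h", "SBP_preg", "GA")
  )
  structure(list(name = name, variables = vars), class = "covariate_set")
}

# outcome vector at one visit, aligned to a subject table
outcome_at_visit <- function(subjects, visits, outcome, visit) {
  v <- visits[visits$measure == outcome & visits$visit_month == visit, ]
  y <- v$value[match(subjects$subject_id, v$subject_id)]
  obs <- v$observed[match(subjects$subject_id, v$subject_id)]
  y[!is.na(obs) & !obs] <- NA
  y
}

effect_row <- function(outcome, visit, estimate, se, n, model_tag,
                       transform = "identity", conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(outcome = outcome, visit_month = visit,
             arm_contrast = "treated_vs_untreated",
             estimate = estimate, se = se,
             ci_low = estimate - z * se, ci_high = estimate + z * se,
             n = n, model_tag = model_tag, transform = transform,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted ART effect at a visit
#'
#' Ordinary least squares of the outcome on ART status plus the adjustment
#' set, fit within each multiply-imputed dataset and pooled by Rubin's rules
#' ([pool_rubin()]); without an imputation set, a single complete-case fit.
#' Log-scale outcomes are reported as percent differences via
#' [percent_difference()].
#'
#' @param subjects Subject table (analysis cohort, e.g. from
#'   [emulated_trial_cohort()]).
#' @param visits Long visit table.
#' @param outcome Measure name in `visits`.
#' @param visit Visit month.
#' @param covset A [covariate_set()].
#' @param imputations Optional [chained_impute()] result over `subjects`.
#' @param log_outcome If TRUE, model ln(outcome) and report % difference.
#' @return One-row effect-estimate data.frame.
#' @export
adjusted_effect <- function(subjects, visits, outcome, visit,
                            covset = covariate_set("pre_pregnancy"),
                            imputations = NULL, log_outcome = FALSE) {
  y <- outcome_at_visit(subjects, visits, outcome, visit)
  if (log_outcome) y <- log(y)
  for (arm_val in c(1, 0)) {
    if (!any(!is.na(y) & subjects$art == arm_val)) {
      stop("adjusted_effect: no observed '", outcome, "' at month ", visit,
           " in the ", c("untreated", "treated")[arm_val + 1], " arm")
    }
  }
  rhs <- paste(c("art", covset$variables), collapse = " + ")
  fml <- stats::as.formula(paste("..y ~", rhs))
  fit_one <- function(d) {
    d$..y <- y
    f <- stats::lm(fml, data = d)
    s <- summary(f)$coefficients
    c(est = s["art", 1], se = s["art", 2], n = sum(!is.na(d$..y) &
        stats::complete.cases(d[c("art", covset$variables)])))
  }
  if (is.null(imputations)) {
    r <- fit_one(subjects)
    out <- effect_row(outcome, visit, r[["est"]], r[["se"]], r[["n"]],
                      paste0("adjusted_", covset$name))
  } else {
    fits <- vapply(imputations$datasets, fit_one, numeric(3))
    pooled <- pool_rubin(fits["est", ], fits["se", ])
    out <- effect_row(outcome, visit, pooled$estimate, pooled$se,
                      max(fits["n", ]),
                      paste0("adjusted_", covset$name, "_mi", imputations$m))
  }
  if (log_outcome) {
    out$transform <- "percent_difference"
    out$estimate <- percent_difference(out$estimate)
    out$ci_low <- percent_difference(out$ci_low)
    out$ci_high <- percent_difference(out$ci_high)
  }
  out
}

#' Inverse-probability weights for treatment and censoring
#'
#' Complete-case logistic regressions predict (1) ART status from the
#' adjustment covariates and (2) being observed (uncensored) for the outcome
#' at the visit from ART status and the covariates. The combined weight per
#' subject is \eqn{[A/g + (1-A)/(1-g)] \times 1 / P(uncensored | A, W)},
#' optionally truncated symmetrically at configured percentiles.
#'
#' @inheritParams adjusted_effect
#' @param truncation Percentile bounds for weight truncation (default
#'   c(0.01, 0.99)); NULL disables truncation.
#' @param positivity_fail Fitted treatment probabilities outside
#'   (0.005, 0.995) raise a warning; beyond this share of rows, an error.
#'   The default tolerates the near-zero probabilities a small treated arm
#'   makes routine (truncation handles the resulting extreme weights).
#' @return A `weight_fit` list: subject ids (complete cases), treatment
#'   probabilities g, censoring probabilities, combined weights, bounds.
#' @export
fit_weights <- function(subjects, visits, outcome, visit,
                        covset = covariate_set("pre_pregnancy"),
                        truncation = c(0.01, 0.99),
                        positivity_fail = 0.3) {
  cc <- stats::complete.cases(subjects[c("art", covset$variables)])
  d <- subjects[cc, , drop = FALSE]
  rhs <- if (length(covset$variables) > 0) {
    paste(covset$variables, collapse = " + ")
  } else "1"
  g_fit <- stats::glm(stats::as.formula(paste("art ~", rhs)),
                      data = d, family = stats::binomial())
  g <- stats::fitted(g_fit)
  y <- outcome_at_visit(d, visits, outcome, visit)
  d$..uncensored <- as.numeric(!is.na(y))
  if (all(d$..uncensored == 1)) {
    p_unc <- rep(1, nrow(d)) # no censoring at this visit
  } else {
    c_fit <- stats::glm(stats::as.formula(paste("..uncensored ~ art +", rhs)),
                        data = d, family = stats::binomial())
    p_unc <- stats::fitted(c_fit)
  }
  extreme <- mean(g < 0.005 | g > 0.995)
  if (extreme > 0) {
    msg <- sprintf("fit_weights: %.1f%% of treatment probabilities outside (0.005, 0.995)",
                   100 * extreme)
    if (extreme > positivity_fail) stop(msg) else warning(msg)
  }
  w <- (d$art / g + (1 - d$art) / (1 - g)) / pmax(p_unc, 1e-6)
  if (!is.null(truncation)) {
    q <- stats::quantile(w, truncation)
    w <- pmin(pmax(w, q[1]), q[2])
  }
  structure(list(subject_id = d$subject_id, treatment_probs = g,
                 censor_probs = p_unc, combined_weights = w,
                 truncation_bounds = truncation,
                 outcome = outcome, visit_month = visit,
                 covset = covset$name),
            class = "weight_fit")
}

#' Inverse-probability-weighted ART effect
#'
#' Weighted least squares of the outcome on ART status (plus optional
#' covariates) using combined treatment-and-censoring weights, with robust
#' (HC0 sandwich) standard errors.
#'
#' @inheritParams adjusted_effect
#' @param weights A [fit_weights()] result for the same outcome and visit.
#' @return One-row effect-estimate data.frame.
#' @export
weighted_effect <- function(subjects, visits, weights, outcome, visit,
                            covset = covariate_set("none")) {
  stopifnot(inherits(weights, "weight_fit"))
  idx <- match(weights$subject_id, subjects$subject_id)
  if (any(is.na(idx))) stop("weighted_effect: weights and rows misaligned")
  d <- subjects[idx, , drop = FALSE]
  d$..w <- weights$combined_weights
  d$..y <- outcome_at_visit(d, visits, outcome, visit)
  d <- d[!is.na(d$..y), , drop = FALSE]
  rhs <- paste(c("art", covset$variables), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("..y ~", rhs)), data = d,
                   weights = ..w)
  vc <- sandwich::vcovHC(fit, type = "HC0")
  effect_row(outcome, visit, stats::coef(fit)[["art"]],
             sqrt(vc["art", "art"]), nrow(d),
             paste0("ipw_", weights$covset))
}

#' Quantitative bias analysis for paternal-weight measurement error
#'
#' Post-conception paternal weight may differentially mismeasure the
#' pre-conception value; this shifts treated-arm paternal weight by each
#' `delta_kg` before refitting the adjusted model, tracing the estimate over
#' the grid.
#'
#' @inheritParams adjusted_effect
#' @param delta_kg_grid Numeric vector of kg shifts applied to the treated
#'   arm's paternal weight.
#' @return Data.frame of effect estimates, one row per delta (column
#'   `delta_kg`).
#' @export
paternal_weight_bias <- function(subjects, visits, outcome, visit,
                                 covset = covariate_set("pre_pregnancy"),
                                 delta_kg_grid = c(-20, -10, -5, 0, 5, 10, 20),
                                 imputations = NULL) {
  rows <- lapply(delta_kg_grid, function(delta) {
    d <- subjects
    tr <- d$art == 1
    d$paternal_weight[tr] <- d$paternal_weight[tr] + delta
    imp <- imputations
    if (!is.null(imp)) {
      imp$datasets <- lapply(imp$datasets, function(dd) {
        dd$paternal_weight[dd$art == 1] <- dd$paternal_weight[dd$art == 1] + delta
        dd
      })
    }
    r <- adjusted_effect(d, visits, outcome, visit, covset, imputations = imp)
    r$delta_kg <- delta
    r
  })
  do.call(rbind, rows)
}
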