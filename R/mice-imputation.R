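#' Multiple imputation by chained equations
#'
#' Fills incomplete columns by iterated conditional draws: each incomplete
#' variable is regressed on all other variables among the completed data and
#' missing cells are replaced by stochastic draws from the fitted
#' conditional — linear regression with residual-noise draws for continuous
#' variables, a logistic Bernoulli draw for binary variables, and a
#' multinomial draw for categorical variables. Cells start from random draws
#' of observed values, cycles repeat `n_cycles` times, and `m` independent
#' chains yield `m` completed datasets. Observed cells are never altered.
#'
#' @param records Data.frame; columns not listed in `variables` are carried
#'   through untouched (and used as predictors if fully observed numeric /
#'   factor).
#' @param variables Columns eligible for imputation and for use as
#'   predictors; default: every column except identifiers.
#' @param m Number of completed datasets (default 10).
#' @param seed RNG seed.
#' @param n_cycles Chained-equation cycles per dataset (default 10).
#' @return An `imputation_set`: list with `m`, `datasets` (list of completed
#'   data.frames), `seed`, `method` tags per variable, and per-cycle mean
#'   traces for convergence inspection.
#' @export
chained_impute <- function(records, variables = NULL, m = 10, seed = 1L,
                           n_cycles = 10) {
  if (is.null(variables)) {
    variables <- setdiff(names(records),
                         c("subject_id", "arm", grep("^excl_", names(records),
                                                     value = TRUE)))
  }
  stopifnot(m >= 2)
  dat <- records[variables]
  miss <- vapply(dat, function(x) any(is.na(x)), logical(1))
  if (any(vapply(dat, function(x) all(is.na(x)), logical(1)))) {
    stop("chained_impute: a variable is 100% missing; no donor information")
  }
  method <- vapply(dat, function(x) {
    if (is.character(x) || is.factor(x)) "multinomial"
    else if (length(unique(stats::na.omit(x))) <= 2) "logistic"
    else "linear"
  }, character(1))

  if (!any(miss)) {
    out <- list(m = m, datasets = replicate(m, records, simplify = FALSE),
                seed = as.integer(seed), method = method, traces = NULL)
    class(out) <- "imputation_set"
    return(out)
  }

  set.seed(seed)
  incomplete <- names(dat)[miss]
  # numeric predictor matrix builder (factors to dummies)
  build_X <- function(d, exclude) {
    cols <- setdiff(names(d), exclude)
    mm <- stats::model.matrix(~ ., data = d[cols])
    mm[, -1, drop = FALSE]
  }

  datasets <- vector("list", m)
  traces <- vector("list", m)
  for (chain in seq_len(m)) {
    filled <- dat
    for (v in incomplete) {
      nas <- is.na(filled[[v]])
      obs <- filled[[v]][!nas]
      filled[[v]][nas] <- sample(obs, sum(nas), replace = TRUE)
    }
    trace <- matrix(NA_real_, n_cycles, length(incomplete),
                    dimnames = list(NULL, incomplete))
    for (cyc in seq_len(n_cycles)) {
      for (v in incomplete) {
        nas <- is.na(dat[[v]])
        X <- build_X(filled, v)
        yv <- filled[[v]]
        if (method[[v]] == "linear") {
          fit <- stats::lm.fit(cbind(1, X[!nas, , drop = FALSE]), yv[!nas])
          sigma <- sqrt(sum(fit$residuals^2) /
                          max(fit$df.residual, 1))
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          pred <- as.vector(cbind(1, X[nas, , drop = FALSE]) %*% beta)
          filled[[v]][nas] <- pred + stats::rnorm(sum(nas), 0, sigma)
        } else if (method[[v]] == "logistic") {
          lv <- sort(unique(stats::na.omit(dat[[v]])))
          ybin <- as.numeric(yv == lv[length(lv)])
          fit <- suppressWarnings(
            stats::glm.fit(cbind(1, X[!nas, , drop = FALSE]), ybin[!nas],
                           family = stats::binomial()))
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          p <- stats::plogis(as.vector(cbind(1, X[nas, , drop = FALSE]) %*% beta))
          draw <- stats::rbinom(sum(nas), 1, p)
          filled[[v]][nas] <- ifelse(draw == 1, lv[length(lv)], lv[1])
        } else {
          fit <- suppressWarnings(
            nnet::multinom(y ~ ., data = cbind(y = factor(yv[!nas]),
                                               filled[!nas, setdiff(names(filled), v),
                                                      drop = FALSE]),
                           trace = FALSE))
          p <- stats::predict(fit,
                              newdata = filled[nas, setdiff(names(filled), v),
                                               drop = FALSE],
                              type = "probs")
          if (is.null(dim(p))) p <- cbind(1 - p, p)
          lv <- fit$lev
          draw <- apply(p, 1, function(pr) sample(lv, 1, prob = pr))
          filled[[v]][nas] <- draw
        }
        trace[cyc, v] <- mean(as.numeric(as.factor(filled[[v]])[is.na(dat[[v]])]))
      }
    }
    completed <- records
    completed[variables] <- filled
    datasets[[chain]] <- completed
    traces[[chain]] <- trace
  }
  out <- list(m = m, datasets = datasets, seed = as.integer(seed),
              method = method, traces = traces)
  class(out) <- "imputation_set"
  out
}

#' Pool repeated-imputation estimates by Rubin's rules
#'
#' estimate = mean of per-imputation estimates; within-imputation variance
#' W = mean(se^2); between-imputation variance B = sample variance of the
#' estimates; total variance T = W + (1 + 1/m) B; se = sqrt(T); Wald CI from
#' the normal quantile.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param ses Numeric vector of per-imputation standard errors.
#' @param conf_level Confidence level (default 0.95).
#' @return List with estimate, W, B, T, se, ci_low, ci_high, m.
#' @export
pool_rubin <- function(estimates, ses, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("pool_rubin: need at least 2 imputation fits")
  if (length(ses) != m) stop("pool_rubin: estimates and ses lengths differ")
  est <- mean(estimates)
  W <- mean(ses^2)
  B <- stats::var(estimates)
  Tt <- W + (1 + 1 / m) * B
  se <- sqrt(Tt)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = est, W = W, B = B, T = Tt, se = se,
       ci_low = est - z * se, ci_high = est + z * se, m = m)
}
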