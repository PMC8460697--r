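#' Collaborative targeted maximum likelihood estimate of the ATE
#'
#' The outcome is min-max scaled to [0, 1] (bounds recorded). An initial
#' outcome regression Q0(A, W) is fit by the stacking ensemble
#' ([superlearner()]) on treatment plus the outcome covariates. The
#' propensity model is then built collaboratively: starting from an
#' intercept-only logistic model, candidate covariates are added greedily,
#' and after each candidate addition an intercept-free logistic fluctuation
#' of the scaled outcome on the clever covariate
#' \eqn{H(A,W) = A/g(W) - (1-A)/(1-g(W))} with offset logit Q0 is fit; the
#' candidate minimizing the cross-validated squared error of the updated
#' outcome prediction is kept, and the search stops at the first step with
#' no improvement. The ATE is the mean of Q*(1, W) - Q*(0, W) under the
#' winning fluctuation, back-transformed to the outcome scale; its standard
#' error comes from the sample variance of the efficient influence function.
#'
#' @param data Data.frame holding outcome, treatment and covariates.
#' @param outcome Name of the (bounded) outcome column.
#' @param treatment Name of the binary 0/1 treatment column.
#' @param q_covariates Covariate columns for the initial outcome regression.
#' @param g_candidates Candidate covariate columns for the greedy propensity
#'   search (default: `q_covariates`). Ties in CV loss break by candidate
#'   order.
#' @param library [learner_library()] for the outcome regression; the default
#'   (`glm` and `observed_mean` only) keeps the initial fit parametric — pass
#'   the full library for the machine-learning ensemble.
#' @param seed RNG seed (ensemble folds and CV split of the greedy search).
#' @param g_bounds Propensity estimates are bounded into this interval before
#'   forming the clever covariate (default c(0.01, 0.99)).
#' @param v_folds Folds for the greedy search's cross-validated loss.
#' @return A `ctmle_fit` list: `ate`, `se`, `ci`, `epsilon`, `g_path`
#'   (covariates in selection order), `chosen_subset`, `y_bounds`, `q0`,
#'   `g`, and the per-step CV losses.
#' @export
ctmle_ate <- function(data, outcome, treatment, q_covariates,
                      g_candidates = q_covariates,
                      library = learner_library(c("glm", "observed_mean")),
                      seed = 1L, g_bounds = c(0.01, 0.99), v_folds = 5) {
  y <- data[[outcome]]
  A <- data[[treatment]]
  stopifnot(all(A %in% c(0, 1)))
  if (length(unique(A)) < 2) stop("ctmle_ate: both arms must be present")
  n <- length(y)
  a <- min(y); b <- max(y)
  if (b <= a) stop("ctmle_ate: outcome is constant")
  ysc <- (y - a) / (b - a)

  W <- as.matrix(data[q_covariates])
  ## initial outcome regression on (A, W)
  sl <- superlearner(cbind(A = A, W), ysc, library = library, seed = seed)
  clamp <- function(p, lo = 5e-4) pmin(pmax(p, lo), 1 - lo)
  q0_obs <- clamp(sl$predict(cbind(A = A, W)))
  q0_1 <- clamp(sl$predict(cbind(A = 1, W)))
  q0_0 <- clamp(sl$predict(cbind(A = 0, W)))

  bound_g <- function(g) pmin(pmax(g, g_bounds[1]), g_bounds[2])
  fit_g <- function(subset, rows = seq_len(n)) {
    Xg <- if (length(subset) == 0) {
      matrix(1, length(rows), 1)
    } else {
      cbind(1, as.matrix(data[rows, subset, drop = FALSE]))
    }
    fit <- suppressWarnings(
      stats::glm.fit(Xg, A[rows], family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    function(new_rows) {
      Xn <- if (length(subset) == 0) {
        matrix(1, length(new_rows), 1)
      } else {
        cbind(1, as.matrix(data[new_rows, subset, drop = FALSE]))
      }
      bound_g(stats::plogis(as.vector(Xn %*% beta)))
    }
  }
  clever <- function(g, A_) A_ / g - (1 - A_) / (1 - g)
  fit_eps <- function(H, ysc_, off) {
    fit <- suppressWarnings(
      stats::glm.fit(matrix(H, ncol = 1), ysc_,
                     family = stats::quasibinomial(), offset = off,
                     intercept = FALSE,
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 200)))
    eps <- fit$coefficients[[1]]
    if (!is.finite(eps)) eps <- 0
    eps
  }

  set.seed(seed + 1L)
  cvf <- sample(rep(seq_len(v_folds), length.out = n))
  cv_loss <- function(subset) {
    loss <- 0
    for (k in seq_len(v_folds)) {
      tr <- which(cvf != k); te <- which(cvf == k)
      gfun <- fit_g(subset, tr)
      g_tr <- gfun(tr); g_te <- gfun(te)
      eps <- fit_eps(clever(g_tr, A[tr]), ysc[tr],
                     stats::qlogis(q0_obs[tr]))
      qstar_te <- stats::plogis(stats::qlogis(q0_obs[te]) +
                                  eps * clever(g_te, A[te]))
      loss <- loss + sum((ysc[te] - qstar_te)^2)
    }
    loss / n
  }

  chosen <- character(0)
  remaining <- g_candidates
  best_loss <- cv_loss(chosen)
  loss_path <- data.frame(step = 0, covariate = "(none)",
                          cv_loss = best_loss, stringsAsFactors = FALSE)
  repeat {
    if (length(remaining) == 0) break
    losses <- vapply(remaining, function(cand) cv_loss(c(chosen, cand)),
                     numeric(1))
    j <- which.min(losses) # first minimum wins ties (candidate order)
    if (losses[j] >= best_loss) break
    best_loss <- losses[j]
    chosen <- c(chosen, remaining[j])
    loss_path <- rbind(loss_path,
                       data.frame(step = length(chosen),
                                  covariate = remaining[j],
                                  cv_loss = best_loss,
                                  stringsAsFactors = FALSE))
    remaining <- remaining[-j]
  }

  gfun <- fit_g(chosen)
  g <- gfun(seq_len(n))
  H_obs <- clever(g, A)
  epsilon <- fit_eps(H_obs, ysc, stats::qlogis(q0_obs))
  qstar_obs <- stats::plogis(stats::qlogis(q0_obs) + epsilon * H_obs)
  qstar_1 <- stats::plogis(stats::qlogis(q0_1) + epsilon / g)
  qstar_0 <- stats::plogis(stats::qlogis(q0_0) - epsilon / (1 - g))
  ate_sc <- mean(qstar_1 - qstar_0)
  eif <- H_obs * (ysc - qstar_obs) + (qstar_1 - qstar_0) - ate_sc
  se_sc <- stats::sd(eif) / sqrt(n)
  ate <- ate_sc * (b - a)
  se <- se_sc * (b - a)
  structure(list(ate = ate, se = se,
                 ci = c(ate - 1.96 * se, ate + 1.96 * se),
                 epsilon = epsilon, g_path = loss_path,
                 chosen_subset = chosen, y_bounds = c(a, b),
                 q0 = list(obs = q0_obs, a1 = q0_1, a0 = q0_0),
                 qstar = list(obs = qstar_obs, a1 = qstar_1, a0 = qstar_0),
                 g = g, meta_weights = sl$meta_weights,
                 score = mean(H_obs * (ysc - qstar_obs))),
            class = "ctmle_fit")
}

#' @export
print.ctmle_fit <- function(x, ...) {
  cat(sprintf("C-TMLE ATE: %.4f (SE %.4f; 95%% CI %.4f, %.4f)\n",
              x$ate, x$se, x$ci[1], x$ci[2]))
  cat("propensity covariates:",
      if (length(x$chosen_subset) == 0) "(none)" else
        paste(x$chosen_subset, collapse = ", "), "\n")
  cat(sprintf("fluctuation epsilon: %.5f; score residual: %.2e\n",
              x$epsilon, x$score))
  invisible(x)
}
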