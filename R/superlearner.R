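#' Learner library for the stacking ensemble
#'
#' Available learners: main-effects least squares (`glm`), least squares
#' with all pairwise interactions (`glm_interactions`), a ridge-penalized
#' linear model (`bayes_glm`, the shrinkage analog of a weakly-informative
#' Bayesian GLM), the observed mean (`observed_mean`), a single-hidden-layer
#' neural network (`neural_net_1hidden`; width 5, capped iterations, seeded),
#' and gradient-boosted trees (`boosted_trees`; depth <= 3, bounded rounds).
#'
#' @param learners Character vector of learner names (>= 2).
#' @param k_folds Cross-validation folds (default 5).
#' @param nn_size Hidden-layer width (default 5).
#' @param nn_maxit Neural-net iteration cap (default 200).
#' @param xgb_nrounds Boosting rounds (default 50).
#' @param xgb_depth Tree depth (default 3).
#' @return A `learner_library` list.
#' @export
learner_library <- function(learners = c("glm", "glm_interactions",
                                         "bayes_glm", "observed_mean",
                                         "neural_net_1hidden",
                                         "boosted_trees"),
                            k_folds = 5, nn_size = 5, nn_maxit = 200,
                            xgb_nrounds = 50, xgb_depth = 3) {
  known <- c("glm", "glm_interactions", "bayes_glm", "observed_mean",
             "neural_net_1hidden", "boosted_trees")
  bad <- setdiff(learners, known)
  if (length(bad) > 0) stop("unknown learner(s): ", paste(bad, collapse = ", "))
  if (length(learners) < 2) stop("learner_library: need at least 2 learners")
  structure(list(learners = learners, k_folds = k_folds, nn_size = nn_size,
                 nn_maxit = nn_maxit, xgb_nrounds = xgb_nrounds,
                 xgb_depth = xgb_depth),
            class = "learner_library")
}

# fit one learner; returns a prediction closure or NULL on failure
fit_learner <- function(name, X, y, lib) {
  X <- as.matrix(X)
  tryCatch(switch(name,
    glm = {
      fit <- stats::lm.fit(cbind(1, X), y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      function(newX) as.vector(cbind(1, as.matrix(newX)) %*% beta)
    },
    glm_interactions = {
      expand <- function(M) {
        M <- as.matrix(M)
        p <- ncol(M)
        if (p < 2) return(M)
        pairs <- utils::combn(p, 2)
        inter <- M[, pairs[1, ], drop = FALSE] * M[, pairs[2, ], drop = FALSE]
        cbind(M, inter)
      }
      Xe <- expand(X)
      fit <- stats::lm.fit(cbind(1, Xe), y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      function(newX) as.vector(cbind(1, expand(newX)) %*% beta)
    },
    bayes_glm = {
      lambda <- 0.01 * stats::sd(y)
      fit <- glmnet::glmnet(X, y, alpha = 0, lambda = lambda,
                            standardize = TRUE)
      function(newX) as.vector(stats::predict(fit, as.matrix(newX)))
    },
    observed_mean = {
      mu <- mean(y)
      function(newX) rep(mu, nrow(as.matrix(newX)))
    },
    neural_net_1hidden = {
      xs <- scale(X)
      ctr <- attr(xs, "scaled:center"); scl <- attr(xs, "scaled:scale")
      scl[scl == 0] <- 1
      fit <- nnet::nnet(x = scale(X, ctr, scl), y = y, size = lib$nn_size,
                        linout = TRUE, maxit = lib$nn_maxit, decay = 0.01,
                        trace = FALSE)
      function(newX) as.vector(stats::predict(fit, scale(as.matrix(newX),
                                                         ctr, scl)))
    },
    boosted_trees = {
      fit <- xgboost::xgboost(x = X, y = y, nrounds = lib$xgb_nrounds,
                              max_depth = lib$xgb_depth,
                              learning_rate = 0.3, nthreads = 1,
                              verbosity = 0)
      function(newX) stats::predict(fit, as.matrix(newX))
    }
  ), error = function(e) NULL)
}

#' Cross-validated stacking ensemble (super learner)
#'
#' Splits the data into `k_folds` equal parts; each learner is fit on the
#' training folds and evaluated on the held-out fold, yielding a full set of
#' out-of-fold predictions per learner. Non-negative least squares of the
#' observed outcome on those cross-validated predictions gives the
#' meta-weights; the learners are then refit on all data and the ensemble
#' prediction is the meta-weighted combination. A learner that fails to fit
#' is dropped with a warning and the weights are renormalized over the
#' survivors.
#'
#' @param X Numeric predictor matrix (or data.frame of numerics).
#' @param y Numeric response.
#' @param library A [learner_library()].
#' @param seed RNG seed (fold assignment and stochastic learners).
#' @return A `superlearner_fit`: list with `predict` (function of new X),
#'   `meta_weights` (named non-negative NNLS coefficients), `cv_predictions`,
#'   `cv_risk` per learner, and `folds`.
#' @export
superlearner <- function(X, y, library = learner_library(), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= library$k_folds, all(is.finite(y)))
  set.seed(seed)
  folds <- sample(rep(seq_len(library$k_folds), length.out = n))
  learners <- library$learners
  Z <- matrix(NA_real_, n, length(learners),
              dimnames = list(NULL, learners))
  failed <- character(0)
  for (j in seq_along(learners)) {
    ok <- TRUE
    for (k in seq_len(library$k_folds)) {
      tr <- folds != k
      f <- fit_learner(learners[j], X[tr, , drop = FALSE], y[tr], library)
      if (is.null(f)) { ok <- FALSE; break }
      Z[!tr, j] <- f(X[!tr, , drop = FALSE])
    }
    if (!ok || any(!is.finite(Z[, j]))) failed <- c(failed, learners[j])
  }
  keep <- setdiff(learners, failed)
  if (length(failed) > 0) {
    warning("superlearner: dropped failing learner(s): ",
            paste(failed, collapse = ", "))
  }
  if (length(keep) == 0) stop("superlearner: all learners failed")
  Zk <- Z[, keep, drop = FALSE]
  # raw NNLS coefficients are used directly as the stacking weights, so the
  # meta-fit's in-sample risk is never above any single learner's
  w <- pracma::lsqnonneg(Zk, y)$x
  if (sum(w) <= 0) { # degenerate; fall back to best single learner
    risks <- colMeans((Zk - y)^2)
    w <- as.numeric(seq_along(keep) == which.min(risks))
  }
  names(w) <- keep
  full_fits <- lapply(keep, function(nm) fit_learner(nm, X, y, library))
  names(full_fits) <- keep
  dropped_full <- vapply(full_fits, is.null, logical(1))
  if (any(dropped_full)) {
    total <- sum(w)
    w <- w[!dropped_full]
    if (sum(w) > 0) w <- w * total / sum(w)
    full_fits <- full_fits[!dropped_full]
  }
  predict_fn <- function(newX) {
    newX <- as.matrix(newX)
    preds <- vapply(names(w), function(nm) full_fits[[nm]](newX),
                    numeric(nrow(newX)))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
    as.vector(preds %*% w)
  }
  structure(list(predict = predict_fn, meta_weights = w,
                 cv_predictions = Zk,
                 cv_risk = colMeans((Zk - y)^2),
                 ensemble_cv_risk = mean((as.vector(Zk[, names(w), drop = FALSE] %*% w) - y)^2),
                 folds = folds),
            class = "superlearner_fit")
}
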