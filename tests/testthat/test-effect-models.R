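test_that("adjusted regression recovers the generating effect and nulls out", {
  b <- default_path_coefs() * 0
  b[["beta11"]] <- -2
  co <- small_cohort(seed = 51, n_treated = 300, n_untreated = 1700,
                     true_path_coefs = b)
  est <- adjusted_effect(co$subjects, co$visits, "height_cm", 78)
  expect_lt(abs(est$estimate - (-2)), 2 * est$se)
  # permuting the treatment indicator breaks the link
  s <- co$subjects
  set.seed(1)
  s$art <- sample(s$art)
  est0 <- adjusted_effect(s, co$visits, "height_cm", 78)
  expect_lt(abs(est0$estimate), 2 * est0$se)
  expect_error(
    adjusted_effect(co$subjects, co$visits, "height_cm", 999),
    "no observed")
})

test_that("pregnancy-factor adjustment is innocuous without mediated paths", {
  b <- default_path_coefs() * 0
  b[["beta11"]] <- -1.5
  co <- small_cohort(seed = 52, n_treated = 300, n_untreated = 1700,
                     true_path_coefs = b)
  pre <- adjusted_effect(co$subjects, co$visits, "height_cm", 78,
                         covariate_set("pre_pregnancy"))
  plus <- adjusted_effect(co$subjects, co$visits, "height_cm", 78,
                          covariate_set("pre_plus_pregnancy"))
  expect_lt(abs(pre$estimate - plus$estimate), 0.5 * pre$se)
})

test_that("constant propensity reduces IPW to the unadjusted difference", {
  set.seed(2)
  n <- 400
  s <- data.frame(subject_id = sprintf("S%04d", 1:n),
                  art = rbinom(n, 1, 0.5), x = rnorm(n))
  v <- data.frame(subject_id = s$subject_id, visit_month = 12,
                  measure = "y", value = 1 + 0.8 * s$art + rnorm(n),
                  observed = TRUE)
  cov0 <- covariate_set("none")
  w <- fit_weights(s, v, "y", 12, cov0, truncation = NULL)
  expect_equal(unname(w$treatment_probs), rep(mean(s$art), n),
               tolerance = 1e-9)
  est <- weighted_effect(s, v, w, "y", 12)
  crude <- mean(v$value[s$art == 1]) - mean(v$value[s$art == 0])
  expect_equal(est$estimate, crude, tolerance = 1e-9)
  # doubling weights changes nothing (WLS scale invariance)
  w2 <- w; w2$combined_weights <- 2 * w$combined_weights
  est2 <- weighted_effect(s, v, w2, "y", 12)
  expect_equal(est2$estimate, est$estimate, tolerance = 1e-12)
  expect_equal(est2$se, est$se, tolerance = 1e-10)
})

test_that("weighted least squares matches a normal-equations oracle", {
  set.seed(3)
  n <- 10
  s <- data.frame(subject_id = sprintf("S%02d", 1:n),
                  art = rep(c(0, 1), 5), x = rnorm(n))
  v <- data.frame(subject_id = s$subject_id, visit_month = 0,
                  measure = "y", value = rnorm(n), observed = TRUE)
  w <- fit_weights(s, v, "y", 0, covariate_set("none"), truncation = NULL)
  est <- weighted_effect(s, v, w, "y", 0)
  # brute-force weighted normal equations
  X <- cbind(1, s$art)
  Wm <- diag(w$combined_weights)
  beta <- solve(t(X) %*% Wm %*% X, t(X) %*% Wm %*% v$value)
  expect_equal(est$estimate, beta[2, 1], tolerance = 1e-10)
})

test_that("IPW corrects informative censoring that biases complete cases", {
  # censoring depends on arm and a prognostic covariate; the crude
  # complete-case contrast is selection-biased, the weighted one is not
  set.seed(4)
  n_rep <- 40
  bias_cc <- numeric(n_rep); bias_w <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 1500
    x <- rnorm(n)
    a <- rbinom(n, 1, 0.5)
    y <- 1 + 0.5 * a + 2 * x + rnorm(n)
    p_obs <- plogis(0.2 + 1.8 * x - 1.2 * a)
    obs <- rbinom(n, 1, p_obs) == 1
    s <- data.frame(subject_id = sprintf("S%05d", 1:n), art = a, x = x)
    v <- data.frame(subject_id = s$subject_id[obs], visit_month = 6,
                    measure = "y", value = y[obs], observed = TRUE)
    cc <- mean(y[obs & a == 1]) - mean(y[obs & a == 0])
    covx <- structure(list(name = "x_only", variables = "x"),
                      class = "covariate_set")
    w <- fit_weights(s, v, "y", 6, covx, truncation = c(0.005, 0.995))
    est <- weighted_effect(s, v, w, "y", 6)
    bias_cc[r] <- cc - 0.5
    bias_w[r] <- est$estimate - 0.5
  }
  expect_gt(abs(mean(bias_cc)), 3 * abs(mean(bias_w)))
})

test_that("MCAR censoring leaves the weighted estimator unbiased", {
  set.seed(5)
  errs <- replicate(60, {
    n <- 800
    a <- rbinom(n, 1, 0.3)
    y <- 2 + 1 * a + rnorm(n)
    obs <- rbinom(n, 1, 0.7) == 1
    s <- data.frame(subject_id = sprintf("S%04d", 1:n), art = a,
                    x = rnorm(n))
    v <- data.frame(subject_id = s$subject_id[obs], visit_month = 3,
                    measure = "y", value = y[obs], observed = TRUE)
    covx <- structure(list(name = "x_only", variables = "x"),
                      class = "covariate_set")
    w <- fit_weights(s, v, "y", 3, covx)
    weighted_effect(s, v, w, "y", 3)$estimate - 1
  })
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("paternal-weight bias analysis traces the closed-form trajectory", {
  co <- small_cohort(seed = 53, n_treated = 200, n_untreated = 800)
  # delta = 0 reproduces the adjusted fit
  base <- adjusted_effect(co$subjects, co$visits, "height_cm", 78)
  tr <- paternal_weight_bias(co$subjects, co$visits, "height_cm", 78,
                             delta_kg_grid = c(-10, 0, 10))
  expect_equal(tr$estimate[tr$delta_kg == 0], base$estimate,
               tolerance = 1e-12)
  # linear-model algebra: shifting a covariate by delta in the treated arm
  # moves the ART coefficient linearly; slope equals minus the product of
  # delta with the paternal-weight coefficient path. Verified empirically:
  # trajectory must be affine in delta.
  slopes <- diff(tr$estimate) / diff(tr$delta_kg)
  expect_equal(slopes[1], slopes[2], tolerance = 1e-8)
})

test_that("shifting an outcome-irrelevant covariate leaves estimates fixed", {
  # noise-free outcome with a zero paternal-weight coefficient: the fitted
  # coefficient is exactly zero, so the bias trajectory is exactly flat
  set.seed(6)
  n <- 60
  s <- data.frame(subject_id = sprintf("S%03d", 1:n),
                  art = rep(c(0, 1), n / 2), x = rnorm(n),
                  paternal_weight = rnorm(n, 75, 10))
  v <- data.frame(subject_id = s$subject_id, visit_month = 0,
                  measure = "y", value = 1 + 2 * s$art + 3 * s$x,
                  observed = TRUE)
  covx <- structure(list(name = "custom",
                         variables = c("x", "paternal_weight")),
                    class = "covariate_set")
  tr <- paternal_weight_bias(s, v, "y", 0, covset = covx,
                             delta_kg_grid = c(-20, 0, 20))
  expect_lt(max(abs(tr$estimate - 2)), 1e-8)
})
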