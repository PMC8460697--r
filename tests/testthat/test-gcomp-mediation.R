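test_that("structural fits recover the generating coefficients", {
  co <- small_cohort(seed = 71, n_treated = 600, n_untreated = 3400)
  s <- with_outcome(co, visit = 78)
  fit <- fit_structural_system(s, "cpg_cg03904042", "..y")
  b <- co$truth$path_coefs
  # treatment coefficients of each equation, with model-based SEs
  checks <- list(
    c("FG", "art", "beta1"), c("SBP_preg", "art", "beta2"),
    c("SBP_preg", "FG", "beta3"), c("GA", "art", "beta4"),
    c("cpg_cg03904042", "art", "beta7"), c("..y", "art", "beta11"),
    c("..y", "cpg_cg03904042", "beta15")
  )
  d <- fit$data
  for (ch in checks) {
    eq <- fit$equations[[ch[1]]]
    est <- eq$coef[[ch[2]]]
    # conservative SE proxy: residual sd over sqrt(n)
    se <- 6 * eq$sigma / sqrt(fit$n)
    expect_lt(abs(est - b[[ch[3]]]), 2 * max(se, 0.05))
  }
  expect_error(
    fit_structural_system(transform(s, art = 1), "cpg_cg03904042", "..y"),
    "constant")
})

test_that("g-computation equals the closed-form path sums to 1e-10", {
  co <- small_cohort(seed = 72, n_treated = 300, n_untreated = 1700)
  s <- with_outcome(co, visit = 78)
  fit <- fit_structural_system(s, "cpg_cg03904042", "..y")
  # independent oracle: path-tracing on the fitted coefficients
  cf <- function(eq, nm) fit$equations[[eq]]$coef[[nm]]
  b1 <- cf("FG", "art")
  b2 <- cf("SBP_preg", "art"); b3 <- cf("SBP_preg", "FG")
  b4 <- cf("GA", "art"); b5 <- cf("GA", "FG"); b6 <- cf("GA", "SBP_preg")
  b7 <- cf("cpg_cg03904042", "art"); b8 <- cf("cpg_cg03904042", "FG")
  b9 <- cf("cpg_cg03904042", "SBP_preg"); b10 <- cf("cpg_cg03904042", "GA")
  b11 <- cf("..y", "art"); b12 <- cf("..y", "FG")
  b13 <- cf("..y", "SBP_preg"); b14 <- cf("..y", "GA")
  b15 <- cf("..y", "cpg_cg03904042")
  dFG <- b1; dSBP <- b2 + b3 * b1; dGA <- b4 + b5 * dFG + b6 * dSBP
  nie_oracle <- b15 * (b7 + b8 * b1 + b9 * (b2 + b3 * b1) +
                         b10 * (b4 + b5 * b1 + b6 * (b2 + b3 * b1)))
  te_oracle <- b11 + b12 * dFG + b13 * dSBP + b14 * dGA + nie_oracle
  res <- gcompute_effects(fit, n_boot = 10, seed = 1)
  expect_equal(res$nie, nie_oracle, tolerance = 1e-10)
  expect_equal(res$te, te_oracle, tolerance = 1e-10)
  expect_equal(res$te, res$nde + res$nie, tolerance = 1e-12)
})

test_that("a severed methylation path gives exactly zero indirect effect", {
  # all inputs to the CpG zeroed in a hand-built linear dataset
  set.seed(73)
  n <- 400
  conf <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
  art <- rbinom(n, 1, 0.3)
  d <- data.frame(art = art, c1 = conf[, 1], c2 = conf[, 2])
  d$FG <- 0.2 * art + 0.1 * d$c1 + rnorm(n, 0, 0.3)
  d$SBP_preg <- 1.1 * art + 0.5 * d$FG + rnorm(n)
  d$GA <- -0.4 * art + rnorm(n, 38, 1)
  d$cpg <- rnorm(n) # no path in
  d$..y <- -1.5 * art - 0.2 * d$FG + 0.3 * d$GA + 0.8 * d$cpg + rnorm(n)
  fit <- fit_structural_system(d, "cpg", "..y", confounders = c("c1", "c2"))
  # force the fitted CpG equation's causal inputs to zero
  fit$equations$cpg$coef[c("art", "FG", "SBP_preg", "GA")] <- 0
  res <- gcompute_effects(fit, n_boot = 5, seed = 2)
  expect_equal(res$nie, 0, tolerance = 1e-12)
  expect_equal(res$te, res$nde, tolerance = 1e-12)
})

test_that("the printed proportion-mediated arithmetic reproduces", {
  expect_equal(round(prop_mediated(-0.17, -2.2), 1), 7.7)
  expect_equal(round(prop_mediated(-0.14, -2.9), 1), 4.8)
})

test_that("bootstrap inference recovers the generator's mediation truth", {
  b <- default_path_coefs()
  co <- small_cohort(seed = 74, n_treated = 500, n_untreated = 2500,
                     true_path_coefs = b)
  s <- with_outcome(co, visit = 78)
  fit <- fit_structural_system(s, "cpg_cg03904042", "..y")
  res <- gcompute_effects(fit, n_boot = 100, seed = 3)
  truth <- oracle_paths(b)
  expect_lt(abs(res$te - truth[["te"]]), 2 * res$te_se)
  expect_lt(abs(res$nde - truth[["nde"]]), 2 * res$nde_se)
  expect_lt(abs(res$nie - truth[["nie"]]), 2 * res$nie_se)
  expect_gt(res$n_boot, 2)
})

test_that("residual-draw propagation agrees with mean propagation on average", {
  co <- small_cohort(seed = 75, n_treated = 300, n_untreated = 1700)
  s <- with_outcome(co, visit = 78)
  fit <- fit_structural_system(s, "cpg_cg03904042", "..y")
  mean_prop <- gcompute_effects(fit, n_boot = 5, seed = 4)
  draws <- vapply(1:20, function(r) {
    gcompute_effects(fit, n_boot = 2, seed = 100 + r,
                     draw_residuals = TRUE)$te
  }, numeric(1))
  expect_lt(abs(mean(draws) - mean_prop$te), 3 * sd(draws) / sqrt(20))
})

test_that("the negative control is null when maternal methylation is inert", {
  hits <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    co <- small_cohort(seed = 7000 + r, n_treated = 150, n_untreated = 850)
    s <- with_outcome(co, visit = 78)
    res <- negative_control_mediation(s, "cpgm_cg03904042", "..y",
                                      n_boot = 40, seed = r)
    hits <- hits + (abs(res$nie) < 2 * res$nie_se)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("a planted unmeasured confounder is flagged by the negative control", {
  nies <- vapply(1:10, function(r) {
    co <- small_cohort(seed = 7100 + r, n_treated = 300, n_untreated = 1700,
                       positivity_bounds = c(0, 1),
                       unmeasured_confounder = list(sd = 1,
                                                    on_treatment = 1.5,
                                                    on_maternal_cpg = 1,
                                                    on_outcome = 2))
    s <- with_outcome(co, visit = 78)
    res <- negative_control_mediation(s, "cpgm_cg03904042", "..y",
                                      n_boot = 40, seed = r)
    res$nie / res$nie_se
  }, numeric(1))
  expect_gt(mean(abs(nies)), 3)
})

test_that("equation reordering under a null system leaves the TE unchanged", {
  b0 <- default_path_coefs() * 0
  co <- small_cohort(seed = 76, n_treated = 200, n_untreated = 800,
                     true_path_coefs = b0)
  s <- with_outcome(co, visit = 78)
  f1 <- fit_structural_system(s, "cpgm_cg03904042", "..y",
                              ordering = "fetal_cpg_last_mediator")
  f2 <- fit_structural_system(s, "cpgm_cg03904042", "..y",
                              ordering = "maternal_cpg_first_mediator")
  # same single-equation OLS fits, reordered: identical total path effect
  expect_equal(linear_path_effects(f1)[["te"]],
               linear_path_effects(f2)[["te"]], tolerance = 1e-10)
})

test_that("per-visit mediation matches single calls and respects subcohorts", {
  co <- small_cohort(seed = 77, n_treated = 200, n_untreated = 1300)
  med <- mediation_over_visits(co$subjects, co$visits, "cpg_cg03904042",
                               "height_cm", c(36, 78), n_boot = 20, seed = 5)
  expect_equal(nrow(med), 2)
  expect_equal(med$visit_month, c(36, 78))
  # single-visit call equals the corresponding row
  one <- mediation_over_visits(co$subjects, co$visits, "cpg_cg03904042",
                               "height_cm", 78, n_boot = 20, seed = 5)
  expect_equal(one$te, med$te[med$visit_month == 78], tolerance = 1e-12)
  expect_equal(one$nie, med$nie[med$visit_month == 78], tolerance = 1e-12)
  # effects grow with the visit multiplier
  expect_gt(abs(med$te[2]), abs(med$te[1]))
  # subcohort restriction on an exchangeable population moves estimates < 2 SE
  sub <- mediation_over_visits(co$subjects, co$visits, "cpg_cg03904042",
                               "height_cm", 78,
                               rule = arm_rule("subfertile_plus_paternal"),
                               n_boot = 20, seed = 5)
  expect_lt(abs(sub$te - one$te), 2 * sub$te_se)
})

test_that("bootstrap SEs are stable in replicate count on a fixed fit", {
  co <- small_cohort(seed = 78, n_treated = 300, n_untreated = 1200)
  s <- with_outcome(co, visit = 78)
  fit <- fit_structural_system(s, "cpg_cg03904042", "..y")
  se100 <- gcompute_effects(fit, n_boot = 100, seed = 6)$nie_se
  se400 <- gcompute_effects(fit, n_boot = 400, seed = 7)$nie_se
  expect_lt(abs(se100 - se400) / se400, 0.25)
  expect_error(gcompute_effects(fit, n_boot = 1), "n_boot")
})
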