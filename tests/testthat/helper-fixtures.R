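# small cohorts reused across tests; built once per test run
small_cohort <- function(seed = 11, n_treated = 150, n_untreated = 850,
                         missing_model = NULL, ...) {
  generate_cohort(generator_config(seed = seed, n_treated = n_treated,
                                   n_untreated = n_untreated,
                                   missing_model = missing_model, ...))
}

# subject table augmented with ethnicity dummies and the outcome at a visit
with_outcome <- function(cohort, outcome = "height_cm", visit = 78) {
  s <- cohort$subjects
  cm <- confounder_matrix(s)
  s <- cbind(s, cm[, setdiff(colnames(cm), names(s)), drop = FALSE])
  s$..y <- artgrowth:::outcome_at_visit(s, cohort$visits, outcome, visit)
  s
}

# closed-form counterfactual contrasts from generating coefficients;
# independent of the package's propagation code
oracle_paths <- function(b) {
  dFG <- b[["beta1"]]
  dSBP <- b[["beta2"]] + b[["beta3"]] * dFG
  dGA <- b[["beta4"]] + b[["beta5"]] * dFG + b[["beta6"]] * dSBP
  dCPG <- b[["beta7"]] + b[["beta8"]] * dFG + b[["beta9"]] * dSBP +
    b[["beta10"]] * dGA
  nde <- b[["beta11"]] + b[["beta12"]] * dFG + b[["beta13"]] * dSBP +
    b[["beta14"]] * dGA
  nie <- b[["beta15"]] * dCPG
  c(te = nde + nie, nde = nde, nie = nie, dCPG = dCPG)
}
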