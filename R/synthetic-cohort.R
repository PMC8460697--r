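#' Default structural path coefficients
#'
#' The generating causal system is a recursive set of linear equations:
#' maternal fasting glucose (FG), pregnancy systolic blood pressure (SBP),
#' gestational age at delivery (GA), fetal methylation residual at the causal
#' CpG (CPG), and the child outcome (Y), each depending on ART status, the
#' upstream variables, and confounders:
#' \preformatted{
#'   FG  = b1*ART + G1*C + a1 + e1
#'   SBP = b2*ART + b3*FG + G2*C + a2 + e2
#'   GA  = b4*ART + b5*FG + b6*SBP + G3*C + a3 + e3
#'   CPG = b7*ART + b8*FG + b9*SBP + b10*GA + G4*C + a4 + e4
#'   Y   = b11*ART + b12*FG + b13*SBP + b14*GA + b15*CPG + G5*C + a5 + e5
#' }
#'
#' @return Named numeric vector beta1..beta15.
#' @export
default_path_coefs <- function() {
  c(beta1 = 0.10, beta2 = 1.50, beta3 = 2.00,
    beta4 = -0.50, beta5 = -0.20, beta6 = -0.02,
    beta7 = -0.30, beta8 = 0.10, beta9 = 0.005, beta10 = 0.05,
    beta11 = -2.00, beta12 = -0.30, beta13 = -0.02, beta14 = 0.50,
    beta15 = 0.50)
}

#' Confounder columns of the structural system
#'
#' Ordered confounder set shared by all structural equations and effect
#' models (ethnicity coded as dummy indicators).
#' @export
STRUCTURAL_CONFOUNDERS <- c(
  "maternal_age", "education", "ethnicity_malay", "ethnicity_indian",
  "parity", "maternal_height", "ppBMI", "smoke_home", "income",
  "paternal_height", "paternal_weight", "child_sex", "prs"
)

#' Numeric confounder design matrix for a subject table
#'
#' Expands ethnicity into dummy indicators and returns the fixed ordered set
#' of confounder columns used throughout the structural system and the
#' effect models.
#'
#' @param subjects Subject data.frame (see [generate_cohort()]).
#' @return Numeric matrix, one row per subject.
#' @export
confounder_matrix <- function(subjects) {
  m <- cbind(
    maternal_age = subjects$maternal_age,
    education = subjects$education,
    ethnicity_malay = as.numeric(subjects$ethnicity == "malay"),
    ethnicity_indian = as.numeric(subjects$ethnicity == "indian"),
    parity = subjects$parity,
    maternal_height = subjects$maternal_height,
    ppBMI = subjects$ppBMI,
    smoke_home = subjects$smoke_home,
    income = subjects$income,
    paternal_height = subjects$paternal_height,
    paternal_weight = subjects$paternal_weight,
    child_sex = subjects$child_sex,
    prs = subjects$prs
  )
  m
}

default_gammas <- function() {
  zero <- stats::setNames(numeric(length(STRUCTURAL_CONFOUNDERS)),
                          STRUCTURAL_CONFOUNDERS)
  g <- list(G1 = zero, G2 = zero, G3 = zero, G4 = zero, G5 = zero)
  g$G1[c("ppBMI", "maternal_age")] <- c(0.025, 0.005)
  g$G2[c("ppBMI", "maternal_age")] <- c(0.35, 0.08)
  g$G3[c("parity", "smoke_home")] <- c(0.10, -0.20)
  g$G4[c("prs", "smoke_home")] <- c(0.05, 0.10)
  g$G5[c("maternal_height", "paternal_height", "child_sex", "prs", "ppBMI")] <-
    c(0.25, 0.20, 1.20, 0.40, 0.05)
  g
}

# theoretical confounder means implied by the default marginals; used to
# center the outcome equation's intercept at the reference growth curve
default_confounder_means <- function() {
  c(maternal_age = 31, education = 3.5, ethnicity_malay = 0.27,
    ethnicity_indian = 0.18, parity = 0.8, maternal_height = 158,
    ppBMI = 22.7, smoke_home = 0.3, income = 3.3, paternal_height = 171,
    paternal_weight = 75.4, child_sex = 0.5, prs = 0)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the scale and structure of a two-arm prospective birth
#' cohort: ~83 ART-conceived and ~1154 spontaneously conceived triads,
#' confounded treatment assignment on sociodemographics and parity, maternal
#' subfertility indication flags, pregnancy mediators, standardized fetal and
#' maternal CpG methylation residuals, and 16 scheduled anthropometry visits
#' from birth to 78 months with MAR covariate missingness and monotone
#' dropout.
#'
#' @param n_treated Expected treated (ART) count.
#' @param n_untreated Expected untreated count.
#' @param seed Integer RNG seed; one shared stream is used in the fixed order
#'   confounders, treatment, indication flags, mediators, CpGs, outcomes,
#'   missingness.
#' @param true_path_coefs Named vector beta1..beta15 (see
#'   [default_path_coefs()]).
#' @param gammas List G1..G5 of named confounder coefficient vectors.
#' @param noise_sds Residual SDs per equation (FG, SBP, GA, CPG) and per
#'   outcome measure.
#' @param treatment_model Named logistic coefficients on confounder columns;
#'   the intercept is calibrated so the mean assignment probability equals
#'   n_treated / (n_treated + n_untreated).
#' @param visit_schedule Ordered months of the visit schedule.
#' @param visit_multiplier Function month -> multiplier applied to the
#'   treatment/mediator structural block of the outcome, so ART effects grow
#'   with age; the default ramps linearly from 0.25 at birth to 1 at the last
#'   visit.
#' @param cpg_ids CpG identifiers to simulate; the first is the causal site
#'   carrying the beta7..beta10 inputs and the beta15 outcome path, the rest
#'   are null sites.
#' @param maternal_cpg_effects Optional list with elements `on_cpg` (ART
#'   effect on maternal CpG) and `on_outcome` (direct maternal CpG to outcome
#'   coefficient); both default 0, the negative-control null.
#' @param unmeasured_confounder Optional list `list(sd=, on_treatment=,
#'   on_maternal_cpg=, on_outcome=)` planting a latent parental trait that
#'   raises the odds of ART conception and shifts maternal methylation and
#'   the child outcome — the unmeasured-confounding scenario the negative
#'   control is designed to flag; defaults to all zero.
#' @param missing_model NULL for fully observed data, or a list with
#'   `covariate` (named list: variable -> named logistic coefficients over
#'   `(intercept, art, education)`) and `dropout` (named coefficients over
#'   `(intercept, art, smoke_home)` for the per-visit dropout hazard after
#'   birth).
#' @param positivity_bounds Admissible range for assignment probabilities.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_treated = 83,
                             n_untreated = 1154,
                             seed = 1L,
                             true_path_coefs = default_path_coefs(),
                             gammas = default_gammas(),
                             noise_sds = c(FG = 0.40, SBP = 8, GA = 1.4,
                                           CPG = 1, height_cm = 2.2,
                                           weight_kg = 1.1, sbp = 7),
                             treatment_model = c(maternal_age = 0.06,
                                                 education = 0.25,
                                                 income = 0.15,
                                                 smoke_home = -0.50,
                                                 parity = -1.00,
                                                 ppBMI = -0.02),
                             visit_schedule = c(0, 1, 3, 6, 9, 12, 15, 18, 24,
                                                36, 48, 54, 60, 66, 72, 78),
                             visit_multiplier = NULL,
                             cpg_ids = c("cg03904042", "cg27431396",
                                         "cg27146050", "cg00000101",
                                         "cg00000202", "cg00000303"),
                             maternal_cpg_effects = list(on_cpg = 0,
                                                         on_outcome = 0),
                             unmeasured_confounder = list(sd = 0,
                                                          on_treatment = 0,
                                                          on_maternal_cpg = 0,
                                                          on_outcome = 0),
                             missing_model = default_missing_model(),
                             positivity_bounds = c(1e-5, 0.8)) {
  if (n_treated < 1) stop("generator_config: n_treated must be >= 1")
  if (any(noise_sds <= 0)) stop("generator_config: all residual SDs must be > 0")
  if (is.unsorted(visit_schedule, strictly = TRUE)) {
    stop("generator_config: visit_schedule must be strictly increasing")
  }
  if (is.null(visit_multiplier)) {
    last <- max(visit_schedule)
    visit_multiplier <- function(month) 0.25 + 0.75 * month / last
  }
  cfg <- list(n_treated = n_treated, n_untreated = n_untreated,
              seed = as.integer(seed), true_path_coefs = true_path_coefs,
              gammas = gammas, noise_sds = noise_sds,
              treatment_model = treatment_model,
              visit_schedule = visit_schedule,
              visit_multiplier = visit_multiplier,
              cpg_ids = cpg_ids,
              maternal_cpg_effects = maternal_cpg_effects,
              unmeasured_confounder = unmeasured_confounder,
              missing_model = missing_model,
              positivity_bounds = positivity_bounds)
  class(cfg) <- "generator_config"
  cfg
}

#' Default MAR missingness model
#'
#' Paternal anthropometry is the most incomplete block (roughly a third
#' missing), followed by pre-pregnancy BMI and income; dropout after birth is
#' a small per-visit hazard, higher with household smoke exposure.
#' @return Missingness model list (see [generator_config()]).
#' @export
default_missing_model <- function() {
  list(
    covariate = list(
      paternal_height = c(intercept = -0.8, art = -0.4, education = 0.05),
      paternal_weight = c(intercept = -0.8, art = -0.4, education = 0.05),
      paternal_age    = c(intercept = -1.0, art = -0.4, education = 0.05),
      ppBMI           = c(intercept = -2.3, art = -0.3, education = 0),
      income          = c(intercept = -2.7, art = 0, education = 0),
      FG              = c(intercept = -3.0, art = 0, education = 0)
    ),
    dropout = c(intercept = -3.3, art = -0.4, smoke_home = 0.4)
  )
}

# closed-form counterfactual contrasts of the all-linear system
path_sums <- function(b) {
  dFG <- b[["beta1"]]
  dSBP <- b[["beta2"]] + b[["beta3"]] * dFG
  dGA <- b[["beta4"]] + b[["beta5"]] * dFG + b[["beta6"]] * dSBP
  dCPG <- b[["beta7"]] + b[["beta8"]] * dFG + b[["beta9"]] * dSBP +
    b[["beta10"]] * dGA
  nde <- b[["beta11"]] + b[["beta12"]] * dFG + b[["beta13"]] * dSBP +
    b[["beta14"]] * dGA
  nie <- b[["beta15"]] * dCPG
  c(dFG = dFG, dSBP = dSBP, dGA = dGA, dCPG = dCPG,
    te = nde + nie, nde = nde, nie = nie)
}

#' Generate a synthetic two-arm cohort
#'
#' Draws confounders, assigns ART status from a logistic model (intercept
#' calibrated to the configured arm sizes), generates subfertility indication
#' flags, propagates mediators, fetal and maternal CpG residuals and
#' visit-level outcomes through the structural equations with Gaussian
#' residuals, then applies MAR missingness and monotone dropout. Outputs are
#' byte-identical across calls with the same configuration.
#'
#' @param config A [generator_config()].
#' @return List of class `art_cohort` with elements `subjects` (one row per
#'   triad), `visits` (long table: subject_id, visit_month, measure, value,
#'   observed), and `truth` (the generating coefficients, the per-visit
#'   closed-form total/natural direct/natural indirect effects on height, and
#'   the assignment probability range).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_treated + config$n_untreated

  ## 1. confounders
  subjects <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    maternal_age = stats::rnorm(n, 31, 5),
    education = sample(1:5, n, replace = TRUE,
                       prob = c(0.06, 0.26, 0.10, 0.25, 0.33)),
    ethnicity = sample(c("chinese", "malay", "indian"), n, replace = TRUE,
                       prob = c(0.55, 0.27, 0.18)),
    income = sample(1:5, n, replace = TRUE,
                    prob = c(0.03, 0.14, 0.31, 0.25, 0.27)),
    maternal_height = stats::rnorm(n, 158, 5.6),
    ppBMI = pmax(stats::rnorm(n, 22.7, 4.4), 14),
    parity = stats::rpois(n, 0.8),
    smoke_home = stats::rbinom(n, 1, 0.3),
    paternal_age = stats::rnorm(n, 34.5, 5.9),
    paternal_height = stats::rnorm(n, 171, 6.2),
    paternal_weight = pmax(stats::rnorm(n, 75.4, 14.3), 40),
    paternal_diabetes = stats::rbinom(n, 1, 0.025),
    paternal_htn = stats::rbinom(n, 1, 0.09),
    child_sex = stats::rbinom(n, 1, 0.5),
    prs = stats::rnorm(n, 0, 1),
    stringsAsFactors = FALSE
  )
  C <- confounder_matrix(subjects)
  uc <- config$unmeasured_confounder
  if (is.null(uc$on_treatment)) uc$on_treatment <- 0
  U <- if (uc$sd > 0) stats::rnorm(n, 0, uc$sd) else numeric(n)

  ## 2. treatment: logistic on confounders, intercept calibrated to arm sizes
  tm <- config$treatment_model
  lp <- as.vector(C[, names(tm), drop = FALSE] %*% tm) + uc$on_treatment * U
  target <- config$n_treated / n
  intercept <- stats::uniroot(
    function(b0) mean(stats::plogis(b0 + lp)) - target,
    interval = c(-30, 30), tol = 1e-10
  )$root
  pscore <- stats::plogis(intercept + lp)
  if (min(pscore) < config$positivity_bounds[1] ||
      max(pscore) > config$positivity_bounds[2]) {
    stop("generate_cohort: assignment probabilities violate positivity bounds [",
         paste(signif(config$positivity_bounds, 3), collapse = ", "), "]")
  }
  art <- stats::rbinom(n, 1, pscore)
  subjects$art <- art
  subjects$arm <- ifelse(art == 1, "treated", "untreated")
  subjects$pscore <- pscore

  ## 3. subfertility indication and paternal risk flags
  flag_base <- c(miscarriages_gt1 = 0.025, pcos = 0.020, fibroids = 0.015,
                 ovarian_cysts = 0.015, thyroid = 0.015, fertility_meds = 0.020)
  for (f in names(flag_base)) {
    p <- stats::plogis(stats::qlogis(flag_base[[f]]) + 2.2 * art)
    subjects[[paste0("flag_", f)]] <- stats::rbinom(n, 1, p)
  }
  pat_bmi <- subjects$paternal_weight / (subjects$paternal_height / 100)^2
  subjects$flag_pat_age_gt40 <- as.integer(subjects$paternal_age > 40)
  subjects$flag_pat_bmi_gt35 <- as.integer(pat_bmi > 35)
  subjects$flag_pat_diabetes <- subjects$paternal_diabetes
  subjects$flag_pat_htn <- subjects$paternal_htn
  for (f in c("excl_gt14wk", "excl_chemo", "excl_psychotropic",
              "excl_t1dm", "excl_multiple_gestation")) {
    subjects[[f]] <- 0L
  }

  ## 4. mediators through the structural chain
  b <- config$true_path_coefs
  g <- config$gammas
  sds <- config$noise_sds
  mu <- default_confounder_means()
  gc <- function(G) as.vector(C %*% G[STRUCTURAL_CONFOUNDERS])
  a1 <- 4.35 - sum(g$G1 * mu)
  FG <- b[["beta1"]] * art + gc(g$G1) + a1 + stats::rnorm(n, 0, sds[["FG"]])
  FG <- pmax(FG, 0.5)
  a2 <- 110 - b[["beta3"]] * 4.35 - sum(g$G2 * mu)
  SBP <- b[["beta2"]] * art + b[["beta3"]] * FG + gc(g$G2) + a2 +
    stats::rnorm(n, 0, sds[["SBP"]])
  a3 <- 38.5 - b[["beta5"]] * 4.35 - b[["beta6"]] * 110 - sum(g$G3 * mu)
  GA <- b[["beta4"]] * art + b[["beta5"]] * FG + b[["beta6"]] * SBP +
    gc(g$G3) + a3 + stats::rnorm(n, 0, sds[["GA"]])
  GA <- pmin(pmax(GA, 21), 44.5)
  subjects$FG <- FG
  subjects$OGTT2h <- pmax(1.4 * FG + 0.4 * art +
                            stats::rnorm(n, 0.5, 1.0), 2)
  subjects$SBP_preg <- SBP
  subjects$GA <- GA

  ## 5. CpG residuals: first id is the causal site, the rest null
  a4 <- -(b[["beta8"]] * 4.35 + b[["beta9"]] * 110 + b[["beta10"]] * 38.5) -
    sum(g$G4 * mu)
  for (i in seq_along(config$cpg_ids)) {
    id <- config$cpg_ids[i]
    if (i == 1) {
      val <- b[["beta7"]] * art + b[["beta8"]] * FG + b[["beta9"]] * SBP +
        b[["beta10"]] * GA + gc(g$G4) + a4 + stats::rnorm(n, 0, sds[["CPG"]])
    } else {
      val <- stats::rnorm(n, 0, sds[["CPG"]])
    }
    subjects[[paste0("cpg_", id)]] <- val
  }
  mce <- config$maternal_cpg_effects
  for (i in seq_along(config$cpg_ids)) {
    id <- config$cpg_ids[i]
    shift <- if (i == 1) mce$on_cpg * art + uc$on_maternal_cpg * U else 0
    subjects[[paste0("cpgm_", id)]] <- shift + stats::rnorm(n, 0, sds[["CPG"]])
  }
  cpg_causal <- subjects[[paste0("cpg_", config$cpg_ids[1])]]
  cpgm_causal <- subjects[[paste0("cpgm_", config$cpg_ids[1])]]

  ## 6. visit-level outcomes
  months <- config$visit_schedule
  struct_block <- b[["beta11"]] * art + b[["beta12"]] * FG +
    b[["beta13"]] * SBP + b[["beta14"]] * GA + b[["beta15"]] * cpg_causal +
    mce$on_outcome * cpgm_causal + uc$on_outcome * U
  struct_center <- b[["beta12"]] * 4.35 + b[["beta13"]] * 110 +
    b[["beta14"]] * 38.5
  g5 <- gc(g$G5)
  g5_center <- sum(g$G5 * mu)
  baselines <- list(
    height_cm = function(m) 50 + 42 * log1p(m / 12),
    weight_kg = function(m) 3.3 + 7.2 * log1p(m / 12),
    sbp = function(m) 92 + 1.2 * (m / 12)
  )
  scales <- c(height_cm = 1, weight_kg = 0.15, sbp = 0.5)
  visit_list <- vector("list", length(months) * length(baselines))
  k <- 0
  for (mm in months) {
    mult <- config$visit_multiplier(mm)
    for (meas in names(baselines)) {
      k <- k + 1
      sc <- scales[[meas]]
      val <- baselines[[meas]](mm) +
        sc * (mult * (struct_block - struct_center) + (g5 - g5_center)) +
        stats::rnorm(n, 0, sds[[meas]])
      visit_list[[k]] <- data.frame(subject_id = subjects$subject_id,
                                    visit_month = mm, measure = meas,
                                    value = val, observed = TRUE,
                                    stringsAsFactors = FALSE)
    }
  }
  visits <- do.call(rbind, visit_list)
  # BMI derived from the generated height and weight at the same visit
  h <- visits[visits$measure == "height_cm", ]
  w <- visits[visits$measure == "weight_kg", ]
  bmi <- h
  bmi$measure <- "bmi"
  bmi$value <- w$value / (h$value / 100)^2
  visits <- rbind(visits, bmi)
  visits <- visits[order(visits$subject_id, visits$visit_month,
                         visits$measure), ]
  rownames(visits) <- NULL

  ## 7. missingness last
  out <- inject_missingness(subjects, visits, config$missing_model,
                            seed = NULL)

  eff <- do.call(rbind, lapply(months, function(mm) {
    mult <- config$visit_multiplier(mm)
    ps <- path_sums(b) # mediator contrasts are unscaled; outcome block scales
    data.frame(visit_month = mm, multiplier = mult,
               te_height = mult * ps[["te"]],
               nde_height = mult * ps[["nde"]],
               nie_height = mult * ps[["nie"]])
  }))
  structure(list(subjects = out$subjects, visits = out$visits,
                 truth = list(path_coefs = b, gammas = g,
                              noise_sds = sds, seed = config$seed,
                              effects_by_visit = eff,
                              pscore_range = range(pscore),
                              causal_cpg = config$cpg_ids[1])),
            class = "art_cohort")
}

#' Apply MAR covariate missingness and monotone visit dropout
#'
#' Covariate missingness is drawn from per-variable logistic models on ART
#' status and maternal education (missing at random given observables); visit
#' dropout is a per-visit hazard after birth, and once a subject drops out
#' all later visits are unobserved. Values are never deleted silently: visit
#' rows keep their `observed` indicator and masked values become NA.
#'
#' @param subjects,visits Tables as produced by [generate_cohort()].
#' @param missing_model See [generator_config()]; NULL is a no-op.
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @return List with modified `subjects` and `visits`.
#' @export
inject_missingness <- function(subjects, visits, missing_model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(missing_model)) {
    return(list(subjects = subjects, visits = visits))
  }
  n <- nrow(subjects)
  art <- subjects$art
  edu <- subjects$education
  for (v in names(missing_model$covariate)) {
    cf <- missing_model$covariate[[v]]
    p <- stats::plogis(cf[["intercept"]] + cf[["art"]] * art +
                         cf[["education"]] * edu)
    miss <- stats::rbinom(n, 1, p) == 1
    subjects[[v]][miss] <- NA
  }
  dz <- missing_model$dropout
  hazard <- stats::plogis(dz[["intercept"]] + dz[["art"]] * art +
                            dz[["smoke_home"]] * subjects$smoke_home)
  months <- sort(unique(visits$visit_month))
  # monotone dropout: geometric first-failure over post-birth visits
  n_after <- length(months) - 1
  dropped_at <- rep(Inf, n)
  if (n_after > 0) {
    for (j in seq_len(n_after)) {
      at_risk <- is.infinite(dropped_at)
      drop_now <- at_risk & (stats::runif(n) < hazard)
      dropped_at[drop_now] <- months[j + 1]
    }
  }
  drop_map <- dropped_at[match(visits$subject_id, subjects$subject_id)]
  masked <- visits$visit_month >= drop_map
  visits$observed <- visits$observed & !masked
  visits$value[!visits$observed] <- NA
  list(subjects = subjects, visits = visits)
}

#' Write a cohort to delimited text plus a metadata sidecar
#'
#' @param cohort An `art_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly. Writes subjects.csv, visits.csv and
#'   metadata.json (generating coefficients and per-visit true effects).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  meta <- cohort$truth
  meta$path_coefs <- as.list(meta$path_coefs)
  meta$noise_sds <- as.list(meta$noise_sds)
  meta$gammas <- lapply(meta$gammas, as.list)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing subjects.csv and visits.csv.
#' @return An `art_cohort` (truth is restored from metadata.json if present).
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE)
  meta_path <- file.path(dir, "metadata.json")
  truth <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  structure(list(subjects = subjects, visits = visits, truth = truth),
            class = "art_cohort")
}
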