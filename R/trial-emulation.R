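#' Comparison-arm rule
#'
#' The emulated trial compares ART-conceived children against untreated
#' (spontaneously conceived) children selected by a priori indications:
#' \itemize{
#'   \item `primary_subfertile`: any maternal subfertility indication
#'     (>1 previous miscarriage, PCOS, uterine fibroids, ovarian cysts,
#'     thyroid disorder, or fertility/endocrine medication use).
#'   \item `subfertile_plus_paternal`: the above, or any paternal risk factor
#'     (age > 40 at first birth, BMI > 35, diabetes, or hypertension
#'     diagnosis).
#'   \item `paternal_only`: paternal risk factors only.
#'   \item `random_none`: a seeded random draw of subjects with none of the
#'     indications.
#' }
#' Predicates combine disjunctively (any one qualifies).
#'
#' @param name Rule name, one of the four above.
#' @param sample_size Draw size for `random_none` (default 204).
#' @param seed Seed for `random_none` draws.
#' @return An `arm_rule` list with the predicate flag names.
#' @export
arm_rule <- function(name = c("primary_subfertile", "subfertile_plus_paternal",
                              "paternal_only", "random_none"),
                     sample_size = 204, seed = 1L) {
  name <- match.arg(name)
  maternal <- c("flag_miscarriages_gt1", "flag_pcos", "flag_fibroids",
                "flag_ovarian_cysts", "flag_thyroid", "flag_fertility_meds")
  paternal <- c("flag_pat_age_gt40", "flag_pat_bmi_gt35",
                "flag_pat_diabetes", "flag_pat_htn")
  predicates <- switch(name,
    primary_subfertile = maternal,
    subfertile_plus_paternal = c(maternal, paternal),
    paternal_only = paternal,
    random_none = character(0)
  )
  if (name == "random_none" &&
      (is.null(sample_size) || is.null(seed))) {
    stop("arm_rule: random_none requires sample_size and seed")
  }
  structure(list(name = name, predicates = predicates,
                 all_flags = c(maternal, paternal),
                 sample_size = sample_size, seed = as.integer(seed)),
            class = "arm_rule")
}

ELIGIBILITY_FLAGS <- c("excl_gt14wk", "excl_chemo", "excl_psychotropic",
                       "excl_t1dm", "excl_multiple_gestation")

#' Apply trial eligibility exclusions
#'
#' Removes subjects flagged for any exclusion criterion (enrollment past 14
#' weeks gestation, chemotherapy, psychotropic medication, pre-existing
#' type I diabetes, or an ART multiple gestation) and records per-criterion
#' exclusion counts as an attribute `exclusion_log`.
#'
#' @param subjects Subject table carrying the `excl_*` flag columns.
#' @return The retained subjects; `attr(, "exclusion_log")` holds the counts.
#' @export
apply_eligibility <- function(subjects) {
  missing_cols <- setdiff(ELIGIBILITY_FLAGS, names(subjects))
  if (length(missing_cols) > 0) {
    stop("apply_eligibility: missing exclusion flag column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  log <- vapply(ELIGIBILITY_FLAGS,
                function(f) sum(subjects[[f]] == 1, na.rm = TRUE), numeric(1))
  excluded <- Reduce(`|`, lapply(ELIGIBILITY_FLAGS,
                                 function(f) subjects[[f]] == 1))
  kept <- subjects[!excluded, , drop = FALSE]
  attr(kept, "exclusion_log") <- log
  kept
}

#' Treated arm accessor
#' @param subjects Subject table.
#' @return The treated (ART) subjects, unchanged.
#' @export
treated_arm <- function(subjects) {
  subjects[subjects$arm == "treated", , drop = FALSE]
}

#' Build an emulated-trial comparison arm
#'
#' Selects untreated subjects satisfying any of the rule's indication flags
#' (OR semantics). For `random_none`, draws `sample_size` untreated subjects
#' with all indication flags zero, using the rule's seed.
#'
#' @param subjects Subject table with flag columns.
#' @param rule An [arm_rule()].
#' @return The selected untreated subjects.
#' @export
build_comparison_arm <- function(subjects, rule) {
  stopifnot(inherits(rule, "arm_rule"))
  untreated <- subjects[subjects$arm == "untreated", , drop = FALSE]
  if (rule$name == "random_none") {
    none <- Reduce(`&`, lapply(rule$all_flags,
                               function(f) untreated[[f]] == 0))
    pool <- untreated[none, , drop = FALSE]
    if (rule$sample_size > nrow(pool)) {
      stop("build_comparison_arm: random_none requested ", rule$sample_size,
           " subjects but only ", nrow(pool), " have no indications (short by ",
           rule$sample_size - nrow(pool), ")")
    }
    set.seed(rule$seed)
    take <- sample(nrow(pool), rule$sample_size)
    return(pool[sort(take), , drop = FALSE])
  }
  any_flag <- Reduce(`|`, lapply(rule$predicates,
                                 function(f) untreated[[f]] == 1))
  untreated[any_flag, , drop = FALSE]
}

#' Assemble the two-arm analysis table for a rule
#'
#' @param subjects Subject table.
#' @param rule An [arm_rule()], or NULL for the full cohort.
#' @return Treated subjects plus the selected comparison arm.
#' @export
emulated_trial_cohort <- function(subjects, rule = NULL) {
  if (is.null(rule)) return(subjects)
  rbind(treated_arm(subjects), build_comparison_arm(subjects, rule))
}
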