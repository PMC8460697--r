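#' Pipeline run configuration
#'
#' Exactly one of `generator` (a [generator_config()]) or `input_dir` (a
#' directory holding subjects.csv / visits.csv as written by
#' [write_cohort()]) must be supplied.
#'
#' @param generator Optional [generator_config()].
#' @param input_dir Optional cohort directory.
#' @param arm Comparison-arm rule name (see [arm_rule()]) or NULL for the
#'   full cohort.
#' @param covset_name Adjustment set name (see [covariate_set()]).
#' @param outcome Visit measure analyzed (default "height_cm").
#' @param visits Visit months for effect estimation and mediation.
#' @param cpg CpG id for the mediation analysis.
#' @param m_imputations Imputed datasets (default 10).
#' @param n_boot Mediation bootstrap replicates (default 100).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = NULL, input_dir = NULL,
                       arm = "primary_subfertile",
                       covset_name = "pre_pregnancy",
                       outcome = "height_cm",
                       visits = c(36, 72), cpg = "cg03904042",
                       m_imputations = 10, n_boot = 100, seed = 1L,
                       out_dir = tempfile("artgrowth_run_")) {
  if (is.null(generator) == is.null(input_dir)) {
    stop("run_config: supply exactly one of generator or input_dir")
  }
  structure(list(generator = generator, input_dir = input_dir, arm = arm,
                 covset_name = covset_name, outcome = outcome,
                 visits = visits, cpg = cpg,
                 m_imputations = m_imputations, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the end-to-end emulation pipeline
#'
#' Stages, in order: simulate or load the cohort; apply trial eligibility;
#' build the comparison arm; multiply impute covariates; estimate the ART
#' effect per visit by covariate-adjusted regression (Rubin-pooled) and by
#' inverse-probability weighting; scan the candidate CpGs; run the
#' g-computation mediation over visits plus the maternal negative control.
#' All artifacts are delimited text under the output directory; a manifest
#' records seeds, configuration and output files. Reruns with the same
#' configuration reproduce every output.
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  stage <- "simulate/load"
  result <- tryCatch({
    cohort <- if (!is.null(config$generator)) {
      generate_cohort(config$generator)
    } else {
      read_cohort(config$input_dir)
    }
    log_line(logf, "cohort: ", nrow(cohort$subjects), " subjects, ",
             nrow(cohort$visits), " visit rows")

    stage <- "eligibility"
    subjects <- apply_eligibility(cohort$subjects)
    excl <- attr(subjects, "exclusion_log")
    log_line(logf, "eligibility: excluded ", sum(excl), " (",
             paste(names(excl), excl, sep = "=", collapse = ", "), ")")

    stage <- "arm"
    rule <- if (is.null(config$arm)) NULL else {
      arm_rule(config$arm, seed = config$seed)
    }
    analysis <- emulated_trial_cohort(subjects, rule)
    log_line(logf, "arm '", config$arm %||% "full_cohort", "': ",
             sum(analysis$art == 1), " treated vs ",
             sum(analysis$art == 0), " comparison")

    stage <- "impute"
    impute_vars <- intersect(
      c(covariate_set("pre_plus_pregnancy")$variables), names(analysis))
    imps <- chained_impute(analysis, variables = c("art", impute_vars),
                           m = config$m_imputations,
                           seed = config$seed + 1L, n_cycles = 5)
    log_line(logf, "impute: m=", imps$m, " over ",
             sum(vapply(analysis[impute_vars],
                        function(x) any(is.na(x)), logical(1))),
             " incomplete variables")

    stage <- "estimate"
    covset <- covariate_set(config$covset_name)
    est <- do.call(rbind, lapply(config$visits, function(v) {
      adj <- adjusted_effect(analysis, cohort$visits, config$outcome, v,
                             covset, imputations = imps)
      crude <- adjusted_effect(analysis, cohort$visits, config$outcome, v,
                               covariate_set("none"))
      wfit <- fit_weights(analysis, cohort$visits, config$outcome, v, covset)
      ipw <- weighted_effect(analysis, cohort$visits, wfit, config$outcome, v)
      log_line(logf, "estimate month ", v, ": adjusted=",
               round(adj$estimate, 3), " ipw=", round(ipw$estimate, 3),
               " (weights truncated at [",
               paste(round(range(wfit$combined_weights), 2), collapse = ", "),
               "])")
      rbind(crude, adj, ipw)
    }))
    utils::write.csv(est, file.path(config$out_dir, "estimates.csv"),
                     row.names = FALSE)

    stage <- "scan"
    cpg_ids <- sub("^cpg_", "", grep("^cpg_", names(analysis), value = TRUE))
    scan <- candidate_cpg_scan(analysis, cpg_ids)
    utils::write.csv(scan, file.path(config$out_dir, "cpg_scan.csv"),
                     row.names = FALSE)
    log_line(logf, "scan: ", nrow(scan), " CpGs, ",
             sum(scan$passes_bonferroni), " pass Bonferroni at ",
             signif(attr(scan, "bonferroni_threshold"), 3))

    stage <- "mediate"
    med <- mediation_over_visits(subjects, cohort$visits,
                                 paste0("cpg_", config$cpg), config$outcome,
                                 config$visits, rule = rule,
                                 n_boot = config$n_boot,
                                 seed = config$seed + 2L)
    utils::write.csv(med, file.path(config$out_dir, "mediation.csv"),
                     row.names = FALSE)
    nc_data <- emulated_trial_cohort(subjects, rule)
    nc_data <- cbind(nc_data,
                     confounder_matrix(nc_data)[, setdiff(STRUCTURAL_CONFOUNDERS,
                                                          names(nc_data)),
                                                drop = FALSE])
    nc_data$..y <- outcome_at_visit(nc_data, cohort$visits, config$outcome,
                                    max(config$visits))
    nc <- negative_control_mediation(nc_data, paste0("cpgm_", config$cpg),
                                     "..y", n_boot = config$n_boot,
                                     seed = config$seed + 3L)
    utils::write.csv(nc, file.path(config$out_dir, "negative_control.csv"),
                     row.names = FALSE)
    log_line(logf, "mediate: NIE at month ", max(config$visits), " = ",
             round(med$nie[med$visit_month == max(config$visits)], 3),
             "; negative-control NIE = ", round(nc$nie, 3))

    manifest <- list(
      package_version = as.character(utils::packageVersion("artgrowth")),
      seed = config$seed,
      arm = config$arm, covset = config$covset_name,
      outcome = config$outcome, visits = config$visits,
      cpg = config$cpg, m_imputations = config$m_imputations,
      n_boot = config$n_boot,
      source = if (is.null(config$input_dir)) "generator" else config$input_dir,
      outputs = c("estimates.csv", "cpg_scan.csv", "mediation.csv",
                  "negative_control.csv", "run.log")
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    config$out_dir
  }, error = function(e) {
    log_line(logf, "ERROR in stage '", stage, "': ", conditionMessage(e))
    stop("run_pipeline failed in stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format the estimate table with significance markers
#'
#' Produces per-row significance markers at 0.05 (*), 0.01 (**) and the
#' Bonferroni bound 0.05 / n_comparisons (\eqn{\dagger}) from Wald z-tests,
#' with percent-difference rows transformed consistently in estimate and CI.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @param n_comparisons Number of comparisons for the Bonferroni marker
#'   (default: number of rows in the estimate table).
#' @return Formatted data.frame (also written to `formatted_estimates.csv`).
#' @export
render_tables <- function(run_dir, n_comparisons = NULL) {
  path <- file.path(run_dir, "estimates.csv")
  if (!file.exists(path)) stop("render_tables: no estimates.csv in ", run_dir)
  est <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) data.frame())
  if (nrow(est) == 0) {
    out <- est
    utils::write.csv(out, file.path(run_dir, "formatted_estimates.csv"),
                     row.names = FALSE)
    return(out)
  }
  if (is.null(n_comparisons)) n_comparisons <- nrow(est)
  bon <- bonferroni_threshold(0.05, n_comparisons)
  z <- est$estimate / est$se
  p <- 2 * stats::pnorm(-abs(z))
  marker <- ifelse(p < bon, "†",
                   ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  out <- data.frame(
    outcome = est$outcome, visit_month = est$visit_month,
    model = est$model_tag,
    display = sprintf("%.2f [%.2f, %.2f]%s", est$estimate, est$ci_low,
                      est$ci_high, marker),
    p = p, bonferroni_threshold = bon,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, file.path(run_dir, "formatted_estimates.csv"),
                   row.names = FALSE)
  out
}
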