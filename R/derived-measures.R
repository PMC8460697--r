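#' Shepard estimated fetal weight
#'
#' Ultrasound-based estimated fetal weight from biparietal diameter (BPD) and
#' abdominal circumference (AC), both in centimeters:
#' \deqn{EFW = 10^{-1.7492 + 0.166\,BPD + 0.046\,AC - 2.646\,(AC \cdot BPD)/1000}}
#' with the result in kilograms.
#'
#' @param bpd_cm Biparietal diameter in cm (> 0).
#' @param ac_cm Abdominal circumference in cm (> 0).
#' @return Estimated fetal weight in kg.
#' @export
#' @examples
#' shepard_efw(9, 30)
shepard_efw <- function(bpd_cm, ac_cm) {
  if (any(bpd_cm <= 0) || any(ac_cm <= 0)) {
    stop("shepard_efw: BPD and AC must be positive (centimeters)")
  }
  10^(-1.7492 + 0.166 * bpd_cm + 0.046 * ac_cm - 2.646 * (ac_cm * bpd_cm) / 1000)
}

#' HOMA indices of beta-cell function and insulin resistance
#'
#' Homeostatic model assessment from fasting glucose (mmol/L) and fasting
#' insulin (mIU/L): HOMA-B = 20 * insulin / (glucose - 3.5) and
#' HOMA-IR = insulin * glucose / 22.5. HOMA-B is set to missing (NA) when
#' fasting glucose is at or below 3.5 mmol/L, where the denominator is
#' non-positive and the index undefined.
#'
#' @param fasting_glucose_mmol Fasting glucose, mmol/L (> 0). Vectorized.
#' @param fasting_insulin_miu Fasting insulin, mIU/L (>= 0). Vectorized.
#' @return A data.frame with columns `homa_beta` (NA when glucose <= 3.5)
#'   and `homa_ir`.
#' @export
homa_indices <- function(fasting_glucose_mmol, fasting_insulin_miu) {
  if (any(fasting_glucose_mmol <= 0, na.rm = TRUE)) {
    stop("homa_indices: fasting glucose must be positive")
  }
  if (any(fasting_insulin_miu < 0, na.rm = TRUE)) {
    stop("homa_indices: fasting insulin must be non-negative")
  }
  homa_ir <- fasting_insulin_miu * fasting_glucose_mmol / 22.5
  homa_beta <- ifelse(fasting_glucose_mmol > 3.5,
                      20 * fasting_insulin_miu / (fasting_glucose_mmol - 3.5),
                      NA_real_)
  data.frame(homa_beta = homa_beta, homa_ir = homa_ir)
}

#' Protocol mean of repeated blood-pressure readings
#'
#' Implements the repeat-and-average measurement rule: two seated readings are
#' always taken; if systolic or diastolic pressure differs by more than
#' 10 mmHg between them, a third reading is required, and the simple mean of
#' all valid readings is reported.
#'
#' @param readings A list of numeric pairs `c(sbp, dbp)` (or a 2-column
#'   matrix), in measurement order; at least two readings.
#' @return A list with `sbp_mean`, `dbp_mean`, and `needed_third` (TRUE iff
#'   the first two readings differed by more than 10 mmHg on either scale).
#' @export
average_bp <- function(readings) {
  if (is.matrix(readings)) readings <- asplit(readings, 1)
  if (length(readings) < 2) {
    stop("average_bp: protocol requires at least two readings")
  }
  m <- do.call(rbind, lapply(readings, function(r) as.numeric(r[1:2])))
  needed_third <- abs(m[1, 1] - m[2, 1]) > 10 || abs(m[1, 2] - m[2, 2]) > 10
  if (needed_third && nrow(m) < 3) {
    warning("average_bp: third reading required by protocol but only two supplied; returning mean of two")
  }
  list(sbp_mean = mean(m[, 1]), dbp_mean = mean(m[, 2]),
       needed_third = needed_third)
}

#' Harmonize recumbent length and standing height
#'
#' Recumbent length and standing height are measured on overlapping age
#' ranges; where only standing height is available in an age window analyzed
#' on the length scale, the standard additive correction of +0.7 cm is
#' applied. Length values pass through unchanged.
#'
#' @param value_cm Measured value, cm (> 0).
#' @param mode Either "length" or "height".
#' @return Value on the length-comparable scale, cm.
#' @export
length_height_harmonize <- function(value_cm, mode = c("length", "height")) {
  mode <- match.arg(mode)
  stopifnot(all(value_cm > 0))
  if (mode == "height") value_cm + 0.7 else value_cm
}

#' Build a synthetic LMS growth reference chart
#'
#' Smooth LMS (skewness L, median M, coefficient of variation S) curves over
#' age for height, weight and BMI, per sex. This is a synthetic chart for
#' testing and demonstration; real reference tables (WHO, AAP) can be
#' supplied in the same format via [read_reference_chart()].
#'
#' @param age_months Ages at which to tabulate (converted to days at
#'   30.4375 days/month).
#' @return A data.frame with columns sex ("M"/"F"), age_days, measure, L, M, S.
#' @export
make_reference_chart <- function(age_months = 0:78) {
  age_days <- round(age_months * 30.4375)
  grid <- expand.grid(sex = c("M", "F"), age_days = age_days,
                      stringsAsFactors = FALSE)
  t <- grid$age_days / 365.25
  male <- grid$sex == "M"
  rows <- function(measure, L, M, S) {
    data.frame(sex = grid$sex, age_days = grid$age_days, measure = measure,
               L = L, M = M, S = S, stringsAsFactors = FALSE)
  }
  # smooth monotone medians loosely shaped like child growth curves
  chart <- rbind(
    rows("height_cm", L = 1,
         M = 50 + 42 * log1p(t) + 1.5 * male,
         S = 0.035 + 0.003 * pmin(t, 5)),
    rows("weight_kg", L = 0.2 - 0.05 * pmin(t, 4),
         M = 3.3 + 7.2 * log1p(t) + 0.25 * male,
         S = 0.11 + 0.01 * pmin(t, 5)),
    rows("bmi", L = -0.5,
         M = 13.5 + 3.5 * exp(-t / 1.2) + 0.4 * pmax(t - 4, 0) / 3,
         S = 0.08)
  )
  chart[order(chart$measure, chart$sex, chart$age_days), ]
}

#' Read / write an LMS reference chart
#'
#' Delimited-text chart with columns sex, age_days, measure, L, M, S.
#' @param path File path.
#' @param chart A chart data.frame as from [make_reference_chart()].
#' @return `read_reference_chart` returns the validated chart data.frame.
#' @export
read_reference_chart <- function(path) {
  chart <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "age_days", "measure", "L", "M", "S")
  if (!all(required %in% names(chart))) {
    stop("reference chart must have columns: ", paste(required, collapse = ", "))
  }
  if (any(chart$M <= 0) || any(chart$S <= 0)) {
    stop("reference chart requires M > 0 and S > 0")
  }
  chart
}

#' @rdname read_reference_chart
#' @export
write_reference_chart <- function(chart, path) {
  utils::write.csv(chart, path, row.names = FALSE)
  invisible(path)
}

#' Age- and sex-standardized LMS z-score
#'
#' z = ((value/M)^L - 1) / (L * S) when L != 0, else log(value/M) / S, with
#' L, M, S linearly interpolated in exact age (days) between tabulated chart
#' rows for the child's sex.
#'
#' @param value Measured value (> 0).
#' @param sex "M" or "F".
#' @param age_days Exact age in days; must lie within the chart's range.
#' @param measure Chart measure name (e.g. "height_cm").
#' @param chart Reference chart data.frame (see [make_reference_chart()]).
#' @return The z-score.
#' @export
lms_zscore <- function(value, sex, age_days, measure, chart) {
  stopifnot(value > 0)
  rows <- chart[chart$sex == sex & chart$measure == measure, ]
  if (nrow(rows) == 0) stop("lms_zscore: chart has no rows for ", sex, "/", measure)
  rows <- rows[order(rows$age_days), ]
  if (age_days < min(rows$age_days) || age_days > max(rows$age_days)) {
    stop("lms_zscore: age ", age_days, " days outside chart coverage [",
         min(rows$age_days), ", ", max(rows$age_days), "]")
  }
  L <- stats::approx(rows$age_days, rows$L, xout = age_days)$y
  M <- stats::approx(rows$age_days, rows$M, xout = age_days)$y
  S <- stats::approx(rows$age_days, rows$S, xout = age_days)$y
  if (abs(L) > 1e-12) ((value / M)^L - 1) / (L * S) else log(value / M) / S
}

#' Invert an LMS z-score back to the measurement scale
#'
#' @inheritParams lms_zscore
#' @param z z-score to invert.
#' @return The measurement value whose z-score is `z`.
#' @export
lms_inverse <- function(z, sex, age_days, measure, chart) {
  rows <- chart[chart$sex == sex & chart$measure == measure, ]
  rows <- rows[order(rows$age_days), ]
  L <- stats::approx(rows$age_days, rows$L, xout = age_days)$y
  M <- stats::approx(rows$age_days, rows$M, xout = age_days)$y
  S <- stats::approx(rows$age_days, rows$S, xout = age_days)$y
  if (abs(L) > 1e-12) M * (1 + L * S * z)^(1 / L) else M * exp(S * z)
}

#' Percent difference from a log-scale regression coefficient
#'
#' For outcomes modeled on the natural-log scale, the treatment coefficient
#' beta corresponds to a multiplicative effect exp(beta); reported as
#' (exp(beta) - 1) * 100 percent.
#'
#' @param beta_log_scale Coefficient (or CI endpoint) from a ln-outcome model.
#' @return Percent difference.
#' @export
percent_difference <- function(beta_log_scale) {
  stopifnot(all(is.finite(beta_log_scale)))
  (exp(beta_log_scale) - 1) * 100
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of comparisons.
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1, alpha > 0, alpha <= 1)
  alpha / m
}
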