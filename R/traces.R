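#' Thermal stimulus trace
#'
#' A time-stamped CoVAS (computerized visual analogue scale, 0-100) pain
#' rating series for one thermal stimulus phase, optionally with the
#' thermode temperature. Pretest phases carry the 0.3 degC/s ramp from a
#' 32 degC baseline; test-stimulus phases (TS1/TS2) are tonic 120-s
#' stimulations at the individually calibrated T50.
#'
#' @param time_s Numeric, seconds from phase onset, strictly increasing.
#' @param covas Numeric, pain rating in \[0, 100\].
#' @param temperature_c Optional numeric, thermode temperature in degC.
#' @param phase One of `"PRETEST_1"`, `"PRETEST_2"`, `"PRETEST_3"`,
#'   `"TS1"`, `"TS2"`.
#' @return An object of class `thermal_trace`.
#' @export
thermal_trace <- function(time_s, covas, temperature_c = NULL,
                          phase = c("TS1", "TS2", "PRETEST_1", "PRETEST_2",
                                    "PRETEST_3")) {
  phase <- match.arg(phase)
  time_s <- as.numeric(time_s)
  covas <- as.numeric(covas)
  if (length(time_s) != length(covas))
    stop("time_s and covas must have equal length")
  if (length(time_s) < 2L) stop("a trace needs at least 2 samples")
  if (anyNA(time_s) || anyNA(covas)) stop("NA in trace samples")
  o <- order(time_s)
  time_s <- time_s[o]; covas <- covas[o]
  if (any(diff(time_s) <= 0)) stop("trace times must be strictly increasing")
  if (!is.null(temperature_c)) {
    temperature_c <- as.numeric(temperature_c)[o]
    if (length(temperature_c) != length(time_s))
      stop("temperature_c length mismatch")
  }
  structure(list(phase = phase, time_s = time_s, covas = covas,
                 temperature_c = temperature_c),
            class = "thermal_trace")
}

#' Cold-pressor conditioning stimulus series
#'
#' Verbal NRS (0-10, 0.5 resolution) pain ratings collected every 15 s
#' during the 120-s cold-pressor immersion, with an optional early
#' withdrawal time. No rating may fall after the withdrawal.
#'
#' @param time_s Rating times, multiples of 15 within (0, 120\].
#' @param nrs Ratings in \[0, 10\].
#' @param withdrawal_time_s Seconds at which the arm was removed, or `NA`.
#' @return An object of class `cold_pressor_series`.
#' @export
cold_pressor_series <- function(time_s, nrs, withdrawal_time_s = NA_real_) {
  time_s <- as.numeric(time_s); nrs <- as.numeric(nrs)
  if (length(time_s) != length(nrs)) stop("time_s and nrs length mismatch")
  o <- order(time_s)
  time_s <- time_s[o]; nrs <- nrs[o]
  if (any(duplicated(time_s))) stop("duplicate cold-pressor rating times")
  structure(list(time_s = time_s, nrs = nrs,
                 withdrawal_time_s = as.numeric(withdrawal_time_s)[1]),
            class = "cold_pressor_series")
}

#' @export
print.thermal_trace <- function(x, ...) {
  cat(sprintf("<thermal_trace %s: %d samples over [%.1f, %.1f] s%s>\n",
              x$phase, length(x$time_s), min(x$time_s), max(x$time_s),
              if (is.null(x$temperature_c)) "" else ", with temperature"))
  invisible(x)
}

#' @export
print.cold_pressor_series <- function(x, ...) {
  cat(sprintf("<cold_pressor_series: %d ratings%s>\n", length(x$time_s),
              if (is.na(x$withdrawal_time_s)) ""
              else sprintf(", withdrawal at %.0f s", x$withdrawal_time_s)))
  invisible(x)
}

# Structural/range issues for a thermal trace; character(0) when clean.
validate_thermal_trace <- function(trace) {
  issues <- character(0)
  if (any(trace$covas < 0 | trace$covas > 100))
    issues <- c(issues, sprintf("%s: covas outside [0,100]", trace$phase))
  if (startsWith(trace$phase, "PRETEST")) {
    if (is.null(trace$temperature_c))
      issues <- c(issues, sprintf("%s: missing temperature", trace$phase))
    else if (any(diff(trace$temperature_c) < -1e-9))
      issues <- c(issues, sprintf("%s: temperature not non-decreasing",
                                  trace$phase))
  }
  if (trace$phase %in% c("TS1", "TS2")) {
    if (min(trace$time_s) > 1e-9 || max(trace$time_s) < 120 - 1e-9)
      issues <- c(issues, sprintf("%s: span does not cover [0,120] s",
                                  trace$phase))
  }
  issues
}

validate_cold_pressor <- function(cs) {
  issues <- character(0)
  if (length(cs$time_s)) {
    if (any(cs$time_s <= 0 | cs$time_s > 120 |
            abs(cs$time_s / 15 - round(cs$time_s / 15)) > 1e-9))
      issues <- c(issues, "CS: rating times not multiples of 15 in (0,120]")
    if (any(cs$nrs < 0 | cs$nrs > 10))
      issues <- c(issues, "CS: nrs outside [0,10]")
    if (!is.na(cs$withdrawal_time_s) &&
        any(cs$time_s > cs$withdrawal_time_s + 1e-9))
      issues <- c(issues, "CS: rating after withdrawal")
  }
  issues
}

#' Participant session
#'
#' Bundles one participant's metadata and raw stimulus traces. A session
#' is "complete" for analysis when both test stimuli and the cold-pressor
#' series are present and T50 is determinable (either supplied directly
#' or derivable from a pretest ramp reaching a rating of 50/100).
#'
#' @param participant_id Opaque identifier string.
#' @param group `"PATIENT"` or `"CONTROL"`.
#' @param gender `"FEMALE"` or `"MALE"`.
#' @param age_years Age in years.
#' @param recruitment Recruitment site label (e.g. `"PAIN_CLINIC"`).
#' @param pain_before_nrs NRS pain before the assessment, or `NA`.
#' @param descriptors Named list of pain descriptors (duration class,
#'   persistent/recurrent pattern, primary location, secondary-sites flag).
#' @param pretest List of up to 3 pretest [thermal_trace] objects.
#' @param ts1,ts2 Test-stimulus [thermal_trace] objects or `NULL`.
#' @param cs A [cold_pressor_series] or `NULL`.
#' @param t50_c Calibrated T50 in degC, or `NA` to derive from pretests.
#' @return An object of class `cpm_session`.
#' @export
cpm_session <- function(participant_id, group, gender, age_years,
                        recruitment = NA_character_,
                        pain_before_nrs = NA_real_,
                        descriptors = list(),
                        pretest = list(), ts1 = NULL, ts2 = NULL, cs = NULL,
                        t50_c = NA_real_) {
  group <- match.arg(toupper(group), c("PATIENT", "CONTROL"))
  gender <- match.arg(toupper(gender), c("FEMALE", "MALE"))
  issues <- character(0)
  for (tr in pretest) issues <- c(issues, validate_thermal_trace(tr))
  for (tr in list(ts1, ts2))
    if (!is.null(tr)) issues <- c(issues, validate_thermal_trace(tr))
  if (!is.null(cs)) issues <- c(issues, validate_cold_pressor(cs))
  if (is.na(t50_c) && length(pretest) == 0L)
    issues <- c(issues, "neither t50_c nor pretest traces present")
  structure(list(participant_id = as.character(participant_id),
                 group = group, gender = gender,
                 age_years = as.numeric(age_years),
                 recruitment = as.character(recruitment),
                 pain_before_nrs = as.numeric(pain_before_nrs),
                 descriptors = descriptors,
                 pretest = pretest, ts1 = ts1, ts2 = ts2, cs = cs,
                 t50_c = as.numeric(t50_c),
                 valid = length(issues) == 0L, issues = issues),
            class = "cpm_session")
}

#' @export
print.cpm_session <- function(x, ...) {
  cat(sprintf("<cpm_session %s (%s, %s, %.1f y): %d pretest, TS1 %s, TS2 %s, CS %s%s>\n",
              x$participant_id, x$group, x$gender, x$age_years,
              length(x$pretest),
              if (is.null(x$ts1)) "absent" else "present",
              if (is.null(x$ts2)) "absent" else "present",
              if (is.null(x$cs)) "absent" else "present",
              if (x$valid) "" else sprintf(", INVALID (%d issues)",
                                           length(x$issues))))
  invisible(x)
}
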