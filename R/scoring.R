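# Per-participant psychophysical scoring.
#
# All trace operations treat the sampled CoVAS series as a piecewise-linear
# function of time: means are trapezoidal time-weighted integrals and level
# crossings are linearly interpolated, so results do not depend on the
# (unspecified, possibly irregular) device sampling grid.

# First upward crossing time of `level`; NA if never reached.
first_crossing_time <- function(time_s, value, level) {
  above <- value > level
  i <- which(above)[1]
  if (is.na(i)) {
    # allow an exact touch to count as reaching the level
    j <- which(value >= level)[1]
    return(if (is.na(j)) NA_real_ else time_s[j])
  }
  if (i == 1L) return(time_s[1])
  v0 <- value[i - 1L]; v1 <- value[i]
  if (v0 >= level) return(time_s[i - 1L])
  time_s[i - 1L] + (level - v0) / (v1 - v0) * (time_s[i] - time_s[i - 1L])
}

trace_value_at <- function(trace, t) {
  stats::approx(trace$time_s, trace$covas, xout = t, rule = 1)$y
}

# CoVAS tolerance above zero that counts as "first report of pain"; keeps
# the interpolated threshold off the sampling grid without being sensitive
# to exact zeros.
PAIN_ONSET_EPS <- 0.25

#' Heat pain threshold from pretest ramps
#'
#' Per pretest trial, the thermode temperature at the first report of pain
#' (CoVAS leaving zero), with the crossing time linearly interpolated
#' between the bracketing samples and the temperature read off the ramp at
#' that time. Returns the mean over trials that report pain.
#'
#' @param pretest List of pretest [thermal_trace] objects (each must carry
#'   temperature).
#' @return Threshold in degC, or `NA_real_` if no trial ever reports pain.
#' @export
heat_pain_threshold <- function(pretest) {
  if (length(pretest) == 0L) stop("no pretest traces")
  per_trial <- vapply(pretest, function(tr) {
    if (is.null(tr$temperature_c)) stop("pretest trace lacks temperature")
    t_cross <- first_crossing_time(tr$time_s, tr$covas, PAIN_ONSET_EPS)
    if (is.na(t_cross)) return(NA_real_)
    stats::approx(tr$time_s, tr$temperature_c, xout = t_cross, rule = 2)$y
  }, numeric(1))
  if (all(is.na(per_trial))) return(NA_real_)
  mean(per_trial, na.rm = TRUE)
}

#' T50 from pretest ramps
#'
#' Per trial, the temperature at the first upward crossing of CoVAS 50
#' (interpolated as in [heat_pain_threshold()]); the mean over trials that
#' reach 50. Trials never reaching 50 are excluded from the mean.
#'
#' @inheritParams heat_pain_threshold
#' @return T50 in degC, or `NA_real_` if no trial reaches 50.
#' @export
pretest_t50 <- function(pretest) {
  if (length(pretest) == 0L) stop("no pretest traces")
  per_trial <- vapply(pretest, function(tr) {
    if (is.null(tr$temperature_c)) stop("pretest trace lacks temperature")
    t_cross <- first_crossing_time(tr$time_s, tr$covas, 50)
    if (is.na(t_cross)) return(NA_real_)
    stats::approx(tr$time_s, tr$temperature_c, xout = t_cross, rule = 2)$y
  }, numeric(1))
  if (all(is.na(per_trial))) return(NA_real_)
  mean(per_trial, na.rm = TRUE)
}

#' Time-weighted mean CoVAS over a window
#'
#' Trapezoidal integral of the piecewise-linear interpolant divided by the
#' window length.
#'
#' @param trace A [thermal_trace].
#' @param window Length-2 numeric `(t_start, t_end)` in seconds; must lie
#'   within the trace span.
#' @return Mean CoVAS over the window.
#' @export
mean_trace_intensity <- function(trace, window = c(0, 120)) {
  t0 <- window[1]; t1 <- window[2]
  if (t1 <= t0) stop("window must have positive length")
  if (t0 < min(trace$time_s) - 1e-9 || t1 > max(trace$time_s) + 1e-9)
    stop("window outside trace span")
  inner <- trace$time_s > t0 & trace$time_s < t1
  tt <- c(t0, trace$time_s[inner], t1)
  vv <- c(trace_value_at(trace, t0), trace$covas[inner],
          trace_value_at(trace, t1))
  n <- length(tt)
  sum(diff(tt) * (vv[-1] + vv[-n]) / 2) / (t1 - t0)
}

#' Temporal summation of pain over the last 60 s
#'
#' Signed change in the interpolated CoVAS over the temporal-summation
#' phase of a 120-s tonic stimulus: `covas(120) - covas(60)`. Positive
#' values indicate summation (facilitation), negative values adaptation.
#'
#' @param trace A [thermal_trace] spanning \[0, 120\] s.
#' @return Signed TSP in CoVAS units.
#' @export
temporal_summation <- function(trace) {
  if (max(trace$time_s) < 120 - 1e-9)
    stop("trace does not span 120 s")
  trace_value_at(trace, 120) - trace_value_at(trace, 60)
}

#' Classify a TSP value
#'
#' A change of 20/100 or more during the temporal-summation phase is
#' clinically significant; the cutoffs are inclusive.
#'
#' @param tsp Signed TSP in \[-100, 100\].
#' @return `"DECREASE"`, `"CONSTANT"` or `"INCREASE"`.
#' @export
classify_tsp <- function(tsp) {
  stopifnot(all(is.finite(tsp)))
  out <- rep("CONSTANT", length(tsp))
  out[tsp >= 20] <- "INCREASE"
  out[tsp <= -20] <- "DECREASE"
  out
}

#' Mean cold-pressor pain with withdrawal imputation
#'
#' Arithmetic mean of the NRS ratings; if the arm was withdrawn before the
#' end of the 120-s immersion, a mean of exactly 10/10 is imputed.
#'
#' @param cs A [cold_pressor_series].
#' @return Mean NRS pain in \[0, 10\].
#' @export
cs_mean_intensity <- function(cs) {
  if (!is.na(cs$withdrawal_time_s) && cs$withdrawal_time_s < 120)
    return(10.0)
  if (length(cs$nrs) == 0L)
    stop("cold-pressor series has no ratings and no withdrawal")
  mean(cs$nrs)
}

#' CPM efficiency
#'
#' Percent change in mean test-stimulus pain after vs before conditioning:
#' `100 * (mean_ts2 - mean_ts1) / mean_ts1`. Negative values indicate
#' inhibition, positive facilitation.
#'
#' @param mean_ts1,mean_ts2 Mean CoVAS over the 120-s test stimuli before
#'   and after conditioning.
#' @return CPM efficiency in percent, or `NA_real_` (with a warning) when
#'   `mean_ts1` is zero and the ratio is undefined.
#' @export
cpm_efficiency <- function(mean_ts1, mean_ts2) {
  if (mean_ts1 <= 0) {
    warning("mean TS1 pain is zero: CPM efficiency undefined")
    return(NA_real_)
  }
  100 * (mean_ts2 - mean_ts1) / mean_ts1
}

#' Classify CPM efficiency
#'
#' Between -100% and -30% is optimal, between -30% and -10% suboptimal,
#' above -10% inefficient; each cutoff belongs to the more-inhibitory
#' class.
#'
#' @param cpm_pct CPM efficiency in percent.
#' @return `"OPTIMAL"`, `"SUBOPTIMAL"` or `"INEFFICIENT"`.
#' @export
classify_cpm <- function(cpm_pct) {
  stopifnot(all(is.finite(cpm_pct)))
  out <- rep("INEFFICIENT", length(cpm_pct))
  out[cpm_pct <= -10] <- "SUBOPTIMAL"
  out[cpm_pct <= -30] <- "OPTIMAL"
  out
}

#' Score one complete session
#'
#' Computes every per-participant quantity: threshold, T50, mean pain over
#' both test stimuli, signed TSP for each, the conditioning-stimulus mean
#' (with withdrawal imputation), CPM efficiency, and all category labels.
#'
#' @param session A complete [cpm_session].
#' @return One-row data frame (a score record).
#' @export
score_session <- function(session) {
  stopifnot(inherits(session, "cpm_session"))
  reason <- session_is_complete(session)
  if (length(reason))
    stop("session ", session$participant_id, " not complete: ",
         paste(reason, collapse = "; "))
  threshold <- if (length(session$pretest))
    heat_pain_threshold(session$pretest) else NA_real_
  t50 <- if (!is.na(session$t50_c)) session$t50_c else
    pretest_t50(session$pretest)
  m1 <- mean_trace_intensity(session$ts1, c(0, 120))
  m2 <- mean_trace_intensity(session$ts2, c(0, 120))
  tsp1 <- temporal_summation(session$ts1)
  tsp2 <- temporal_summation(session$ts2)
  csm <- cs_mean_intensity(session$cs)
  cpm <- cpm_efficiency(m1, m2)
  data.frame(participant_id = session$participant_id,
             group = session$group, gender = session$gender,
             age_years = session$age_years,
             t50_c = t50, threshold_c = threshold,
             mean_ts1 = m1, mean_ts2 = m2,
             tsp1 = tsp1, tsp2 = tsp2, cs_mean = csm, cpm_pct = cpm,
             cpm_class = if (is.na(cpm)) NA_character_ else classify_cpm(cpm),
             tsp1_class = classify_tsp(tsp1),
             tsp2_class = classify_tsp(tsp2),
             withdrawal = !is.na(session$cs$withdrawal_time_s) &&
               session$cs$withdrawal_time_s < 120,
             stringsAsFactors = FALSE)
}

#' Score every complete session of a cohort
#'
#' Applies [filter_complete()] and [score_session()] across the cohort.
#'
#' @param cohort A `cpm_cohort`.
#' @return A list with `scores` (data frame, one row per retained
#'   participant) and `exclusions` (from [filter_complete()]).
#' @export
score_cohort <- function(cohort) {
  flt <- filter_complete(cohort)
  scores <- do.call(rbind, lapply(flt$cohort$sessions, score_session))
  rownames(scores) <- NULL
  list(scores = scores, exclusions = flt$exclusions)
}
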