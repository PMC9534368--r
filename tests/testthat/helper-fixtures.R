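# Fixture builders shared across the suite. Everything is constructed in
# code; no files ship with the package.

# Tonic test-stimulus trace: plateau for the first 60 s, linear drift of
# `tsp` over the last 60 s, sampled at `rate` Hz.
fix_ts_trace <- function(phase = "TS1", plateau = 50, tsp = 0, rate = 1) {
  tt <- seq(0, 120, by = 1 / rate)
  v <- ifelse(tt <= 60, plateau, plateau + tsp * (tt - 60) / 60)
  thermal_trace(tt, pmin(100, pmax(0, v)), phase = phase)
}

# Pretest ramp from 32 degC at 0.3 degC/s; CoVAS 0 until `threshold_c`,
# then linear so that it crosses 50 at `t50_c`.
fix_pretest_trace <- function(phase = "PRETEST_1", t50_c = 43, threshold_c = 38.5,
                              rate = 1) {
  t_end <- (t50_c + 2 - 32) / 0.3
  tt <- seq(0, t_end, by = 1 / rate)
  temp <- 32 + 0.3 * tt
  t_on <- (threshold_c - 32) / 0.3
  slope <- 50 / ((t50_c - threshold_c) / 0.3)
  thermal_trace(tt, pmin(100, pmax(0, slope * (tt - t_on))),
                temperature_c = temp, phase = phase)
}

fix_cs <- function(nrs = c(5, 6, 6, 7, 7, 8, 8, 8), withdrawal = NA_real_) {
  cold_pressor_series(seq(15, by = 15, length.out = length(nrs)), nrs,
                      withdrawal_time_s = withdrawal)
}

fix_session <- function(id = "P1", group = "PATIENT", gender = "FEMALE",
                        age = 15, t50 = 43, ts1 = fix_ts_trace("TS1"),
                        ts2 = fix_ts_trace("TS2"), cs = fix_cs(),
                        pretest = list()) {
  cpm_session(participant_id = id, group = group, gender = gender,
              age_years = age, pretest = pretest, ts1 = ts1, ts2 = ts2,
              cs = cs, t50_c = t50)
}

fix_cohort <- function(sessions) {
  structure(list(sessions = stats::setNames(
    sessions, vapply(sessions, `[[`, character(1), "participant_id")),
    provenance = list(metadata_path = "<fixture>",
                      traces_path = "<fixture>", log = character(0))),
    class = "cpm_cohort")
}

# Write a small two-participant cohort CSV pair into `dir` and return the
# two paths. `mutate` can edit the trace data frame before writing.
fix_cohort_csvs <- function(dir, mutate = identity) {
  meta <- data.frame(
    participant_id = c("P1", "P2"),
    group = c("PATIENT", "CONTROL"),
    gender = c("FEMALE", "MALE"),
    age_years = c(14.5, 16),
    recruitment = c("PAIN_CLINIC", "COMMUNITY"),
    pain_before_nrs = c(4, ""),
    pain_duration = c("MORE_THAN_6MO", ""),
    pain_pattern = c("PERSISTENT", ""),
    pain_primary_location = c("BACK", ""),
    pain_secondary_sites = c("YES", ""),
    t50_c = c(43.2, 42.5),
    withdrawal_time_s = c("", ""),
    stringsAsFactors = FALSE)
  tr <- function(pid, phase, kind, t, v, temp = "")
    data.frame(participant_id = pid, phase = phase, stimulus_kind = kind,
               time_s = t, value = v, temperature_c = temp,
               stringsAsFactors = FALSE)
  tt <- seq(0, 120, by = 10)
  traces <- rbind(
    tr("P1", "TS1", "thermal", tt, rep(50, length(tt))),
    tr("P1", "TS2", "thermal", tt, rep(35, length(tt))),
    tr("P1", "CS", "cold", seq(15, 120, 15), c(5, 6, 6, 7, 7, 8, 8, 8)),
    tr("P2", "TS1", "thermal", tt, rep(40, length(tt))),
    tr("P2", "TS2", "thermal", tt, rep(40, length(tt))),
    tr("P2", "CS", "cold", seq(15, 120, 15), rep(4, 8)))
  traces <- mutate(traces)
  meta_path <- file.path(dir, "cohort.csv")
  traces_path <- file.path(dir, "traces.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(traces, traces_path, row.names = FALSE, quote = FALSE)
  c(metadata = meta_path, traces = traces_path)
}

# Random indicator-like matrix for clustering property tests.
fix_matrix <- function(n = 30, p = 4, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * p), n, p,
         dimnames = list(NULL, paste0("v", seq_len(p))))
}

# Draw one representable indicator target vector from the default patient
# mixture: the designed traces stay inside the CoVAS range, so scoring
# reproduces the targets exactly (up to NRS rounding).
fix_feasible_target <- function(specs = default_phenotypes()) {
  repeat {
    sp <- specs[[sample(1:3, 1, prob = c(0.446, 0.306, 0.248))]]
    t <- list(tsp1 = min(100, max(-100, stats::rnorm(1, sp$tsp1_mean, sp$tsp1_sd))),
              cs = min(10, max(0, stats::rnorm(1, sp$cs_mean, sp$cs_sd))),
              tsp2 = min(100, max(-100, stats::rnorm(1, sp$tsp2_mean, sp$tsp2_sd))),
              cpm = min(100, max(-100, stats::rnorm(1, sp$cpm_mean, sp$cpm_sd))))
    m1 <- 50 + t$tsp1 / 4
    b2 <- m1 * (1 + t$cpm / 100) - t$tsp2 / 4
    if (b2 >= 0 && b2 <= 100 &&
        50 + t$tsp1 >= 0 && 50 + t$tsp1 <= 100 &&
        b2 + t$tsp2 >= 0 && b2 + t$tsp2 <= 100) return(t)
  }
}

fix_demographics <- function(id = "X", group = "PATIENT") {
  list(participant_id = id, group = group, gender = "FEMALE",
       age_years = 15, t50 = 43.4, threshold = 39)
}
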