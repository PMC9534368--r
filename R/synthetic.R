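# Synthetic cohort generator.
#
# Latent indicator targets (TSP1, CS mean, TSP2, CPM%) are drawn first
# from per-phenotype normal distributions (clipped at the scale bounds),
# then raw session traces are constructed to score back to those targets
# (inverse construction), so the whole pipeline can be exercised end to
# end against a known ground truth.

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
round_half <- function(x) round(x * 2) / 2  # NRS 0.5 resolution

#' Phenotype specification
#'
#' Distributional parameters of one latent phenotype: indicator means/SDs
#' (CoVAS units for TSP, NRS for CS, percent for CPM), early-withdrawal
#' probability, demographic composition, and the T50 distribution.
#'
#' @param name Label.
#' @param weight Mixture proportion (patients; controls use `NA`).
#' @param tsp1_mean,tsp1_sd,cs_mean,cs_sd,tsp2_mean,tsp2_sd,cpm_mean,cpm_sd
#'   Indicator distribution parameters.
#' @param withdrawal_prob Expected cold-pressor withdrawal rate. Withdrawal
#'   events are generated for sessions whose CS target sits at the scale
#'   ceiling (see [generate_session()]); this field documents the rate that
#'   ceiling mass implies at the phenotype's CS parameters.
#' @param female_prob Probability a participant is female.
#' @param age_mean,age_sd Age distribution in years (clipped to 8-21).
#' @param t50_mean,t50_sd T50 distribution in degC.
#' @return List of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, weight, tsp1_mean, tsp1_sd, cs_mean, cs_sd,
                           tsp2_mean, tsp2_sd, cpm_mean, cpm_sd,
                           withdrawal_prob, female_prob,
                           age_mean, age_sd, t50_mean, t50_sd) {
  stopifnot(tsp1_sd > 0, cs_sd > 0, tsp2_sd > 0, cpm_sd > 0,
            withdrawal_prob >= 0, withdrawal_prob <= 1,
            female_prob >= 0, female_prob <= 1)
  structure(as.list(environment()), class = "phenotype_spec")
}

#' Default phenotype mixture
#'
#' Three patient phenotypes plus a control specification. The patient
#' mixture reproduces the published cluster profile of the pediatric
#' chronic-pain CPM cohort this generator emulates: a large inhibitory
#' phenotype with high cold-pressor pain (weight 0.446), an inhibitory
#' phenotype with low cold-pressor pain (0.306), and a facilitatory
#' phenotype with inefficient CPM (0.248). CS targets are clipped to
#' \[0, 10\] and TSP/CPM targets to \[-100, 100\].
#'
#' @return Named list of four `phenotype_spec` objects
#'   (`cluster1`, `cluster2`, `cluster3`, `control`).
#' @export
default_phenotypes <- function() {
  list(
    cluster1 = phenotype_spec("cluster1", 0.446,
                              -10.62, 20.17, 8.16, 1.47, -6.11, 16.42,
                              -41.06, 34.19,
                              withdrawal_prob = 0.084, female_prob = 0.81,
                              age_mean = 15.18, age_sd = 2.14,
                              t50_mean = 43.4, t50_sd = 2.4),
    cluster2 = phenotype_spec("cluster2", 0.306,
                              6.89, 17.72, 4.04, 1.70, 2.10, 14.11,
                              -33.10, 37.84,
                              withdrawal_prob = 0.084, female_prob = 0.81,
                              age_mean = 15.18, age_sd = 2.14,
                              t50_mean = 43.4, t50_sd = 2.4),
    cluster3 = phenotype_spec("cluster3", 0.248,
                              12.39, 19.23, 8.24, 1.32, 15.78, 20.66,
                              9.25, 44.27,
                              withdrawal_prob = 0.084, female_prob = 0.81,
                              age_mean = 15.18, age_sd = 2.14,
                              t50_mean = 43.4, t50_sd = 2.4),
    control = phenotype_spec("control", NA_real_,
                             6.46, 19.05, 6.31, 2.41, 5.16, 14.49,
                             -32.67, 35.47,
                             withdrawal_prob = 0.10, female_prob = 0.48,
                             age_mean = 15.06, age_sd = 2.23,
                             t50_mean = 42.8, t50_sd = 2.4))
}

#' Generator configuration
#'
#' @param n_patients,n_controls Cohort sizes.
#' @param phenotypes Output of [default_phenotypes()] (or a compatible
#'   list; the entry named `control` is used for controls, the rest as
#'   the patient mixture).
#' @param noise_sd Gaussian noise SD added per CoVAS sample (CoVAS units);
#'   cold-pressor rating jitter is `noise_sd / 4` NRS units.
#' @param sample_rate_hz Trace sampling rate.
#' @param seed RNG seed (mandatory; the generator is fully reproducible).
#' @param incomplete_fraction Fraction of sessions with one randomly
#'   deleted phase, to exercise the exclusion bookkeeping.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_patients = 639, n_controls = 60,
                             phenotypes = default_phenotypes(),
                             noise_sd = 2, sample_rate_hz = 1,
                             seed, incomplete_fraction = 31 / 639) {
  stopifnot(!missing(seed), n_patients >= 0, n_controls >= 0,
            noise_sd >= 0, sample_rate_hz > 0,
            incomplete_fraction >= 0, incomplete_fraction < 1)
  w <- vapply(phenotypes[names(phenotypes) != "control"], `[[`,
              numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-6) stop("patient mixture weights must sum to 1")
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 phenotypes = phenotypes, noise_sd = noise_sd,
                 sample_rate_hz = sample_rate_hz, seed = as.integer(seed),
                 incomplete_fraction = incomplete_fraction),
            class = "generator_config")
}

draw_targets <- function(spec, rng_n = 1L) {
  list(tsp1 = clip(stats::rnorm(rng_n, spec$tsp1_mean, spec$tsp1_sd), -100, 100),
       cs = clip(stats::rnorm(rng_n, spec$cs_mean, spec$cs_sd), 0, 10),
       tsp2 = clip(stats::rnorm(rng_n, spec$tsp2_mean, spec$tsp2_sd), -100, 100),
       cpm = clip(stats::rnorm(rng_n, spec$cpm_mean, spec$cpm_sd), -100, 100))
}

# Plateau level of TS1; the protocol calibrates the test temperature to a
# pain rating of 50/100.
TS_PLATEAU <- 50

# A test-stimulus trace is a plateau over [0,60] s followed by a linear
# ramp to plateau + tsp at 120 s; its (unclipped) time-weighted mean is
# plateau + tsp/4. Samples are clipped to the 0-100 CoVAS range, as the
# rating device itself saturates, so extreme target combinations are
# compressed rather than discarded (the caller logs when this happens).
build_ts_trace <- function(phase, plateau, tsp, noise_sd, rate) {
  tt <- seq(0, 120, by = 1 / rate)
  v <- ifelse(tt <= 60, plateau, plateau + tsp * (tt - 60) / 60)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  thermal_trace(tt, clip(v, 0, 100), phase = phase)
}

build_pretest_trace <- function(phase, t50, threshold, noise_sd, rate) {
  t_end <- (t50 + 2 - 32) / 0.3
  tt <- seq(0, t_end, by = 1 / rate)
  temp <- 32 + 0.3 * tt
  t_on <- (threshold - 32) / 0.3
  slope <- 50 / ((t50 - threshold) / 0.3)
  v <- pmax(0, slope * (tt - t_on))
  if (noise_sd > 0) {
    ramping <- tt > t_on
    v[ramping] <- v[ramping] + stats::rnorm(sum(ramping), 0, noise_sd)
  }
  thermal_trace(tt, clip(v, 0, 100), temperature_c = temp, phase = phase)
}

#' Construct a raw session scoring back to given indicator targets
#'
#' Inverse construction: TS1 is a plateau at 50 for the first 60 s with a
#' linear drift to `50 + tsp1` at 120 s (so its time-weighted mean is
#' `50 + tsp1/4`); the TS2 level is chosen in closed form so the TS2 mean
#' equals `mean_TS1 * (1 + cpm/100)`; the cold-pressor series is 8
#' ratings at the 0.5 NRS resolution averaging to the CS target, or a
#' withdrawal event (scored 10/10); pretest ramps cross CoVAS 50 at the
#' participant's T50. Trace samples are clipped to the 0-100 CoVAS range
#' (the rating scale saturates), so target combinations whose designed
#' ramp leaves the scale are compressed toward it; every such clipping is
#' reported via the `"clipped"` attribute of the returned session.
#'
#' A withdrawal event is generated exactly when the CS target sits at the
#' scale ceiling (rounds to 10/10), mirroring the scoring-side imputation
#' rule; at the default phenotype parameters this yields the expected
#' withdrawal rate of roughly 8-10%.
#'
#' @param targets List with `tsp1`, `cs`, `tsp2`, `cpm`.
#' @param demographics List with `participant_id`, `group`, `gender`,
#'   `age_years`, `t50`, `threshold`, plus optional metadata fields
#'   (`recruitment`, `pain_before_nrs`, descriptor entries).
#' @param config A `generator_config`.
#' @return A [cpm_session], or `NULL` when the implied TS2 plateau falls
#'   outside \[0, 100\] by more than 5 CoVAS units (the caller then
#'   resamples the targets).
#' @export
generate_session <- function(targets, demographics, config) {
  rate <- config$sample_rate_hz
  noise <- config$noise_sd
  mean_ts1 <- TS_PLATEAU + targets$tsp1 / 4
  b2 <- mean_ts1 * (1 + targets$cpm / 100) - targets$tsp2 / 4
  if (b2 < -5 || b2 > 105) return(NULL)
  clipped <- character(0)
  if (b2 < 0 || b2 > 100) {
    clipped <- c(clipped, sprintf("TS2 plateau %.1f clipped into [0,100]", b2))
    b2 <- clip(b2, 0, 100)
  }
  if (TS_PLATEAU + targets$tsp1 < 0 || TS_PLATEAU + targets$tsp1 > 100)
    clipped <- c(clipped, "TS1 ramp endpoint clipped into [0,100]")
  if (b2 + targets$tsp2 < 0 || b2 + targets$tsp2 > 100)
    clipped <- c(clipped, "TS2 ramp endpoint clipped into [0,100]")
  pretest <- lapply(paste0("PRETEST_", 1:3), build_pretest_trace,
                    t50 = demographics$t50,
                    threshold = demographics$threshold,
                    noise_sd = noise, rate = rate)
  ts1 <- build_ts_trace("TS1", TS_PLATEAU, targets$tsp1, noise, rate)
  ts2 <- build_ts_trace("TS2", b2, targets$tsp2, noise, rate)
  if (round_half(targets$cs) >= 10) {
    wt <- stats::runif(1, 20, 115)
    rt <- seq(15, 120, by = 15)
    rt <- rt[rt < wt]
    ratings <- clip(round_half(stats::rnorm(length(rt), targets$cs,
                                            max(noise / 4, 0.25))), 0, 10)
    cs <- cold_pressor_series(rt, ratings, withdrawal_time_s = wt)
  } else {
    jitter <- stats::rnorm(8, 0, noise / 4)
    ratings <- clip(round_half(targets$cs + jitter - mean(jitter)), 0, 10)
    cs <- cold_pressor_series(seq(15, 120, by = 15), ratings)
  }
  session <- cpm_session(
    participant_id = demographics$participant_id,
    group = demographics$group, gender = demographics$gender,
    age_years = demographics$age_years,
    recruitment = demographics$recruitment %||% NA_character_,
    pain_before_nrs = demographics$pain_before_nrs %||% NA_real_,
    descriptors = demographics$descriptors %||% list(),
    pretest = pretest, ts1 = ts1, ts2 = ts2, cs = cs,
    t50_c = demographics$t50)
  attr(session, "clipped") <- clipped
  session
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cohort-level demographic rates mirroring the emulated clinical cohort.
draw_descriptors <- function(group) {
  if (group == "CONTROL")
    return(list(duration = NA_character_, pattern = NA_character_,
                primary_location = NA_character_,
                secondary_sites = NA_character_))
  locs <- c("BACK", "LOWER_LIMBS", "HEAD_NECK", "ABDOMEN", "UPPER_LIMBS",
            "THORAX", "GROIN")
  lp <- c(410, 109, 31, 24, 18, 14, 1)
  list(duration = sample(c("MORE_THAN_6MO", "3_6MO"), 1,
                         prob = c(0.934, 0.066)),
       pattern = sample(c("PERSISTENT", "RECURRENT"), 1,
                        prob = c(0.596, 0.404)),
       primary_location = sample(locs, 1, prob = lp / sum(lp)),
       secondary_sites = sample(c("YES", "NO"), 1, prob = c(0.51, 0.49)))
}

#' Generate a full synthetic cohort
#'
#' Draws phenotype memberships, latent indicator targets and demographics,
#' constructs raw sessions, and optionally deletes one phase from a fixed
#' number of sessions (`round(incomplete_fraction * n)` per group's
#' patients) so that downstream exclusion counts are exercised. Fully
#' reproducible given `config$seed`.
#'
#' @param config A `generator_config`.
#' @return List with `cohort` (a `cpm_cohort`), `latent` (data frame:
#'   `participant_id`, `phenotype`, and the four generating targets) and
#'   `events` (character log of clipping/resampling interventions).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  events <- character(0)
  specs <- config$phenotypes
  patient_specs <- specs[names(specs) != "control"]
  w <- vapply(patient_specs, `[[`, numeric(1), "weight")

  make_one <- function(spec, pid, group) {
    demo <- list(
      participant_id = pid, group = group,
      gender = if (stats::runif(1) < spec$female_prob) "FEMALE" else "MALE",
      age_years = round(clip(stats::rnorm(1, spec$age_mean, spec$age_sd),
                             8, 21), 1),
      t50 = round(clip(stats::rnorm(1, spec$t50_mean, spec$t50_sd),
                       36, 49.5), 2),
      recruitment = if (group == "PATIENT")
        sample(c("PAIN_CLINIC", "OUTPATIENT"), 1, prob = c(0.426, 0.574))
      else "COMMUNITY",
      pain_before_nrs = if (group == "PATIENT" && stats::runif(1) < 0.7023)
        round_half(clip(stats::rnorm(1, 4.16, 2.16), 0.5, 10)) else NA_real_,
      descriptors = draw_descriptors(group))
    demo$threshold <- round(demo$t50 - clip(stats::rnorm(1, 4.46, 1.2),
                                            1.5, 8), 2)
    targets <- draw_targets(spec)
    session <- generate_session(targets, demo, config)
    tries <- 0L
    while (is.null(session) && tries < 100L) {
      tries <- tries + 1L
      targets <- draw_targets(spec)
      session <- generate_session(targets, demo, config)
    }
    if (is.null(session)) stop("could not draw feasible targets for ", pid)
    if (tries > 0L)
      events <<- c(events, sprintf(
        "%s: resampled targets %d time(s) for infeasible TS2 level",
        pid, tries))
    if (length(attr(session, "clipped")))
      events <<- c(events, sprintf("%s: %s", pid,
                                   attr(session, "clipped")))
    list(session = session, targets = targets)
  }

  sessions <- list()
  latent <- list()
  if (config$n_patients > 0) {
    members <- sample(names(patient_specs), config$n_patients,
                      replace = TRUE, prob = w)
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%04d", i)
      one <- make_one(patient_specs[[members[i]]], pid, "PATIENT")
      sessions[[pid]] <- one$session
      latent[[pid]] <- data.frame(
        participant_id = pid, phenotype = members[i],
        tsp1_target = one$targets$tsp1, cs_target = one$targets$cs,
        tsp2_target = one$targets$tsp2, cpm_target = one$targets$cpm,
        stringsAsFactors = FALSE)
    }
  }
  if (config$n_controls > 0) {
    for (i in seq_len(config$n_controls)) {
      pid <- sprintf("C%04d", i)
      one <- make_one(specs$control, pid, "CONTROL")
      sessions[[pid]] <- one$session
      latent[[pid]] <- data.frame(
        participant_id = pid, phenotype = "control",
        tsp1_target = one$targets$tsp1, cs_target = one$targets$cs,
        tsp2_target = one$targets$tsp2, cpm_target = one$targets$cpm,
        stringsAsFactors = FALSE)
    }
  }

  n_incomplete <- round(config$incomplete_fraction * config$n_patients)
  if (n_incomplete > 0) {
    pidx <- sample(sprintf("P%04d", seq_len(config$n_patients)),
                   n_incomplete)
    for (pid in pidx) {
      phase <- sample(c("ts1", "ts2", "cs"), 1)
      sessions[[pid]][[phase]] <- NULL
      events <- c(events, sprintf("%s: deleted %s (forced incomplete)",
                                  pid, phase))
    }
  }

  cohort <- structure(list(sessions = sessions,
                           provenance = list(metadata_path = "<synthetic>",
                                             traces_path = "<synthetic>",
                                             log = character(0))),
                      class = "cpm_cohort")
  list(cohort = cohort,
       latent = do.call(rbind, c(latent, list(make.row.names = FALSE))),
       events = events)
}
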