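# Cohort assembly and CSV round-trip.
#
# Two long-format files describe a cohort:
#   cohort.csv — one row per participant (metadata + optional direct T50
#                and cold-pressor withdrawal time),
#   traces.csv — one row per sample: participant_id, phase, stimulus_kind,
#                time_s, value, temperature_c (empty when absent).
# CS rows use phase "CS", stimulus_kind "cold"; thermal rows use phases
# PRETEST_1..3 / TS1 / TS2 with stimulus_kind "thermal".

METADATA_REQUIRED <- c("participant_id", "group", "gender", "age_years")
METADATA_OPTIONAL <- c("recruitment", "pain_before_nrs", "pain_duration",
                       "pain_pattern", "pain_primary_location",
                       "pain_secondary_sites", "t50_c", "withdrawal_time_s")
TRACE_COLUMNS <- c("participant_id", "phase", "stimulus_kind", "time_s",
                   "value", "temperature_c")
THERMAL_PHASES <- c("PRETEST_1", "PRETEST_2", "PRETEST_3", "TS1", "TS2")

#' Read a cohort from metadata and trace CSV files
#'
#' Assembles validated participant sessions from the two long-format CSV
#' files. Malformed trace rows (non-numeric time or value) are logged with
#' their line numbers and skipped; out-of-range samples flag the owning
#' session invalid but never drop it silently; duplicate
#' (participant, phase, time) rows and missing required columns are hard
#' errors.
#'
#' @param metadata_path Path to the participant metadata CSV.
#' @param traces_path Path to the long-format trace CSV.
#' @return An object of class `cpm_cohort`: a list with `sessions` (named
#'   list of [cpm_session]) and `provenance` (source paths plus a load log).
#' @export
read_cohort <- function(metadata_path, traces_path) {
  meta <- utils::read.csv(metadata_path, colClasses = "character",
                          check.names = FALSE)
  missing_cols <- setdiff(METADATA_REQUIRED, names(meta))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(dup <- duplicated(meta$participant_id)))
    stop("duplicate participant_id in metadata: ",
         paste(unique(meta$participant_id[dup]), collapse = ", "))

  traces <- utils::read.csv(traces_path, colClasses = "character",
                            check.names = FALSE)
  missing_cols <- setdiff(setdiff(TRACE_COLUMNS, "temperature_c"),
                          names(traces))
  if (length(missing_cols))
    stop("traces file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  log <- character(0)

  time_num <- suppressWarnings(as.numeric(traces$time_s))
  value_num <- suppressWarnings(as.numeric(traces$value))
  bad <- which(is.na(time_num) | is.na(value_num))
  if (length(bad)) {
    # +1 for the header line
    log <- c(log, sprintf("line %d: non-numeric time_s/value, row skipped",
                          bad + 1L))
    traces <- traces[-bad, , drop = FALSE]
    time_num <- time_num[-bad]; value_num <- value_num[-bad]
  }
  traces$time_s <- time_num
  traces$value <- value_num
  key <- paste(traces$participant_id, traces$phase, traces$time_s)
  if (any(dupk <- duplicated(key)))
    stop("duplicate (participant, phase, time) rows, first at data line ",
         which(dupk)[1] + 1L)
  temp_num <- if ("temperature_c" %in% names(traces))
    suppressWarnings(as.numeric(traces$temperature_c)) else
      rep(NA_real_, nrow(traces))

  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  get_opt <- function(row, col, default = NA_character_)
    if (col %in% names(meta)) row[[col]] else default

  sessions <- list()
  by_pid <- split(seq_len(nrow(traces)), traces$participant_id)
  for (i in seq_len(nrow(meta))) {
    row <- meta[i, , drop = FALSE]
    pid <- row$participant_id
    idx <- by_pid[[pid]]
    pretest <- list(); ts1 <- NULL; ts2 <- NULL; cs <- NULL
    extra_issues <- character(0)
    if (!is.null(idx)) {
      for (ph in split(idx, traces$phase[idx])) {
        phase <- traces$phase[ph[1]]
        tm <- traces$time_s[ph]; vl <- traces$value[ph]
        o <- order(tm); tm <- tm[o]; vl <- vl[o]
        if (phase == "CS") {
          wt <- num_or_na(get_opt(row, "withdrawal_time_s"))
          cs <- cold_pressor_series(tm, vl, wt)
        } else if (phase %in% THERMAL_PHASES) {
          # clamp for construction; range violations become session issues
          tc <- temp_num[ph][o]
          if (all(is.na(tc))) tc <- NULL
          tr <- thermal_trace(tm, pmin(100, pmax(0, vl)), tc, phase)
          if (any(vl < 0 | vl > 100))
            extra_issues <- c(extra_issues,
                              sprintf("%s: covas outside [0,100]", phase))
          if (startsWith(phase, "PRETEST")) pretest <- c(pretest, list(tr))
          else if (phase == "TS1") ts1 <- tr else ts2 <- tr
        } else {
          log <- c(log, sprintf("participant %s: unknown phase '%s' ignored",
                                pid, phase))
        }
      }
    }
    s <- cpm_session(participant_id = pid, group = row$group,
                     gender = row$gender,
                     age_years = num_or_na(row$age_years),
                     recruitment = get_opt(row, "recruitment"),
                     pain_before_nrs = num_or_na(get_opt(row, "pain_before_nrs")),
                     descriptors = list(
                       duration = get_opt(row, "pain_duration"),
                       pattern = get_opt(row, "pain_pattern"),
                       primary_location = get_opt(row, "pain_primary_location"),
                       secondary_sites = get_opt(row, "pain_secondary_sites")),
                     pretest = pretest, ts1 = ts1, ts2 = ts2, cs = cs,
                     t50_c = num_or_na(get_opt(row, "t50_c")))
    if (length(extra_issues)) {
      s$issues <- unique(c(s$issues, extra_issues))
      s$valid <- FALSE
    }
    if (!s$valid)
      log <- c(log, sprintf("participant %s flagged invalid: %s", pid,
                            paste(s$issues, collapse = "; ")))
    sessions[[pid]] <- s
  }
  structure(list(sessions = sessions,
                 provenance = list(metadata_path = metadata_path,
                                   traces_path = traces_path, log = log)),
            class = "cpm_cohort")
}

#' @export
print.cpm_cohort <- function(x, ...) {
  n <- length(x$sessions)
  nv <- sum(vapply(x$sessions, `[[`, logical(1), "valid"))
  cat(sprintf("<cpm_cohort: %d sessions (%d valid), %d log entries>\n",
              n, nv, length(x$provenance$log)))
  invisible(x)
}

session_is_complete <- function(s) {
  reason <- character(0)
  if (!s$valid)
    reason <- c(reason, paste("invalid:", paste(s$issues, collapse = "; ")))
  if (is.null(s$ts1)) reason <- c(reason, "missing TS1")
  if (is.null(s$ts2)) reason <- c(reason, "missing TS2")
  if (is.null(s$cs)) reason <- c(reason, "missing CS")
  if (is.na(s$t50_c)) {
    t50 <- tryCatch(pretest_t50(s$pretest), error = function(e) NA_real_)
    if (is.na(t50)) reason <- c(reason, "T50 not determinable")
  }
  reason
}

#' Retain complete sessions
#'
#' A session is retained when both test stimuli and the cold-pressor
#' series are present, the session passed validation, and T50 is
#' determinable. Retained sessions are untouched; every exclusion is
#' reported with its reason.
#'
#' @param cohort A `cpm_cohort`.
#' @return A list with `cohort` (retained sessions) and `exclusions`
#'   (data frame with columns `participant_id`, `reason`).
#' @export
filter_complete <- function(cohort) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  reasons <- lapply(cohort$sessions, session_is_complete)
  keep <- lengths(reasons) == 0L
  if (!any(keep)) stop("no complete sessions remain after filtering")
  excl <- data.frame(
    participant_id = names(cohort$sessions)[!keep],
    reason = vapply(reasons[!keep], paste, character(1), collapse = "; "),
    row.names = NULL, stringsAsFactors = FALSE)
  retained <- cohort
  retained$sessions <- cohort$sessions[keep]
  list(cohort = retained, exclusions = excl)
}

SCORE_COLUMNS <- c("participant_id", "group", "gender", "age_years",
                   "t50_c", "threshold_c", "mean_ts1", "mean_ts2",
                   "tsp1", "tsp2", "cs_mean", "cpm_pct", "cpm_class",
                   "tsp1_class", "tsp2_class", "withdrawal")

#' Write / read per-participant score records
#'
#' One row per participant with a stable column order; numeric values
#' round-trip losslessly (within 1e-9) through [read_scores()].
#'
#' @param records Data frame of score records (from [score_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no score records to write")
  missing_cols <- setdiff(SCORE_COLUMNS, names(records))
  if (length(missing_cols))
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[SCORE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SCORE_COLUMNS, names(sc))
  if (length(missing_cols))
    stop("scores file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  sc$withdrawal <- as.logical(sc$withdrawal)
  sc
}

#' Write a cohort back to the CSV pair
#'
#' Emits `cohort.csv` and `traces.csv` (the same schema [read_cohort()]
#' consumes) into a directory.
#'
#' @param cohort A `cpm_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector with the two file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 10,
                                                 scientific = FALSE,
                                                 trim = TRUE))
  meta_rows <- lapply(cohort$sessions, function(s) {
    d <- s$descriptors
    data.frame(participant_id = s$participant_id, group = s$group,
               gender = s$gender, age_years = fmt(s$age_years),
               recruitment = ifelse(is.na(s$recruitment), "", s$recruitment),
               pain_before_nrs = fmt(s$pain_before_nrs),
               pain_duration = if (is.null(d$duration) || is.na(d$duration)) "" else d$duration,
               pain_pattern = if (is.null(d$pattern) || is.na(d$pattern)) "" else d$pattern,
               pain_primary_location = if (is.null(d$primary_location) || is.na(d$primary_location)) "" else d$primary_location,
               pain_secondary_sites = if (is.null(d$secondary_sites) || is.na(d$secondary_sites)) "" else d$secondary_sites,
               t50_c = fmt(s$t50_c),
               withdrawal_time_s = fmt(if (is.null(s$cs)) NA_real_ else
                 s$cs$withdrawal_time_s),
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta_rows)
  trace_rows <- lapply(cohort$sessions, function(s) {
    out <- list()
    for (tr in c(s$pretest, list(s$ts1, s$ts2))) {
      if (is.null(tr)) next
      out[[length(out) + 1L]] <- data.frame(
        participant_id = s$participant_id, phase = tr$phase,
        stimulus_kind = "thermal", time_s = fmt(tr$time_s),
        value = fmt(tr$covas),
        temperature_c = if (is.null(tr$temperature_c)) "" else
          fmt(tr$temperature_c),
        stringsAsFactors = FALSE)
    }
    if (!is.null(s$cs) && length(s$cs$time_s))
      out[[length(out) + 1L]] <- data.frame(
        participant_id = s$participant_id, phase = "CS",
        stimulus_kind = "cold", time_s = fmt(s$cs$time_s),
        value = fmt(s$cs$nrs), temperature_c = "",
        stringsAsFactors = FALSE)
    do.call(rbind, out)
  })
  traces <- do.call(rbind, trace_rows)
  meta_path <- file.path(dir, "cohort.csv")
  traces_path <- file.path(dir, "traces.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(traces, traces_path, row.names = FALSE, quote = FALSE)
  invisible(c(metadata = meta_path, traces = traces_path))
}
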