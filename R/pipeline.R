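# End-to-end orchestration: simulate (or load) -> score -> cluster ->
# report, with the two summary tables (demographics by cluster;
# indicator variables and category counts by cluster + controls).

#' Round half up at a fixed number of decimals
#'
#' Report tables use commercial (half-up) rounding, e.g. `271/608` as a
#' percentage prints as 44.57.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Pipeline run configuration
#'
#' Exactly one of `sim_config` (a [generator_config()]) or the pair
#' `metadata_path`/`traces_path` must be supplied.
#'
#' @param sim_config Optional `generator_config` for a simulated cohort.
#' @param metadata_path,traces_path Optional paths to an existing cohort.
#' @param k_min,k_max Candidate partition range for the clustering.
#' @param seed Seed for the consolidation (and reporting reproducibility).
#' @param out_dir Output directory for the report bundle.
#' @param precision Decimal places for report tables.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim_config = NULL, metadata_path = NULL,
                       traces_path = NULL, k_min = 2, k_max = 6,
                       seed = 1L, out_dir = "results", precision = 2) {
  has_sim <- !is.null(sim_config)
  has_paths <- !is.null(metadata_path) || !is.null(traces_path)
  if (has_sim == has_paths)
    stop("supply exactly one of sim_config or metadata_path/traces_path")
  if (has_paths && (is.null(metadata_path) || is.null(traces_path)))
    stop("both metadata_path and traces_path are required")
  structure(list(sim_config = sim_config, metadata_path = metadata_path,
                 traces_path = traces_path, k_min = k_min, k_max = k_max,
                 seed = as.integer(seed), out_dir = out_dir,
                 precision = precision),
            class = "run_config")
}

#' Category contingency tables by cluster (plus controls)
#'
#' Cross-tabulates the TSP1, TSP2 and CPM category labels against the
#' cluster columns and a control column, and runs [pearson_chi2()] on
#' each table (all-zero category rows are dropped before the test, which
#' is noted in the result).
#'
#' @param patient_scores Score rows of the clustered patients.
#' @param assignments Integer cluster labels aligned with
#'   `patient_scores`.
#' @param control_scores Score rows of the control participants (may have
#'   zero rows).
#' @return Named list (`tsp1_class`, `tsp2_class`, `cpm_class`); each
#'   entry has `counts`, `chi2`, and `dropped_rows`.
#' @export
report_category_table <- function(patient_scores, assignments,
                                  control_scores) {
  stopifnot(nrow(patient_scores) == length(assignments))
  specs <- list(
    tsp1_class = c("DECREASE", "CONSTANT", "INCREASE"),
    tsp2_class = c("DECREASE", "CONSTANT", "INCREASE"),
    cpm_class = c("INEFFICIENT", "SUBOPTIMAL", "OPTIMAL"))
  cols <- c(paste0("cluster", sort(unique(assignments))),
            if (nrow(control_scores) > 0) "control")
  out <- list()
  for (var in names(specs)) {
    cats <- specs[[var]]
    counts <- matrix(0L, nrow = length(cats), ncol = length(cols),
                     dimnames = list(cats, cols))
    for (kk in sort(unique(assignments))) {
      tb <- table(factor(patient_scores[[var]][assignments == kk],
                         levels = cats))
      counts[, paste0("cluster", kk)] <- as.integer(tb)
    }
    if (nrow(control_scores) > 0)
      counts[, "control"] <- as.integer(
        table(factor(control_scores[[var]], levels = cats)))
    dropped <- rownames(counts)[rowSums(counts) == 0]
    test_counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    chi2 <- if (nrow(test_counts) >= 2L && ncol(test_counts) >= 2L)
      pearson_chi2(test_counts) else NULL
    out[[var]] <- list(counts = counts, chi2 = chi2,
                       dropped_rows = dropped)
  }
  out
}

fmt_count_pct <- function(n, total, precision = 2) {
  sprintf("%d (%s)", n,
          format(round_half_up(100 * n / total, precision), nsmall = precision))
}

fmt_mean_sd <- function(x, precision = 2) {
  sprintf("%s ± %s",
          format(round_half_up(mean(x), precision), nsmall = precision),
          format(round_half_up(stats::sd(x), precision), nsmall = precision))
}

# Demographics by cluster with chi-squared / gender-controlled ANOVA
# columns (patients only).
make_table1 <- function(patient_scores, assignments, cohort,
                        precision = 2) {
  ks <- sort(unique(assignments))
  n_by <- table(assignments)
  desc <- lapply(patient_scores$participant_id, function(pid)
    cohort$sessions[[pid]]$descriptors)
  pain_before <- vapply(patient_scores$participant_id, function(pid)
    cohort$sessions[[pid]]$pain_before_nrs, numeric(1))
  recruitment <- vapply(patient_scores$participant_id, function(pid)
    cohort$sessions[[pid]]$recruitment, character(1))
  get_desc <- function(field) vapply(desc, function(d)
    as.character(d[[field]] %||% NA_character_), character(1))

  rows <- list()
  add_row <- function(variable, level, cells, statistic = NA_real_,
                      p = NA_real_, test = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level,
      t(stats::setNames(cells, paste0("cluster", ks))),
      statistic = statistic, p_value = p, test = test,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  cat_block <- function(variable, values) {
    values <- factor(values)
    tab <- table(values, assignments)
    test <- tryCatch(pearson_chi2(as.matrix(tab)),
                     error = function(e) NULL)
    add_row(variable, "",
            rep("", length(ks)),
            statistic = if (is.null(test)) NA_real_ else
              round_half_up(test$statistic, precision),
            p = if (is.null(test)) NA_real_ else
              round_half_up(test$p_value, 3),
            test = "chi2")
    for (lv in levels(values))
      add_row(variable, lv, vapply(seq_along(ks), function(j)
        fmt_count_pct(tab[lv, j], n_by[[j]], precision), character(1)))
  }
  num_block <- function(variable, values) {
    ok <- !is.na(values)
    test <- tryCatch(
      anova_gender_controlled(values[ok], assignments[ok],
                              patient_scores$gender[ok]),
      error = function(e) NULL)
    add_row(variable, "mean_sd", vapply(ks, function(kk)
      fmt_mean_sd(values[ok & assignments == kk], precision), character(1)),
      statistic = if (is.null(test)) NA_real_ else
        round_half_up(test$F_group, precision),
      p = if (is.null(test)) NA_real_ else round_half_up(test$p_value, 3),
      test = "anova_gender_controlled")
  }

  cat_block("recruitment", recruitment)
  num_block("age_years", patient_scores$age_years)
  cat_block("gender", patient_scores$gender)
  cat_block("pain_duration", get_desc("duration"))
  cat_block("pain_pattern", get_desc("pattern"))
  cat_block("primary_location", get_desc("primary_location"))
  cat_block("secondary_pain_sites", get_desc("secondary_sites"))
  cat_block("pain_before_assessment",
            ifelse(is.na(pain_before), "NO", "YES"))
  num_block("pain_before_intensity", pain_before)
  do.call(rbind, rows)
}

scheffe_letters <- function(pairs, groups, alpha = 0.05) {
  letters_by <- stats::setNames(rep("", length(groups)), groups)
  code <- stats::setNames(letters[seq_along(groups)], groups)
  for (i in seq_len(nrow(pairs))) {
    if (pairs$p_value[i] < alpha) {
      a <- pairs$group_a[i]; b <- pairs$group_b[i]
      letters_by[a] <- paste0(letters_by[a], code[b])
      letters_by[b] <- paste0(letters_by[b], code[a])
    }
  }
  letters_by
}

# Indicator variables and category counts by cluster + controls, with
# gender-controlled ANOVA, omega^2 and Scheffe letter codes.
make_table2 <- function(patient_scores, assignments, control_scores,
                        precision = 2) {
  ks <- sort(unique(assignments))
  group_label <- c(paste0("cluster", assignments),
                   rep("control", nrow(control_scores)))
  group_label <- factor(group_label,
                        levels = c(paste0("cluster", ks), "control"))
  gender <- c(patient_scores$gender, control_scores$gender)
  vars <- c(threshold_c = "heat_pain_threshold_c",
            t50_c = "test_temperature_c",
            tsp1 = "tsp1_covas", cs_mean = "cs_mean_nrs",
            tsp2 = "tsp2_covas", cpm_pct = "cpm_efficiency_pct")
  rows <- list()
  for (v in names(vars)) {
    values <- c(patient_scores[[v]], control_scores[[v]])
    ok <- !is.na(values)
    fit <- anova_gender_controlled(values[ok], group_label[ok], gender[ok])
    sch <- scheffe_pairwise(values[ok], group_label[ok], gender[ok])
    lets <- scheffe_letters(sch, levels(group_label))
    cells <- vapply(levels(group_label), function(g) {
      xs <- values[ok & group_label == g]
      paste0(fmt_mean_sd(xs, precision),
             if (nzchar(lets[g])) paste0(" [", lets[g], "]") else "")
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = vars[[v]], level = "mean_sd",
      t(cells), statistic = round_half_up(fit$F_group, precision),
      p_value = round_half_up(fit$p_value, 3),
      omega_sq = round_half_up(fit$omega_sq, precision),
      magnitude = fit$magnitude, test = "anova_gender_controlled",
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  tables <- report_category_table(patient_scores, assignments,
                                  control_scores)
  var_of <- c(tsp1_class = "tsp1_covas", tsp2_class = "tsp2_covas",
              cpm_class = "cpm_efficiency_pct")
  for (v in names(tables)) {
    tb <- tables[[v]]
    n_col <- colSums(tb$counts)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = var_of[[v]], level = "categories",
      t(stats::setNames(rep("", ncol(tb$counts)), colnames(tb$counts))),
      statistic = if (is.null(tb$chi2)) NA_real_ else
        round_half_up(tb$chi2$statistic, precision),
      p_value = if (is.null(tb$chi2)) NA_real_ else
        round_half_up(tb$chi2$p_value, 3),
      omega_sq = NA_real_, magnitude = NA_character_, test = "chi2",
      stringsAsFactors = FALSE, check.names = FALSE)
    for (lv in rownames(tb$counts))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = var_of[[v]], level = lv,
        t(vapply(seq_along(n_col), function(j)
          fmt_count_pct(tb$counts[lv, j], n_col[j], precision),
          character(1), USE.NAMES = FALSE) |>
            stats::setNames(colnames(tb$counts))),
        statistic = NA_real_, p_value = NA_real_, omega_sq = NA_real_,
        magnitude = NA_character_, test = NA_character_,
        stringsAsFactors = FALSE, check.names = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full phenotyping pipeline
#'
#' Simulates (or loads) a cohort, retains complete sessions, scores them,
#' clusters the patients on the four z-scored indicators, and writes the
#' report bundle: `scores.csv`, `assignments.csv`, `diagnostics.json`,
#' `table1.csv` (demographics by cluster), `table2.csv` (indicators and
#' category counts by cluster + controls), `exclusions.csv` and
#' `manifest.json` (seed, sizes, and every clipping/resampling event).
#'
#' @param config A [run_config()].
#' @return The bundle as a list (`scores`, `exclusions`, `clusters`,
#'   `table1`, `table2`, `category_tables`, `paths`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  events <- character(0)
  if (!is.null(config$sim_config)) {
    sim <- generate_cohort(config$sim_config)
    cohort <- sim$cohort
    latent <- sim$latent
    events <- sim$events
  } else {
    cohort <- read_cohort(config$metadata_path, config$traces_path)
    latent <- NULL
  }
  scored <- score_cohort(cohort)
  scores <- scored$scores
  patients <- scores[scores$group == "PATIENT", , drop = FALSE]
  controls <- scores[scores$group == "CONTROL", , drop = FALSE]
  clusters <- cluster_cohort(patients, k_min = config$k_min,
                             k_max = config$k_max, seed = config$seed)
  idx <- match(clusters$participant_ids, patients$participant_id)
  cpat <- patients[idx, , drop = FALSE]
  tab1 <- make_table1(cpat, clusters$labels, cohort, config$precision)
  tab2 <- make_table2(cpat, clusters$labels, controls, config$precision)
  cat_tables <- report_category_table(cpat, clusters$labels, controls)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    scores = file.path(config$out_dir, "scores.csv"),
    assignments = file.path(config$out_dir, "assignments.csv"),
    diagnostics = file.path(config$out_dir, "diagnostics.json"),
    table1 = file.path(config$out_dir, "table1.csv"),
    table2 = file.path(config$out_dir, "table2.csv"),
    exclusions = file.path(config$out_dir, "exclusions.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_scores(scores, paths$scores)
  utils::write.csv(data.frame(participant_id = clusters$participant_ids,
                              cluster = clusters$labels),
                   paths$assignments, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(k = clusters$k, within_by_k = clusters$within_by_k,
         delta = as.list(clusters$delta),
         explained_fraction = clusters$explained_fraction,
         cluster_sizes = as.list(table(clusters$labels)),
         seed = clusters$seed),
    paths$diagnostics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(tab1, paths$table1, row.names = FALSE)
  utils::write.csv(tab2, paths$table2, row.names = FALSE)
  utils::write.csv(scored$exclusions, paths$exclusions, row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         simulated = !is.null(config$sim_config),
         n_sessions = length(cohort$sessions),
         n_scored = nrow(scores),
         n_patients_clustered = length(clusters$labels),
         n_excluded = nrow(scored$exclusions),
         k = clusters$k,
         events = events,
         consolidation_events = clusters$consolidation_events,
         r_version = as.character(getRversion())),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(scores = scores, exclusions = scored$exclusions,
                 clusters = clusters, latent = latent,
                 table1 = tab1, table2 = tab2,
                 category_tables = cat_tables, paths = paths))
}
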