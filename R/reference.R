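# Published cross-tabulations of the pediatric chronic-pain CPM cohort
# (n = 608 patients in three phenotype clusters, n = 60 controls) that the
# synthetic generator emulates. These printed counts are the inputs for the
# chi-squared reproduction checks; the statistics are always recomputed.

#' Published category counts of the emulated cohort
#'
#' Integer contingency tables as printed for the original clinical cohort:
#' CPM-efficiency, TSP1 and TSP2 category counts across the three patient
#' clusters and the control group, and demographic cross-tabulations
#' (gender, recruitment site, pain duration, secondary pain sites) across
#' the three clusters.
#'
#' @return Named list of integer matrices with informative dimnames.
#' @export
published_category_tables <- function() {
  cl <- c("cluster1", "cluster2", "cluster3")
  clc <- c(cl, "control")
  list(
    cpm_class = matrix(
      c(45, 44, 97, 14,
        61, 44, 24, 12,
        165, 98, 30, 34), nrow = 3, byrow = TRUE,
      dimnames = list(c("INEFFICIENT", "SUBOPTIMAL", "OPTIMAL"), clc)),
    tsp1_class = matrix(
      c(73, 12, 6, 5,
        189, 139, 102, 43,
        9, 35, 43, 12), nrow = 3, byrow = TRUE,
      dimnames = list(c("DECREASE", "CONSTANT", "INCREASE"), clc)),
    tsp2_class = matrix(
      c(39, 11, 7, 4,
        222, 157, 86, 47,
        10, 18, 58, 9), nrow = 3, byrow = TRUE,
      dimnames = list(c("DECREASE", "CONSTANT", "INCREASE"), clc)),
    gender = matrix(
      c(218, 156, 118,
        53, 30, 33), nrow = 2, byrow = TRUE,
      dimnames = list(c("FEMALE", "MALE"), cl)),
    recruitment = matrix(
      c(106, 81, 72,
        165, 105, 79), nrow = 2, byrow = TRUE,
      dimnames = list(c("PAIN_CLINIC", "OUTPATIENT"), cl)),
    duration = matrix(
      c(18, 9, 13,
        253, 177, 138), nrow = 2, byrow = TRUE,
      dimnames = list(c("3_6MO", "MORE_THAN_6MO"), cl)),
    secondary_sites = matrix(
      c(139, 94, 65,
        132, 92, 86), nrow = 2, byrow = TRUE,
      dimnames = list(c("NO", "YES"), cl)))
}

#' Published cluster sizes of the emulated cohort
#'
#' @return Named integer vector (`cluster1`, `cluster2`, `cluster3`).
#' @export
published_cluster_sizes <- function() {
  c(cluster1 = 271L, cluster2 = 186L, cluster3 = 151L)
}
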