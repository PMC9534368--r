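# Patient phenotyping: z-scored indicator matrix -> Ward hierarchy ->
# partition by highest relative loss of inertia -> k-means consolidation.
#
# Inertia is the sum of squared Euclidean distances to a centroid; Ward
# merge heights are reported as the inertia gain of each merge, so the
# heights sum to the total inertia of the standardized data.

INDICATOR_COLUMNS <- c("tsp1", "cs_mean", "tsp2", "cpm_pct")

#' Build the indicator matrix for clustering
#'
#' Selects the four quantitative indicators (TSP1, CS mean pain, TSP2,
#' CPM efficiency) from a score table, dropping rows with any undefined
#' indicator.
#'
#' @param scores Score data frame (see [score_cohort()]).
#' @param patients_only Keep only `group == "PATIENT"` rows (controls are
#'   held out of the clustering and compared post hoc).
#' @return A list of class `indicator_matrix`: `values` (n x 4 matrix),
#'   `participant_ids`, `standardized` flag, `center`, `scale`.
#' @export
indicator_matrix <- function(scores, patients_only = TRUE) {
  stopifnot(is.data.frame(scores),
            all(INDICATOR_COLUMNS %in% names(scores)))
  if (patients_only && "group" %in% names(scores))
    scores <- scores[scores$group == "PATIENT", , drop = FALSE]
  values <- as.matrix(scores[INDICATOR_COLUMNS])
  keep <- stats::complete.cases(values)
  values <- values[keep, , drop = FALSE]
  structure(list(values = values,
                 participant_ids = scores$participant_id[keep],
                 standardized = FALSE,
                 center = NULL, scale = NULL),
            class = "indicator_matrix")
}

#' Standardize indicator columns to z-scores
#'
#' Centers each column and divides by its population standard deviation
#' (divisor n), so that after standardization the total inertia equals
#' `ncol * n`.
#'
#' @param m An `indicator_matrix`.
#' @return The standardized `indicator_matrix` (with `center` and `scale`
#'   recorded).
#' @export
standardize <- function(m) {
  stopifnot(inherits(m, "indicator_matrix"))
  x <- m$values
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sdp <- sqrt(colMeans(xc^2))
  if (any(zero <- sdp <= 0))
    stop("zero-variance indicator column(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  m$values <- sweep(xc, 2, sdp, "/")
  m$standardized <- TRUE
  m$center <- ctr
  m$scale <- sdp
  m
}

# Within-cluster inertia of a labelled partition.
within_inertia <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(i) {
    xi <- x[i, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}

total_inertia <- function(x) sum(sweep(x, 2, colMeans(x))^2)

#' Ward hierarchy on the standardized indicators
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean distances. Merge heights are the within-cluster inertia gain
#' of each merge (the hierarchy is computed on squared Euclidean
#' dissimilarities divided by two), so `sum(heights)` equals the total
#' inertia.
#'
#' @param z A standardized `indicator_matrix` or plain numeric matrix.
#' @return A list of class `ward_tree` with the underlying
#'   [stats::hclust] object (`hclust`), `heights`, and `n`.
#' @export
ward_tree <- function(z) {
  x <- if (inherits(z, "indicator_matrix")) z$values else as.matrix(z)
  if (nrow(x) < 2L) stop("need at least 2 points")
  d <- stats::as.dist(as.matrix(stats::dist(x))^2 / 2)
  hc <- stats::hclust(d, method = "ward.D")
  structure(list(hclust = hc, heights = hc$height, n = nrow(x)),
            class = "ward_tree")
}

#' Choose the partition by highest relative loss of inertia
#'
#' For each candidate k, `W(k)` is the within-cluster inertia of the
#' k-cluster cut of the hierarchy; the relative loss is
#' `delta(k) = (W(k-1) - W(k)) / W(k-1)`. The chosen k maximizes
#' `delta(k)` over `k_min..k_max`, ties broken toward smaller k
#' (parsimony).
#'
#' @param tree A `ward_tree`.
#' @param z The matrix the tree was built on.
#' @param k_min,k_max Candidate range (defaults 2..6).
#' @return List with `k`, `within` (W(1)..W(k_max)) and `delta`
#'   (named, k = 2..k_max).
#' @export
select_partition <- function(tree, z, k_min = 2, k_max = 6) {
  stopifnot(inherits(tree, "ward_tree"))
  x <- if (inherits(z, "indicator_matrix")) z$values else as.matrix(z)
  if (tree$n < k_max) stop("fewer points than k_max")
  W <- vapply(seq_len(k_max), function(k)
    within_inertia(x, stats::cutree(tree$hclust, k)), numeric(1))
  delta <- (W[seq_len(k_max - 1)] - W[-1]) / W[seq_len(k_max - 1)]
  names(delta) <- as.character(2:k_max)
  cand <- delta[as.character(k_min:k_max)]
  best <- max(cand)
  k <- as.integer(names(cand)[which(cand >= best - 1e-12)[1]])
  list(k = k, within = W, delta = delta)
}

#' Consolidate a hierarchical partition by k-means
#'
#' Lloyd iterations initialized at the centroids of the hierarchical
#' partition, run until the maximum centroid shift falls below `tol` or
#' `max_iter` iterations. Should a cluster empty during iteration, the
#' point farthest from its assigned centroid is reassigned to it (logged
#' in the returned `events`). Within-cluster inertia never increases.
#'
#' @param z Standardized `indicator_matrix` or matrix.
#' @param labels Integer cluster labels of the initial partition.
#' @param seed RNG seed (governs only tie-breaking).
#' @param max_iter,tol Convergence controls.
#' @return List with `labels`, `centroids`, `iterations`, `within`, and
#'   `events` (character log).
#' @export
kmeans_consolidate <- function(z, labels, seed = 1L, max_iter = 100L,
                               tol = 1e-8) {
  x <- if (inherits(z, "indicator_matrix")) z$values else as.matrix(z)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x))
  set.seed(seed)
  k <- length(unique(labels))
  levs <- sort(unique(labels))
  labels <- match(labels, levs)
  centroids <- t(vapply(seq_len(k), function(j)
    colMeans(x[labels == j, , drop = FALSE]), numeric(ncol(x))))
  events <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- vapply(seq_len(k), function(j)
      rowSums(sweep(x, 2, centroids[j, ])^2), numeric(nrow(x)))
    assign <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(assign == j)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
        events <- c(events, sprintf(
          "iteration %d: cluster %d emptied; reassigned farthest point %d",
          iter, j, far))
        assign[far] <- j
      }
    }
    new_centroids <- t(vapply(seq_len(k), function(j)
      colMeans(x[assign == j, , drop = FALSE]), numeric(ncol(x))))
    shift <- sqrt(max(rowSums((new_centroids - centroids)^2)))
    centroids <- new_centroids
    labels <- assign
    if (shift < tol || iter >= max_iter) break
  }
  list(labels = labels, centroids = centroids, iterations = iter,
       within = within_inertia(x, labels), events = events)
}

#' Cluster a scored cohort on the four indicators
#'
#' Full phenotyping pipeline: standardize the indicator matrix, build the
#' Ward hierarchy, choose k by highest relative loss of inertia, and
#' consolidate with k-means started from the hierarchical centroids.
#' Cluster ids are renumbered in decreasing cluster size (cluster 1 is
#' the largest).
#'
#' @param scores Score data frame; only patients with all four indicators
#'   defined enter the clustering.
#' @param k_min,k_max Candidate partition range.
#' @param seed RNG seed passed to the consolidation.
#' @return An object of class `cluster_result`: `k`, `participant_ids`,
#'   `labels_hierarchical`, `labels` (consolidated, renumbered by size),
#'   `merge_heights`, `within_by_k`, `delta`, `explained_fraction`,
#'   `within`, `total`, `seed`, `center`, `scale`, `consolidation_events`.
#' @export
cluster_cohort <- function(scores, k_min = 2, k_max = 6, seed = 1L) {
  z <- standardize(indicator_matrix(scores))
  tree <- ward_tree(z)
  sel <- select_partition(tree, z, k_min = k_min, k_max = k_max)
  h_labels <- stats::cutree(tree$hclust, sel$k)
  cons <- kmeans_consolidate(z, h_labels, seed = seed)
  tot <- total_inertia(z$values)
  renumber <- function(lab) {
    sizes <- table(lab)
    ord <- order(-as.integer(sizes), as.integer(names(sizes)))
    match(lab, as.integer(names(sizes))[ord])
  }
  structure(list(k = sel$k,
                 participant_ids = z$participant_ids,
                 labels_hierarchical = renumber(h_labels),
                 labels = renumber(cons$labels),
                 merge_heights = tree$heights,
                 within_by_k = sel$within,
                 delta = sel$delta,
                 within = cons$within,
                 total = tot,
                 explained_fraction = 1 - cons$within / tot,
                 seed = seed,
                 center = z$center, scale = z$scale,
                 consolidation_events = cons$events),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k = %d over %d patients; sizes %s; %.2f%% of total inertia between clusters>\n",
              x$k, length(x$labels),
              paste(table(x$labels), collapse = "/"),
              100 * x$explained_fraction))
  invisible(x)
}
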