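mk_im <- function(x) {
  colnames(x) <- INDICATOR_COLS_FOR_TESTS[seq_len(ncol(x))]
  structure(list(values = x, participant_ids = paste0("P", seq_len(nrow(x))),
                 standardized = FALSE, center = NULL, scale = NULL),
            class = "indicator_matrix")
}
INDICATOR_COLS_FOR_TESTS <- c("tsp1", "cs_mean", "tsp2", "cpm_pct")

test_that("standardization centers to z-scores with the population SD", {
  im <- mk_im(cbind(c(1, 2, 3), c(4, 0, 2), c(1, 1, 2), c(0, 5, 10)))
  z <- standardize(im)
  expect_equal(z$values[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(colMeans(z$values)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(sqrt(colMeans(sweep(z$values, 2,
                                          colMeans(z$values))^2))),
               rep(1, 4), tolerance = 1e-9)
  # idempotence and the 4n total-inertia identity
  z2 <- standardize(z)
  expect_equal(z2$values, z$values, tolerance = 1e-9)
  expect_equal(sum(sweep(z$values, 2, colMeans(z$values))^2), 4 * 3,
               tolerance = 1e-9)
  # zero-variance column named in the error
  bad <- mk_im(cbind(c(1, 2, 3), c(5, 5, 5), c(1, 0, 2), c(3, 2, 1)))
  expect_error(standardize(bad), "cs_mean")
})

test_that("Ward heights are inertia gains and sum to the total inertia", {
  # two points distance d apart merge at height d^2/2
  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  tw <- ward_tree(two)
  expect_equal(tw$heights, 25 / 2)
  # sum of merge heights equals the total inertia (random matrices)
  for (seed in 1:5) {
    x <- fix_matrix(n = 20 + seed, seed = seed)
    tr <- ward_tree(x)
    expect_equal(sum(tr$heights), sum(sweep(x, 2, colMeans(x))^2),
                 tolerance = 1e-8)
  }
  # a far outlier is absorbed last
  x <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(50, 50))
  tr <- ward_tree(x)
  expect_equal(which.max(tr$heights), 3)
  expect_true(4 %in% abs(tr$hclust$merge[3, ]))
})

test_that("inertia decomposes as total = within + between at every cut", {
  for (seed in 1:5) {
    x <- fix_matrix(n = 25, seed = seed)
    tr <- ward_tree(x)
    total <- sum(sweep(x, 2, colMeans(x))^2)
    for (k in 1:6) {
      lab <- stats::cutree(tr$hclust, k)
      within <- sum(vapply(split(seq_len(nrow(x)), lab), function(i) {
        xi <- x[i, , drop = FALSE]
        sum(sweep(xi, 2, colMeans(xi))^2)
      }, numeric(1)))
      between <- sum(vapply(split(seq_len(nrow(x)), lab), function(i)
        length(i) * sum((colMeans(x[i, , drop = FALSE]) - colMeans(x))^2),
        numeric(1)))
      expect_equal(total, within + between, tolerance = 1e-8)
    }
  }
})

test_that("partition selection finds well-separated blob counts", {
  blobs <- function(centers, n_per, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      sweep(matrix(stats::rnorm(n_per * ncol(centers)), n_per), 2,
            centers[i, ], "+")))
  }
  # three blobs, centres 6 SD apart
  x3 <- blobs(rbind(c(0, 0), c(6, 0), c(3, 6)), 100, seed = 5)
  z3 <- scale(x3) * sqrt(nrow(x3) / (nrow(x3) - 1))
  tr3 <- ward_tree(z3)
  expect_equal(select_partition(tr3, z3)$k, 3)
  # two blobs
  x2 <- blobs(rbind(c(0, 0), c(6, 6)), 100, seed = 6)
  z2 <- scale(x2) * sqrt(nrow(x2) / (nrow(x2) - 1))
  expect_equal(select_partition(ward_tree(z2), z2)$k, 2)
})

test_that("exact relative-loss ties resolve to the smaller k", {
  # square corners: W(1)=2a^2, W(2)=a^2, W(3)=a^2/2 so delta(2)=delta(3)=1/2
  sq <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  tr <- ward_tree(sq)
  sel <- select_partition(tr, sq, k_min = 2, k_max = 3)
  expect_equal(unname(sel$delta["2"]), unname(sel$delta["3"]))
  expect_equal(sel$k, 2)
})

test_that("k-means consolidation is a fixed point / descent / repair method", {
  # already-optimal partition is unchanged
  set.seed(3)
  x <- rbind(matrix(stats::rnorm(60, 0), 30), matrix(stats::rnorm(60, 8), 30))
  lab <- rep(1:2, each = 30)
  cons <- kmeans_consolidate(x, lab, seed = 1)
  expect_equal(cons$labels, lab)
  # 5% mislabelled points are restored to their blobs
  lab_bad <- lab
  flip <- c(2, 17, 44)
  lab_bad[flip] <- 3 - lab_bad[flip]
  cons2 <- kmeans_consolidate(x, lab_bad, seed = 1)
  agree <- max(mean(cons2$labels == lab), mean(cons2$labels == 3 - lab))
  expect_equal(agree, 1)
  # matches stats::kmeans started from the same centroids
  cent <- rbind(colMeans(x[lab_bad == 1, ]), colMeans(x[lab_bad == 2, ]))
  km <- stats::kmeans(x, centers = cent, algorithm = "Lloyd", iter.max = 100)
  expect_equal(cons2$labels, unname(km$cluster))
  # descent: consolidation never increases within-cluster inertia
  wi <- function(x, f) sum(vapply(split(seq_len(nrow(x)), f), function(i) {
    xi <- x[i, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
  for (seed in 1:20) {
    set.seed(seed)
    xr <- fix_matrix(n = 40, seed = seed)
    labr <- sample(1:3, 40, replace = TRUE)
    before <- wi(xr, labr)
    expect_lte(kmeans_consolidate(xr, labr, seed = seed)$within,
               before + 1e-9)
  }
})

test_that("cluster_cohort renumbers by size and is permutation invariant", {
  set.seed(9)
  sim <- generate_cohort(generator_config(n_patients = 120, n_controls = 0,
                                          seed = 9, incomplete_fraction = 0))
  scores <- score_cohort(sim$cohort)$scores
  cl <- cluster_cohort(scores, seed = 9)
  sizes <- as.integer(table(cl$labels))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(cl$labels %in% seq_len(cl$k)))
  expect_true(all(diff(cl$within_by_k) <= 1e-9))
  expect_gte(cl$explained_fraction, 0)
  expect_lte(cl$explained_fraction, 1)
  # permutation of rows changes nothing but the ordering
  perm <- sample(nrow(scores))
  clp <- cluster_cohort(scores[perm, ], seed = 9)
  m <- match(cl$participant_ids, clp$participant_ids)
  tab <- table(cl$labels, clp$labels[m])
  expect_equal(sum(apply(tab, 1, max)), length(cl$labels))
  # identical rows cannot be standardized
  const <- scores[rep(1, 10), ]
  const$participant_id <- paste0("Q", 1:10)
  expect_error(cluster_cohort(const), "zero-variance")
})
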