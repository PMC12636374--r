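make_blobs <- function(centers, n_per, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
    list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

test_that("silhouette maximization recovers the planted cluster number", {
  two <- make_blobs(rbind(c(0, 0), c(12, 0)), 8, seed = 2)
  sel2 <- choose_k(two$X, 2:6, seed = 10)
  expect_equal(sel2$k, 2L)
  expect_gt(sel2$metrics$silhouette[sel2$metrics$k == 2], 0.8)
  three <- make_blobs(rbind(c(0, 0), c(14, 0), c(0, 14)), 7, seed = 4)
  expect_equal(choose_k(three$X, 2:6, seed = 10)$k, 3L)
  expect_error(choose_k(two$X[1:2, ], 3:6), "fewer models")
})

test_that("validity indices agree with the reference implementations", {
  b <- make_blobs(rbind(c(0, 0), c(6, 1)), 6, sd = 1, seed = 8)
  lab <- kmeans_labels <- screenkit::cluster_models(b$X, 2)$assignments$cluster + 1L
  csv <- withr::local_tempfile(fileext = ".csv")
  write.table(cbind(b$X, lab), csv, sep = ",", row.names = FALSE,
              col.names = FALSE)
  script <- paste(
    "import sys, numpy as np",
    "from sklearn import metrics",
    "d = np.loadtxt(sys.argv[1], delimiter=',')",
    "X, y = d[:, :2], d[:, 2]",
    "print(metrics.silhouette_score(X, y))",
    "print(metrics.davies_bouldin_score(X, y))",
    "print(metrics.calinski_harabasz_score(X, y))",
    sep = "\n")
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(script, py)
  ref <- as.numeric(system2("python", c(py, csv), stdout = TRUE))
  expect_equal(screenkit:::silhouette_mean(b$X, lab), ref[1], tolerance = 1e-6)
  expect_equal(screenkit:::davies_bouldin(b$X, lab), ref[2], tolerance = 1e-6)
  expect_equal(screenkit:::calinski_harabasz(b$X, lab), ref[3],
               tolerance = 1e-6)
})

test_that("k-means labels recover a planted partition and renumber by size", {
  b <- make_blobs(rbind(c(0, 0), c(15, 0)), 5, seed = 6)
  X <- rbind(b$X, matrix(rnorm(4 * 2, sd = 0.3), 4) +
               matrix(c(15, 0), 4, 2, byrow = TRUE))
  planted <- c(b$labels, c(2, 2, 2, 2))
  fit <- cluster_models(X, 2, seed = 3)
  # adjusted agreement: identical partition up to relabeling
  tab <- table(fit$assignments$cluster, planted)
  expect_equal(sum(apply(tab, 1, max)), nrow(X))
  # cluster 0 is the larger one
  expect_equal(fit$occupancy$cluster, c(0L, 1L))
  expect_true(all(diff(fit$occupancy$n_models) <= 0))
  expect_equal(sum(fit$occupancy$n_models), nrow(X))
  # k = 1 puts everything in one cluster
  one <- cluster_models(X, 1)
  expect_true(all(one$assignments$cluster == 0L))
})

test_that("consensus outliers are excluded from the fit but assigned for occupancy", {
  b <- make_blobs(rbind(c(0, 0), c(15, 0)), 5, seed = 6)
  X <- rbind(b$X, c(500, 500))
  out <- c(rep(FALSE, 10), TRUE)
  fit <- cluster_models(X, 2, outlier = out, seed = 3)
  expect_equal(sum(fit$occupancy$n_models), 11L)
  expect_true(fit$assignments$excluded[11])
  expect_true(fit$assignments$cluster[11] %in% c(0L, 1L))
})

test_that("representative voting picks the central member", {
  # three collinear flattened-coordinate points: B is the midpoint
  ids <- c(10L, 20L, 30L)
  X <- rbind(c(0, 0), c(1, 0), c(2, 0))
  rownames(X) <- ids
  mat <- as.matrix(dist(X))
  dimnames(mat) <- list(ids, ids)
  sel <- select_representative(ids, mat, X)
  expect_equal(sel$representative, 20L)
  expect_equal(nrow(sel$votes), 4L)
  expect_true(all(sel$votes$candidate == 20L |
                    sel$votes$method == "density"))
  # singleton: its only member with all four votes
  s <- select_representative(10L, mat, X)
  expect_equal(s$representative, 10L)
  expect_equal(unique(s$votes$candidate), 10L)
  expect_error(select_representative(integer(), mat, X), "empty cluster")
})

test_that("quality scores are bounded, perfect for singletons, and monotone", {
  ids <- 1:4
  mat <- matrix(c(0, 1, 1, 1.5,
                  1, 0, 1.2, 1.8,
                  1, 1.2, 0, 2.2,
                  1.5, 1.8, 2.2, 0), 4, 4, dimnames = list(ids, ids))
  q <- representative_quality(1L, ids, mat)
  expect_gte(q$score, 0); expect_lte(q$score, 1)
  expect_equal(representative_quality(3L, 3L, mat)$score, 1.0)
  # inflating the representative's distances lowers its score
  worse <- mat
  worse[1, -1] <- worse[-1, 1] <- worse[1, -1] + 1.2
  expect_lt(representative_quality(1L, ids, worse)$score, q$score)
  expect_error(representative_quality(9L, ids, mat), "not in cluster")
})

test_that("quality components match a hand-computed example", {
  ids <- 1:3
  mat <- matrix(c(0, 1, 3,
                  1, 0, 4,
                  3, 4, 0), 3, 3, dimnames = list(ids, ids))
  # avg RMSD: model1 = 2, model2 = 2.5, model3 = 3.5; max: 3, 4, 4
  q <- representative_quality(1L, ids, mat)
  expect_equal(q$components$n_avg, 1)            # best avg
  expect_equal(q$components$n_max, 1)            # best max
  expect_equal(q$components$coverage, 0.5)       # member 2 within 2 A, 3 not
  expect_equal(q$components$centrality, 1)       # rank 1 -> 1/1
  expect_equal(q$score, 0.35 + 0.25 + 0.25 * 0.5 + 0.15)
})

test_that("cluster diversity reports pair statistics with the singleton convention", {
  ids <- 1:3
  mat <- matrix(c(0, 3, 3, 3, 0, 3, 3, 3, 0), 3, 3,
                dimnames = list(ids, ids))
  d <- cluster_diversity(1:2, mat)
  expect_equal(d$mean_intra_rmsd, 3)
  expect_equal(d$diameter, 3)
  expect_equal(d$compactness, 1)  # intra mean equals global mean here
  s <- cluster_diversity(2L, mat)
  expect_equal(unlist(s[, 1:3]),
               c(mean_intra_rmsd = 0, diameter = 0, compactness = 1))
})

test_that("PCA ratios are a non-increasing unit partition and catch rank-1 data", {
  withr::local_seed(12)
  direction <- rnorm(6)
  X <- outer(rnorm(8), direction)  # rank-1 variation
  p <- pca_project(X)
  expect_equal(p$explained_variance_ratio[1], 1, tolerance = 1e-10)
  Y <- matrix(rnorm(10 * 6), 10)
  py <- pca_project(Y)
  r <- py$explained_variance_ratio
  expect_equal(sum(r), 1)
  expect_true(all(diff(r) <= 1e-12))
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(nrow(py$scores), 10L)
})
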