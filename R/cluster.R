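# Internal clustering validity indices, computed in the same Euclidean
# flattened-coordinate space the k-means fit uses.

silhouette_mean <- function(X, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  mean(cluster::silhouette(labels, dist(X))[, "sil_width"])
}

davies_bouldin <- function(X, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2L) return(NA_real_)
  cent <- t(vapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]),
                   numeric(ncol(X))))
  scatter <- vapply(seq_along(ks), function(i) {
    pts <- X[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, numeric(1))
  r <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      (scatter[i] + scatter[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

calinski_harabasz <- function(X, labels) {
  ks <- sort(unique(labels))
  n <- nrow(X); k <- length(ks)
  if (k < 2L || n <= k) return(NA_real_)
  grand <- colMeans(X)
  b <- sum(vapply(ks, function(g) {
    pts <- X[labels == g, , drop = FALSE]
    nrow(pts) * sum((colMeans(pts) - grand)^2)
  }, numeric(1)))
  w <- sum(vapply(ks, function(g) {
    pts <- X[labels == g, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, numeric(1)))
  (b / (k - 1)) / (w / (n - k))
}

#' Select the cluster number by internal validity indices
#'
#' Runs k-means (20 restarts) for each candidate k and records the
#' silhouette coefficient, Davies-Bouldin index, Calinski-Harabasz score
#' and inertia (within-cluster sum of squares). The returned k maximizes
#' the silhouette coefficient; the full metric table is exposed so the
#' other indices can be inspected. `k_range` is truncated to at most
#' `n - 1` clusters.
#'
#' @param X numeric matrix (rows = models, flattened aligned coordinates),
#'   normally restricted to non-outlier models.
#' @param k_range candidate cluster numbers (default `2:6`).
#' @param n_init k-means restarts per k (default 20).
#' @param seed integer RNG seed.
#' @return list: `k` (chosen), `metrics` (tibble with one row per k:
#'   `k`, `silhouette`, `davies_bouldin`, `calinski_harabasz`, `inertia`).
#' @export
choose_k <- function(X, k_range = 2:6, n_init = 20L, seed = 20251104L) {
  X <- as.matrix(X)
  k_range <- k_range[k_range <= nrow(X) - 1L & k_range >= 1L]
  if (length(k_range) == 0L)
    abort("cluster stage: fewer models than the smallest candidate k")
  metrics <- purrr::map_dfr(k_range, function(k) {
    km <- kmeans_seeded(X, k, n_init, seed)
    tibble(k = k,
           silhouette = silhouette_mean(X, km$cluster),
           davies_bouldin = davies_bouldin(X, km$cluster),
           calinski_harabasz = calinski_harabasz(X, km$cluster),
           inertia = km$tot.withinss)
  })
  list(k = metrics$k[which.max(metrics$silhouette)], metrics = metrics)
}

kmeans_seeded <- function(X, k, n_init = 20L, seed = 20251104L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  if (k == 1L) {
    ctr <- matrix(colMeans(X), 1)
    return(list(cluster = rep(1L, nrow(X)), centers = ctr,
                tot.withinss = sum(sweep(X, 2, ctr[1, ])^2)))
  }
  kmeans(X, centers = k, nstart = n_init, iter.max = 100L)
}

#' Cluster the ensemble models with k-means
#'
#' Fits k-means (best of `n_init` restarts) on the non-outlier models'
#' flattened coordinates, then assigns each consensus outlier to its
#' nearest centroid so occupancy counts cover all M models; outliers stay
#' marked as excluded from the fit. Cluster ids are renumbered by
#' descending occupancy so cluster 0 is always the dominant basin.
#'
#' @param X numeric matrix of all models' flattened coordinates.
#' @param k number of clusters.
#' @param outlier logical vector: consensus-outlier flags per model.
#' @param model_ids model identifiers.
#' @param n_init,seed k-means restarts and RNG seed.
#' @return list: `assignments` tibble (`model`, `cluster` 0-based,
#'   `excluded`), `centers` matrix (rows named by 0-based cluster id),
#'   `occupancy` tibble (`cluster`, `n_models`, `fraction`).
#' @export
cluster_models <- function(X, k, outlier = rep(FALSE, nrow(X)),
                           model_ids = seq_len(nrow(X)),
                           n_init = 20L, seed = 20251104L) {
  X <- as.matrix(X)
  keep <- !outlier
  if (sum(keep) < k) abort("cluster stage: fewer non-outlier models than k")
  km <- kmeans_seeded(X[keep, , drop = FALSE], k, n_init, seed)
  lab <- integer(nrow(X))
  lab[keep] <- km$cluster
  if (any(outlier)) {
    for (i in which(outlier)) {
      d2 <- rowSums(sweep(km$centers, 2, X[i, ], "-")^2)
      lab[i] <- which.min(d2)
    }
  }
  # renumber by descending total occupancy (0-based, ties by old id)
  tab <- sort(table(lab), decreasing = TRUE)
  remap <- setNames(seq_along(tab) - 1L, names(tab))
  new_lab <- unname(remap[as.character(lab)])
  centers <- km$centers[as.integer(names(tab)), , drop = FALSE]
  rownames(centers) <- seq_along(tab) - 1L
  occ <- tibble(cluster = seq_along(tab) - 1L,
                n_models = as.integer(tab),
                fraction = as.integer(tab) / nrow(X))
  list(assignments = tibble(model = model_ids, cluster = new_lab,
                            excluded = outlier),
       centers = centers, occupancy = occ)
}

#' Select a cluster representative by four-method consensus voting
#'
#' Candidates are nominated by four criteria — medoid (minimum average
#' RMSD to members), centroid proximity (minimum Euclidean distance of the
#' flattened coordinates to the cluster mean), minimax (minimum of the
#' maximum RMSD to members), and density peak (maximum number of members
#' within the 25th percentile of the cluster's pairwise RMSDs) — and the
#' modal candidate wins. Ties go to the medoid's choice, then the lowest
#' model id.
#'
#' @param members model ids in the cluster (consensus outliers should be
#'   removed by the caller).
#' @param mat full pairwise RMSD matrix with model ids as dimnames.
#' @param X full flattened-coordinate matrix (rows follow `mat`'s order).
#' @return list: `representative` (model id), `votes` tibble
#'   (`method`, `candidate`).
#' @export
select_representative <- function(members, mat, X) {
  if (length(members) == 0L) abort("representative stage: empty cluster")
  ids <- as.integer(rownames(mat))
  pos <- match(members, ids)
  if (anyNA(pos)) abort("representative stage: member id not in matrix")
  if (length(members) == 1L) {
    votes <- tibble(method = c("medoid", "centroid", "minimax", "density"),
                    candidate = rep(members, 4))
    return(list(representative = members, votes = votes))
  }
  sub <- mat[pos, pos, drop = FALSE]
  avg <- rowSums(sub) / (length(members) - 1L)
  medoid <- members[which.min(avg)]
  ctr <- colMeans(X[pos, , drop = FALSE])
  d_ctr <- sqrt(rowSums(sweep(X[pos, , drop = FALSE], 2, ctr)^2))
  centroid <- members[which.min(d_ctr)]
  minimax <- members[which.min(apply(sub, 1, max))]
  thr <- quantile(sub[upper.tri(sub)], 0.25, type = 7, names = FALSE)
  dens <- vapply(seq_along(members),
                 function(i) sum(sub[i, -i] <= thr), integer(1))
  density_peak <- members[which.max(dens)]
  votes <- tibble(method = c("medoid", "centroid", "minimax", "density"),
                  candidate = c(medoid, centroid, minimax, density_peak))
  tab <- table(votes$candidate)
  top <- as.integer(names(tab)[tab == max(tab)])
  rep_id <- if (length(top) == 1L) top
    else if (medoid %in% top) medoid
    else min(top)
  list(representative = rep_id, votes = votes)
}

#' Composite quality score of a cluster representative
#'
#' Weighted composite on `[0, 1]`:
#' `0.35 * n_avg + 0.25 * n_max + 0.25 * coverage + 0.15 * centrality`,
#' where `n_avg`/`n_max` min-max normalize the representative's average and
#' maximum RMSD to cluster members across members (best member scores 1),
#' coverage is the fraction of the other members within `coverage_cutoff`
#' (2 Angstrom) of the representative, and centrality is the inverse rank
#' of the representative when members are sorted by average RMSD. A
#' component on which all members tie scores 1; a singleton cluster scores
#' a perfect 1.
#'
#' @param rep_id representative model id.
#' @param members model ids in the cluster.
#' @param mat full pairwise RMSD matrix with model ids as dimnames.
#' @param coverage_cutoff Angstrom cutoff for the coverage term (default 2).
#' @param inclusive_coverage also count the representative itself in the
#'   coverage numerator and denominator (default `FALSE`).
#' @return list: `score`, and `components` (one-row tibble with `n_avg`,
#'   `n_max`, `coverage`, `centrality`).
#' @export
representative_quality <- function(rep_id, members, mat,
                                   coverage_cutoff = 2.0,
                                   inclusive_coverage = FALSE) {
  if (!rep_id %in% members)
    abort("quality stage: representative not in cluster")
  if (length(members) == 1L) {
    comp <- tibble(n_avg = 1, n_max = 1, coverage = 1, centrality = 1)
    return(list(score = 1.0, components = comp))
  }
  ids <- as.integer(rownames(mat))
  pos <- match(members, ids)
  sub <- mat[pos, pos, drop = FALSE]
  n <- length(members)
  avg <- rowSums(sub) / (n - 1L)
  mx <- apply(sub + diag(-Inf, n), 1, max)
  ri <- match(rep_id, members)
  minmax_norm <- function(v, i) {
    if (max(v) - min(v) < .Machine$double.eps) return(1)
    unname((max(v) - v[i]) / (max(v) - min(v)))
  }
  n_avg <- minmax_norm(avg, ri)
  n_max <- minmax_norm(mx, ri)
  within <- unname(sub[ri, -ri] <= coverage_cutoff)
  coverage <- if (inclusive_coverage) (sum(within) + 1) / n
              else mean(within)
  centrality <- 1 / rank(avg, ties.method = "min")[ri]
  if (max(avg) - min(avg) < .Machine$double.eps) centrality <- 1
  comp <- tibble(n_avg = n_avg, n_max = n_max,
                 coverage = coverage, centrality = unname(centrality))
  list(score = 0.35 * n_avg + 0.25 * n_max + 0.25 * coverage +
         0.15 * comp$centrality,
       components = comp)
}

#' Intra-cluster diversity metrics
#'
#' Mean pairwise RMSD, cluster diameter (maximum pairwise RMSD), and a
#' compactness score. Compactness has no canonical definition; the default
#' (`"relative_mean"`) is the cluster's mean intra-RMSD divided by the
#' global off-diagonal mean RMSD (small = tight relative to the ensemble).
#' Singletons return `(0, 0, 1)` by convention.
#'
#' @param members model ids in the cluster.
#' @param mat full pairwise RMSD matrix with model ids as dimnames.
#' @param compactness `"relative_mean"` (default) or a function
#'   `(sub_matrix, full_matrix) -> numeric`.
#' @return one-row tibble: `mean_intra_rmsd`, `diameter`, `compactness`,
#'   `definition`.
#' @export
cluster_diversity <- function(members, mat, compactness = "relative_mean") {
  if (length(members) <= 1L)
    return(tibble(mean_intra_rmsd = 0, diameter = 0, compactness = 1,
                  definition = "singleton_convention"))
  ids <- as.integer(rownames(mat))
  sub <- mat[match(members, ids), match(members, ids), drop = FALSE]
  vals <- sub[upper.tri(sub)]
  comp <- if (is.function(compactness)) {
    c(compactness(sub, mat), "user")
  } else {
    global <- mean(mat[upper.tri(mat)])
    c(mean(vals) / global, "relative_mean")
  }
  tibble(mean_intra_rmsd = mean(vals), diameter = max(vals),
         compactness = as.numeric(comp[1]), definition = comp[2])
}

#' PCA projection of the ensemble coordinate space
#'
#' Mean-centered principal component analysis of the flattened aligned
#' coordinates; returns the first two component scores per model along
#' with every component's explained-variance ratio (non-increasing,
#' summing to 1).
#'
#' @param X numeric matrix (models x flattened coordinates).
#' @param model_ids model identifiers.
#' @return list: `scores` tibble (`model`, `pc1`, `pc2`),
#'   `explained_variance_ratio` numeric vector over all components.
#' @export
pca_project <- function(X, model_ids = seq_len(nrow(X))) {
  p <- prcomp(as.matrix(X), center = TRUE, scale. = FALSE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  scores <- tibble(model = model_ids,
                   pc1 = p$x[, 1],
                   pc2 = if (ncol(p$x) >= 2) p$x[, 2] else 0)
  list(scores = scores, explained_variance_ratio = ratio)
}
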