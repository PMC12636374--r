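#' IQR-based outlier flags on per-model mean RMSD
#'
#' Flags models whose mean RMSD to the rest of the ensemble falls outside
#' `[Q1 - factor*IQR, Q3 + factor*IQR]`.
#'
#' @param values numeric vector (one mean RMSD per model, Angstrom).
#' @param factor the Tukey fence multiplier (default 1.5).
#' @return logical vector, one flag per model.
#' @export
outliers_iqr <- function(values, factor = 1.5) {
  if (length(values) < 4L) {
    warn("fewer than 4 models: IQR outlier test not applied")
    return(rep(FALSE, length(values)))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  eps <- 1e-9  # numerically constant vectors flag nothing
  values < q[1] - factor * iqr - eps | values > q[2] + factor * iqr + eps
}

# --- isolation forest ------------------------------------------------------
# Classic isolation forest (random axis-aligned splits, path-length anomaly
# score): no R implementation is available in this stack, so it is built
# here. Only the pieces the ensemble workflow needs are provided.

# average unsuccessful-search path length of a BST with n points
iso_c <- function(n) {
  if (n <= 1) return(0)
  if (n == 2) return(1)
  2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

iso_build <- function(X, idx, depth, max_depth) {
  n <- length(idx)
  if (n <= 1L || depth >= max_depth)
    return(list(type = "leaf", size = n))
  sub <- X[idx, , drop = FALSE]
  rng <- matrixStats_range(sub)
  splittable <- which(rng[2, ] - rng[1, ] > 1e-9)
  if (length(splittable) == 0L)
    return(list(type = "leaf", size = n))
  q <- splittable[sample.int(length(splittable), 1L)]
  p <- runif(1, rng[1, q], rng[2, q])
  left <- idx[X[idx, q] < p]
  right <- idx[X[idx, q] >= p]
  if (length(left) == 0L || length(right) == 0L)
    return(list(type = "leaf", size = n))
  list(type = "node", feature = q, split = p,
       left = iso_build(X, left, depth + 1L, max_depth),
       right = iso_build(X, right, depth + 1L, max_depth))
}

matrixStats_range <- function(m) {
  rbind(apply(m, 2, min), apply(m, 2, max))
}

iso_path <- function(tree, x, depth = 0) {
  if (tree$type == "leaf") return(depth + iso_c(tree$size))
  if (x[tree$feature] < tree$split)
    iso_path(tree$left, x, depth + 1)
  else
    iso_path(tree$right, x, depth + 1)
}

#' Isolation-forest outlier flags on flattened coordinates
#'
#' Fits an isolation forest (100 trees, subsample size `min(256, M)`) to
#' the `M x 3A` flattened coordinate matrix and flags the
#' `ceiling(contamination * M)` models with the highest anomaly score.
#' Deterministic for a fixed `seed`.
#'
#' @param X numeric matrix, rows = models.
#' @param contamination expected outlier fraction (default 0.1).
#' @param n_trees number of isolation trees (default 100).
#' @param seed integer RNG seed.
#' @return logical flags with attribute `"score"` (anomaly scores in
#'   `(0, 1)`, higher = more anomalous).
#' @export
outliers_isolation_forest <- function(X, contamination = 0.1, n_trees = 100L,
                                      seed = 20251104L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) abort("outlier stage: isolation forest needs >= 3 models")
  psi <- min(256L, n)
  max_depth <- ceiling(log2(psi))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  paths <- matrix(0, n, n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, psi, replace = FALSE)
    tree <- iso_build(X, idx, 0L, max_depth)
    paths[, t] <- vapply(seq_len(n), function(i) iso_path(tree, X[i, ]),
                         numeric(1))
  }
  score <- 2^(-rowMeans(paths) / iso_c(psi))
  k <- ceiling(contamination * n)
  thr <- sort(score, decreasing = TRUE)[k]
  flags <- score >= thr
  attr(flags, "score") <- score
  flags
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Ward-linkage singleton outlier flags
#'
#' Builds a Ward dendrogram on the pairwise RMSD matrix, cuts it at
#' `mu + sigma_factor * sigma` of the merge heights, and flags every model
#' that ends up alone in its cluster.
#'
#' @param mat symmetric RMSD matrix.
#' @param sigma_factor multiplier on the merge-height SD (default 2).
#' @return logical flags, one per model.
#' @export
outliers_hier_singleton <- function(mat, sigma_factor = 2.0) {
  n <- nrow(mat)
  if (n < 3L) abort("outlier stage: singleton analysis needs >= 3 models")
  hc <- hclust(as.dist(mat), method = "ward.D2")
  cut_h <- mean(hc$height) + sigma_factor * sd(hc$height)
  labels <- cutree(hc, h = cut_h)
  sizes <- table(labels)
  unname(sizes[as.character(labels)] == 1L)
}

#' Consensus outlier report over the three detection methods
#'
#' A model is a consensus outlier when at least `min_votes` of the three
#' orthogonal detectors (IQR on mean RMSD, isolation forest on flattened
#' coordinates, Ward singleton analysis) flag it. Adding a vote can never
#' un-flag a model.
#'
#' @param iqr,iforest,singleton logical flag vectors of equal length.
#' @param model_ids model identifiers (default sequential).
#' @param min_votes votes needed for consensus (default 2).
#' @param params list of method parameters, stored in the report.
#' @return tibble of class `outlier_report`: `model`, `iqr`, `iforest`,
#'   `singleton`, `votes`, `consensus`; parameters kept in
#'   `attr(, "method_params")`.
#' @export
consensus_outliers <- function(iqr, iforest, singleton,
                               model_ids = seq_along(iqr),
                               min_votes = 2L, params = list()) {
  stopifnot(length(iqr) == length(iforest),
            length(iqr) == length(singleton))
  votes <- as.integer(iqr) + as.integer(iforest) + as.integer(singleton)
  out <- tibble(model = model_ids,
                iqr = as.logical(iqr), iforest = as.logical(iforest),
                singleton = as.logical(singleton),
                votes = votes, consensus = votes >= min_votes)
  attr(out, "method_params") <- utils::modifyList(
    list(iqr_factor = 1.5, contamination = 0.1, singleton_sigma = 2.0,
         consensus_min_votes = min_votes), params)
  class(out) <- c("outlier_report", class(out))
  out
}

#' Run all three outlier detectors on a superposed ensemble
#'
#' @param x a superposed [conformer_ensemble].
#' @param mat its pairwise RMSD matrix (computed if missing).
#' @param iqr_factor,contamination,singleton_sigma,min_votes detector
#'   parameters (see the individual detectors).
#' @param seed RNG seed for the isolation forest.
#' @return an `outlier_report` tibble (see [consensus_outliers()]).
#' @export
detect_outliers <- function(x, mat = pairwise_rmsd(x), iqr_factor = 1.5,
                            contamination = 0.1, singleton_sigma = 2.0,
                            min_votes = 2L, seed = 20251104L) {
  per_model <- rmsd_summary(mat)$per_model$mean_rmsd
  consensus_outliers(
    iqr = outliers_iqr(per_model, iqr_factor),
    iforest = outliers_isolation_forest(flatten_coords(x), contamination,
                                        seed = seed),
    singleton = outliers_hier_singleton(mat, singleton_sigma),
    model_ids = x$model_ids, min_votes = min_votes,
    params = list(iqr_factor = iqr_factor, contamination = contamination,
                  singleton_sigma = singleton_sigma,
                  consensus_min_votes = min_votes, seed = seed)
  )
}
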