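#' End-to-end conformational analysis of a multi-model ensemble
#'
#' Runs the full workflow on a multi-model structure: read (or accept) the
#' backbone ensemble, superpose onto the reference model, compute the
#' pairwise RMSD matrix and flexibility metrics, flag consensus outliers
#' with three orthogonal detectors, choose k over a candidate range by
#' silhouette maximization, cluster with k-means, select quality-scored
#' representatives per cluster by four-method voting, and project the
#' conformational landscape onto its first two principal components.
#' Deterministic for a fixed input and seed.
#'
#' @param x path to a multi-model PDB file, or a [conformer_ensemble].
#' @param chain,atom_names atom selection, see [read_multimodel_pdb()].
#' @param k_range candidate cluster numbers (default `2:6`).
#' @param seed integer seed driving the isolation forest and k-means.
#' @param contamination,iqr_factor,singleton_sigma,min_votes outlier
#'   detector parameters, see [detect_outliers()].
#' @param n_init k-means restarts (default 20).
#' @param coverage_cutoff Angstrom cutoff of the quality-score coverage
#'   term (default 2).
#' @param per_pair_rmsd refit each model pair before measuring RMSD
#'   instead of using the common reference alignment.
#' @return An object of class `ensemble_analysis`; see [tidy.ensemble_analysis()],
#'   [glance.ensemble_analysis()], [autoplot.ensemble_analysis()] and
#'   [write_ensemble_report()].
#' @export
analyze_ensemble <- function(x, chain = "A",
                             atom_names = c("N", "CA", "C", "O"),
                             k_range = 2:6, seed = 20251104L,
                             contamination = 0.1, iqr_factor = 1.5,
                             singleton_sigma = 2.0, min_votes = 2L,
                             n_init = 20L, coverage_cutoff = 2.0,
                             per_pair_rmsd = FALSE) {
  ens <- if (inherits(x, "conformer_ensemble")) x
         else read_multimodel_pdb(x, chain = chain, atom_names = atom_names)
  ens <- superpose_models(ens)
  mat <- pairwise_rmsd(ens, per_pair = per_pair_rmsd)
  rs <- rmsd_summary(mat)
  flex <- rmsf_profile(ens)
  X <- flatten_coords(ens)
  outliers <- detect_outliers(ens, mat, iqr_factor = iqr_factor,
                              contamination = contamination,
                              singleton_sigma = singleton_sigma,
                              min_votes = min_votes, seed = seed)
  keep <- !outliers$consensus
  sel <- choose_k(X[keep, , drop = FALSE], k_range = k_range,
                  n_init = n_init, seed = seed)
  clus <- cluster_models(X, sel$k, outlier = outliers$consensus,
                         model_ids = ens$model_ids,
                         n_init = n_init, seed = seed)
  clusters <- purrr::map_dfr(clus$occupancy$cluster, function(cl) {
    members_all <- clus$assignments$model[clus$assignments$cluster == cl]
    members_fit <- clus$assignments$model[clus$assignments$cluster == cl &
                                            !clus$assignments$excluded]
    rep_sel <- select_representative(members_fit, mat, X)
    qual <- representative_quality(rep_sel$representative, members_fit, mat,
                                   coverage_cutoff = coverage_cutoff)
    div <- cluster_diversity(members_fit, mat)
    tibble(cluster = cl,
           n_models = length(members_all),
           occupancy = length(members_all) / n_models(ens),
           representative = rep_sel$representative,
           quality_score = qual$score,
           coverage = qual$components$coverage,
           mean_intra_rmsd = div$mean_intra_rmsd,
           diameter = div$diameter,
           compactness = div$compactness,
           votes = list(rep_sel$votes),
           quality_components = list(qual$components))
  })
  reps <- clusters$representative
  inter_rep <- if (length(reps) >= 2) {
    pos <- match(reps, as.integer(rownames(mat)))
    pr <- mat[pos, pos]
    mean(pr[upper.tri(pr)])
  } else NA_real_
  pca <- pca_project(X, model_ids = ens$model_ids)
  structure(
    list(ensemble = ens, rmsd_matrix = mat, rmsd_stats = rs$stats,
         per_model = dplyr::left_join(rs$per_model,
                                      radius_of_gyration(ens), by = "model"),
         flexibility = flex, outliers = outliers,
         k = sel$k, k_metrics = sel$metrics,
         assignments = clus$assignments, occupancy = clus$occupancy,
         clusters = clusters, inter_representative_rmsd = inter_rep,
         pca = pca,
         config = list(chain = chain, atom_names = atom_names,
                       k_range = k_range, seed = seed,
                       contamination = contamination,
                       iqr_factor = iqr_factor,
                       singleton_sigma = singleton_sigma,
                       min_votes = min_votes, n_init = n_init,
                       coverage_cutoff = coverage_cutoff,
                       per_pair_rmsd = per_pair_rmsd)),
    class = "ensemble_analysis"
  )
}

#' @export
print.ensemble_analysis <- function(x, ...) {
  s <- x$rmsd_stats
  cat(sprintf("<ensemble_analysis> %d models x %d atoms\n",
              n_models(x$ensemble), n_atoms(x$ensemble)))
  cat(sprintf("  pairwise RMSD %.3f-%.3f A (mean %.3f +/- %.3f)\n",
              s$min, s$max, s$mean, s$sd))
  cat(sprintf("  consensus outliers: %s\n",
              if (any(x$outliers$consensus))
                paste(x$outliers$model[x$outliers$consensus], collapse = ", ")
              else "none"))
  cat(sprintf("  k = %d | occupancies: %s\n", x$k,
              paste(sprintf("%d (%.1f%%)", x$occupancy$n_models,
                            100 * x$occupancy$fraction), collapse = " / ")))
  cat(sprintf("  representatives: %s | quality: %s\n",
              paste(x$clusters$representative, collapse = ", "),
              paste(sprintf("%.3f", x$clusters$quality_score), collapse = ", ")))
  if (!is.na(x$inter_representative_rmsd))
    cat(sprintf("  inter-representative RMSD: %.3f A\n",
                x$inter_representative_rmsd))
  cat(sprintf("  PC1+PC2 variance: %.1f%%\n",
              100 * sum(x$pca$explained_variance_ratio[1:2])))
  invisible(x)
}

#' Tidy the per-model results of an ensemble analysis
#'
#' @param x an `ensemble_analysis`.
#' @param ... unused.
#' @return tibble with one row per model: mean RMSD to other models, radius
#'   of gyration, outlier votes/flags, cluster assignment, excluded flag,
#'   representative flag and PCA scores.
#' @export
tidy.ensemble_analysis <- function(x, ...) {
  x$per_model |>
    dplyr::left_join(x$outliers, by = "model") |>
    dplyr::left_join(x$assignments, by = "model") |>
    dplyr::left_join(x$pca$scores, by = "model") |>
    dplyr::mutate(representative = .data$model %in% x$clusters$representative)
}

#' One-row summary of an ensemble analysis
#'
#' @param x an `ensemble_analysis`.
#' @param ... unused.
#' @return one-row tibble: model/atom counts, RMSD statistics, chosen k,
#'   silhouette and Davies-Bouldin at k, outlier count, representative ids,
#'   inter-representative RMSD, PC1+PC2 explained variance, mean RMSF.
#' @export
glance.ensemble_analysis <- function(x, ...) {
  at_k <- x$k_metrics[x$k_metrics$k == x$k, ]
  tibble(
    n_models = n_models(x$ensemble), n_atoms = n_atoms(x$ensemble),
    rmsd_min = x$rmsd_stats$min, rmsd_mean = x$rmsd_stats$mean,
    rmsd_sd = x$rmsd_stats$sd, rmsd_max = x$rmsd_stats$max,
    k = x$k, silhouette = at_k$silhouette,
    davies_bouldin = at_k$davies_bouldin,
    n_outliers = sum(x$outliers$consensus),
    representatives = paste(x$clusters$representative, collapse = ","),
    inter_representative_rmsd = x$inter_representative_rmsd,
    pc12_variance = sum(x$pca$explained_variance_ratio[1:2]),
    rmsf_mean = x$flexibility$rmsf_mean
  )
}
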