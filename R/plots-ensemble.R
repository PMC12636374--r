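# hclust -> segment tibble for a ggplot dendrogram (no dendrogram-plotting
# package in this stack)
hclust_segments <- function(hc) {
  n <- length(hc$order)
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  seg <- list()
  for (i in seq_len(nrow(hc$merge))) {
    ch <- hc$merge[i, ]
    cx <- numeric(2); chh <- numeric(2)
    for (s in 1:2) {
      if (ch[s] < 0) {
        cx[s] <- xpos[-ch[s]]; chh[s] <- 0
      } else {
        cx[s] <- node_x[ch[s]]; chh[s] <- node_h[ch[s]]
      }
    }
    node_x[i] <- mean(cx)
    seg[[i]] <- tibble(
      x = c(cx[1], cx[2], cx[1]), xend = c(cx[1], cx[2], cx[2]),
      y = c(chh[1], chh[2], node_h[i]), yend = c(node_h[i], node_h[i], node_h[i])
    )
  }
  dplyr::bind_rows(seg)
}

#' Plot panels of an ensemble analysis
#'
#' Renders the standard report panels: `"mean_rmsd"` per-model mean RMSD
#' bars (outliers and representatives highlighted), `"occupancy"` cluster
#' membership, `"k_metrics"` silhouette and Davies-Bouldin versus k,
#' `"pca"` the 2-D principal component projection, `"dendrogram"` the
#' Ward tree on the RMSD matrix, `"quality"` representative quality
#' scores, `"diversity"` intra-cluster diversity metrics, `"rg"` radius
#' of gyration per model, and `"rmsf"` the per-residue flexibility
#' profile with the 75th-percentile high-flexibility markers.
#'
#' @param object an `ensemble_analysis`.
#' @param type one of the panel names above.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ensemble_analysis <- function(object, type = "pca", ...) {
  x <- object
  td <- tidy(x)
  switch(
    type,
    mean_rmsd = ggplot2::ggplot(td, ggplot2::aes(
        x = factor(.data$model), y = .data$mean_rmsd,
        fill = .data$representative, colour = .data$consensus)) +
      ggplot2::geom_col(linewidth = 0.8) +
      ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "goldenrod")) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = NA, `TRUE` = "red")) +
      ggplot2::labs(x = "model", y = "mean RMSD to other models (Å)",
                    title = "Per-model mean backbone RMSD"),
    occupancy = ggplot2::ggplot(x$occupancy, ggplot2::aes(
        x = factor(.data$cluster), y = .data$fraction)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
      ggplot2::labs(x = "cluster", y = "occupancy",
                    title = "Cluster membership distribution"),
    k_metrics = x$k_metrics |>
      tidyr::pivot_longer(c("silhouette", "davies_bouldin"),
                          names_to = "metric") |>
      ggplot2::ggplot(ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$metric)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_vline(xintercept = x$k, linetype = "dashed",
                          colour = "darkgreen") +
      ggplot2::labs(x = "k", y = "index value",
                    title = "Cluster-number selection metrics"),
    pca = ggplot2::ggplot(td, ggplot2::aes(
        x = .data$pc1, y = .data$pc2, colour = factor(.data$cluster),
        shape = .data$consensus)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(
        x = sprintf("PC1 (%.1f%%)", 100 * x$pca$explained_variance_ratio[1]),
        y = sprintf("PC2 (%.1f%%)", 100 * x$pca$explained_variance_ratio[2]),
        colour = "cluster", shape = "outlier",
        title = "Principal component projection"),
    dendrogram = {
      hc <- hclust(as.dist(x$rmsd_matrix), method = "ward.D2")
      labs <- tibble(xx = seq_along(hc$order),
                     model = as.integer(rownames(x$rmsd_matrix))[hc$order])
      ggplot2::ggplot(hclust_segments(hc)) +
        ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                           y = .data$y, yend = .data$yend)) +
        ggplot2::scale_x_continuous(breaks = labs$xx,
                                    labels = labs$model) +
        ggplot2::labs(x = "model", y = "Ward merge height (Å)",
                      title = "Ward dendrogram on pairwise RMSD")
    },
    quality = ggplot2::ggplot(x$clusters, ggplot2::aes(
        x = factor(.data$cluster), y = .data$quality_score)) +
      ggplot2::geom_col(fill = "goldenrod") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "cluster", y = "composite quality score",
                    title = "Representative quality (35/25/25/15 weighting)"),
    diversity = x$clusters |>
      dplyr::mutate(compactness_x5 = 5 * .data$compactness) |>
      tidyr::pivot_longer(c("mean_intra_rmsd", "diameter", "compactness_x5"),
                          names_to = "metric") |>
      ggplot2::ggplot(ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$value, fill = .data$metric)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "cluster", y = "Å (compactness scaled x5)",
                    title = "Intra-cluster diversity"),
    rg = ggplot2::ggplot(td, ggplot2::aes(
        x = factor(.data$model), y = .data$rg,
        fill = factor(.data$cluster))) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "model", y = "radius of gyration (Å)",
                    fill = "cluster", title = "Radius of gyration"),
    rmsf = {
      pr <- x$flexibility$per_residue
      ggplot2::ggplot(pr, ggplot2::aes(x = .data$resno, y = .data$rmsf)) +
        ggplot2::geom_line(colour = "steelblue") +
        ggplot2::geom_point(data = pr[pr$high_flex, ], colour = "red") +
        ggplot2::geom_hline(yintercept = mean(pr$rmsf), linetype = "dashed",
                            colour = "red") +
        ggplot2::labs(x = "residue", y = "RMSF (Å)",
                      title = sprintf("Per-residue RMSF (mean %.2f Å)",
                                      mean(pr$rmsf)))
    },
    abort(paste0("unknown plot type: ", type))
  )
}

ensemble_panels <- c("mean_rmsd", "occupancy", "k_metrics", "pca",
                     "dendrogram", "quality", "diversity", "rg", "rmsf")

#' Write the machine-readable report and plot panels of an analysis
#'
#' Writes `report.json` (all statistics, flags and metrics),
#' `rmsd_matrix.csv`, `rmsf.csv` (per-residue and per-atom), the tidy
#' per-model table `models.csv`, and one PNG per report panel.
#'
#' @param x an `ensemble_analysis`.
#' @param outdir output directory (created if needed).
#' @param plots render the PNG panels too (default `TRUE`).
#' @return `outdir`, invisibly.
#' @export
write_ensemble_report <- function(x, outdir, plots = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    n_models = n_models(x$ensemble), n_atoms = n_atoms(x$ensemble),
    rmsd_stats = as.list(x$rmsd_stats),
    outliers = as.list(x$outliers[, c("model", "iqr", "iforest",
                                      "singleton", "votes", "consensus")]),
    method_params = attr(x$outliers, "method_params"),
    k = x$k, k_metrics = x$k_metrics,
    occupancy = x$occupancy,
    clusters = x$clusters[, c("cluster", "n_models", "occupancy",
                              "representative", "quality_score", "coverage",
                              "mean_intra_rmsd", "diameter", "compactness")],
    inter_representative_rmsd = x$inter_representative_rmsd,
    explained_variance_ratio = x$pca$explained_variance_ratio,
    rmsf_mean = x$flexibility$rmsf_mean,
    high_flex_residues = x$flexibility$per_residue$resno[
      x$flexibility$per_residue$high_flex],
    config = x$config
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(as.data.frame(unclass(x$rmsd_matrix)),
            file.path(outdir, "rmsd_matrix.csv"))
  write.csv(x$flexibility$per_residue, file.path(outdir, "rmsf.csv"),
            row.names = FALSE)
  write.csv(x$flexibility$per_atom, file.path(outdir, "rmsf_per_atom.csv"),
            row.names = FALSE)
  write.csv(tidy(x)[, setdiff(names(tidy(x)), c())],
            file.path(outdir, "models.csv"), row.names = FALSE)
  if (plots) {
    for (p in ensemble_panels) {
      ggplot2::ggsave(file.path(outdir, paste0("panel_", p, ".png")),
                      autoplot(x, type = p), width = 6, height = 4, dpi = 120)
    }
  }
  invisible(outdir)
}
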