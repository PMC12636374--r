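# Five complementary rank aggregation strategies over (docking score,
# MM-GBSA dG_bind) pairs. Both metrics are in kcal/mol and lower = better
# throughout; every method returns fractional (average) ranks on ties.

rank_asc <- function(v) rank(v, ties.method = "average")

zscore_col <- function(v, label) {
  s <- sd(v)
  if (!is.finite(s) || s == 0) {
    warn(paste0("hitrank: zero variance in ", label, "; z-scores set to 0"))
    return(rep(0, length(v)))
  }
  (v - mean(v)) / s
}

check_score_table <- function(data) {
  need <- c("compound_id", "gscore", "dg_bind")
  if (!all(need %in% names(data)))
    abort(paste0("hitrank: table must have columns ",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(data$compound_id))
    abort("hitrank: compound_id must be unique")
  invisible(data)
}

#' Equal-weight z-score ranking
#'
#' Standardizes both metrics to zero mean and unit variance, averages the
#' two z-scores, and ranks ascending (most negative combined score = rank
#' 1). A zero-variance column contributes z = 0 with a warning.
#'
#' @param data tibble with columns `compound_id`, `gscore`, `dg_bind`.
#' @return the input tibble plus `combined` and `rank` columns, ordered as
#'   the input.
#' @export
zscore_rank <- function(data) {
  check_score_table(data)
  combined <- (zscore_col(data$gscore, "gscore") +
                 zscore_col(data$dg_bind, "dg_bind")) / 2
  dplyr::mutate(as_tibble(data), combined = combined,
                rank = rank_asc(combined))
}

#' Percentile-based ranking
#'
#' Converts each metric to a goodness percentile (most negative value =
#' 100), averages the two percentiles, and ranks descending combined
#' percentile ascending (best = rank 1). Robust to outliers since only
#' order information is used.
#'
#' @inheritParams zscore_rank
#' @return input tibble plus `combined` (mean percentile) and `rank`.
#' @export
percentile_rank <- function(data) {
  check_score_table(data)
  n <- nrow(data)
  pct <- function(v) 100 * rank(-v, ties.method = "average") / n
  combined <- (pct(data$gscore) + pct(data$dg_bind)) / 2
  dplyr::mutate(as_tibble(data), combined = combined,
                rank = rank_asc(-combined))
}

#' Weighted z-score ranking
#'
#' Like [zscore_rank()] but with unequal weights on the two standardized
#' metrics; the defaults weight the MM-GBSA binding energy at 60% and the
#' docking score at 40%.
#'
#' @inheritParams zscore_rank
#' @param w_gscore,w_dg_bind metric weights (default 0.4 / 0.6).
#' @return input tibble plus `combined` and `rank`.
#' @export
weighted_zscore_rank <- function(data, w_gscore = 0.4, w_dg_bind = 0.6) {
  check_score_table(data)
  combined <- w_gscore * zscore_col(data$gscore, "gscore") +
    w_dg_bind * zscore_col(data$dg_bind, "dg_bind")
  dplyr::mutate(as_tibble(data), combined = combined,
                rank = rank_asc(combined))
}

# one sweep: logical index of the non-dominated rows among `g`, `dg`
# (minimization; a dominates b iff a <= b on both and < on at least one)
pareto_front_mask <- function(g, dg) {
  n <- length(g)
  ord <- order(g, dg)
  nd <- logical(n)
  best_strictless <- Inf   # min dg among rows with strictly smaller g
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && g[ord[j + 1]] == g[ord[i]]) j <- j + 1
    grp <- ord[i:j]
    gmin <- min(dg[grp])
    nd[grp] <- dg[grp] == gmin & gmin < best_strictless
    best_strictless <- min(best_strictless, gmin)
    i <- j + 1
  }
  nd
}

#' Pareto-frontier (non-dominated sorting) ranking
#'
#' Row a dominates row b when a is no worse on both metrics and strictly
#' better on at least one; exact ties are mutually non-dominating. The
#' non-dominated set receives rank 1, is removed, and the peeling repeats
#' to assign hierarchical frontier ranks.
#'
#' @inheritParams zscore_rank
#' @return input tibble plus `rank` (frontier index, 1 = Pareto-optimal).
#' @export
pareto_rank <- function(data) {
  check_score_table(data)
  n <- nrow(data)
  front <- integer(n)
  remaining <- seq_len(n)
  level <- 1L
  while (length(remaining) > 0L) {
    nd <- pareto_front_mask(data$gscore[remaining], data$dg_bind[remaining])
    front[remaining[nd]] <- level
    remaining <- remaining[!nd]
    level <- level + 1L
  }
  dplyr::mutate(as_tibble(data), rank = front)
}

#' Strict dual-cutoff ranking
#'
#' Compounds passing both inclusive thresholds (`gscore <= g_cut` and
#' `dg_bind <= dg_cut`) are z-score-ranked among themselves; non-passers
#' are placed after all passers, ordered by their own z-score, so that a
#' total order exists for ensemble averaging.
#'
#' @inheritParams zscore_rank
#' @param g_cut,dg_cut inclusive thresholds in kcal/mol
#'   (defaults -6.0 and -40.0).
#' @return input tibble plus `pass`, `combined` and `rank`; the pass count
#'   and fraction are stored in attributes `n_pass` / `pass_fraction`.
#' @export
strict_cutoff_rank <- function(data, g_cut = -6.0, dg_cut = -40.0) {
  check_score_table(data)
  data <- as_tibble(data)
  pass <- data$gscore <= g_cut & data$dg_bind <= dg_cut
  combined <- rep(NA_real_, nrow(data))
  rk <- rep(NA_real_, nrow(data))
  for (grp in list(which(pass), which(!pass))) {
    if (length(grp) == 0L) next
    cmb <- if (length(grp) == 1L) 0 else
      (zscore_col(data$gscore[grp], "gscore (cutoff group)") +
         zscore_col(data$dg_bind[grp], "dg_bind (cutoff group)")) / 2
    combined[grp] <- cmb
    rk[grp] <- rank_asc(cmb)
  }
  rk[!pass] <- rk[!pass] + sum(pass)
  out <- dplyr::mutate(data, pass = pass, combined = combined, rank = rk)
  attr(out, "n_pass") <- sum(pass)
  attr(out, "pass_fraction") <- mean(pass)
  out
}

#' Consensus ranking of virtual-screening hits
#'
#' Applies all five ranking strategies — equal-weight z-score, percentile,
#' weighted z-score, Pareto frontier peeling and strict dual-cutoff — and
#' averages the five per-method ranks into an ensemble rank (lower =
#' better). Rows with a missing value in either metric are excluded before
#' ranking and reported separately.
#'
#' @inheritParams zscore_rank
#' @param w_gscore,w_dg_bind weights of the weighted method.
#' @param g_cut,dg_cut thresholds of the strict-cutoff method (kcal/mol).
#' @return object of class `hit_ranking`: `table` (per-compound tibble
#'   with the five rank columns, `ensemble_rank`, final `ensemble_position`
#'   and `pareto_front` flag), `excluded` (rows dropped for missing
#'   values), `summary` (see [score_summary()]), `params`.
#' @export
rank_hits <- function(data, w_gscore = 0.4, w_dg_bind = 0.6,
                      g_cut = -6.0, dg_cut = -40.0) {
  data <- as_tibble(data)
  check_score_table(data)
  ok <- complete.cases(data[, c("gscore", "dg_bind")])
  excluded <- data[!ok, ]
  data <- data[ok, ]
  if (nrow(data) == 0L) abort("hitrank: no complete rows to rank")
  cut <- strict_cutoff_rank(data, g_cut, dg_cut)
  tab <- data |>
    dplyr::mutate(
      rank_zscore = zscore_rank(data)$rank,
      rank_percentile = percentile_rank(data)$rank,
      rank_weighted = weighted_zscore_rank(data, w_gscore, w_dg_bind)$rank,
      rank_pareto = pareto_rank(data)$rank,
      rank_cutoff = cut$rank,
      cutoff_pass = cut$pass
    ) |>
    dplyr::mutate(
      ensemble_rank = (.data$rank_zscore + .data$rank_percentile +
                         .data$rank_weighted + .data$rank_pareto +
                         .data$rank_cutoff) / 5,
      ensemble_position = rank_asc(.data$ensemble_rank),
      pareto_front = .data$rank_pareto == 1L
    )
  structure(
    list(table = tab, excluded = excluded,
         summary = score_summary(data, plots = FALSE),
         params = list(w_gscore = w_gscore, w_dg_bind = w_dg_bind,
                       g_cut = g_cut, dg_cut = dg_cut,
                       n_excluded_missing = nrow(excluded),
                       n_pass = attr(cut, "n_pass"),
                       pass_fraction = attr(cut, "pass_fraction"))),
    class = "hit_ranking"
  )
}

#' Distribution summary of a score table
#'
#' Per-metric mean, SD, median, min and max, the Pearson correlation
#' between the two metrics, and the row count. With a zero-variance
#' column the correlation is reported as `NA` with a warning.
#'
#' @inheritParams zscore_rank
#' @param plots unused here; kept so callers can signal intent.
#' @return list: `metrics` tibble (one row per metric), `pearson_r`, `n`.
#' @export
score_summary <- function(data, plots = FALSE) {
  check_score_table(data)
  data <- data[complete.cases(data[, c("gscore", "dg_bind")]), ]
  r <- if (sd(data$gscore) == 0 || sd(data$dg_bind) == 0 ||
           nrow(data) < 3) {
    warn("hitrank: correlation undefined (constant column or n < 3)")
    NA_real_
  } else cor(data$gscore, data$dg_bind)
  one <- function(v, nm) tibble(metric = nm, mean = mean(v), sd = sd(v),
                                median = median(v), min = min(v), max = max(v))
  list(metrics = dplyr::bind_rows(one(data$gscore, "gscore"),
                                  one(data$dg_bind, "dg_bind")),
       pearson_r = r, n = nrow(data))
}

#' @export
print.hit_ranking <- function(x, ...) {
  cat(sprintf("<hit_ranking> %d compounds (%d excluded for missing values)\n",
              nrow(x$table), nrow(x$excluded)))
  cat(sprintf("  Pareto front: %d compounds | cutoff pass: %d (%.1f%%)\n",
              sum(x$table$pareto_front), x$params$n_pass,
              100 * x$params$pass_fraction))
  cat(sprintf("  Pearson R(gscore, dG_bind) = %.3f\n", x$summary$pearson_r))
  top <- dplyr::arrange(x$table, .data$ensemble_position) |> head(5)
  cat("  top of ensemble ranking:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %d. %s (gscore %.2f, dG %.2f, ensemble rank %.1f)\n",
                i, top$compound_id[i], top$gscore[i], top$dg_bind[i],
                top$ensemble_rank[i]))
  invisible(x)
}

#' @rdname rank_hits
#' @param x a `hit_ranking`.
#' @param ... unused.
#' @export
tidy.hit_ranking <- function(x, ...) x$table

#' @rdname rank_hits
#' @export
glance.hit_ranking <- function(x, ...) {
  m <- x$summary$metrics
  tibble(n = x$summary$n, n_excluded = nrow(x$excluded),
         gscore_mean = m$mean[1], gscore_sd = m$sd[1],
         dg_mean = m$mean[2], dg_sd = m$sd[2],
         pearson_r = x$summary$pearson_r,
         n_pareto_front = sum(x$table$pareto_front),
         n_pass = x$params$n_pass,
         pass_fraction = x$params$pass_fraction)
}

#' Plot panels of a hit ranking
#'
#' Types: `"hist_gscore"` and `"hist_dg"` score histograms with the
#' median marked, `"pareto"` the score scatter colored by frontier rank
#' with the Pareto-optimal set and the top-20 ensemble compounds
#' highlighted, `"box"` side-by-side score box plots, `"scatter"` the
#' correlation scatter.
#'
#' @param object a `hit_ranking`.
#' @param type panel name (see above).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hit_ranking <- function(object, type = "pareto", ...) {
  tab <- object$table
  switch(
    type,
    hist_gscore = ggplot2::ggplot(tab, ggplot2::aes(x = .data$gscore)) +
      ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
      ggplot2::geom_vline(xintercept = median(tab$gscore),
                          colour = "red", linetype = "dashed") +
      ggplot2::labs(x = "docking score (kcal/mol)", y = "count",
                    title = "Docking score distribution"),
    hist_dg = ggplot2::ggplot(tab, ggplot2::aes(x = .data$dg_bind)) +
      ggplot2::geom_histogram(bins = 40, fill = "darkseagreen") +
      ggplot2::geom_vline(xintercept = median(tab$dg_bind),
                          colour = "red", linetype = "dashed") +
      ggplot2::labs(x = "MM-GBSA dG_bind (kcal/mol)", y = "count",
                    title = "Binding free-energy distribution"),
    pareto = {
      front <- dplyr::arrange(tab[tab$pareto_front, ], .data$gscore)
      top20 <- dplyr::slice_min(tab, .data$ensemble_position, n = 20)
      ggplot2::ggplot(tab, ggplot2::aes(x = .data$gscore, y = .data$dg_bind)) +
        ggplot2::geom_point(ggplot2::aes(colour = .data$rank_pareto),
                            alpha = 0.6) +
        ggplot2::geom_point(data = top20, shape = 21, size = 3,
                            fill = "green3", colour = "black") +
        ggplot2::geom_line(data = front, colour = "red",
                           linetype = "dashed") +
        ggplot2::geom_point(data = front, colour = "red", shape = 8,
                            size = 3) +
        ggplot2::scale_colour_viridis_c(name = "Pareto rank") +
        ggplot2::labs(x = "docking score (kcal/mol)",
                      y = "MM-GBSA dG_bind (kcal/mol)",
                      title = "Pareto frontier analysis")
    },
    box = tab |>
      tidyr::pivot_longer(c("gscore", "dg_bind"), names_to = "metric") |>
      ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$value)) +
      ggplot2::geom_boxplot(fill = "grey85") +
      ggplot2::stat_summary(fun = mean, geom = "point", shape = 24,
                            fill = "green3") +
      ggplot2::labs(x = NULL, y = "kcal/mol", title = "Score distributions"),
    scatter = ggplot2::ggplot(tab, ggplot2::aes(x = .data$gscore,
                                                y = .data$dg_bind)) +
      ggplot2::geom_point(alpha = 0.5, colour = "steelblue") +
      ggplot2::labs(
        x = "docking score (kcal/mol)", y = "MM-GBSA dG_bind (kcal/mol)",
        title = sprintf("Score correlation (R = %.3f, n = %d)",
                        object$summary$pearson_r, object$summary$n)),
    abort(paste0("unknown plot type: ", type))
  )
}

#' Write a ranked hit table, summary and plot panels
#'
#' @param x a `hit_ranking`.
#' @param outdir output directory (created if needed).
#' @param plots render PNG panels (default `TRUE`).
#' @return `outdir`, invisibly.
#' @export
write_hitrank_report <- function(x, outdir, plots = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(dplyr::arrange(x$table, .data$ensemble_position),
            file.path(outdir, "ranked_hits.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary_metrics = x$summary$metrics,
         pearson_r = x$summary$pearson_r, n = x$summary$n,
         params = x$params,
         pareto_front_ids = x$table$compound_id[x$table$pareto_front]),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (plots) {
    for (p in c("hist_gscore", "hist_dg", "pareto", "box", "scatter"))
      ggplot2::ggsave(file.path(outdir, paste0("panel_", p, ".png")),
                      autoplot(x, type = p), width = 6, height = 4, dpi = 120)
  }
  invisible(outdir)
}
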