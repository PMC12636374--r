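score_tbl <- function(g, dg, ids = sprintf("C%02d", seq_along(g))) {
  tibble::tibble(compound_id = ids, gscore = g, dg_bind = dg)
}

brute_force_front <- function(tab) {
  n <- nrow(tab)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i &&
        tab$gscore[j] <= tab$gscore[i] && tab$dg_bind[j] <= tab$dg_bind[i] &&
        (tab$gscore[j] < tab$gscore[i] || tab$dg_bind[j] < tab$dg_bind[i])
    }, logical(1)))
  }, logical(1))
  tab$compound_id[!dominated]
}

test_that("z-score ranking matches hand-computed standardization", {
  tab <- score_tbl(c(-8, -7, -6, -5, -4), c(-60, -30, -50, -20, -40))
  z <- zscore_rank(tab)
  zg <- (tab$gscore - mean(tab$gscore)) / sd(tab$gscore)
  zd <- (tab$dg_bind - mean(tab$dg_bind)) / sd(tab$dg_bind)
  expect_equal(z$combined, (zg + zd) / 2)
  expect_equal(z$rank, rank((zg + zd) / 2))
  # dominance: better on both metrics ranks first
  two <- zscore_rank(score_tbl(c(-10, -5), c(-60, -30)))
  expect_equal(two$rank, c(1, 2))
  expect_warning(expect_warning(one <- zscore_rank(score_tbl(-7, -40)),
                                "zero variance"), "zero variance")
  expect_equal(one$rank, 1)
  expect_warning(zscore_rank(score_tbl(c(-5, -5), c(-10, -20))),
                 "zero variance")
})

test_that("percentile ranking is order-isomorphic to z-scores on monotone tables", {
  tab <- score_tbl(seq(-9, -5, by = 1), seq(-65, -25, by = 10))
  expect_equal(percentile_rank(tab)$rank, zscore_rank(tab)$rank)
  expect_equal(percentile_rank(tab)$rank[1], 1)
  # an extreme outlier reorders mid-table rows under z-scoring but leaves
  # their percentile ordering untouched
  base <- score_tbl(c(-9, -8.0, -7.6, -7.4, -5), c(-55, -35, -41, -42, -20))
  spiked <- base
  spiked$gscore[5] <- -60   # absurdly good docking score
  mid <- 2:4
  expect_equal(order(percentile_rank(spiked)$rank[mid]),
               order(percentile_rank(base)$rank[mid]))
  expect_false(identical(order(zscore_rank(spiked)$rank[mid]),
                         order(zscore_rank(base)$rank[mid])))
})

test_that("weighted z-scores reduce to equal weighting and to projections", {
  withr::local_seed(2)
  tab <- score_tbl(rnorm(20, -7), rnorm(20, -40, 8))
  expect_equal(weighted_zscore_rank(tab, 0.5, 0.5)$rank, zscore_rank(tab)$rank)
  expect_equal(weighted_zscore_rank(tab, 1, 0)$rank, rank(tab$gscore))
  # equal z-margins: the MM-GBSA-better row wins under 0.4/0.6
  m <- score_tbl(c(-7, -7 - 0.91, -7), c(-40, -40, -40 - 9.65))
  w <- weighted_zscore_rank(m)
  expect_lt(w$rank[3], w$rank[2])
})

test_that("Pareto peeling reproduces the worked 4-row frontier sequence", {
  tab <- score_tbl(c(-10, -9, -8, -10), c(-60, -65, -50, -50),
                   ids = c("A", "B", "C", "D"))
  pr <- pareto_rank(tab)
  expect_equal(pr$rank, c(1L, 1L, 3L, 2L))
  # duplicates are mutually non-dominating
  dup <- pareto_rank(score_tbl(c(-5, -5), c(-30, -30)))
  expect_equal(dup$rank, c(1L, 1L))
})

test_that("peeled frontier 1 equals the brute-force non-dominated set", {
  withr::local_seed(14)
  for (i in 1:30) {
    n <- sample(2:60, 1)
    tab <- score_tbl(round(rnorm(n, -7), 2), round(rnorm(n, -40, 9), 1))
    pr <- pareto_rank(tab)
    expect_setequal(pr$compound_id[pr$rank == 1], brute_force_front(tab))
  }
})

test_that("strict cutoffs are inclusive conjunctions with passers ranked first", {
  tab <- score_tbl(c(-6.0, -5.9, -7, -6.5), c(-40.0, -60, -39.9, -45))
  sc <- strict_cutoff_rank(tab)
  expect_equal(sc$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(sc, "pass_fraction"), 0.5)
  expect_true(all(sc$rank[sc$pass] < sc$rank[!sc$pass]))
  expect_equal(sort(sc$rank), 1:4)
})

test_that("ensemble ranking averages five methods and respects invariances", {
  withr::local_seed(33)
  tab <- score_tbl(rnorm(40, -7), rnorm(40, -40, 9))
  hr <- rank_hits(tab)
  expect_equal(hr$table$ensemble_rank,
               (hr$table$rank_zscore + hr$table$rank_percentile +
                  hr$table$rank_weighted + hr$table$rank_pareto +
                  hr$table$rank_cutoff) / 5)
  # a strictly dominating row is rank 1 for every method
  dom <- dplyr::bind_rows(tab, score_tbl(-99, -99, "BEST"))
  hd <- rank_hits(dom)$table
  best <- hd[hd$compound_id == "BEST", ]
  expect_equal(best$rank_zscore, 1)
  expect_equal(best$rank_percentile, 1)
  expect_equal(best$rank_weighted, 1)
  expect_equal(best$rank_pareto, 1L)
  expect_equal(best$rank_cutoff, 1)
  expect_equal(best$ensemble_position, 1)
  # permutation invariance
  perm <- withr::with_seed(4, tab[sample(nrow(tab)), ])
  hp <- rank_hits(perm)$table
  merged <- dplyr::left_join(hr$table, hp,
                             by = "compound_id", suffix = c("", ".p"))
  expect_equal(merged$ensemble_rank, merged$ensemble_rank.p)
  # improving both metrics never worsens the ensemble rank
  better <- tab
  better$gscore[7] <- better$gscore[7] - 2
  better$dg_bind[7] <- better$dg_bind[7] - 10
  hb <- rank_hits(better)$table
  expect_lte(hb$ensemble_rank[7], hr$table$ensemble_rank[7])
})

test_that("rows with missing metrics are excluded and reported", {
  tab <- score_tbl(c(-7, NA, -6), c(-40, -50, NA))
  suppressWarnings(hr <- rank_hits(tab))  # n = 1: correlation undefined
  expect_equal(nrow(hr$table), 1L)
  expect_equal(nrow(hr$excluded), 2L)
  expect_equal(hr$params$n_excluded_missing, 2L)
})

test_that("score summaries match hand arithmetic and flag degenerate input", {
  tab <- score_tbl(c(-6, -7, -8), c(-30, -40, -50))
  s <- score_summary(tab)
  expect_equal(s$metrics$mean, c(-7, -40))
  expect_equal(s$metrics$median, c(-7, -40))
  expect_equal(s$metrics$sd, c(1, 10))
  expect_equal(s$metrics$min, c(-8, -50))
  expect_equal(s$metrics$max, c(-6, -30))
  expect_equal(s$pearson_r, 1)
  expect_equal(s$n, 3L)
  expect_warning(s0 <- score_summary(score_tbl(c(-6, -6), c(-30, -40))),
                 "undefined")
  expect_true(is.na(s0$pearson_r))
})
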