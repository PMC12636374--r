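#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Computes the proper rotation `R` and translation `t` minimizing the RMSD
#' between two paired coordinate sets, by SVD of the covariance matrix with
#' the usual determinant correction so that no reflection is introduced.
#'
#' @param mobile numeric `A x 3` matrix to be moved.
#' @param target numeric `A x 3` matrix to move onto.
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `mobile %*% rotation + translation` best fits `target`, and `rmsd`, the
#'   residual RMSD after fitting.
#' @export
kabsch <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target), ncol(mobile) == 3, ncol(target) == 3)
  if (nrow(mobile) < 3L)
    abort("superpose stage: need at least 3 atoms")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  sp <- svd(P)$d
  if (sp[2] < 1e-8 * max(sp[1], 1))  # rank < 2: all atoms collinear
    abort("superpose stage: degenerate (collinear) geometry")
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)          # right-multiplication convention
  t_vec <- ct - as.vector(cm %*% R)
  fitted <- mobile %*% R + rep(t_vec, each = nrow(mobile))
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

#' Superpose every model of an ensemble onto the reference model
#'
#' Applies a least-squares rigid fit ([kabsch()]) of each non-reference
#' model onto the reference model over all atoms of the ensemble's
#' selection. The reference model itself is left untouched.
#'
#' @param x a [conformer_ensemble].
#' @return the ensemble with transformed coordinates and `superposed = TRUE`.
#' @export
superpose_models <- function(x) {
  stopifnot(inherits(x, "conformer_ensemble"))
  if (n_models(x) < 2L) abort("superpose stage: need at least 2 models")
  ref <- x$coords[x$reference_index, , ]
  for (m in seq_len(n_models(x))) {
    if (m == x$reference_index) next
    fit <- kabsch(x$coords[m, , ], ref)
    x$coords[m, , ] <- x$coords[m, , ] %*% fit$rotation +
      rep(fit$translation, each = n_atoms(x))
  }
  x$superposed <- TRUE
  x
}

# plain coordinate RMSD between two A x 3 matrices, no refitting
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Pairwise RMSD matrix over a superposed ensemble
#'
#' Entry (i, j) is the root mean squared coordinate deviation over all
#' selected atoms between models i and j *as aligned to the common
#' reference* — models are not re-fitted pair by pair, matching the
#' align-then-measure order of operations of the ensemble workflow. Set
#' `per_pair = TRUE` to refit every pair before measuring instead.
#'
#' @param x a [conformer_ensemble] (superposed; a warning is issued if not).
#' @param per_pair refit each model pair with [kabsch()] before measuring.
#' @return symmetric `M x M` matrix of class `rmsd_matrix`, in Angstrom,
#'   with `model_ids` as dimnames.
#' @export
pairwise_rmsd <- function(x, per_pair = FALSE) {
  stopifnot(inherits(x, "conformer_ensemble"))
  if (!x$superposed)
    warn("ensemble is not superposed; RMSDs include rigid-body differences")
  m <- n_models(x)
  out <- matrix(0, m, m, dimnames = list(x$model_ids, x$model_ids))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      out[i, j] <- out[j, i] <- if (per_pair)
        kabsch(x$coords[j, , ], x$coords[i, , ])$rmsd
      else
        coord_rmsd(x$coords[i, , ], x$coords[j, , ])
    }
  }
  class(out) <- c("rmsd_matrix", class(out))
  out
}

#' Summary statistics of a pairwise RMSD matrix
#'
#' Mean, SD, min and max are taken over the strictly off-diagonal entries
#' with each unordered model pair counted once. The per-model mean is the
#' mean of each row excluding the diagonal (each model's average RMSD to
#' all other models).
#'
#' @param mat an `rmsd_matrix` (any symmetric matrix works).
#' @return list with `stats` (one-row tibble: `mean`, `sd`, `min`, `max`,
#'   `n_pairs`) and `per_model` (tibble: `model`, `mean_rmsd`).
#' @export
rmsd_summary <- function(mat) {
  m <- nrow(mat)
  if (m < 2L) abort("rmsd stage: need at least 2 models")
  vals <- mat[upper.tri(mat)]
  ids <- if (!is.null(rownames(mat))) as.integer(rownames(mat)) else seq_len(m)
  per_model <- vapply(seq_len(m), function(i) mean(mat[i, -i]), numeric(1))
  list(
    stats = tibble(mean = mean(vals),
                   sd = if (length(vals) > 1) sd(vals) else 0,
                   min = min(vals), max = max(vals),
                   n_pairs = length(vals)),
    per_model = tibble(model = ids, mean_rmsd = per_model)
  )
}

#' Radius of gyration of each model
#'
#' Mass-unweighted Rg: the root mean square distance of the selected atoms
#' from their geometric centroid.
#'
#' @param x a [conformer_ensemble], or a single `A x 3` coordinate matrix.
#' @return tibble with `model` and `rg` (Angstrom); for a bare matrix, a
#'   single number.
#' @export
radius_of_gyration <- function(x) {
  rg1 <- function(xyz) {
    ctr <- colMeans(xyz)
    sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  }
  if (is.matrix(x)) return(rg1(x))
  stopifnot(inherits(x, "conformer_ensemble"))
  tibble(model = x$model_ids,
         rg = vapply(seq_len(n_models(x)), function(m) rg1(x$coords[m, , ]),
                     numeric(1)))
}

#' Per-residue flexibility (RMSF) profile
#'
#' Per atom, the RMSF is the root mean square deviation of that atom's
#' position across models from its ensemble-mean position; per residue, the
#' mean of its backbone atoms' RMSFs. Residues with RMSF above the 75th
#' percentile of the per-residue vector are flagged as high-flexibility.
#'
#' @param x a superposed [conformer_ensemble].
#' @return list of class `flexibility_profile`: `per_atom` tibble
#'   (`atom_index`, `chain`, `resno`, `insert`, `atom`, `rmsf`),
#'   `per_residue` tibble (`chain`, `resno`, `insert`, `rmsf`, `high_flex`),
#'   `rmsf_mean` (mean of per-residue RMSF), `threshold_75` and
#'   `rg` tibble from [radius_of_gyration()].
#' @export
rmsf_profile <- function(x) {
  stopifnot(inherits(x, "conformer_ensemble"))
  if (n_models(x) < 2L) {
    warn("single-model ensemble: all RMSF values are zero")
    atom_rmsf <- rep(0, n_atoms(x))
  } else {
    mean_pos <- apply(x$coords, c(2, 3), mean)
    dev2 <- sweep(x$coords, c(2, 3), mean_pos)^2
    atom_rmsf <- sqrt(colMeans(dev2[, , 1] + dev2[, , 2] + dev2[, , 3]))
  }
  per_atom <- dplyr::bind_cols(tibble(atom_index = seq_len(n_atoms(x))),
                               x$atoms[, c("chain", "resno", "insert", "atom")],
                               tibble(rmsf = atom_rmsf))
  per_res <- per_atom |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert) |>
    dplyr::summarise(rmsf = mean(.data$rmsf), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
  thr <- unname(quantile(per_res$rmsf, 0.75, type = 7))
  per_res$high_flex <- per_res$rmsf > thr
  structure(
    list(per_atom = per_atom, per_residue = per_res,
         rmsf_mean = mean(per_res$rmsf), threshold_75 = thr,
         rg = radius_of_gyration(x)),
    class = "flexibility_profile"
  )
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat(sprintf("<flexibility_profile> %d residues | mean RMSF %.3f A | 75th pct %.3f A | %d high-flex\n",
              nrow(x$per_residue), x$rmsf_mean, x$threshold_75,
              sum(x$per_residue$high_flex)))
  invisible(x)
}
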