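# Synthetic inputs with planted ground truth. The "proteins" are
# geometric helical backbones (ideal-bond polylines), which is all the
# RMSD/clustering machinery needs; they make no attempt at physically
# valid structures.

# idealized backbone for n_residues: helical CA trace with N/C/O offsets
backbone_template <- function(n_residues) {
  t <- seq_len(n_residues)
  ca <- cbind(8 * cos(t * 100 * pi / 180), 8 * sin(t * 100 * pi / 180),
              1.5 * t)
  offs <- list(N = c(-1.2, 0.3, -0.5), CA = c(0, 0, 0),
               C = c(1.0, 0.4, 0.6), O = c(1.3, 1.5, 0.8))
  atoms <- tidyr::expand_grid(resno = t, atom = c("N", "CA", "C", "O"))
  xyz <- as.matrix(ca[atoms$resno, ]) +
    t(vapply(atoms$atom, function(a) offs[[a]], numeric(3)))
  list(atoms = tibble(chain = "A", resno = atoms$resno, insert = "",
                      atom = atoms$atom, resid = "ALA"),
       xyz = xyz)
}

#' Generate a synthetic multi-state conformer ensemble
#'
#' Builds a backbone-only chain-A ensemble with planted cluster structure:
#' cluster mean conformations differ by an internal hinge displacement of
#' the C-terminal third of the chain (so the separation survives
#' superposition), every model gets isotropic Gaussian coordinate noise,
#' and optional outlier models carry an additional large internal
#' displacement of the central segment. Byte-identical output for a fixed
#' seed.
#'
#' @param n_models total number of models, outliers included (default 15).
#' @param n_residues chain length (default 127 residues, 4 backbone atoms
#'   each).
#' @param occupancies cluster occupancy fractions, summing to 1
#'   (default `c(0.87, 0.13)`, a dominant basin plus a minor state).
#' @param shift inter-cluster hinge displacement in Angstrom (default 6).
#' @param noise_sigma isotropic Gaussian noise SD per coordinate in
#'   Angstrom (default 0.5).
#' @param n_outliers number of planted outlier models (default 0).
#' @param outlier_shift outlier displacement in Angstrom (default 50).
#' @param seed integer RNG seed.
#' @param path optional file path; when given the ensemble is also
#'   written as a multi-model PDB.
#' @return list: `ensemble` (a [conformer_ensemble]), `labels` tibble
#'   (`model`, `cluster` planted 1-based id, `outlier`), `spec` (the
#'   arguments).
#' @export
make_two_state_ensemble <- function(n_models = 15L, n_residues = 127L,
                                    occupancies = c(0.87, 0.13),
                                    shift = 6, noise_sigma = 0.5,
                                    n_outliers = 0L, outlier_shift = 50,
                                    seed = 20251104L, path = NULL) {
  stopifnot(abs(sum(occupancies) - 1) < 1e-8, noise_sigma >= 0, shift >= 0,
            n_outliers < n_models)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  tmpl <- backbone_template(n_residues)
  n_atoms <- nrow(tmpl$atoms)
  n_core <- n_models - n_outliers
  sizes <- floor(occupancies * n_core)
  rem <- n_core - sum(sizes)
  if (rem > 0) {
    give <- order(occupancies * n_core - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[give] <- sizes[give] + 1L
  }
  cluster_of <- sample(rep(seq_along(sizes), sizes))
  outlier_models <- if (n_outliers > 0)
    sample(n_models, n_outliers) else integer()
  labels <- integer(n_models)
  labels[setdiff(seq_len(n_models), outlier_models)] <- cluster_of
  # cluster k mean: hinge-displace the C-terminal third by (k-1)*shift in x
  hinge <- tmpl$atoms$resno > (2 * n_residues) %/% 3
  mid <- tmpl$atoms$resno > n_residues %/% 4 &
    tmpl$atoms$resno <= (3 * n_residues) %/% 4
  coords <- array(NA_real_, c(n_models, n_atoms, 3))
  for (m in seq_len(n_models)) {
    xyz <- tmpl$xyz
    if (m %in% outlier_models) {
      xyz[mid, 2] <- xyz[mid, 2] + outlier_shift
    } else {
      xyz[hinge, 1] <- xyz[hinge, 1] + (labels[m] - 1L) * shift
    }
    xyz <- xyz + matrix(rnorm(length(xyz), sd = noise_sigma), ncol = 3)
    coords[m, , ] <- xyz
  }
  ens <- conformer_ensemble(coords, tmpl$atoms, model_ids = seq_len(n_models))
  if (!is.null(path)) write_multimodel_pdb(ens, path)
  list(ensemble = ens,
       labels = tibble(model = seq_len(n_models), cluster = labels,
                       outlier = seq_len(n_models) %in% outlier_models),
       spec = list(n_models = n_models, n_residues = n_residues,
                   occupancies = occupancies, shift = shift,
                   noise_sigma = noise_sigma, n_outliers = n_outliers,
                   outlier_shift = outlier_shift, seed = seed))
}

#' Generate a synthetic docking/MM-GBSA score table
#'
#' Draws (docking score, binding energy) pairs from a bivariate normal
#' with the requested means, SDs and Pearson correlation. When
#' `pass_fraction` is given, the minimal number of rows is mirrored
#' across the cutoff boundary so that exactly `round(pass_fraction * n)`
#' rows pass both inclusive cutoffs; the realized pass set is recorded as
#' ground truth either way.
#'
#' @param n number of compounds.
#' @param g_mean,g_sd docking-score distribution (kcal/mol; defaults
#'   -6.80 / 0.91).
#' @param dg_mean,dg_sd binding-energy distribution (kcal/mol; defaults
#'   -41.47 / 9.65).
#' @param r target Pearson correlation (default 0.363).
#' @param pass_fraction optional exact dual-cutoff pass fraction to plant.
#' @param g_cut,dg_cut the cutoffs the pass set refers to.
#' @param seed integer RNG seed.
#' @param path optional CSV output path.
#' @return tibble (`compound_id`, `gscore`, `dg_bind`) with
#'   `attr(, "planted")`: the generating parameters, pass ids and realized
#'   pass fraction.
#' @export
make_score_table <- function(n, g_mean = -6.80, g_sd = 0.91,
                             dg_mean = -41.47, dg_sd = 9.65, r = 0.363,
                             pass_fraction = NULL, g_cut = -6.0,
                             dg_cut = -40.0, seed = 20251104L,
                             path = NULL) {
  stopifnot(n >= 2, abs(r) < 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  g <- g_mean + g_sd * z1
  dg <- dg_mean + dg_sd * z2
  if (!is.null(pass_fraction)) {
    target <- round(pass_fraction * n)
    pass <- g <= g_cut & dg <= dg_cut
    if (sum(pass) > target) {
      # push the weakest passers just over the nearer cutoff
      margin <- pmin((g_cut - g[pass]) / g_sd, (dg_cut - dg[pass]) / dg_sd)
      flip <- which(pass)[order(margin)][seq_len(sum(pass) - target)]
      nearer <- (g_cut - g[flip]) / g_sd <= (dg_cut - dg[flip]) / dg_sd
      g[flip][nearer] <- 2 * g_cut - g[flip][nearer]
      dg[flip][!nearer] <- 2 * dg_cut - dg[flip][!nearer]
    } else if (sum(pass) < target) {
      # mirror the closest non-passers across their failing cutoff(s)
      excess <- pmax(g - g_cut, 0) / g_sd + pmax(dg - dg_cut, 0) / dg_sd
      flip <- which(!pass)[order(excess[!pass])][seq_len(target - sum(pass))]
      gbad <- g[flip] > g_cut
      g[flip][gbad] <- 2 * g_cut - g[flip][gbad]
      dbad <- dg[flip] > dg_cut
      dg[flip][dbad] <- 2 * dg_cut - dg[flip][dbad]
    }
  }
  out <- tibble(compound_id = sprintf("CMPD%05d", seq_len(n)),
                gscore = g, dg_bind = dg)
  pass <- g <= g_cut & dg <= dg_cut
  attr(out, "planted") <- list(
    g_mean = g_mean, g_sd = g_sd, dg_mean = dg_mean, dg_sd = dg_sd, r = r,
    g_cut = g_cut, dg_cut = dg_cut, seed = seed,
    pass_ids = out$compound_id[pass], pass_fraction = mean(pass))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

# deterministic pools of molecules with known filter outcomes
smiles_pool <- function(category, n) {
  out <- switch(
    category,
    # small neutral amides and alcohols: pass every default filter
    pass = {
      grid <- tidyr::expand_grid(a = 1:8, b = 0:8)
      grid <- grid[grid$a + grid$b <= 9, ]
      amides <- paste0(strrep("C", grid$a), "C(=O)N",
                       ifelse(grid$b > 0, strrep("C", grid$b), ""))
      eth <- tidyr::expand_grid(a = 1:8, b = 1:8)
      eth <- eth[eth$a <= eth$b & eth$a + eth$b <= 9, ]  # symmetric dups out
      ethers <- paste0(strrep("C", eth$a), "O", strrep("C", eth$b))
      alcohols <- paste0(strrep("C", 2:9), "O")
      c(alcohols, amides, ethers)
    },
    # MW > 500 (and cLogP > 5): fail at the Lipinski stage
    lipinski = paste0(strrep("C", 36:75), "O"),
    # long diols and PEG chains: > 10 rotatable bonds, Lipinski-clean
    druglike = c(paste0("OC", strrep("C", 10:14), "CO"),
                 paste0("O", strrep("CCO", 5:9))),
    # rhodanine (PAINS) and acyl-halide (BRENK) chemotypes
    alert = c(paste0("O=C1CSC(=S)N1", c("", "C", "CC", "CCC", "CCCC")),
              paste0(strrep("C", 1:5), "C(=O)Cl"),
              paste0("S1C(=S)N(", strrep("C", 6:9), ")C(=O)C1"),
              paste0("O=C(Cl)c1ccc(", strrep("C", 1:6), ")cc1")),
    # small quaternary ammonium ions: a permanent +1 that passes every
    # earlier filter and only the charge screen can remove
    charged = c(paste0("C[N+](C)(C)", strrep("C", 1:8)),
                paste0("C[N+](C)(C)", strrep("C", 2:7), "O"),
                "C[N+](C)(C)Cc1ccccc1", "CC[N+](CC)(CC)CC",
                "C[N+]1(C)CCCCC1", "C[N+]1(C)CCCC1",
                "C[N+]1(C)CCOCC1", "C[N+](C)(C)CC(C)C"),
    # invalid atom symbols / unclosed rings and branches
    malformed = c("XYZ123", "C1CCC", "c1ccc", ")(", "QQ", "Cl(=O)=Q",
                  paste0("C1CC", 2:45))
  )
  if (n > length(out))
    abort(sprintf("fixtures: only %d '%s' molecules available (%d asked)",
                  length(out), category, n))
  out[seq_len(n)]
}

#' Generate a SMILES fixture with planted filter outcomes
#'
#' Emits a compound table mixing molecules planted to pass all default
#' filters, to fail the Lipinski, drug-likeness, structural-alert or
#' neutrality stage, to be unparseable, or to duplicate an earlier passer
#' (written as the reversed SMILES string of a chain alcohol, so the
#' duplicate is only detectable after canonicalization). Rows are
#' shuffled deterministically under the seed.
#'
#' @param n_pass,n_lipinski,n_druglike,n_alert,n_charged,n_malformed,n_duplicates
#'   counts per category.
#' @param seed integer RNG seed.
#' @param path optional CSV output path.
#' @return tibble (`compound_id`, `smiles`, `category`); category is the
#'   planted ground truth, with `attr(, "planted")` the count table.
#' @export
make_smiles_fixture <- function(n_pass = 10L, n_lipinski = 0L,
                                n_druglike = 0L, n_alert = 0L,
                                n_charged = 0L, n_malformed = 0L,
                                n_duplicates = 0L, seed = 20251104L,
                                path = NULL) {
  if (n_duplicates > 0L && n_pass < n_duplicates)
    abort("fixtures: need at least as many passers as duplicates")
  rows <- list(
    tibble(smiles = smiles_pool("pass", n_pass), category = "pass"),
    tibble(smiles = smiles_pool("lipinski", n_lipinski),
           category = "lipinski_fail"),
    tibble(smiles = smiles_pool("druglike", n_druglike),
           category = "druglike_fail"),
    tibble(smiles = smiles_pool("alert", n_alert), category = "alert_fail"),
    tibble(smiles = smiles_pool("charged", n_charged),
           category = "charged_fail"),
    tibble(smiles = smiles_pool("malformed", n_malformed),
           category = "malformed")
  )
  if (n_duplicates > 0L) {
    # rewrite each duplicated passer from the other end of the molecule:
    # chain alcohols/ethers reverse as strings, amides swap to the
    # N-first spelling; either way the canonical form collides
    dups <- vapply(smiles_pool("pass", n_duplicates), function(s) {
      m <- regmatches(s, regexec("^(C*)C\\(=O\\)N(C*)$", s))[[1]]
      if (length(m) == 3L) paste0(m[3], "NC(=O)", m[2])
      else paste(rev(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    rows <- c(rows, list(tibble(smiles = dups, category = "duplicate")))
  }
  out <- dplyr::bind_rows(rows)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  out <- out[sample(nrow(out)), ]
  out <- dplyr::mutate(out, compound_id = sprintf("FIX%04d",
                                                  dplyr::row_number()),
                       .before = 1)
  attr(out, "planted") <- list(n_pass = n_pass, n_lipinski = n_lipinski,
                               n_druglike = n_druglike, n_alert = n_alert,
                               n_charged = n_charged,
                               n_malformed = n_malformed,
                               n_duplicates = n_duplicates, seed = seed)
  if (!is.null(path))
    write.csv(out[, c("compound_id", "smiles")], path, row.names = FALSE)
  out
}
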