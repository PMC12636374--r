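#' Conformer ensemble container
#'
#' Holds the backbone coordinates of a multi-model structure as an
#' `M x A x 3` array (models x atoms x xyz, in Angstrom) together with the
#' atom labels shared by every model. All models are guaranteed to carry an
#' identical atom list; downstream RMSD/RMSF machinery relies on that.
#'
#' @param coords numeric array `M x A x 3`, finite.
#' @param atoms tibble with one row per atom: `chain`, `resno`, `insert`,
#'   `atom` (atom name), `resid` (residue name, may be `NA`).
#' @param model_ids integer vector of length `M` (PDB MODEL numbers).
#' @param reference_index index (into `model_ids`) of the superposition
#'   reference model.
#' @param superposed logical; `TRUE` once [superpose_models()] has been run.
#'
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(coords, atoms, model_ids = seq_len(dim(coords)[1]),
                               reference_index = 1L, superposed = FALSE) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    abort("`coords` must be an M x A x 3 array.")
  if (!all(is.finite(coords)))
    abort("`coords` must be finite.")
  atoms <- as_tibble(atoms)
  if (nrow(atoms) != dim(coords)[2])
    abort("`atoms` must have one row per atom column of `coords`.")
  if (length(model_ids) != dim(coords)[1])
    abort("`model_ids` must have one entry per model.")
  if (reference_index < 1L || reference_index > dim(coords)[1])
    abort("`reference_index` is not a valid model index.")
  structure(
    list(coords = coords, atoms = atoms,
         model_ids = as.integer(model_ids),
         reference_index = as.integer(reference_index),
         superposed = isTRUE(superposed)),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d models x %d atoms (%s)\n",
              n_models(x), n_atoms(x),
              if (x$superposed) "superposed" else "raw"))
  cat(sprintf("  chains: %s | residues: %d | reference model: %d\n",
              paste(unique(x$atoms$chain), collapse = ","),
              length(unique(residue_keys(x))),
              x$model_ids[x$reference_index]))
  invisible(x)
}

#' @rdname conformer_ensemble
#' @param x a `conformer_ensemble`.
#' @export
n_models <- function(x) dim(x$coords)[1]

#' @rdname conformer_ensemble
#' @export
n_atoms <- function(x) dim(x$coords)[2]

# unique residue key per atom, insertion codes retained
residue_keys <- function(x) {
  paste(x$atoms$chain, x$atoms$resno, x$atoms$insert, sep = "|")
}

# M x 3A flattened coordinate matrix (x1,y1,z1,x2,...) used for k-means,
# PCA and the isolation forest
flatten_coords <- function(x) {
  m <- n_models(x); a <- n_atoms(x)
  out <- matrix(aperm(x$coords, c(3, 2, 1)), nrow = m, ncol = 3 * a, byrow = TRUE)
  rownames(out) <- x$model_ids
  out
}

#' Read a multi-model PDB file into a conformer ensemble
#'
#' Parses a PDB (or mmCIF) file containing at least two MODEL records,
#' restricts atoms to one chain and a set of atom names (backbone
#' N, CA, C, O by default), and checks that every model carries the exact
#' same atom list. Alternate locations are resolved to the
#' highest-occupancy record (first on ties); insertion codes are kept as
#' part of the residue key.
#'
#' @param path path to a PDB/mmCIF file.
#' @param chain chain identifier to keep (default `"A"`).
#' @param atom_names atom names to keep (default backbone `N, CA, C, O`).
#' @param reference 1-based model index used as superposition reference.
#'
#' @return A [conformer_ensemble].
#' @export
read_multimodel_pdb <- function(path, chain = "A",
                                atom_names = c("N", "CA", "C", "O"),
                                reference = 1L) {
  if (!file.exists(path)) abort(paste0("read stage: file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("read stage: cannot parse PDB: ",
                                     conditionMessage(e)))
  )
  n_mod <- nrow(pdb$xyz)
  if (is.null(n_mod) || n_mod < 2L)
    abort("read stage: file contains fewer than 2 MODEL records")
  check_model_consistency(path, chain, atom_names)

  at <- pdb$atom
  keep <- at$type == "ATOM" & at$chain %in% chain & at$elety %in% atom_names
  if (!any(at$chain %in% chain & at$type == "ATOM"))
    abort(paste0("read stage: requested chain '", chain, "' absent"))
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  idx <- which(keep)
  # altloc: highest occupancy wins, first record on ties
  key <- paste(at$chain[idx], at$resno[idx], at$insert[idx], at$elety[idx])
  ord <- idx[order(match(key, unique(key)), -at$o[idx], seq_along(idx))]
  ord <- ord[!duplicated(paste(at$chain[ord], at$resno[ord],
                               at$insert[ord], at$elety[ord]))]
  ord <- sort(ord)
  if (length(ord) < 1L)
    abort("read stage: no atoms match the requested chain/atom names")

  xyz_cols <- as.vector(rbind(3 * ord - 2, 3 * ord - 1, 3 * ord))
  coords <- array(NA_real_, dim = c(n_mod, length(ord), 3))
  for (m in seq_len(n_mod)) {
    coords[m, , ] <- matrix(pdb$xyz[m, xyz_cols], ncol = 3, byrow = TRUE)
  }
  atoms <- tibble(
    chain = at$chain[ord], resno = at$resno[ord],
    insert = at$insert[ord], atom = at$elety[ord], resid = at$resid[ord]
  )
  conformer_ensemble(coords, atoms, model_ids = seq_len(n_mod),
                     reference_index = reference)
}

# Line-level scan of MODEL blocks: bio3d recycles the first model's atom
# table, so unequal/reordered atom lists across models must be caught here.
check_model_consistency <- function(path, chain, atom_names) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  starts <- which(trimws(rec) == "MODEL")
  if (length(starts) < 2L) return(invisible(TRUE))
  ends <- which(trimws(rec) == "ENDMDL")
  if (length(ends) < length(starts))
    abort("read stage: MODEL record without matching ENDMDL")
  sig <- character(length(starts))
  for (i in seq_along(starts)) {
    blk <- lines[starts[i]:ends[i]]
    blk <- blk[substr(blk, 1, 6) == "ATOM  "]
    ch <- substr(blk, 22, 22)
    name <- trimws(substr(blk, 13, 16))
    keep <- ch %in% chain & name %in% atom_names
    alt <- substr(blk, 17, 17)
    keep <- keep & alt %in% c(" ", "A", "1")
    sig[i] <- paste(name[keep], trimws(substr(blk, 23, 27)[keep]),
                    collapse = ";")
  }
  if (length(unique(sig)) != 1L)
    abort("read stage: inconsistent atom lists across models")
  invisible(TRUE)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' Emits standard `MODEL`/`ATOM`/`ENDMDL` records. Used mainly by the
#' synthetic-fixture generator; the format is round-trippable through
#' [read_multimodel_pdb()].
#'
#' @param x a [conformer_ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- x$atoms
  resid <- ifelse(is.na(at$resid), "GLY", at$resid)
  for (m in seq_len(n_models(x))) {
    writeLines(sprintf("MODEL     %4d", x$model_ids[m]), con)
    lines <- sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(n_atoms(x)),
      ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom), "",
      resid, at$chain, at$resno, ifelse(at$insert == "", " ", at$insert),
      x$coords[m, , 1], x$coords[m, , 2], x$coords[m, , 3],
      1, 0, substr(at$atom, 1, 1)
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Locate or download a PDB entry
#'
#' Looks for `<id>.pdb` in `dir`, the package's `extdata` folder and the
#' working directory before attempting a download from RCSB. Returns
#' `NULL` (with a message) when the entry cannot be obtained, e.g. on an
#' offline machine, so callers can degrade gracefully.
#'
#' @param id 4-character PDB accession (e.g. `"1B8Q"`).
#' @param dir cache directory for downloads (default `tempdir()`).
#' @return path to the PDB file, or `NULL` if unobtainable.
#' @export
fetch_pdb_entry <- function(id, dir = tempdir()) {
  fname <- paste0(toupper(id), ".pdb")
  candidates <- c(file.path(dir, fname),
                  system.file("extdata", fname, package = "screenkit"),
                  file.path(getwd(), fname))
  for (p in candidates) if (nzchar(p) && file.exists(p)) return(p)
  dest <- file.path(dir, fname)
  url <- paste0("https://files.rcsb.org/download/", fname)
  ok <- tryCatch({
    suppressWarnings(utils::download.file(url, dest, quiet = TRUE,
                                          mode = "wb"))
    file.exists(dest) && file.size(dest) > 1000
  }, error = function(e) FALSE)
  if (isTRUE(ok)) return(dest)
  message("PDB entry ", id, " is not cached locally and could not be ",
          "downloaded (offline?)")
  NULL
}
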