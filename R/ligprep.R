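#' Detect the delimiter of a SMILES table
#'
#' Picks the candidate (comma, tab, semicolon) that yields a consistent
#' column count of at least 2 over the first 50 non-empty lines; the comma
#' wins ties.
#'
#' @param x a file path, or a character vector of lines.
#' @return single delimiter string.
#' @export
sniff_delimiter <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x))
    readLines(x, n = 50L, warn = FALSE) else as.character(x)
  lines <- head(lines[nzchar(trimws(lines))], 50L)
  if (length(lines) == 0L) abort("ligprep: empty input")
  for (delim in c(",", "\t", ";")) {
    # field count = delimiter occurrences + 1 (keeps trailing empties)
    counts <- nchar(lines) - nchar(gsub(delim, "", lines, fixed = TRUE)) + 1L
    if (all(counts == counts[1]) && counts[1] >= 2L) return(delim)
  }
  abort("ligprep: no delimiter yields a consistent table of >= 2 columns")
}

#' Parse a delimited SMILES table
#'
#' Reads a delimited file (delimiter auto-detected unless given), locates
#' the SMILES and id columns (by name, case-insensitively, unless named
#' explicitly), and returns one record per row. Rows with an empty SMILES
#' field are logged as malformed, never raised.
#'
#' @param path input file.
#' @param delimiter explicit delimiter, or `NULL` to auto-detect.
#' @param smiles_col,id_col column names; `NULL` picks a column named like
#'   `smiles` and an id-like column (falling back to row numbers).
#' @return tibble: `row`, `compound_id`, `smiles`; malformed rows are in
#'   `attr(, "malformed")`.
#' @export
parse_smiles_table <- function(path, delimiter = NULL,
                               smiles_col = NULL, id_col = NULL) {
  if (!file.exists(path)) abort(paste0("ligprep: file not found: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(trimws(first))) {
    warn("ligprep: empty input file")
    out <- tibble(row = integer(), compound_id = character(),
                  smiles = character())
    attr(out, "malformed") <- tibble(row = integer(), reason = character())
    return(out)
  }
  delimiter <- delimiter %||% sniff_delimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", fill = TRUE)
  nm <- tolower(names(df))
  sc <- smiles_col %||% names(df)[match(TRUE, grepl("smiles", nm))]
  if (is.na(sc) || is.null(sc))
    abort("ligprep: no SMILES column found (name one with `smiles_col`)")
  ic <- id_col %||% names(df)[match(TRUE, nm %in%
                                      c("id", "compound_id", "name", "title",
                                        "compound", "idnumber"))]
  ids <- if (is.null(ic) || is.na(ic)) sprintf("row%d", seq_len(nrow(df)))
         else as.character(df[[ic]])
  smiles <- trimws(as.character(df[[sc]]))
  bad <- !nzchar(smiles) | is.na(smiles)
  out <- tibble(row = which(!bad), compound_id = ids[!bad],
                smiles = smiles[!bad])
  attr(out, "malformed") <- tibble(row = which(bad),
                                   reason = "empty_smiles_field")
  out
}

# --- per-molecule stages ---------------------------------------------------

#' Standardize molecules to canonical, neutral parent tautomers
#'
#' Three steps, each via OpenBabel: (1) keep the largest fragment and
#' neutralize protonatable/deprotonatable groups; (2) canonicalize the
#' tautomer through a standard-InChI round trip, which collapses
#' heteroatom-centred (mobile-H) tautomers such as lactam/lactim pairs to
#' one representative; (3) emit canonical SMILES. The result is
#' idempotent: standardizing twice equals standardizing once.
#' Carbon-centred keto/enol pairs are outside the mobile-H model and are
#' not interconverted.
#'
#' @param smiles character vector of SMILES.
#' @return tibble: `smiles_in`, `smiles_canonical` (`NA` where
#'   standardization failed), `inchi`, `net_charge`.
#' @export
standardize_molecules <- function(smiles) {
  ids <- sprintf("m%d", seq_along(smiles))
  parent <- ob_smiles(smiles, ids, "-r")
  parsed <- unname(!is.na(parent))
  inchi <- rep(NA_character_, length(smiles))
  if (any(parsed))
    inchi[parsed] <- ob_inchi(unname(parent[parsed]), ids[parsed])[ids[parsed]]
  charge <- inchi_net_charge(unname(inchi))
  # neutralize only molecules whose parent is net-charged; running the
  # uncharger on a balanced zwitterion would protonate one side only
  fix <- parsed & !is.na(charge) & charge != 0
  if (any(fix)) {
    neut <- ob_smiles(unname(parent[fix]), ids[fix], "--neutralize")[ids[fix]]
    ok <- !is.na(neut)
    inchi[fix][ok] <- ob_inchi(unname(neut[ok]),
                               ids[fix][ok])[ids[fix][ok]]
    charge <- inchi_net_charge(unname(inchi))
  }
  taut <- rep(NA_character_, length(smiles))
  ok <- !is.na(inchi)
  if (any(ok))
    taut[ok] <- ob_inchi_to_smiles(unname(inchi[ok]), ids[ok])[ids[ok]]
  tibble(smiles_in = smiles, parsed = parsed,
         smiles_canonical = unname(taut),
         inchi = unname(inchi),
         net_charge = charge)
}

#' Compute the screening descriptor panel
#'
#' Molecular weight, cLogP, hydrogen-bond donors and acceptors and TPSA
#' come from the OpenBabel descriptor set (Lipinski-style N+O acceptor
#' count); rotatable bonds and the sp3 carbon fraction are counted by
#' SMARTS matching (single non-ring bonds between non-terminal heavy
#' atoms; `[CX4]` over all carbons).
#'
#' @param smiles character vector of valid canonical SMILES.
#' @return tibble: `mw`, `clogp`, `hbd`, `hba`, `tpsa`, `rotb`, `fsp3`.
#' @export
compute_descriptors <- function(smiles) {
  if (length(smiles) == 0L)
    return(tibble(mw = numeric(), clogp = numeric(), hbd = numeric(),
                  hba = numeric(), tpsa = numeric(), rotb = numeric(),
                  fsp3 = numeric()))
  nm <- sprintf("m%d", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, nm)))
  valid <- ChemmineR::validSDF(sdf)
  sdf <- sdf[valid]
  out <- tibble(mw = rep(NA_real_, length(smiles)), clogp = NA_real_,
                hbd = NA_real_, hba = NA_real_, tpsa = NA_real_,
                rotb = NA_real_, fsp3 = NA_real_)
  if (sum(valid) == 0L) return(out)
  pr <- ChemmineR::propOB(sdf)
  count <- function(pat) {
    as.numeric(ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = FALSE))
  }
  rot <- count("[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]") / 2
  n_c <- count("[#6]")
  n_sp3 <- count("[CX4]")
  idx <- match(ChemmineR::cid(sdf), nm)
  out$mw[idx] <- pr$MW; out$clogp[idx] <- pr$logP
  out$hbd[idx] <- pr$HBD; out$hba[idx] <- pr$HBA1
  out$tpsa[idx] <- pr$TPSA; out$rotb[idx] <- rot
  out$fsp3[idx] <- ifelse(n_c > 0, n_sp3 / n_c, 0)
  out
}

#' Lipinski rule-of-five verdicts
#'
#' Default strict mode fails a molecule breaching any of MW > 500,
#' cLogP > 5, HBD > 5, HBA > 10, with one reason code per breached bound;
#' `max_violations = 1` gives the classic one-violation-allowed mode.
#'
#' @param desc descriptor tibble from [compute_descriptors()].
#' @param max_violations violations tolerated before failing (default 0).
#' @return tibble: `pass` logical, `reasons` (`;`-joined codes, `""` when
#'   passing).
#' @export
lipinski_filter <- function(desc, max_violations = 0L) {
  viol <- cbind("MW>500" = desc$mw > 500, "cLogP>5" = desc$clogp > 5,
                "HBD>5" = desc$hbd > 5, "HBA>10" = desc$hba > 10)
  reasons <- apply(viol, 1, function(v)
    paste(colnames(viol)[which(v)], collapse = ";"))
  tibble(pass = rowSums(viol) <= max_violations, reasons = reasons)
}

#' Additional drug-likeness verdicts
#'
#' Defaults: TPSA at most 140 Angstrom^2, at most 10 rotatable bonds, and
#' no lower bound on the sp3 carbon fraction (a pass-through unless
#' configured). All thresholds are configurable; the published workflow
#' this follows names the properties but not its cutoffs, so the defaults
#' are the conventional screening values and are recorded in the run log.
#'
#' @param desc descriptor tibble from [compute_descriptors()].
#' @param tpsa_max,rotb_max,fsp3_min thresholds.
#' @return tibble: `pass`, `reasons`.
#' @export
druglike_filter <- function(desc, tpsa_max = 140, rotb_max = 10,
                            fsp3_min = 0) {
  viol <- cbind(desc$tpsa > tpsa_max, desc$rotb > rotb_max,
                desc$fsp3 < fsp3_min)
  colnames(viol) <- c(sprintf("TPSA>%g", tpsa_max),
                      sprintf("RotB>%g", rotb_max),
                      sprintf("Fsp3<%g", fsp3_min))
  reasons <- apply(viol, 1, function(v)
    paste(colnames(viol)[which(v)], collapse = ";"))
  tibble(pass = rowSums(viol) == 0, reasons = reasons)
}

#' Match molecules against the structural-alert catalogs
#'
#' Substructure-matches every molecule against the PAINS/BRENK/NIH
#' patterns of [alert_catalog()] (or a user-supplied table of the same
#' shape); any match rejects the molecule with the alert identifiers
#' listed.
#'
#' @param smiles character vector of valid SMILES.
#' @param catalog alert table (`catalog`, `alert`, `smarts`).
#' @param catalogs which catalogs to apply (default all three).
#' @return tibble: `pass`, `reasons` (matched `catalog:alert` codes).
#' @export
structural_alerts <- function(smiles, catalog = alert_catalog(),
                              catalogs = c("PAINS", "BRENK", "NIH")) {
  catalog <- catalog[catalog$catalog %in% catalogs, , drop = FALSE]
  if (length(smiles) == 0L)
    return(tibble(pass = logical(), reasons = character()))
  nm <- sprintf("m%d", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, nm)))
  sdf <- sdf[ChemmineR::validSDF(sdf)]
  hits <- matrix(FALSE, length(smiles), nrow(catalog))
  idx <- match(ChemmineR::cid(sdf), nm)
  for (j in seq_len(nrow(catalog))) {
    hits[idx, j] <- as.numeric(
      ChemmineR::smartsSearchOB(sdf, catalog$smarts[j],
                                uniqueMatches = FALSE)) > 0
  }
  labels <- paste0(catalog$catalog, ":", catalog$alert)
  reasons <- apply(hits, 1, function(v) paste(labels[which(v)], collapse = ";"))
  tibble(pass = rowSums(hits) == 0, reasons = reasons)
}

#' Generate 2D or 3D coordinates and write an SDF V2000 file
#'
#' Embeds each molecule with OpenBabel and attaches the descriptor panel
#' as SD tags. 2D uses the rule-based layout (`--gen2d`); 3D relaxes that
#' layout with an MMFF94 steepest-descent minimization, a fully
#' deterministic route (OpenBabel's stochastic conformer search has no
#' seed control, so it is deliberately not used).
#'
#' @param records accepted-records tibble (needs `compound_id`,
#'   `smiles_canonical` and the descriptor columns).
#' @param path output SDF path.
#' @param gen3d embed 3D coordinates instead of 2D (default `FALSE`).
#' @return character vector of compound ids that failed embedding.
#' @export
write_ligand_sdf <- function(records, path, gen3d = FALSE) {
  if (nrow(records) == 0L) { file.create(path); return(character()) }
  ids <- sprintf("m%d", seq_len(nrow(records)))
  out <- ob_convert(paste0(records$smiles_canonical, "\t", ids),
                    "smi", "sdf", "--gen2d")
  if (gen3d) {
    # deterministic 3D: rule-based 2D layout, then force-field relaxation
    # (steepest descent, fixed step budget); OpenBabel's stochastic
    # conformer search is avoided so identical inputs embed identically
    out <- ob_convert(out, "sdf", "sdf",
                      c("--minimize", "--ff", "MMFF94",
                        "--steps", "500", "--sd"))
  }
  blocks <- split_sdf_blocks(out)
  got <- vapply(blocks, function(b) trimws(b[1]), character(1))
  keep <- match(ids, got)
  failed <- records$compound_id[is.na(keep)]
  con <- file(path, "w")
  on.exit(close(con))
  tags <- c(mw = "MW", clogp = "cLogP", hbd = "HBD", hba = "HBA",
            tpsa = "TPSA", rotb = "RotBonds", fsp3 = "Fsp3",
            net_charge = "NetCharge")
  for (i in which(!is.na(keep))) {
    b <- blocks[[keep[i]]]
    mol <- b[seq_len(grep("^M  END", b)[1])]
    mol[1] <- records$compound_id[i]
    mol[2] <- if (gen3d) " screenkit          3D" else " screenkit          2D"
    writeLines(mol, con)
    writeLines(c("> <SMILES>", records$smiles_canonical[i], ""), con)
    for (k in names(tags)) {
      if (!k %in% names(records)) next
      writeLines(c(sprintf("> <%s>", tags[k]),
                   format(records[[k]][i], trim = TRUE), ""), con)
    }
    writeLines("$$$$", con)
  }
  failed
}

split_sdf_blocks <- function(lines) {
  idx <- cumsum(c(1L, head(lines, -1) == "$$$$"))
  unname(split(lines, idx))
}
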