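# Thin wrapper around the OpenBabel CLI. Molecules travel as
# "SMILES<TAB>id" lines; obabel is run with -e (skip bad molecules) and
# the id/title column is used to re-align output with input, so a parse
# failure surfaces as a missing id rather than a shifted table.

have_obabel <- function() nzchar(Sys.which("obabel"))

assert_obabel <- function() {
  if (!have_obabel())
    abort("ligprep: the `obabel` executable is required but not on the PATH")
}

ob_convert <- function(lines, in_format, out_format, args = character()) {
  assert_obabel()
  fin <- tempfile(fileext = paste0(".", in_format))
  on.exit(unlink(fin))
  writeLines(lines, fin)
  out <- suppressWarnings(
    system2("obabel", c(fin, paste0("-o", out_format), "-e", args),
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0 && length(out) == 0L)
    abort(paste0("ligprep: obabel failed (exit ", status, ")"))
  as.character(out)
}

# SMILES + ids -> named character of output SMILES (missing = failed)
ob_smiles <- function(smiles, ids, args = character()) {
  out <- ob_convert(paste0(smiles, "\t", ids), "smi", "can", args)
  parts <- strsplit(out, "\t", fixed = TRUE)
  res <- vapply(parts, function(p) trimws(p[1]), character(1))
  names(res) <- vapply(parts, function(p) trimws(p[2]), character(1))
  res[ids]  # NA for molecules obabel dropped
}

# SMILES + ids -> named InChI strings (missing = failed)
ob_inchi <- function(smiles, ids) {
  out <- ob_convert(paste0(smiles, "\t", ids), "smi", "inchi", "-xt")
  out <- out[startsWith(out, "InChI=")]
  sp <- regexpr(" ", out, fixed = TRUE)
  res <- substr(out, 1, sp - 1)
  names(res) <- trimws(substring(out, sp + 1))
  res[ids]
}

# InChI + ids -> named canonical SMILES (missing = failed). The InChI
# reader drops titles, so alignment is positional; if any molecule is
# skipped the batch falls back to one-at-a-time conversion.
ob_inchi_to_smiles <- function(inchi, ids) {
  out <- ob_convert(inchi, "inchi", "can")
  smi <- trimws(vapply(strsplit(out, "\t", fixed = TRUE),
                       function(p) p[1], character(1)))
  if (length(smi) == length(inchi)) {
    return(setNames(smi, ids))
  }
  one <- vapply(inchi, function(x) {
    o <- ob_convert(x, "inchi", "can")
    if (length(o) == 1L) trimws(strsplit(o, "\t", fixed = TRUE)[[1]][1])
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
  setNames(one, ids)
}

# net formal charge from the standard-InChI /q and /p layers
inchi_net_charge <- function(inchi) {
  vapply(inchi, function(x) {
    if (is.na(x)) return(NA_real_)
    q <- 0
    mq <- regmatches(x, regexpr("/q([+-]?[0-9;+-]*)", x))
    if (length(mq)) {
      vals <- strsplit(sub("^/q", "", mq), ";", fixed = TRUE)[[1]]
      q <- q + sum(as.numeric(vals[nzchar(vals)]), na.rm = TRUE)
    }
    mp <- regmatches(x, regexpr("/p([+-][0-9]+)", x))
    if (length(mp)) q <- q + as.numeric(sub("^/p", "", mp))
    q
  }, numeric(1), USE.NAMES = FALSE)
}
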