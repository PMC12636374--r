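#' Remove duplicate molecules by canonical SMILES
#'
#' The first occurrence (input order) is kept; later duplicates are
#' rejected with a reason naming the kept compound id.
#'
#' @param records tibble with `compound_id` and `smiles_canonical`.
#' @param keep_duplicates retain duplicates (default `FALSE`).
#' @return tibble: `pass`, `reasons`, aligned to `records`.
#' @export
deduplicate <- function(records, keep_duplicates = FALSE) {
  if (keep_duplicates || nrow(records) == 0L)
    return(tibble(pass = rep(TRUE, nrow(records)),
                  reasons = rep("", nrow(records))))
  dup <- duplicated(records$smiles_canonical)
  first_id <- records$compound_id[match(records$smiles_canonical,
                                        records$smiles_canonical)]
  tibble(pass = !dup,
         reasons = ifelse(dup, paste0("duplicate_of:", first_id), ""))
}

ligprep_stages <- c("parse", "standardize", "lipinski", "druglike",
                    "alerts", "net_charge", "dedup", "embed")

# per-molecule stages (standardize -> descriptors -> lipinski -> druglike
# -> alerts -> net charge) for one chunk of records; returns the chunk
# with status/stage/reasons and descriptor columns filled in
ligprep_chunk <- function(chunk, config) {
  n <- nrow(chunk)
  std <- standardize_molecules(chunk$smiles)
  chunk$smiles_canonical <- std$smiles_canonical
  chunk$inchi <- std$inchi
  chunk$net_charge <- std$net_charge
  reject <- function(chunk, idx, stage, reasons) {
    idx <- idx & chunk$status == "accepted"
    chunk$status[idx] <- "rejected"
    chunk$stage[idx] <- stage
    chunk$reasons[idx] <- reasons[idx]
    chunk
  }
  chunk <- reject(chunk, !std$parsed, "parse", rep("parse_error", n))
  chunk <- reject(chunk, std$parsed & is.na(std$smiles_canonical),
                  "standardize", rep("standardization_error", n))
  live <- chunk$status == "accepted"
  desc <- tibble(mw = rep(NA_real_, n), clogp = NA_real_, hbd = NA_real_,
                 hba = NA_real_, tpsa = NA_real_, rotb = NA_real_,
                 fsp3 = NA_real_)
  if (any(live)) {
    d <- compute_descriptors(chunk$smiles_canonical[live])
    desc[live, ] <- d
    bad <- rep(FALSE, n); bad[live] <- is.na(d$mw)
    chunk <- reject(chunk, bad, "standardize", rep("descriptor_error", n))
  }
  chunk <- dplyr::bind_cols(chunk, desc)
  live <- chunk$status == "accepted"

  if (!config$skip_lipinski && any(live)) {
    v <- lipinski_filter(desc[live, ], config$lipinski_max_violations)
    full <- rep("", n); full[live] <- v$reasons
    bad <- rep(FALSE, n); bad[live] <- !v$pass
    chunk <- reject(chunk, bad, "lipinski", full)
    live <- chunk$status == "accepted"
  }
  if (any(live)) {
    v <- druglike_filter(desc[live, ], config$tpsa_max, config$rotb_max,
                         config$fsp3_min)
    full <- rep("", n); full[live] <- v$reasons
    bad <- rep(FALSE, n); bad[live] <- !v$pass
    chunk <- reject(chunk, bad, "druglike", full)
    live <- chunk$status == "accepted"
  }
  if (any(live)) {
    v <- structural_alerts(chunk$smiles_canonical[live],
                           catalogs = config$alert_catalogs)
    full <- rep("", n); full[live] <- v$reasons
    bad <- rep(FALSE, n); bad[live] <- !v$pass
    chunk <- reject(chunk, bad, "alerts", full)
    live <- chunk$status == "accepted"
  }
  chunk <- reject(chunk, live & chunk$net_charge != 0, "net_charge",
                  rep("net_charge", n))
  chunk
}

#' Run the full ligand-preparation pipeline
#'
#' Converts a raw SMILES table into a standardized, filtered, neutral,
#' de-duplicated molecule set with a full per-stage rejection log. The
#' stage order (first failure wins) is: parse, standardize, Lipinski,
#' drug-likeness, structural alerts, net charge, de-duplication,
#' embedding. Molecules are processed in `workers` parallel chunks and
#' reassembled in input order, so the output is independent of the worker
#' count.
#'
#' @param input path to a delimited SMILES table, or a tibble with
#'   `compound_id` and `smiles` columns.
#' @param output optional output SDF path; when given, the SDF and the
#'   plain-text logs (`<output>.log`, `<output>.summary.json`) are
#'   written.
#' @param delimiter,smiles_col,id_col input parsing, see
#'   [parse_smiles_table()].
#' @param enable_3d embed 3D instead of 2D coordinates.
#' @param skip_lipinski disable the Lipinski stage.
#' @param keep_duplicates disable de-duplication.
#' @param lipinski_max_violations Lipinski violations tolerated
#'   (default 0 = strict all-four mode).
#' @param tpsa_max,rotb_max,fsp3_min drug-likeness thresholds.
#' @param alert_catalogs catalogs to enforce (default PAINS, BRENK, NIH).
#' @param workers parallel worker count (default 1).
#' @param seed integer, recorded in the log (all stages are
#'   deterministic).
#' @return object of class `ligprep_result`: `records` (one row per input
#'   row with descriptors, `status`, `stage`, `reasons`), `summary`
#'   (per-stage counts), `config`.
#' @export
run_ligprep <- function(input, output = NULL, delimiter = NULL,
                        smiles_col = NULL, id_col = NULL,
                        enable_3d = FALSE, skip_lipinski = FALSE,
                        keep_duplicates = FALSE,
                        lipinski_max_violations = 0L,
                        tpsa_max = 140, rotb_max = 10, fsp3_min = 0,
                        alert_catalogs = c("PAINS", "BRENK", "NIH"),
                        workers = 1L, seed = 20251104L) {
  config <- list(enable_3d = enable_3d, skip_lipinski = skip_lipinski,
                 keep_duplicates = keep_duplicates,
                 lipinski_max_violations = lipinski_max_violations,
                 tpsa_max = tpsa_max, rotb_max = rotb_max,
                 fsp3_min = fsp3_min, alert_catalogs = alert_catalogs,
                 workers = max(1L, as.integer(workers)), seed = seed)
  if (is.character(input)) {
    tab <- parse_smiles_table(input, delimiter, smiles_col, id_col)
    malformed <- attr(tab, "malformed")
  } else {
    input <- as_tibble(input)
    if (!all(c("compound_id", "smiles") %in% names(input)))
      abort("ligprep: tibble input needs `compound_id` and `smiles`")
    tab <- dplyr::mutate(input[, c("compound_id", "smiles")],
                         row = dplyr::row_number(), .before = 1)
    malformed <- tibble(row = integer(), reason = character())
  }
  rec <- dplyr::mutate(tab, status = "accepted", stage = NA_character_,
                       reasons = "")
  if (nrow(rec) > 0L) {
    nw <- min(config$workers, nrow(rec))
    split_idx <- sort(rep_len(seq_len(nw), nrow(rec)))
    chunks <- split(rec, split_idx)
    done <- if (nw > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(chunks, ligprep_chunk, config = config,
                         mc.cores = nw)
    } else {
      lapply(chunks, ligprep_chunk, config = config)
    }
    rec <- dplyr::arrange(dplyr::bind_rows(done), .data$row)
  } else {
    rec <- dplyr::bind_cols(rec, tibble(smiles_canonical = character(),
                                        inchi = character(),
                                        net_charge = numeric(),
                                        mw = numeric(), clogp = numeric(),
                                        hbd = numeric(), hba = numeric(),
                                        tpsa = numeric(), rotb = numeric(),
                                        fsp3 = numeric()))
  }
  live <- rec$status == "accepted"
  if (any(live)) {
    dd <- deduplicate(rec[live, ], keep_duplicates)
    rec$status[live][!dd$pass] <- "rejected"
    rec$stage[live][!dd$pass] <- "dedup"
    rec$reasons[live][!dd$pass] <- dd$reasons[!dd$pass]
  }
  if (!is.null(output)) {
    accepted <- rec[rec$status == "accepted", ]
    failed_embed <- write_ligand_sdf(accepted, output, gen3d = enable_3d)
    if (length(failed_embed)) {
      idx <- rec$compound_id %in% failed_embed & rec$status == "accepted"
      rec$status[idx] <- "rejected"
      rec$stage[idx] <- "embed"
      rec$reasons[idx] <- "embed_failed"
      write_ligand_sdf(rec[rec$status == "accepted", ], output,
                       gen3d = enable_3d)
    }
  }
  if (nrow(malformed) > 0L) {
    rec <- dplyr::bind_rows(
      rec,
      tibble(row = malformed$row, compound_id = sprintf("row%d", malformed$row),
             smiles = NA_character_, status = "rejected",
             stage = "parse", reasons = malformed$reason)) |>
      dplyr::arrange(.data$row)
  }
  summary <- ligprep_summary(rec)
  res <- structure(list(records = rec, summary = summary, config = config,
                        n_malformed = nrow(malformed)),
                   class = "ligprep_result")
  if (!is.null(output)) {
    writeLines(ligprep_log_lines(res), paste0(output, ".log"))
    jsonlite::write_json(list(summary = summary, config = config),
                         paste0(output, ".summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

ligprep_summary <- function(rec) {
  counts <- vapply(ligprep_stages, function(s)
    sum(rec$status == "rejected" & rec$stage == s, na.rm = TRUE), integer(1))
  dplyr::bind_rows(
    tibble(stage = "input", n = nrow(rec)),
    tibble(stage = paste0("rejected_", ligprep_stages), n = unname(counts)),
    tibble(stage = "accepted", n = sum(rec$status == "accepted"))
  )
}

ligprep_log_lines <- function(x) {
  cfg <- x$config
  hdr <- c(
    sprintf("# ligand preparation log (screenkit %s)",
            as.character(packageVersion("screenkit"))),
    sprintf("# thresholds: lipinski_max_violations=%d tpsa_max=%g rotb_max=%g fsp3_min=%g",
            cfg$lipinski_max_violations, cfg$tpsa_max, cfg$rotb_max,
            cfg$fsp3_min),
    sprintf("# catalogs: %s | 3d=%s | keep_duplicates=%s | workers=%d | seed=%d",
            paste(cfg$alert_catalogs, collapse = ","), cfg$enable_3d,
            cfg$keep_duplicates, cfg$workers, cfg$seed))
  rej <- x$records[x$records$status == "rejected", ]
  body <- sprintf("row=%d id=%s stage=%s reasons=%s",
                  rej$row, rej$compound_id, rej$stage, rej$reasons)
  c(hdr, body)
}

#' @export
print.ligprep_result <- function(x, ...) {
  cat(sprintf("<ligprep_result> %d records in, %d accepted\n",
              x$summary$n[x$summary$stage == "input"],
              x$summary$n[x$summary$stage == "accepted"]))
  rej <- x$summary[grepl("^rejected_", x$summary$stage) & x$summary$n > 0, ]
  if (nrow(rej))
    cat(paste0("  ", sub("^rejected_", "rejected at ", rej$stage), ": ",
               rej$n, collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname run_ligprep
#' @param x a `ligprep_result`.
#' @param ... unused.
#' @export
tidy.ligprep_result <- function(x, ...) as_tibble(x$records)

#' @rdname run_ligprep
#' @export
glance.ligprep_result <- function(x, ...) {
  s <- setNames(as.list(x$summary$n), x$summary$stage)
  as_tibble(s)
}

#' Plot the per-stage attrition of a ligand-preparation run
#'
#' @param object a `ligprep_result`.
#' @param type `"funnel"` (records surviving each stage) or `"reasons"`
#'   (rejection counts by stage).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ligprep_result <- function(object, type = "funnel", ...) {
  s <- object$summary
  rej <- s[grepl("^rejected_", s$stage), ]
  rej$stage <- sub("^rejected_", "", rej$stage)
  rej$stage <- factor(rej$stage, levels = ligprep_stages)
  switch(
    type,
    reasons = ggplot2::ggplot(rej, ggplot2::aes(x = .data$stage,
                                                y = .data$n)) +
      ggplot2::geom_col(fill = "indianred") +
      ggplot2::labs(x = "stage", y = "rejected",
                    title = "Rejections by pipeline stage"),
    funnel = {
      surv <- tibble(
        stage = factor(c("input", as.character(rej$stage)),
                       levels = c("input", ligprep_stages)),
        n = s$n[s$stage == "input"] - cumsum(c(0, rej$n)))
      ggplot2::ggplot(surv, ggplot2::aes(x = .data$stage, y = .data$n,
                                         group = 1)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "after stage", y = "surviving records",
                      title = "Pipeline attrition")
    },
    abort(paste0("unknown plot type: ", type))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
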