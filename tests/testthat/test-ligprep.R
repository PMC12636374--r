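test_that("delimiter sniffing picks the consistent candidate", {
  expect_equal(sniff_delimiter(c("id,smiles", "C1,CCO")), ",")
  expect_equal(sniff_delimiter(c("id\tsmiles", "C1\tCCO")), "\t")
  expect_equal(sniff_delimiter(c("id;smiles", "C1;CCO")), ";")
  expect_error(sniff_delimiter(c("id smiles", "C1 CCO")), "no delimiter")
})

test_that("SMILES tables parse with malformed rows logged, not raised", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles", "a,CCO", "b,CCN", "c,", "d,CCC"), path)
  tab <- parse_smiles_table(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "malformed")$row, 3L)
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_warning(t0 <- parse_smiles_table(empty), "empty")
  expect_equal(nrow(t0), 0L)
})

test_that("standardization neutralizes, strips salts and canonicalizes tautomers", {
  std <- standardize_molecules(c("CC(=O)[O-]", "CCO.[Na+].[Cl-]",
                                 "Oc1ccccn1", "O=C1NC=CC=C1", "CCO"))
  # acetate -> acetic acid (neutral), salt -> parent ethanol fragment
  expect_equal(std$net_charge[1], 0)
  expect_match(std$smiles_canonical[1], "CC\\(=O\\)O|OC\\(=O\\)C|OC\\(C\\)=O")
  expect_equal(std$smiles_canonical[2], std$smiles_canonical[5])
  # lactam/lactim pair collapses to one canonical tautomer
  expect_equal(std$smiles_canonical[3], std$smiles_canonical[4])
  # idempotence: standardizing the output changes nothing
  again <- standardize_molecules(std$smiles_canonical)
  expect_equal(again$smiles_canonical, std$smiles_canonical)
})

test_that("unparseable SMILES come back as NA without breaking the batch", {
  std <- standardize_molecules(c("CCO", "XYZ123", "CCN"))
  expect_equal(std$parsed, c(TRUE, FALSE, TRUE))
  expect_equal(is.na(std$smiles_canonical), c(FALSE, TRUE, FALSE))
})

test_that("Lipinski verdicts carry one reason per breached bound", {
  desc <- compute_descriptors(c("CCO", strrep("C", 40)))
  v <- lipinski_filter(desc)
  expect_true(v$pass[1]); expect_equal(v$reasons[1], "")
  expect_false(v$pass[2])
  expect_match(v$reasons[2], "MW>500")
  expect_match(v$reasons[2], "cLogP>5")
  # one violation tolerated in the classic mode
  mild <- tibble::tibble(mw = 510, clogp = 2, hbd = 1, hba = 3,
                         tpsa = 60, rotb = 4, fsp3 = 0.5)
  expect_false(lipinski_filter(mild)$pass)
  expect_true(lipinski_filter(mild, max_violations = 1)$pass)
})

test_that("drug-likeness thresholds fire independently and Fsp3 defaults to pass-through", {
  desc <- tibble::tibble(mw = c(300, 300, 300), clogp = 2, hbd = 1,
                         hba = 4, tpsa = c(200, 60, 60),
                         rotb = c(3, 12, 3), fsp3 = c(0.5, 0.5, 0))
  v <- druglike_filter(desc)
  expect_equal(v$pass, c(FALSE, FALSE, TRUE))
  expect_equal(v$reasons[1], "TPSA>140")
  expect_equal(v$reasons[2], "RotB>10")
  # Fsp3 only fails when a floor is configured
  expect_false(druglike_filter(desc, fsp3_min = 0.25)$pass[3])
})

test_that("structural alerts flag rhodanine and acyl-halide chemotypes only", {
  v <- structural_alerts(c("O=C1CSC(=S)N1C", "CC(=O)Cl", "CCO"))
  expect_equal(v$pass, c(FALSE, FALSE, TRUE))
  expect_match(v$reasons[1], "PAINS:rhodanine")
  expect_match(v$reasons[2], "BRENK:acyl_halide")
  expect_equal(v$reasons[3], "")
  # catalog restriction disables the other lists
  v2 <- structural_alerts(c("O=C1CSC(=S)N1C", "CC(=O)Cl"),
                          catalogs = "PAINS")
  expect_equal(v2$pass, c(FALSE, TRUE))
  # every catalog SMARTS is valid for the matcher (none throws)
  cat <- alert_catalog()
  sdf <- ChemmineR::smiles2sdf(c(probe = "O=C1CSC(=S)N1CC(=O)Clc1ccccc1"))
  for (p in cat$smarts)
    expect_no_error(ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = FALSE))
})

test_that("net-charge screening rejects quaternary ammonium but accepts zwitterions", {
  std <- standardize_molecules(c("C[N+](C)(C)C",
                                 "NCC(=O)O",
                                 "C[N+](C)(C)CC([O-])=O"))
  expect_equal(std$net_charge, c(1, 0, 0))
})

test_that("deduplication keeps the first canonical occurrence", {
  std <- standardize_molecules(c("CCO", "OCC", "CCN"))
  rec <- tibble::tibble(compound_id = c("a", "b", "c"),
                        smiles_canonical = std$smiles_canonical)
  dd <- deduplicate(rec)
  expect_equal(dd$pass, c(TRUE, FALSE, TRUE))
  expect_equal(dd$reasons[2], "duplicate_of:a")
  expect_true(all(deduplicate(rec, keep_duplicates = TRUE)$pass))
})

test_that("embedding writes SDF with descriptor tags and is deterministic", {
  fx <- make_smiles_fixture(n_pass = 4, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".sdf")
  p2 <- withr::local_tempfile(fileext = ".sdf")
  r1 <- run_ligprep(fx[, c("compound_id", "smiles")], output = p1,
                    enable_3d = TRUE)
  r2 <- run_ligprep(fx[, c("compound_id", "smiles")], output = p2,
                    enable_3d = TRUE)
  expect_identical(readLines(p1), readLines(p2))
  lines <- readLines(p1)
  expect_equal(sum(lines == "$$$$"), 4L)
  expect_true(any(lines == "> <cLogP>"))
  # 3D: some z-coordinates are non-zero
  coord_re <- "^\\s*-?\\d+\\.\\d{4}\\s+-?\\d+\\.\\d{4}\\s+-?\\d+\\.\\d{4}"
  cl <- grep(coord_re, lines, value = TRUE)
  z <- vapply(strsplit(trimws(cl), "\\s+"),
              function(p) as.numeric(p[3]), numeric(1))
  expect_true(any(abs(z) > 1e-3))
})

test_that("the pipeline conserves records across stages with planted counts", {
  fx <- make_smiles_fixture(n_pass = 12, n_lipinski = 4, n_druglike = 3,
                            n_alert = 5, n_charged = 4, n_malformed = 5,
                            n_duplicates = 3, seed = 9)
  res <- run_ligprep(fx[, c("compound_id", "smiles")])
  s <- setNames(res$summary$n, res$summary$stage)
  expect_equal(unname(s["input"]), nrow(fx))
  expect_equal(unname(s["rejected_parse"]), 5L)
  expect_equal(unname(s["rejected_lipinski"]), 4L)
  expect_equal(unname(s["rejected_druglike"]), 3L)
  expect_equal(unname(s["rejected_alerts"]), 5L)
  expect_equal(unname(s["rejected_net_charge"]), 4L)
  expect_equal(unname(s["rejected_dedup"]), 3L)
  expect_equal(unname(s["accepted"]), 12L)
  # conservation: every record is accepted or rejected at exactly one stage
  expect_equal(unname(s["input"]),
               unname(s["accepted"]) + sum(s[grepl("^rejected", names(s))]))
  rec <- tidy(res)
  expect_true(all(rec$status %in% c("accepted", "rejected")))
  expect_true(all(nzchar(rec$reasons[rec$status == "rejected"])))
  # accepted records are neutral and alert-free by construction
  acc <- rec[rec$status == "accepted", ]
  expect_true(all(acc$net_charge == 0))
  expect_true(all(structural_alerts(acc$smiles_canonical)$pass))
})

test_that("a fully rejected input still yields a valid empty SDF and log", {
  fx <- make_smiles_fixture(n_pass = 0, n_malformed = 3, seed = 4)
  out <- withr::local_tempfile(fileext = ".sdf")
  res <- run_ligprep(fx[, c("compound_id", "smiles")], output = out)
  expect_equal(res$summary$n[res$summary$stage == "accepted"], 0L)
  expect_true(file.exists(out))
  expect_equal(length(readLines(out)), 0L)
  expect_true(file.exists(paste0(out, ".log")))
})
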