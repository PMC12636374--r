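#' Structural-alert catalog (curated subset)
#'
#' A curated subset of widely used substructure alerts, hand-transcribed
#' as SMARTS from the three published catalogs: PAINS (pan-assay
#' interference chemotypes), BRENK (reactive/toxicophoric groups
#' unsuitable for screening libraries) and NIH (assay-interfering and
#' reactive functionalities). The subset covers the most common
#' chemotypes of each catalog, not the full published lists; the full
#' catalogs contain several hundred patterns. Supply your own table in
#' the same shape to [structural_alerts()] to use a different or complete
#' catalog.
#'
#' @return tibble with columns `catalog` (`PAINS`/`BRENK`/`NIH`), `alert`
#'   (chemotype name) and `smarts`.
#' @export
alert_catalog <- function() {
  tibble::tribble(
    ~catalog, ~alert, ~smarts,
    "PAINS", "rhodanine_core",        "S1C(=S)NC(=O)C1",
    "PAINS", "rhodanine_lactim",      "S1C(=S)N=C(O)C1",
    "PAINS", "thiazolidinedione_lactim", "S1C(=O)N=C(O)C1",
    "PAINS", "ene_rhodanine",         "S1C(=S)NC(=O)C1=C",
    "PAINS", "thiazolidinedione",     "S1C(=O)NC(=O)C1",
    "PAINS", "quinone",               "O=C1C=CC(=O)C=C1",
    "PAINS", "catechol",              "[OX2H]c1ccccc1[OX2H]",
    "PAINS", "azo_aryl",              "c[NX2]=[NX2]c",
    "PAINS", "ene_one_ene",           "C=CC(=O)C=C",
    "PAINS", "hydroxyphenyl_hydrazone", "[OX2H]c1ccccc1/C=N/N",
    "BRENK", "acyl_halide",           "[CX3](=O)[F,Cl,Br,I]",
    "BRENK", "aldehyde",              "[CX3H1](=O)[#6]",
    "BRENK", "isocyanate",            "[NX2]=C=O",
    "BRENK", "epoxide",               "C1OC1",
    "BRENK", "aziridine",             "C1NC1",
    "BRENK", "nitro",                 "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
    "BRENK", "azide",                 "[NX2]=[NX2+]=[NX1-]",
    "BRENK", "hydrazine",             "[NX3;H2][NX3;H2]",
    "BRENK", "thiol",                 "[SX2H]",
    "BRENK", "alkyl_halide",          "[CX4][Cl,Br,I]",
    "BRENK", "peroxide",              "[OX2][OX2]",
    "BRENK", "sulfonyl_halide",       "S(=O)(=O)[F,Cl,Br,I]",
    "NIH",   "isothiocyanate",        "[NX2]=C=S",
    "NIH",   "maleimide",             "O=C1C=CC(=O)N1",
    "NIH",   "beta_lactam",           "O=C1CCN1",
    "NIH",   "halopyridine_2",        "[F,Cl,Br,I]c1ccccn1",
    "NIH",   "diazonium",             "[NX1]#[NX2+]",
    "NIH",   "michael_acceptor_nitrile", "C=CC#N",
    "NIH",   "anhydride",             "C(=O)OC(=O)"
  )
}
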