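---
title: "Consensus toolkits for ensemble-based virtual screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus toolkits for ensemble-based virtual screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenkit)
```

Virtual screening against a flexible protein target faces three recurring
chores: deciding *which conformations of the receptor* to dock against,
turning a raw vendor SMILES table into a clean, screening-ready ligand
set, and merging *two imperfect affinity estimates* (a docking score and
an MM-GBSA binding free energy) into one defensible priority list.
`screenkit` implements each chore as a small, tested, deterministic
pipeline. This vignette records the methods, the tunable parameters and
the design decisions — including the places where the underlying
procedures are genuinely open to choice and what we chose.

# Conformational ensemble analysis

## Model and procedure

The input is a multi-model structure (typically an NMR ensemble) read as
an `M × A × 3` array of backbone coordinates — by default the N, CA, C
and O atoms of one chain, with alternate locations resolved to the
highest-occupancy record and insertion codes kept in the residue key.
Every model must carry an identical atom list; a mismatch is an error,
never a silent truncation, because all downstream matrices assume
positional correspondence.

The workflow is:

1. **Superposition.** Every model is rigidly fitted onto the reference
   model (model 1 by default) by the Kabsch algorithm: SVD of the
   coordinate covariance with the determinant correction, so the fit is a
   proper rotation — no reflection can be introduced. Fitting all models
   to a *common* reference, rather than each pair to each other, is a
   deliberate convention (see "Numerical choices").
2. **Pairwise RMSD matrix.** Entry $(i,j)$ is the root mean squared
   coordinate deviation over all selected atoms between the two aligned
   models. The matrix is symmetric with a zero diagonal; summary
   statistics use each unordered pair once.
3. **Flexibility metrics.** The mass-unweighted radius of gyration per
   model; per-atom RMSF about the ensemble-mean position, averaged into a
   per-residue profile; residues above the 75th percentile of that
   profile are flagged high-flexibility.
4. **Consensus outlier detection** with three orthogonal detectors:
   * Tukey fences on the per-model mean RMSD
     ($[Q_1 - 1.5\,\mathrm{IQR},\, Q_3 + 1.5\,\mathrm{IQR}]$);
   * an isolation forest on the flattened `M × 3A` coordinate matrix
     (100 trees, subsample $\min(256, M)$, contamination 0.1, so
     $\lceil 0.1\,M \rceil$ models are flagged). No isolation-forest
     implementation ships with this R stack, so the package carries its
     own, seeded, following the original random-split/path-length
     formulation;
   * Ward-linkage clustering of the RMSD matrix cut at
     $\mu + 2\sigma$ of the merge heights, flagging singleton clusters.

   A model flagged by **at least two** detectors is a consensus outlier.
   Consensus outliers are excluded from cluster-number selection, the
   k-means fit and representative selection, then assigned to their
   nearest centroid afterwards so occupancy counts still cover all $M$
   models.
5. **Cluster-number selection.** For each $k$ in 2–6 (truncated to
   $M-1$), k-means with 20 restarts is scored by silhouette coefficient,
   Davies–Bouldin index, Calinski–Harabasz score and inertia, all in the
   same flattened Euclidean coordinate space as the fit. The silhouette
   maximum decides $k$; the other indices are reported, not voted —
   a single transparent criterion is easier to audit than an ad hoc
   vote among correlated indices.
6. **Clustering and renumbering.** Final k-means labels are renumbered
   by descending occupancy, so cluster 0 is always the dominant basin.
7. **Representative selection** by four-method voting within each
   cluster: medoid (minimum average RMSD to members), centroid proximity
   (minimum Euclidean distance to the cluster's mean flattened
   coordinates), minimax (minimum worst-case RMSD), and density peak
   (most neighbours within the 25th percentile of the cluster's pairwise
   RMSDs). The modal candidate wins; ties fall back to the medoid, then
   the lowest model id.
8. **Representative quality score** on $[0,1]$:
   $0.35\,\tilde a + 0.25\,\tilde m + 0.25\,c + 0.15\,r^{-1}$, where
   $\tilde a$ and $\tilde m$ min–max-normalize the representative's
   average and maximum RMSD to members across the cluster (best member
   → 1, worst → 0), $c$ is the fraction of *other* members within 2 Å
   of the representative, and $r^{-1}$ is the inverse of the
   representative's rank by average RMSD. A component on which all
   members tie contributes 1, so a singleton cluster scores a perfect
   1.000 by construction.
9. **Diversity and projection.** Mean intra-cluster RMSD, cluster
   diameter, a compactness score, the mean RMSD between cluster
   representatives, and a mean-centred PCA of the flattened coordinates
   with all explained-variance ratios (they are non-increasing and sum
   to 1).

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `atom_names` | N, CA, C, O | — | backbone-only comparison; side chains would swamp the backbone signal |
| `k_range` | 2–6 | clusters | NMR ensembles are small (10–30 models); more clusters than $M/3$ are rarely interpretable |
| `contamination` | 0.1 | fraction | the forest's flag quota; at $M=15$ it nominates 2 candidates that still need a second vote |
| `iqr_factor` | 1.5 | — | the conventional Tukey fence |
| `singleton_sigma` | 2.0 | SD of merge heights | flags only merges far above the typical agglomeration scale |
| `min_votes` | 2 | votes | single detectors have distinct failure modes; two independent confirmations control false positives |
| `n_init` | 20 | restarts | k-means restarts; the flattened space is low-dimensional in samples, 20 restarts reach the best inertia reliably at this size |
| `coverage_cutoff` | 2.0 | Å | "within 2 Å of the representative" as the coverage criterion |

## Numerical choices

* **Reference-aligned RMSD, not per-pair refits.** The matrix is
  computed on coordinates aligned to the common reference, matching the
  align-then-measure order of the workflow; `per_pair = TRUE` switches
  to per-pair refitting when a pure shape distance is wanted. The two
  agree closely for compact ensembles and diverge for very dissimilar
  model pairs (the reference-aligned value is an upper bound).
* **Degenerate inputs.** Constant per-model means flag nothing (the
  fences carry an absolute epsilon of $10^{-9}$ Å); coordinates that
  agree to better than $10^{-9}$ Å are unsplittable for the isolation
  forest; a single-model ensemble yields all-zero RMSF with a warning;
  collinear atom sets are rejected before the SVD.
* **Ties.** Representative voting breaks ties medoid-first, then lowest
  model id; cluster renumbering breaks occupancy ties by original label
  order. Both make reruns bit-identical.
* **Centrality** is implemented as $1/\mathrm{rank}$ (rank 1 → 1,
  rank 2 → 0.5, …). A linear alternative $(M - \mathrm{rank} + 1)/M$
  was considered and rejected: the hyperbolic form rewards being *the*
  most central member, which is what a single representative should be.
* **Compactness** has no canonical definition; the default is the
  cluster's mean intra-RMSD divided by the global off-diagonal mean
  RMSD (small = tight relative to the ensemble), the definition name is
  recorded in the report, and a user function can replace it. Singleton
  clusters report (0, 0, 1) by convention. Because the definition is a
  package choice, no correctness claim is attached to compactness
  values beyond determinism.
* The RMSF profile is reported per residue (the per-atom vector is
  exported alongside), and the isolation-forest seed is recorded in the
  report's method parameters.

# Ligand preparation

## Stage order

Raw SMILES tables pass through: **parse → standardize → Lipinski →
drug-likeness → structural alerts → net charge → de-duplication →
embedding**. The first failing stage claims the record (one rejection
reason set per record, joined by `;` within a stage), which keeps the
rejection log unambiguous and makes the stage counts add up exactly:
`records_in = accepted + Σ rejected_by_stage`.

## Standardization

Chemistry runs on OpenBabel (through the `obabel` CLI and ChemmineR).
Each molecule is reduced to its largest fragment (salt stripping), then:

* **Charge handling.** The net formal charge is read from the standard
  InChI `/q` and `/p` layers. Only molecules whose *parent* is
  net-charged are passed through the uncharger — running it on a
  balanced zwitterion would protonate one side and manufacture a net
  charge. Molecules still charged afterwards (e.g. quaternary ammonium)
  are rejected at the net-charge stage. This approximates "neutral at
  physiological pH" without a pKa model, and that approximation is a
  documented limit of the pipeline.
* **Canonical tautomer.** A standard-InChI round trip
  (SMILES → InChI → SMILES) collapses heteroatom-centred (mobile-H)
  tautomers — lactam/lactim, amide/imidol and the like — to one
  deterministic representative. Carbon-centred keto/enol pairs are
  outside InChI's mobile-H model and are *not* interconverted; users
  needing full tautomer canonicalization should pre-process with a
  dedicated tool.
* The final canonical SMILES is idempotent: standardizing the pipeline's
  own output changes nothing, which is what makes re-runs no-ops.

## Filters

Lipinski bounds (MW ≤ 500 g/mol, cLogP ≤ 5, HBD ≤ 5, HBA ≤ 10) are
enforced strictly by default — every breached bound is its own reason
code — with the classic one-violation mode available. The drug-likeness
stage defaults to TPSA ≤ 140 Å², rotatable bonds ≤ 10 and no Fsp3 floor
(a pass-through unless configured); these cutoffs are conventional
screening values, are fully configurable, and are recorded in the log
header of every run rather than hidden. Descriptors come from the
OpenBabel descriptor set (MW, logP, TPSA, Lipinski-style N+O acceptor
and donor counts); rotatable bonds and the sp³ carbon fraction are
SMARTS counts (non-ring single bonds between non-terminal heavy atoms;
`[CX4]` over all carbons).

The structural-alert stage matches a **curated subset** of the three
published alert catalogs (PAINS, BRENK, NIH), hand-transcribed as SMARTS
by chemotype — rhodanines (both tautomeric spellings), quinones,
catechols, azo aryls, acyl and sulfonyl halides, Michael-type acceptors,
epoxides, nitro, azide, peroxide and so on. It is a subset, not the full
several-hundred-pattern lists; `alert_catalog()` returns the table and
`structural_alerts()` accepts any user-supplied table of the same shape,
so a complete catalog can be dropped in.

## Embedding and determinism

2D coordinates use OpenBabel's rule-based layout. 3D coordinates relax
that layout with an MMFF94 steepest-descent minimization under a fixed
step budget. This route is chosen *because it is deterministic*:
OpenBabel's stochastic conformer search exposes no random seed, and a
preparation pipeline whose SDF output changes between identical runs is
unusable for audit trails. The price is a locally-minimized, not
globally-searched, conformer — acceptable for a starting geometry that
docking software will re-sample anyway, and stated here so nobody
mistakes the output for a conformer-search result.

Records are processed in contiguous chunks across `workers` processes
and reassembled in input order; every stage is a pure per-molecule
function up to de-duplication, so the output is byte-identical for any
worker count.

# Consensus hit ranking

Input is a table of `(compound_id, gscore, dg_bind)` — a docking score
and an MM-GBSA binding free energy, both in kcal/mol, lower better.
Rows missing either metric are excluded up front and reported. Five
rankings are computed, each producing average (fractional) ranks on
ties so that the later averaging is unbiased:

1. **Z-score**: standardize both columns, average, rank ascending. A
   zero-variance column contributes z = 0 with a warning.
2. **Percentile**: per-column goodness percentiles (most negative →
   100), averaged; only order information is used, so single extreme
   values cannot drag mid-table compounds around.
3. **Weighted z-score**: $0.4\,z_g + 0.6\,z_{\Delta G}$ by default,
   weighting the MM-GBSA term higher.
4. **Pareto frontier peeling**: row $a$ dominates $b$ iff $a \le b$ on
   both metrics and $<$ on at least one (exact ties are mutually
   non-dominating). The non-dominated set gets rank 1, is removed, and
   the peel repeats. The implementation is a sort-and-sweep; the test
   suite proves it equivalent to the brute-force $O(n^2)$ definition on
   random tables.
5. **Strict dual cutoff**: compounds with gscore ≤ −6.0 *and*
   ΔG ≤ −40.0 kcal/mol (inclusive) are z-ranked among themselves.
   Non-passers are placed after all passers, ordered by their own
   z-score — the published scheme only ranks passers, but ensemble
   averaging needs a total order, so this extension is a documented
   package decision.

The **ensemble rank** is the arithmetic mean of the five per-method
ranks; the final list orders by it ascending. Note the Pareto method
contributes frontier indices (small integers) rather than 1..n ranks —
that is inherent to hierarchical non-dominated sorting and gives the
frontier structure a strong say in the consensus.

# The synthetic-fixture generators

Every stage above is testable offline because the `fixtures` functions
generate inputs with planted ground truth:

* `make_two_state_ensemble()` builds a helical poly-alanine-like
  backbone (ideal-bond polyline, 4 backbone atoms per residue) and
  plants cluster structure as an *internal hinge displacement* of the
  C-terminal third of the chain — a whole-body shift would be removed
  by superposition, a hinge is not. Isotropic Gaussian noise is added
  per coordinate, and outlier models carry a large internal displacement
  of the central segment. Defaults mirror the two-state study
  conditions: 15 models, 127 residues, 87/13 occupancy, 6 Å separation,
  0.5 Å noise.
* `make_score_table()` draws from a bivariate normal with requested
  means, SDs and Pearson correlation (defaults −6.80 ± 0.91 and
  −41.47 ± 9.65 kcal/mol, r = 0.363, the published screening-campaign
  distributions). When an exact dual-cutoff pass fraction is requested,
  the minimal number of rows is mirrored across the cutoff boundary —
  the rows nearest the boundary move least, so the moments stay within
  sampling tolerance.
* `make_smiles_fixture()` emits molecules planted to pass everything,
  or to fail exactly one stage: oversized alkyl alcohols (Lipinski),
  long diols and PEG chains (rotatable bonds, Lipinski-clean),
  rhodanines and acyl halides (alerts), small quaternary ammonium ions
  (net charge), assorted invalid strings (parse), and duplicates written
  from the other end of the molecule so only canonicalization can catch
  them.

What the generators deliberately do **not** emulate: real PDZ-domain
geometry or side-chain packing, anisotropic or correlated coordinate
noise, real docking-score landscapes (score–pose coupling, binned score
artifacts), or real vendor-library chemistry space. Passing the planted
tests therefore demonstrates that the *algorithms* do what they claim
under known ground truth — it does not certify behaviour on any
particular real ensemble or library.

# Problem sizes and determinism

The test suite and the acceptance script run at the study-condition
sizes the methods are built for: 15-model × 127-residue ensembles
(508 backbone atoms), a 9 353-row score table, and a 200-molecule
ligand library with planted outcomes; the Pareto oracle check uses 100
random tables of up to 500 rows. Every stochastic step (fixture noise,
isolation forest, k-means restarts) takes an explicit integer seed, RNG
state is restored after use, and the full ensemble workflow is
bit-reproducible for a fixed input and seed.

# Known limitations

* The reference reproduction of the published 15-model nNOS PDZ
  ensemble analysis requires the public structure file, which the
  package fetches on demand (`fetch_pdb_entry("1B8Q")`); on a machine
  with no network and no cached copy that check reports failure rather
  than silently passing.
* Tautomer canonicalization covers mobile-H tautomers only (see above).
* No pKa model: "neutral at physiological pH" is approximated by
  uncharging plus a net-formal-charge screen.
* The alert catalog is a curated subset of the published lists.
* 3D embedding is a deterministic minimization, not a conformer search.
* Isolation-forest flags depend on the seed only through tree
  construction; the *consensus* outlier set additionally requires
  agreement from a deterministic detector, which in practice makes it
  stable across seeds.
* When the dominant basin is very tight (as in the idealized
  iid-noise fixtures), the Tukey fences narrow and the forest's fixed
  flag quota must land somewhere, so a genuine minor-state model can
  join the consensus outlier set alongside a true outlier. The
  nearest-centroid reassignment then still places it with its own
  cluster in the occupancy table, and the planted partition is
  recovered exactly — but representative selection for that cluster
  proceeds without it. Real NMR ensembles, whose dominant clusters are
  internally heterogeneous, widen the fences and make this much less
  likely.
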