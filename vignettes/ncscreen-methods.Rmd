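---
title: "Screening food-derived natural compounds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening food-derived natural compounds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ncscreen is a desk-scale pipeline for prioritising food-derived natural
compounds (NCs) against a panel of disease-related protein targets. This
vignette describes the statistical and cheminformatic machinery, the
tunable parameters and their defaults, what the synthetic fixtures do and
do not emulate, and the design decisions taken where the methodology was
genuinely open.

## The screening model

The pipeline chains six analyses, each available as a standalone
function and orchestrated end to end by `run_pipeline()`:

1. **Featurization** (`parse_compounds()`, `compute_fingerprints()`,
   `compute_descriptors()`). Structures enter as SMILES, are
   canonicalised through OpenBabel, and are represented two ways: a
   hashed circular (Morgan-style) fingerprint for learning and
   similarity, and a small physicochemical descriptor set (MolWt, LogP,
   HBD, HBA, TPSA) for SAR profiling and permeability rules.
2. **QSAR regression** (`train_qsar()`). One random-forest regressor per
   protein target maps fingerprint bits to pIC50, where
   `pIC50 = -log10(IC50 x 1e-9)` for IC50 in nM. Data are split 80:20
   into training and validation; k-fold cross-validation metrics are
   retained on the model alongside MSE, R^2, MAE and RMSE.
3. **Applicability-domain filtering** (`filter_applicability()`). Two
   stages: records below a pIC50 floor (default 5.0, i.e. weaker than
   10 uM) are dropped, then records whose absolute residual
   |observed - predicted| exceeds the 95th percentile of the residual
   distribution are excluded. The percentile is the linear-interpolation
   quantile, so at least ceiling(0.95 n) - 1 records always survive.
4. **Similarity matching** (`predict_candidates()`). Candidate NCs are
   compared against each target's retained actives by cosine similarity
   of fingerprints; the best-matching active is recorded and a pair is a
   hit when similarity is strictly greater than 0.5.
5. **Profiling** (`choose_k()`, `cluster_kmeans()`, `sar_summary()`,
   `classify_activity()`, `find_mcs()`, `detect_functional_groups()`).
   Hits are assigned a predicted potency, stratified into tiers
   (low: pIC50 <= 5, medium: 5 < pIC50 <= 7, high: pIC50 > 7), clustered
   by k-means on standardized descriptors + predicted potency, and
   summarised per cluster and per tier (maximum common substructure,
   functional groups, descriptor statistics).
6. **Permeability and provenance** (`bbb_score()`, `source_map()`).
   Five inclusive physicochemical criteria score blood-brain-barrier
   permeability in 20% steps; food-source sets are ranked and their
   exact Venn regions computed.

## Chemistry layer

All structure handling is delegated to OpenBabel via
ChemmineR/ChemmineOB: SMILES parsing and canonicalisation
(`convertFormat`), physicochemical properties (`prop_OB`), and SMARTS
substructure matching (`smartsSearch_OB`). Two consequences worth
knowing:

* **LogP** is OpenBabel's atom-contribution model and **TPSA** the Ertl
  fragment sum; **HBA** uses the Lipinski-style N/O acceptor SMARTS
  (`HBA2`), **HBD** the standard donor count. The BBB regression panel
  (below) fixes this choice: it reproduces the reference percentages for
  five of the seven embedded phenolics.
* Salt forms are stripped to their largest contiguous fragment before
  canonicalisation (`strip_salts = TRUE`), since candidate tables often
  carry counter-ions. Stereochemistry is preserved when present, never
  required.

### Circular fingerprints

No installed R toolkit exposes circular fingerprints (OpenBabel offers
only path-based FP2/FP4/MACCS), so the neighbourhood-hashing step is
implemented in the package on the OpenBabel-derived molecular graph.
Atom environments are distinguished by element, heavy-atom degree,
attached hydrogen count, ring membership (2-core of the heavy-atom
graph) and bond orders, then iteratively refined out to `radius` bonds;
every environment hashes to an integer (plain 31-bit modular arithmetic,
so results are platform-independent) and folds modulo `n_bits`.
Defaults are radius 2 and 2048 bits — the de facto QSAR standard — and
both are configurable everywhere. Because molecules are always
fingerprinted from their canonical SMILES, equivalent encodings give
bit-identical vectors.

### Maximum common substructure

`find_mcs()` is a McGregor-style backtracking search over connected atom
mappings (atoms compared by element; bonds by order, or by mere
connectivity with `bond_compare = "any"`), with best-so-far
branch-and-bound pruning and a wall-clock deadline per molecule pair
(default 10 s). On timeout the best mapping found so far is returned and
flagged `exact = FALSE`. Multi-molecule sets fold pairwise from the
smallest molecule up. We abandoned the classical modular-product
maximum-clique formulation: its co-non-adjacency edges make the product
graph dense, and even C implementations stall on fused-ring systems,
whereas connected-mapping backtracking solves desk-scale molecules in
milliseconds. The result is emitted as an element/any-bond SMARTS so
that the "pattern matches every input molecule" invariant can be
verified independently through the OpenBabel matcher (`mcs_matches()`).

### Functional groups

`fg_library()` ships five editable SMARTS definitions: ether, ketone,
aldehyde, carboxyl, aromatic. Patterns use element-generic `[#8]`/`[#6]`
atoms so aromatic ring oxygens and ring carbonyls count (flavonoids owe
their ether + ketone signature to exactly those atoms), and encode the
exclusion rules: a carboxyl carbon is not also a ketone or aldehyde
(those patterns demand carbon neighbours on the carbonyl carbon), and
ester/lactone oxygens are not ethers.

## Statistical choices

* **Forest hyperparameters.** 500 trees, single-threaded, seeded, and
  `mtry = p/3` — the long-standing regression convention (the ranger
  default `sqrt(p)` is the classification convention and starves splits
  of informative bits when most of the ~hundreds of active fingerprint
  columns are noise). Constant-valued bits are dropped before fitting.
  Five CV folds by default; `k_folds = 0` skips CV when only held-out
  metrics are needed.
* **Residual cutoff.** Absolute residuals, not signed: the filter is
  meant to remove symmetric outliers, and a one-sided 95th percentile of
  signed residuals would only trim over-predictions. Quantiles use
  linear interpolation between order statistics (R type 7), the most
  common default, and are tested against an independent hand-written
  interpolation oracle.
* **Cluster-count selection.** `choose_k()` reports both the SSE curve
  (elbow = largest second difference) and the mean silhouette per k.
  When the two disagree the silhouette wins and the elbow is reported
  alongside — a deterministic precedence is required because a single k
  must feed the downstream profiling. A best silhouette below 0.25
  flags "no clear cluster structure".
* **Tier boundaries.** Both boundary values fall in the lower tier
  (pIC50 = 5 is low, 7 is medium), matching the printed inequalities;
  the three tiers partition the real line and this is property-tested.
* **Similarity threshold.** "Above 0.5" is read as strictly greater;
  the boundary case is covered by a test. A candidate's overall status
  is the union of its per-target hits.
* **Per-candidate potency.** When several per-target models score a
  candidate, the pipeline keeps the maximum predicted pIC50 (the
  best-predicted interaction); multi-target screens care about the
  strongest predicted effect.

## The BBB rule set

A compound scores 20 percentage points for each criterion met, all
bounds inclusive: MW <= 400 Da; -0.5 <= LogP <= 5; HBD <= 3; HBA <= 7;
TPSA <= 90 A^2. The package embeds seven well-characterised phenolics
(`flavonoid_panel()`) as a regression suite; with the descriptor layer
above, five reproduce their reference percentages exactly (coumarin
100%, dihydromyricetin 40%, quercetin 60%, kaempferol 60%, luteolin
60%). The remaining two are known discrepancies and deliberately
excluded rather than forced: astragalin computes 20% (MW 448 > 400,
HBD 7, HBA 11, TPSA 190 all fail) and apigenin 80% (TPSA 90.9
marginally exceeds 90), while their commonly cited values are 60% and
100%. No descriptor was tuned to close that gap; the criteria are
applied exactly as stated.

## Synthetic fixtures: what they emulate

`generate_compounds()` draws structures by decorating a small scaffold
library (benzene, benzopyranone, chromone/flavone, flavanone, short
aliphatic chains) with OH/OMe/Me/CHO/COOH/aryl substituents. Every draw
is valid by construction (validated over 10,000 draws in the test
suite) and shares genuine substructure with other draws — which the
similarity and MCS stages need to be meaningfully exercised.

`generate_activities()` plants a linear signal in fingerprint space:
pIC50 = 6 + sum of planted bit weights + N(0, noise_sd), with
`ic50_nm = 10^(9 - pIC50)`. Two well-definedness guarantees:

* planted bits are chosen with intermediate prevalence (20-80%) and
  **linearly independent** of each other and the intercept, so the
  planted weights are identifiable and a noise-free table is recovered
  exactly by least squares (tested to 1e-8);
* the drawn weights are rescaled so the realized signal SD equals
  `signal_sd` (default 1.0 pIC50 units). With the default noise SD of
  0.3 this fixes the population R^2 at ~0.92 instead of leaving the
  signal-to-noise ratio to the luck of the draw.

The recovery study conditions used by the test suite are n = 500
compounds, noise SD 0.3, five seeds; the forest's held-out RMSE must
stay within twice the noise SD and R^2 above 0.7. Cluster fixtures
place blob centres on distinct vertices of a scaled hypercube so any
two centres are at least `separation x noise_sd` apart (default 10
sigma, 6 blobs — silhouette selection recovers the planted count in at
least 18 of 20 seeds). Source-map fixtures plant exact per-source counts
(defaults 40, 37, 32, 32, 31, 31) and a 25-compound all-source
intersection.

What the fixtures do **not** emulate: real medicinal-chemistry property
distributions, activity cliffs, assay heterogeneity between databases,
measurement error in IC50, or class imbalance between actives and
inactives. Passing tests therefore demonstrate that the machinery is
correct and well-calibrated on data whose structure is known — not that
any particular accuracy will be attained on database-scale ligand sets,
whose per-target error statistics depend on data we do not ship.

## Numerical notes and degenerate inputs

* `ic50_to_pic50()` rejects non-positive and non-finite input; the
  inverse `pic50_to_ic50()` is exact to floating-point round trip.
* `split_dataset()` sizes the training set as `round(n x fraction)`,
  clamped so both partitions are non-empty.
* k-means uses 10 random restarts per k under a fixed seed; ties in
  `top_sources()` break alphabetically so rankings are stable.
* Single-atom molecules fingerprint correctly (at least one bit set);
  molecules with no common element yield an explicit "no MCS" result
  rather than an error.
* Unparseable SMILES never abort a batch: readers skip and report them,
  `predict_potency()` logs and drops them.

## Limitations

* OpenBabel's LogP/TPSA/HBA values differ in places from other
  toolkits' implementations; rule-based scores inherit those
  differences (see the astragalin/apigenin notes above).
* The similarity stage implements the stated cosine decision rule over
  fingerprints; it does not learn pair embeddings, so it cannot
  generalise beyond fingerprint similarity.
* MCS results on large molecules may be sub-maximal under the deadline;
  they are flagged, and the folded multi-molecule result depends on the
  fold order (smallest first, deterministic).
* Database-scale quantities — per-target error statistics of models
  trained on tens of thousands of ligands, absolute hit counts, docking
  energies — are out of the package's reach by design; the test suite
  covers the machinery with planted-truth analogues instead.
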