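---
title: "Nonadditivity analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonadditivity analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtcna)
```

## The model

SAR analysis routinely assumes additivity: in a Free-Wilson picture the
activity of a compound is a baseline plus independent contributions of its
substituents. `dtcna` tests that assumption locally. Two compounds that
differ by one localized transformation under a constant context form a
matched molecular pair; four compounds in which two transformations are
each applied twice form a double-transformation cycle (DTC). Writing
`pAct` for the negative decadic logarithm of a molar activity, the cycle
statistic is

$$\Delta\Delta \mathrm{pAct} = (\mathrm{pAct}_2 - \mathrm{pAct}_1) -
  (\mathrm{pAct}_3 - \mathrm{pAct}_4),$$

with c1 the corner from which both transformations depart, c2 and c4 the
singly-transformed corners and c3 the doubly-transformed corner. If the
two transformations contribute independently the statistic is exactly
zero, whatever the contributions are. A non-zero value means either a
substituent interaction (steric clash, changed binding mode, internal
hydrogen bond, ...) or accumulated measurement error. Separating those two
explanations is the core of the method.

### Noise propagation

Each of the four activities enters the statistic once, so independent
per-measurement errors of standard deviation $\sigma$ propagate to

$$\mathrm{Var}(\Delta\Delta \mathrm{pAct}) = 4\sigma^2,$$

i.e. the statistic is twice as noisy as a single measurement. The package
models the null as $N(0, (2\sigma)^2)$ (`theoretical_noise_density()`).
Defaults follow established estimates of assay reproducibility:
$\sigma = 0.3$ log units for homogeneous (single-protocol, in-house style)
data and $\sigma = 0.5$ for heterogeneous public data. A cycle is
*significant* when $|\Delta\Delta \mathrm{pAct}| > 2\sigma$ (0.6 or 1.0
log units respectively) — the point at which the observed deviation
exceeds twice the propagated uncertainty's standard deviation — and
*strong* above 2.0 log units, a hundred-fold departure from additivity.
These are thresholds, not hypothesis tests; no multiplicity correction is
applied, matching the framework's established usage.

### Orientation and the sign

A cycle has eight symmetric orientations; $|\Delta\Delta \mathrm{pAct}|$
is invariant and the sign flips with orientation. For reproducible signed
output each cycle is emitted once in a canonical orientation: the
lexicographically smaller transformation (by canonical fragment SMILES) is
transformation A, and c1 is the corner from which both transformations
depart. Per-compound profiles re-orient every cycle around the focal
compound: the reported *additivity shift* is the observed pActivity minus
the additive expectation computed from the other three corners, so a
compound that is more potent than additivity predicts has a positive mean
shift. (The same quantity with the opposite sign convention is the
c3-oriented cycle statistic.) The null band for a compound in $n$ cycles
is $\pm 1.96 \cdot 2\sigma/\sqrt{n}$; note the shifts of overlapping
cycles are correlated, so the band is approximate.

A compound is flagged as showing significant nonadditivity when at least
one of its cycles is significant. This matches how per-compound counts
aggregate naturally from cycle tables; an alternative — mean shift outside
the null band — can be derived from the profile columns directly and is
less sensitive to a single noisy cycle (the profile table carries both
`na_max_abs` and `mean_shift`/`ci_high` for that reason).

## Curation

Raw measurement tables are curated per assay, in a fixed order, with a
per-step audit report:

1. endpoint selection is a user-supplied allowlist (judgement-based, not
   automated text mining);
2. structures are standardized (charge neutralization + canonical SMILES
   via OpenBabel; unparseable structures are dropped with a reason). No
   canonical-tautomer step is applied — proprietary standardizers that
   include one will produce slightly different duplicate merges, so counts
   on public-database extracts can deviate marginally;
3. missing, qualified (`<`, `>`) and negative values are removed, then
   records without a defined concentration unit
   (M, mM, µM, nM, pM, fM);
4. values are converted to pActivity; values outside the open
   (10 pM, 10 mM) interval — i.e. pActivity at or beyond 2.0 / 11.0 — are
   dropped, as are pre-logged values carrying a unit annotation. Boundary
   values are dropped (the strict reading of "lower/higher than");
5. compounds whose replicate pActivities spread over more than 2.5 log
   units (max − min, computed after unit conversion) are removed; the
   rest collapse to their median. Only the offending compound is dropped,
   never the assay;
6. distinct compound IDs with one standardized structure keep the entry
   with the highest pActivity (ties broken by compound ID for
   determinism);
7. molecules above 70 heavy atoms (atomic number > 1) are removed;
8. assays with fewer than 25 unique compounds are discarded.

Replicate handling (step 5) runs per compound ID *before* the
structure-level merge (step 6), following the printed step order; an
implementation that merges structures first could collapse replicates
differently when one structure hides under several IDs.

## MMP indexing choices

Fragmentation enumerates every single, acyclic bond between heavy atoms
(Hussain–Rea single cuts). Hydrogen replacements are not generated, so an
H→R change is invisible to the pair index; multi-cut MMPs are out of
scope. The transformation-size rule — the variable fragment may not exceed
one third of a molecule's heavy atoms — is enforced on *both* molecules of
a pair at indexing time rather than inside `fragment()`: the enumeration
itself stays complete (a symmetric ethane cut is still reported), and
whether the original size rule bound one or both partners is not
documented, so the stricter both-molecule variant was chosen. Fragment
keys are canonical SMILES with a `*` attachment atom, so identical
contexts written from different spellings collide by construction.

## The synthetic generator

The generator emulates what the method needs from real data, with ground
truth attached:

* a combinatorial two-site R-group library on an amide-linked diaryl
  scaffold; 25 distinct series are produced by aromatic C→N ring-isomer
  patterns drawn from distinct mirror-symmetry classes, so no two series
  can be related by a single acyclic-bond cut (ring mutations are not
  cuts, and transformations of half the molecule are removed by the
  1/3 size rule) — cross-series cycles provably cannot form;
* substituent alphabets of small groups (methyl, ethyl, methoxy, halogen,
  amino, hydroxy, nitrile; at most 2 heavy atoms) whose stems are unique,
  so cuts inside a substituent cannot create unplanned transformations.
  Hydrogen is supported as a site occupant but not used in defaults,
  because H-cuts are excluded from the MMP dialect and H↔R pairs would be
  invisible;
* a Free-Wilson activity model: per-series baseline (N(4.8, 0.3²) log
  units, placing the library across the pActivity-5 classification
  boundary), global per-substituent contributions (uniform on ±0.8 log
  units, consistent across series as in real SAR) with small per-series
  deviations (sd 0.1), and optional pairwise interaction terms of chosen
  magnitude injected at chosen grid corners;
* measurement: i.i.d. Gaussian noise in log units, back-conversion to
  concentrations in sampled units (µM/nM; the round trip is lossless to
  well below 1e-9 log units), optional replicate measurements, qualified
  records and duplicate compound IDs to exercise the curation filters.

The default ML-study assay uses 25 series with 6×6 grids at 50% random
occupancy (~450 compounds). Sparse occupancy keeps the number of cycles
per compound low (a few), as in public SAR data; in a dense combinatorial
block nearly every compound would sit in dozens of cycles and the
any-cycle significance flag would saturate under noise alone. Interactions
of δ = 2.0 log units are injected at present grid corners, one series at a
time, until about 10% of all designed cycles are nonadditive. The designed
cycle set (all complete 2×2 sub-blocks) and the injected corners are
emitted as ground truth.

What the generator does *not* emulate: scaffold diversity beyond ring
isomerism, correlated (systematic) assay errors, censored dose-response
tails, activity-dependent noise, and interactions spanning more than one
site pair. Passing tests therefore demonstrate correctness of the
machinery and the statistic's behavior under the stated noise model, not
performance on any particular real assay.

## The QSAR study

Compounds are labeled from cycle membership at the heterogeneous-data
threshold (1.0 log unit): *nonadditive* if any of their cycles exceeds it,
*additive* if they sit only in cycles below it, *no_dtc* otherwise.
Models are trained on additive data only and evaluated on an additive
held-out test set and the nonadditive hold-out:

* **DTC split** — cycle members only, stratified 80/20 on pActivity
  deciles (the stratification variable is the response, preserving
  activity-range coverage between train and test);
* **all split** — as above with non-cycle compounds assumed additive;
* **A-B-AB split** — cycle-informed: iterating cycles in canonical order
  from a seed-chosen random starting point, corners c1/c2/c4 go to
  training and the doubly-transformed corner c3 to the AB test set; an
  already-assigned compound keeps its role and conflicting cycles are
  skipped. Nonadditive compounds never remain in training. The procedure
  is seeded (defaults 4 and 7 are conventional) and isolated in one
  function; it is an interpretation of the idea "train on A and B,
  predict AB", not a reconstruction of any specific published variant.

Features are ECFP6-style circular substructure *counts* (radius 3), hashed
and folded to 2048 positions (the community-default length; configurable).
Counts rather than bits retain substructure multiplicity. The in-package
implementation stops emitting an atom's identifiers once its neighborhood
stops growing, so each environment is counted once per center; it is a
faithful member of the circular-fingerprint family rather than a bit-exact
replica of any toolkit's variant.

Hyperparameters are searched by randomized sampling (RF: trees 100–1000,
mtry fraction 0.05–0.6, node size; SVM-RBF: cost and gamma log-uniform;
PLS: 2–50 components) scored by mean 5-fold cross-validated R², then the
best configuration is refit on the full training set. Randomized search
replaces surrogate-model optimization; with the modest trial budgets used
here the difference is immaterial, and the search is seeded and
reproducible. Regression metrics are R² and RMSE; for classification the
truths and predictions are dichotomized at pActivity 5 (class 1 strictly
above 5, so an exact 5.0 is inactive) and summarized by MCC with the full
confusion matrix.

Mixin experiments add 0.6%, 1.3% and 2.6% (relative to training-set size)
of nonadditive compounds to training, reusing previously established
hyperparameters. The draws are nested (Q1 ⊂ median ⊂ Q3), so the fixed
nonadditive hold-out — the pool minus the largest draw — is identical
across fractions and never contaminated by training.

## Numerical choices and degenerate inputs

* Free-Wilson exactness is asserted to 1e-9 (floating-point cancellation
  of sums, not an algorithmic tolerance).
* Distribution summaries use classical moment estimators; kurtosis is
  reported as *excess* kurtosis (normal = 0) and labelled as such.
  Normality is checked by a Kolmogorov–Smirnov test against
  N(0, sample sd) — using the estimated sd makes the p-value approximate,
  which is acceptable for its descriptive role.
* Two-sample comparisons use Kruskal–Wallis and two-sided Mann–Whitney
  tests (normal approximation with ties correction); an all-tied pooled
  sample is flagged degenerate with `NA` p-values.
* Empty cycle sets yield zero-count summaries with `NA` statistics;
  single-class test sets yield `NA` MCC; zero-variance responses abort
  training with a message.
* Problem sizes in the shipped tests and the acceptance script are chosen
  for fast, deterministic runs: 100,000 simulated noise cycles, toy pair
  sets of ≤ 16 compounds against an exhaustive quadruple-enumeration
  oracle, one ~450-compound synthetic assay per seed, and RF searches of
  3–5 random trials. All sampling flows from explicit seeds.

## Known limitations

* The MMP dialect (single cuts, no hydrogen replacement, both-molecule
  1/3 rule) affects pair and cycle counts; comparisons against tools with
  other dialects will differ at the margins.
* The open standardizer (neutralization + canonical SMILES, no tautomer
  canonicalization) can split tautomer duplicates that a stronger
  standardizer would merge.
* The per-compound null band ignores correlation between overlapping
  cycles.
* The A-B-AB assignment is greedy and order-dependent by design (seeded);
  different seeds give different, equally valid splits.
* PLS regression requires the suggested mixOmics package.
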