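---
title: "Profiling focused chemical libraries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling focused chemical libraries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

libprof characterizes focused screening libraries — collections of
molecules designed or assembled around one biological target — along four
axes: drug-likeness, synthetic accessibility, structural diversity, and
predicted activity. This vignette documents the models and procedures
behind each axis, the tunable parameters and their defaults, the numerical
choices the implementation makes, and the limits of what the synthetic
test data can demonstrate.

## Curation

All chemistry flows through one canonical-SMILES dialect (OpenBabel
canonical SMILES via ChemmineOB). Canonical strings from different
toolkits are **not** interchangeable; within the package, equality of
canonical SMILES is the definition of structural identity.

`curate_library()` applies, in order: parsing; largest-fragment selection
for multi-component inputs (most heavy atoms, ties by molecular weight,
then lexicographic canonical SMILES — the tie-breaks are a package
convention); an element whitelist (H, B, C, N, O, F, Si, P, S, Cl, Se,
Br, I), applied *after* largest-fragment selection so an exotic counterion
does not reject its parent; charge neutralization; stereochemistry
stripping (disabled with `keep_stereo = TRUE`, intended for de novo
designs whose stereocentres are meaningful); and canonical-duplicate
removal keeping the first occurrence in input order.

**Limitation.** The toolkit has no tautomer enumerator, so no canonical
tautomer is generated: tautomeric duplicates drawn differently can survive
deduplication. The curation report records this. Likewise "reionization"
(reassigning acid/base sites after neutralization) is not performed.

Curation is idempotent — a second pass reports zero removals — and the
report satisfies the identity
`n_output = n_input - n_parse_failed - n_element_rejected - n_duplicates_removed`
on every input; both properties are enforced by tests.

## Descriptors

The descriptor vector is MW, HBD, HBA, TPSA (Ertl), logP
(Wildman–Crippen as implemented by OpenBabel), nRotB (single acyclic
bonds between non-terminal, non-triple-bonded atoms, by SMARTS), ESOL,
SAscore, QED, and an optional externally computed logD. Donor/acceptor
counts follow OpenBabel's definitions; they can differ by one from other
toolkits on edge cases (e.g. amide nitrogens), which matters only if
numbers are compared across toolkits.

**ESOL** is Delaney's published regression
`log10 S = 0.16 − 0.63 logP − 0.0062 MW + 0.066 nRotB − 0.74 AP`,
with `AP` the aromatic fraction of heavy atoms. It approximates the
commercial solubility descriptor sometimes used for the same purpose.

**QED** is the published weighted-geometric-mean formulation: eight
properties (MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS) transformed by
asymmetric-double-sigmoid desirability functions with the published
parameters and weights, including the published structural-alert SMARTS
set (two alert patterns expressed as count thresholds because
dot-disconnected SMARTS are not portable). Aromatic-ring counts (AROM)
use rings of size ≤ 8, a practical stand-in for SSSR that coincides with
it on drug-like molecules. On probe molecules where the underlying
property definitions coincide across toolkits, the package reproduces the
reference implementation's QED to ~1e-5; the conventional "attractive"
threshold is 0.67.

**SAscore** keeps the published architecture — a fragment-familiarity
term plus complexity penalties, rescaled to [1, 10] with scores above 6
flagged "not synthetically feasible" — but the familiarity table is
parameterized differently. The original table aggregates circular-fragment
frequencies over ~1M compounds and is several megabytes; libprof instead
ships a *procedure*, `sa_fragment_table()`, that scores each circular
(ECFP4) fragment bit as `log10(1000 · frequency)` over any reference
corpus, and a compact built-in default corpus (~600 molecules enumerated
from the package's scaffold/substituent chemistry). Complexity penalties
cover size (`n^1.005 − n`), stereocentres, fused and spiro ring pairs,
macrocycles (a ring bond not covered by any ring of size ≤ 8), and a
repetition bonus when many atoms map to few distinct fragments.
Consequences: scores are *comparable within an analysis* and
rank-correlate strongly with the original implementation (tested,
Spearman > 0.7 on a structurally diverse probe set), but absolute values
run higher than the original because a small corpus makes ordinary
fragments look rarer. Supplying a table trained on a large in-house
corpus recovers absolute comparability.

## Range-based de novo scoring

`denovo_score()` mirrors the scoring function used by ligand-based
generators: each of seven descriptors (MW, HBD, HBA, logP, ESOL, SAscore,
TPSA) contributes 1 if it lies inside a closed interval and 0 otherwise;
the score is the arithmetic mean of the seven contributions; if any
penalty substructure matches, the score is multiplied by
`1 − penalty_value` (default 1, a hard veto). Intervals default to
mean ± 1 SD over a profiled active set (`derive_score_rules()`), the
convention used to focus generation on property space occupied by known
actives. The 0/1 gate (rather than a graded ramp) is a deliberate choice:
only the intervals are published for this class of scoring function, not
the desirability shape, and the hard gate is the reproducible reading.
The default nucleoside-like penalty SMARTS (ribofuranose cores) are
configuration, not constants; serious use should supply target-specific
patterns via the YAML interface (`read_score_rules()`).

## Fragments and diversity selection

`recap_fragments()` implements the RECAP bond classes — amide, ester,
amine, urea, ether, olefin, quaternary nitrogen, aromatic N–aliphatic C,
lactam N–aliphatic C, biaryl C–C, sulfonamide — as local graph predicates;
only acyclic bonds are cut, all cleavable bonds are cut simultaneously,
and the connected components (leaf fragments) are emitted. Fragments carry
`*` dummy-atom attachment markers; `growing_sites` are the 0-based
positions of those markers in the fragment's canonical atom order,
supporting downstream growing-site annotation. Fragment MW weighs the
hydrogen-capped fragment.

`maxmin_select()` is greedy MaxMin on Tanimoto distance. The first pick is
`seed mod pool-size` — a deterministic, documented initialization
(published descriptions leave initialization open); each subsequent pick
maximizes its minimum distance to the picked set, ties to the earliest
pool index. The classic greedy guarantee (min-distance within a factor 2
of optimal) is verified empirically on small pools against exhaustive
search.

The two pipelines follow the field's conventions exactly as to bounds:
training sets keep MW **strictly greater** than 300 then MaxMin (MACCS
keys, 166 bits) to 285; fragment libraries keep MW **strictly below** 300
(RO3) with H2O/NH3/HCl always excluded, MaxMin to 400, logD **≤ 3**
(closed bound; logD is an input column, computed externally), MaxMin to
177. Under-filled stages return everything with a warning.

## Scaffold and similarity diversity

Bemis–Murcko chemotypes are computed by iterative pruning of terminal
non-ring atoms (leaving rings plus linkers) followed by restoration of
atoms multiple-bonded to the retained frame (carbonyl linkers); ring-free
molecules map to an `ACYCLIC` pseudo-chemotype. By default `ACYCLIC`
participates in the counts, N, CSR and SSE — so acyclic-rich sets
register as less diverse — while the acyclic fraction is also reported
separately; `include_acyclic = FALSE` switches to the cyclic-only
convention. The CSR (cyclic-system-retrieval) curve plots cumulative
molecule fraction against chemotype fraction, most frequent first, with
the origin prepended and linear interpolation; AUC is trapezoidal
(0.5 = all chemotypes unique, → 1 = one dominant chemotype). F50 is the
smallest chemotype fraction recovering half the molecules. The scaled
Shannon entropy SSE_n renormalizes the top-n chemotype counts among
themselves and divides by `log n` (using `log N` when fewer than n
chemotypes exist), so it is log-base invariant, 1 exactly for even
occupancy and 0 for a single chemotype.

Pairwise similarity statistics (median/mean/CDF of Tanimoto over all
off-diagonal pairs) stream over row blocks; the full similarity matrix is
never materialized. Tanimoto of two all-zero fingerprints is defined
as 1. Property-space diversity is the median pairwise Euclidean distance
over the six z-scored properties (MW, HBD, HBA, TPSA, nRotB, logP);
median and z-scoring are package choices, and when several datasets are
compared (consensus diversity plots) the scaling is computed over the
pooled datasets so all distances share one scale. A consensus diversity
plot places each dataset at (median MACCS/Tanimoto, scaffold AUC) with
property distance as color and size as dataset size.

Chemical-space embeddings use PCA (`prcomp`, deterministic,
explained-variance reported) or exact t-SNE. The t-SNE is the standard
O(n²) formulation — perplexity-calibrated Gaussian affinities,
early exaggeration 12 for 100 iterations, momentum 0.5→0.8, learning
rate 200, seed-deterministic initialization — written for the desk-scale
sets this package embeds (hundreds to a few thousand molecules); no
tree approximation is used.

## Activity classification

IC50 records are labeled at a 10 µM threshold: `=`, `<`, `≤` at or below
threshold → active; `=` above, and `>`, `≥` at or above threshold →
inactive; combinations that do not pin the class (e.g. `< 100 µM`,
`> 1 µM`) are ambiguous and removed. Duplicated structures (canonical
equality after curation) with conflicting labels are removed entirely;
concordant duplicates collapse to the record carrying the median value.
Units nM/µM/mM are converted; anything else is an error, not a guess.

The model grid crosses five algorithms (k-NN, random forest, gradient
boosting, RBF-kernel SVM, single-hidden-layer feed-forward network) with
three fingerprints (MACCS 166, circular ECFP4 2048, and the linear-path
FP2 1024 as the path-based fingerprint family member). Hyperparameter
menus are deliberately tiny and user-overridable
(`default_hyper_grids()`): k ∈ {1,3,5}; 200 trees; depth-3 boosting with
50 rounds; SVM cost 1 (larger costs make the SMO solver's run time
explode on these Gram matrices for no accuracy gain); hidden width 8
with weight decay 1e-3. Selection
uses leave-one-out cross-validated balanced accuracy
(BA = (sensitivity + specificity)/2), aggregating all held-out
predictions into one confusion matrix; ties in BA resolve to the earlier
grid entry.

Implementation notes, for the record: the SVM uses a precomputed RBF Gram
matrix (median-heuristic width) so the LOO loop refits on submatrices;
the feed-forward network is implemented in-package as a
single-hidden-layer tanh/logistic classifier trained full-batch with Adam
and an early-stopping rule, because the classic BFGS-based
implementations scale quadratically in weight count and are impractical
for LOO over 2048-bit inputs; k-NN breaks voting ties with the nearest
neighbour's class to stay deterministic.

**Distance to model.** Confidence is the mean Jaccard distance (1 −
Tanimoto, circular fingerprints) from a query to the training compounds.
Evaluation records are split into four equal-occupancy quartiles by their
LOO distances (stable input order breaks ties; quartile boundaries are
the 25/50/75th percentiles), and per-quartile precision/recall for the
active class quantify how performance degrades with distance. For
deployment the model is retrained on the full labeled set; a query whose
distance exceeds the largest evaluation distance is binned `BEYOND` —
unknown confidence — rather than being forced into Q4. A quartile with no
predicted actives reports precision `NA`, never 0/0.

## Synthetic data: what it does and does not show

The generators build molecules from a fixed, curated table of scaffold
templates (benzene, pyridine, pyrimidine, naphthalene, quinoline,
thiophene, furan, piperidine, cyclohexane, morpholine) decorated with
acyclic substituents — combinations chosen so substitution can never
alter the Bemis–Murcko chemotype, and asserted per emitted molecule
rather than trusted. Scaffold frequencies, acyclic counts, class sizes,
IC50 distributions (lognormal around 1 µM for actives and 100 µM for
inactives, truncated to the correct side of the 10 µM threshold so
ground truth and threshold label coincide), ambiguous-qualifier fractions
and contradictory duplicates are all spec-controlled, and every generator
is a pure function of its spec including the seed.

The activity generator's `separability` knob interpolates between
class-disjoint scaffold pools (1: structure determines class; a sound
model should approach BA 1) and fully mixed pools (0: labels independent
of structure; any honest model sits near BA 0.5). Test sizes are chosen
for a laptop-scale run: 200-compound activity sets for the recovery
analyses, 100-molecule sets for similarity-statistic validation.

What passing tests on these data *do* show: the statistics, filters,
selection algorithms and evaluation machinery compute what they claim,
exactly, under known ground truth. What they do *not* show: performance
on real medicinal chemistry. The synthetic chemistry is narrow (ten
scaffolds, two substitution sites, no stereochemistry, no tautomerism, no
salt forms), classes separate by scaffold identity — far easier than real
SAR — and property distributions are narrower than screening decks. Model
BA on synthetic data says nothing about BA on a real target's data.

## Numerical conventions

Closed intervals throughout the de novo score; strict bounds `< 300` /
`> 300` and closed `≤ 3` in the fragment pipelines, pinned by tests.
Chemotype count ties sort lexicographically; duplicate removal keeps the
first occurrence; MaxMin ties take the earliest index; DM-quartile ties
keep input order. Degenerate cases are defined, not accidental: Tanimoto
of empty fingerprints is 1, SSE of a single chemotype is 0, precision
without predicted positives is NA, zero-variance PCA input is an error.
All stochastic steps (splits, generators, t-SNE, stochastic learners)
take explicit integer seeds.
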