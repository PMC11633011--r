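---
title: "Predicting molecular flavor profiles: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting molecular flavor profiles: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most food metabolomics studies annotate far more compounds than have a known
sensory profile. `flavorcast` closes that gap for seven flavor categories —
bitter, floral, fruity, off-flavor, nutty, sour, sweet — by treating each
category as an independent binary classification task over molecular
structure. A query given as isomeric SMILES is first looked up in a curated
table of compounds with known profiles; only unmatched structures are passed
to the seven classifiers, which return a probability per category. Labels
are non-exclusive: a molecule can be fruity and sweet at once, and each of
the seven models votes independently.

## The pipeline

**Curation.** Raw tables (name, PubChem id, SMILES, free-text flavor terms,
source) are cleaned with first-match drop rules: structures that do not
parse, multi-fragment species (salts are dropped rather than desalted,
because the ionic-versus-neutral representation of a salt is ambiguous and
desalting silently changes the structure being labelled), molecules with
fewer than two heavy atoms, rows without any flavor term, and duplicates.
Duplicate detection is by canonical *isomeric* SMILES equality, since
stereoisomers can smell different; duplicate rows have their raw terms
merged and the union re-mapped, so conflicting labels resolve to the union.
Fine-grained sensory terms map to the seven categories through an editable
flavor-wheel config (`inst/extdata/flavor_wheel.tsv`). Published wheels
differ between commodities, so the packaged vocabulary is deliberately a
replaceable stand-in; any result that hinges on a specific term mapping is
config-sensitive and should be re-run with the project's own lexicon.

**Featurization.** Two representations are produced. (1) A ~107-column 2-D
physicochemical descriptor matrix: OpenBabel baseline properties (MolWt,
MolLogP, MolMR, TPSA, H-bond donor/acceptor counts), composition, bond and
ring counts, Kier–Hall E-state indices, chi connectivity and kappa shape
indices, Wiener/Zagreb/Balaban topological indices, Gasteiger PEOE partial
charges, a Labute-style approximate van der Waals surface area, and the
binned VSA families (PEOE_VSA, SMR_VSA, EState_VSA, VSA_EState). The set is
assembled in-package on the heavy-atom graph with implicit hydrogens; it is
smaller than the ~200-descriptor sets of the large Python toolkits but
covers the same families, including every descriptor that the downstream
importance analyses single out (TPSA, MolLogP, PEOE_VSA, EState_VSA,
SMR_VSA1, MinEStateIndex). (2) Radius-2 circular fingerprints (the
ECFP4-equivalent) hashed to 2048 bits by default. The implementation keeps
the map from every set bit back to its atom environments, which is what
makes `bit_to_fragments()` possible; its environment-counting convention
matches OpenBabel's ECFP (environments are emitted at every radius, without
de-duplicating those that stop growing), which the tests exploit as an
independent oracle on symmetric molecules. 2048 bits is standard practice;
the value is configurable and only changes the collision rate.

**Feature filters.** Fixed order: columns with any non-finite value, then
near-constant columns (single most frequent value in more than 97% of
rows), then — for descriptors only — a greedy Pearson filter that walks
columns in order and drops any later column with |r| > 0.95 against an
already-kept one. Absolute correlation is used because an anti-correlated
duplicate carries no additional information; keeping the *earlier* column
makes the scan deterministic. Fingerprint bits skip the correlation filter.
Filters are computed on the full dataset before the 80:20 split, matching
the workflow this package operationalizes; the filters only inspect
marginal column distributions, so the leakage risk is minor, but
re-filtering on the training partition is a one-line change for the
cautious.

**Split.** A per-flavor stratified 80:20 split. Stratification matters
because the rarest class (sour-like, ~3% positive) can otherwise land zero
positives in the test fold, making recall undefined.

**Imbalance correction.** Applied strictly to the training partition, per
flavor. SMOTE grows the minority to the majority count by interpolating
between a minority sample and one of its 5 nearest minority neighbours;
cluster-centroid undersampling replaces the majority by the centroids of a
k-means with k equal to the minority count. SMOTE on binary fingerprints
produces fractional rows; these are intentionally *not* re-binarized —
interpolation in bit space is the standard behaviour, and rounding would
destroy the convexity property the tests rely on. Per-row provenance flags
(`original`/`synthetic`/`centroid`) make the no-leakage guarantee
assertable.

**Training.** Seven independent binary classifiers. The backbone uses the
winning combination per flavor: random forest on SMOTE-oversampled
fingerprints for bitter, fruity, sweet and off-flavor; random forest on
descriptors for floral and nutty; k-nearest-neighbours on SMOTE-oversampled
fingerprints for sour. The resampler for the two descriptor-based models is
not pinned down by the source workflow; SMOTE is the default here and is
exposed in `backbone_config()`. Hyperparameters come from an exhaustive
grid search scored by mean ROC AUC over five stratified CV folds (ROC AUC
is the headline metric and is threshold-free, which matters when the
classes are resampled). The full grids are forest {100/300/500 trees,
unlimited/10/20 depth, min leaf 1/5} and neighbours {k 3/5/7/11,
uniform/distance weights}; `train_backbone()` defaults to a small "fast"
subset (forest: 300 trees, min leaf 1/5; neighbours: k 3/5, distance)
because on the datasets used in the examples the extra grid points change
selection rarely and cost several-fold more compute. Binary calls use a
fixed 0.5 probability threshold throughout.

**Metrics.** Recall and specificity from exact counts; ROC AUC by the
rank statistic (equal to exhaustive positive/negative pair counting,
ties counted half). Majority-class bias is defined as specificity minus
recall, and the overfit score as train recall minus test recall (negative
values flag underfitting). Both are plain differences: the regimes of
interest ("bias above 40%", "recall drop of 20–90% from train to test")
are statements about differences of rates, and any monotone variant would
order models identically. Train-phase metrics are means over the five CV
folds.

**Interpretability.** For forests, impurity-based VIP scores normalized to
sum to one; for neighbour models, permutation importance (mean ROC AUC drop
over 10 shuffles of a column, clamped at zero so a constant column scores
exactly 0). `bit_to_fragments()` inverts the fingerprint: for a bit of
interest it extracts, from every molecule setting the bit, the circular
environments hashing to it as fragment SMILES with `*` attachment points.

## The synthetic data generator

`generate_fixture()` builds molecules from a fragment grammar — branched
alkyl scaffolds decorated with esters, free carboxylic acids, vicinal
diols, methyl-branched unsaturated alcohols (a terpenoid-like motif),
thiols/aldehydes, pyridines and pyrazines — so that every generated SMILES
is valid by construction and the noise-free labels are decidable by
substructure rules (ester → fruity, acid → sour, vicinal diol → sweet,
terpenoid alcohol → floral, thiol/aldehyde → off-flavor, pyridine →
bitter, pyrazine → nutty). Default positive fractions mimic the curated
collection the package targets: sweet nearly balanced (0.48), sour rare
(0.03), the others near 0.2 — on average ~20% positives per task. Intent
probabilities are adjusted by a fixed-point iteration so the achieved
marginals match these targets after conditioning on at least one flavor
per molecule (a record without any term would be dropped in curation).
Optional label noise flips each stored label independently with
probability ε; `truth_table()` always re-derives the rule labels.

What the generator does *not* emulate: the chemical diversity of a real
curated table (thousands of scaffolds versus one grammar), label
subjectivity that is *structured* rather than independent Bernoulli noise,
and structure–flavor ambiguity (here a motif implies a flavor by
construction). Consequently, passing the recovery tests shows that the
pipeline can learn planted structure–label rules through the full
curation→featurize→balance→train→evaluate path — it does not certify
real-data accuracy. One visible consequence: on noise-free fixtures the
forest models separate classes almost perfectly, so the majority-class
bias that motivates resampling only manifests in combinations that cannot
memorize the motif. The imbalance-contrast experiment therefore uses
uniform k-NN on unscaled descriptors, where Euclidean distance is
dominated by molecular size and the 97:3 prior collapses predictions to
the majority class (bias ≈ 0.8–0.9); SMOTE restores the class balance
among neighbours and cuts the bias by well over half. That is the same
mechanism — prior correction in the feature space — that resampling
provides on real data.

## Numerical choices and degenerate inputs

* Problem sizes: the end-to-end tests and the acceptance script train the
  backbone on a 2000-compound fixture with five-fold CV and the fast grid
  preset; the package's own experiments showed the full grids change model
  selection only marginally on this data.
* Random seeds flow from a single integer: splits, fold assignment, SMOTE
  draws, k-means restarts and forest fits are all seeded, so identical
  seeds give bit-identical backbones.
* Ties: grid search takes the first grid point on equal CV AUC; the
  correlation filter keeps the earlier column; k-means uses 5 restarts
  under the seed, and distance-weighted k-NN regularizes 1/d with a 1e-8
  floor so exact-duplicate neighbours do not produce infinities.
* Unparsable query SMILES never abort a prediction batch; the row is kept
  with `source = "error"`. Zero-variance columns reaching the correlation
  filter raise an explicit error (the near-constant filter removes them in
  the standard pipeline order).
* PubChem identifiers are validated structurally only (positive integers);
  no live lookups are performed, so the whole package runs offline.

## Known limitations

* The descriptor set is ~107 features, not the ~200 of the big Python
  toolkits; families are covered but tail descriptors (e.g. fragment-count
  SMARTS libraries, BCUT eigenvalues) are absent.
* The flavor wheel is a generic stand-in; category assignments for
  ambiguous terms ("green", "spicy") are editorial.
* Binary calls at a fixed 0.5 threshold are not calibrated probabilities.
* Flavor thresholds (detection concentrations) and mixture/matrix effects
  are out of scope; predictions are per-molecule and binary.
* Replicating the published full-table metrics requires the original
  curated 13,387-compound collection, which is not redistributed here; see
  `replicate_reported_metrics()` for the entry point that runs once the
  table is supplied locally.
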