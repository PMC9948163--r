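---
title: "Methods: curation, scaffolds, landscapes and QSAR in chemlandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, scaffolds, landscapes and QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes, the choices
behind each stage, and what the synthetic validation does and does not
demonstrate.

## Curation model

A bioactivity record is kept when it carries an IC50 value *or* a pChEMBL
value *and* its relation is exactly `"="`; censored measurements (`>`, `<`)
say only that the true potency lies beyond the assay window and cannot be
placed on the pIC50 scale. Deduplication is by molecule identifier, keeping
the **first** occurrence in file order. The source data do not say which of
several duplicate measurements is authoritative, so determinism is the only
defensible default; a `dedup = "median"` option aggregates the duplicate
values by median instead, which is the usual choice when conflicting
replicates must be reconciled.

pIC50 is `-log10(IC50 [mol/L])`, i.e. `9 - log10(value)` for nM and
`6 - log10(value)` for uM. When a record carries both a pChEMBL value and
a convertible standard value, the pChEMBL value wins (it is the database's
own standardized quantity); disagreements above 0.01 log units are counted
in the curation log. Records that fail SMILES parsing or unit conversion
are excluded and counted, never silently dropped.

Class boundaries: potent `[8, inf)`, active `[7, 8)`, intermediate
`[6, 7)`, inactive `(-inf, 6)`. Reading the active band as right-open makes
the four intervals tile the line, so classification is total and monotone.

Steroid flagging is a substructure question with no universal operational
definition; the package matches the gonane skeleton — the fused 6-6-6-5
all-carbon tetracycle — with bond orders unconstrained, so aromatic-A-ring
steroids (estradiol) match alongside saturated ones. The match runs as a
colour-constrained VF2 subgraph isomorphism on the molecular graph; a
SMARTS pattern can be supplied instead where a different definition is
wanted.

## Descriptors, group statistics, PCA

The six properties are MW (Da), log P (Crippen-type atomic-contribution
estimate from the OpenBabel backend), hydrogen-bond acceptor and donor
counts, rotatable bonds, and Ertl TPSA (A^2). Exact parity with
GUI-platform property implementations' log P estimators is not a
goal: those models are not reproducible from their publications, and every
downstream statistic is estimator-agnostic. Rotatable bonds are counted
directly on the graph — single, non-ring bonds between two non-terminal
heavy atoms, excluding atoms in triple bonds — which is the convention
under which n-butane has exactly one rotor.

Group comparisons use a two-sided Mann–Whitney U test implemented in the
package: exact enumeration of all rank assignments when the smaller group
has at most 8 observations (ties handled by mid-ranks in the enumeration),
otherwise a tie-corrected normal approximation *without* continuity
correction. Skewness is adjusted Fisher–Pearson (type 2) and kurtosis is
excess kurtosis (type 2), the common spreadsheet conventions; a constant
sample reports `NaN` moments rather than a fabricated zero.

PCA standardizes each property to zero mean and unit variance first — the
six properties live on incommensurate scales, and an unscaled PCA would be
an MW analysis. Components come from `prcomp`; each loading column is
sign-fixed so its largest-magnitude coefficient is positive, which is the
only way to make loading signs reproducible across linear-algebra
implementations.

## Scaffolds

The Bemis–Murcko scaffold is computed on the molecular graph as the 2-core
(iterated removal of terminal atoms leaves exactly the ring systems plus
their connecting linkers) plus any atom attached to that core by a bond of
order ≥ 2, so exocyclic carbonyls stay on the scaffold. The cyclic
skeleton (CSK) then replaces every atom by carbon and every bond by a
single bond before re-canonicalisation; both reductions together are what
makes pyridine and benzene, or quinoline and naphthalene, CSK-equivalent.
Both operations are idempotent, and `Ncsk <= Ns <= N` holds on any input.

Acyclic molecules have an empty scaffold; they are collected into a single
record flagged `acyclic`, excluded from the CSK count. Diversity reports
per activity class compute each class independently, so scaffolds shared
between classes appear in several rows and class counts may sum to more
than the complete row — this mirrors how the class tables are usually
presented.

The enrichment factor treats "active molecules" as group 1
(potent + active): `EF = (group-1 members / frequency) / (group-1 total /
N)`. Frequency-weighted EF therefore averages to exactly 1 over any
scaffold table, a useful invariant check. EF is reported `NA` for class
subsets that contain no group-1 molecules at all.

R-group decomposition matches the canonicalised scaffold into each member
(VF2 with element colours; bond orders are deliberately not matched so
that differently kekulised aromatic rings still align) and labels
positions `R1..Rk` by the scaffold's canonical atom order. Among symmetric
matches the lexicographically smallest atom mapping is used, making labels
deterministic. Unsubstituted positions report `[H]`; multiple substituents
on one position are dot-joined.

## Structure–activity landscape

Fingerprints: `ecfp4` is the backend's radius-2 circular fingerprint
OR-folded from 4096 to 2048 bits; `maccs` is the 166 MACCS keys;
`pubchem` is an 881-position substructure-key fingerprint laid out in the
PubChem key families — hierarchic element counts, ring-topology keys
(cyclomatic number, smallest-ring sizes through each ring bond,
heteroatoms in rings, fusion atoms), bonded element-pair keys and
three-atom-path keys — computed natively on the molecular graph. It is a
key set of this package: positions beyond the implemented families stay
zero, and the landscape statistics are by design pluggable in the
fingerprint.

The SAS map enumerates all n(n−1)/2 unordered pairs. Quadrants use strict
inequalities — cliff: sim > 0.9 and ΔpIC50 > 2; smooth: sim > 0.9,
Δ ≤ 2; nondescript: sim ≤ 0.9, Δ > 2; scaffold hop: both at or below.
(The descriptive prose around SAS maps in the literature sometimes
conflates the two right-hand quadrants; the package implements the
standard convention just stated.) SALI is Δ/(1 − sim); pairs with
identical fingerprints (sim = 1) have undefined SALI, are flagged
`duplicate_structure`, are excluded from SALI rankings, but still count as
cliffs when Δ > 2 — a potency conflict between indistinguishable
structures is the most extreme cliff there is. Consensus cliffs are the
set intersection of per-fingerprint cliff sets; generators are molecules
appearing in at least `min_count` cliff pairs, ranked by count with id as
tie-break.

At n = 1678 the full enumeration is ~1.4 M pairs and runs in minutes on
one CPU via matrix cross-products; no approximation is used.

## QSAR bench

Twelve one-vs-rest classifiers: decision tree, extra trees, random forest
(500 trees, mtry 3, Gini), depthwise gradient boosting (500 rounds,
learning rate 0.1, depth 3), histogram leaf-wise boosting (500 rounds, 31
leaves), default extreme gradient boosting (500 rounds), RBF SVM, a
single-hidden-layer perceptron (100 ReLU units trained by full-batch Adam,
300 iterations, seeded He initialisation — quasi-Newton training is
impractical at this width), logistic regression, 5-NN, naive Bayes and a
Gaussian process. Tree/ensemble seeds are fixed; every stochastic step
derives from the single `seed` argument.

Order of operations matters. The default `safe` mode splits first
(stratified 80:20), fits feature selection on the training portion only,
and oversamples inside each training fold, so no evaluation molecule is
ever duplicated into a fitting set. `published-parity` mode reproduces the
common published order — oversample everything to the majority class,
select features globally, then split — which leaks duplicated molecules
across the split and flatters test metrics; it is retained because
reproducing that pipeline faithfully is sometimes the point. Feature
selection removes columns with variance < 0.1, then scans left to right
dropping any later column correlated above 0.95 (phi coefficient for
binary columns) with a retained one — keeping the *earlier* column is the
deterministic reading of an otherwise unspecified rule.

Metrics come from the pooled 4-class confusion matrix: accuracy, macro
recall (absent classes contribute 0), and the multiclass R_K form of the
MCC, which reduces to the familiar binary formula for two classes.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the package's reference study conditions:
8 scaffold families × 40 members, family mean pIC50s
{8.7, 8.3, 7.6, 7.2, 6.6, 6.2, 5.4, 5.0} (sd 0.3) so all four classes are
populated with realistic imbalance, 30 duplicate rows, 10 value-blanked
and 10 censored-relation rows, and 10 planted cliffs at ΔpIC50 = 2.5,
seed 42.

Each family is built from a distinct ring-topology core (imidazolidine-
thione, carbazole, acridine, quinoline, indole, ether-linked biphenyl,
biphenyl, azepane) so families map one-to-one onto CSKs, decorated with a
constant four-ring amide/sulfonamide arm, with two variable positions
filled from a 10-substituent vocabulary (H, methyl, ethyl, F, Cl, nitrile,
hydroxyl, CF3, methoxy, amino). Planted cliffs swap a terminal fluorine
for chlorine at the end of a butyl tether: a one-atom change on a
drug-sized (~60 heavy atoms) molecule perturbs only a handful of circular
environments, so the pair's ECFP4 Tanimoto stays above the 0.9 cliff
threshold *by construction* (0.91–0.93 across the family templates,
measured when the templates were designed); their ΔpIC50 is set exactly,
not sampled, so cliff detection is a sharp pass/fail. Cliffs are planted
round-robin in the four largest-template families. IC50s are stored as
`10^(9 − pIC50)` nM, making the pIC50 round trip exact.

What the generator does **not** emulate: real assay noise models,
salt/tautomer standardization issues, pharmacologically meaningful
property distributions, scaffold overlap between families, or
activity-class structure that is independent of scaffold membership. A
passing synthetic suite therefore shows that the machinery is correct and
deterministic — filters remove exactly what was planted, scaffold and
cliff recovery are exact, models beat the majority baseline on learnable
structure. It does not show that any particular real dataset is modelable
or that the bench's metric values transfer to real targets.

## Numerical and engineering choices

* Batch SMILES/SDF conversions run through the OpenBabel command line in
  single invocations; the in-process bindings are used for fingerprints
  and SMARTS. Zero-bond molecules (e.g. methane) break the in-process SDF
  round trip, so their fingerprints come from the CLI's hex dump — a path
  verified bit-identical to the in-process one on bonded molecules.
* Canonical SMILES are the backend's stereo-free canonical form; all
  scaffold/R-group string comparisons happen in that one canonical space.
* Test and example problem sizes: module tests use 2–4 family synthetic
  sets (16–40 molecules); the end-to-end validation uses the full
  reference conditions (370 rows, 320 curated molecules, ~51k pairs per
  fingerprint) and a 3-ensemble bench subset, which keeps the whole suite
  in the low minutes on one CPU. The full 12-algorithm bench runs on a
  constructed separable fixture instead of the synthetic study, where its
  expected behaviour (near-perfect training accuracy for ensembles) is
  known a priori.

## Known limitations

* The PubChem-style fingerprint implements the key families, not the
  verbatim 881 PaDEL keys; bit-exact parity with PaDEL-derived models is
  out of scope, and a different key generator can be plugged in where
  parity matters.
* log P is an atomic-contribution estimate; absolute property values are
  backend-dependent even though group comparisons and PCA structure are
  not.
* R-group decomposition assumes the scaffold occurs once (up to symmetry)
  in each member; repeated-scaffold molecules would silently use the
  smallest mapping.
* The Mann–Whitney normal branch omits the continuity correction; for the
  group sizes where this matters the exact branch is used anyway.
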