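---
title: "Low-dimensional feature models for anticancer peptide classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-dimensional feature models for anticancer peptide classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpselect)
```

## The problem

Anticancer peptides (ACPs) are short peptides — typically five to thirty
residues — that interact with the anionic membrane components of cancer
cells and kill them selectively. Benchmarks for sequence-based ACP
prediction are small (a few hundred labeled peptides, usually imbalanced;
the classic layout is 138 positives against 206 negatives), while the
descriptor families used to encode peptides easily produce thousands of
features. Fitting classifiers in that regime invites the curse of
dimensionality: models that look good in-sample and transfer poorly.

`acpselect` implements the rank-then-incrementally-evaluate route to
low-dimensional models: encode with many descriptor families, order the
features once by a relevance-plus-diversity composite, trace the
cross-validated metric curve of the nested top-$m$ subsets, and read
compact models off that curve — the smallest F-score-maximizing dimension,
and the individual "slope point" features whose addition produced large
jumps.

## Descriptor families

All encoders take a peptide tibble (`id`, `sequence`) and return a tibble
with one column per feature; every feature name parses back to its
generating encoder via `resolve_feature()`. For a sequence of length $N$:

* **AAC / DPC / TPC** — frequencies of residues, adjacent pairs and
  adjacent triples, with denominators $N$, $N-1$, $N-2$ (20 / 400 / 8000
  features). Each vector sums to 1.
* **CKSAAP** — for each gap $k = 0..k_{max}$, the ordered pair $(a,b)$
  feature counts positions $i$ with $p_i = a$, $p_{i+k+1} = b$, divided by
  $N-k-1$; gap 0 is DPC. We use the $N-k-1$ denominator for every gap so
  each 400-feature gap block is itself a composition summing to 1,
  consistent with the $N-1$ denominator of the gap-0 block. Default
  $k_{max} = 5$ (2400 features); the named feature `GL.gap4` requires only
  $k_{max} \ge 4$, and `encode_selected()` raises the floor automatically.
* **GAAC / GDPC / GTPC / CKSAAGP** — the same computations after mapping
  residues to five physicochemical groups: aliphatic {G,A,V,L,M,I},
  aromatic {F,Y,W}, positive {K,R,H}, negative {D,E}, uncharged
  {S,T,C,P,N,Q}. This is the established five-way partition; it covers all
  twenty residues exactly once and gives GAAC dimension 5.
* **CT (conjoint triads)** — residues collapse to seven classes ({A,G,V},
  {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K}, {D,E}, {C}; the original
  conjoint-triad partition by side-chain dipole and volume), and the
  $N-2$ overlapping class triads are counted (343 features). Triads of
  class-equivalent residues (GLM, VFT) are deliberately indistinguishable.
  The default normalization is the plain frequency, count$/(N-2)$; a
  min–max variant ((count − min)/max) is selectable with
  `normalize = "minmax"` because both conventions circulate for this
  descriptor.
* **CTDC / CTDT / CTDD** — per-property composition, transition and
  distribution descriptors over three-group residue partitions. We
  implement the full 13-property set (seven hydrophobicity scales, normal
  van der Waals volume, polarity, polarizability, charge, secondary
  structure, solvent accessibility): the property names that appear in
  shipped feature names such as `polarizability.2.residue0` and
  `secondarystruct.1.residue0` only exist under this set, so the
  three-property subset sometimes described for this family would be too
  narrow. Distribution uses the first occurrence for `residue0` and the
  $\lceil q \cdot n_g \rceil$-th occurrence for quantiles
  $q \in \{0.25, 0.5, 0.75, 1\}$, as position$/N \times 100$. A group that
  never occurs gets all five descriptors set to 0 — the one convention
  that keeps the encoder total without inventing positions.
* **PAAC / APAAC** — amino acid composition augmented with $\lambda$
  sequence-order correlation factors built from the classic
  hydrophobicity, hydrophilicity and side-chain-mass scales, each
  standardized to zero mean and unit variance over the twenty residues
  (population variance, the classic pseudo-AAC normalization). Defaults
  $\lambda = 8$, $w = 0.05$: $\lambda = 8$ is the smallest value for which
  the order-tier feature `Pc2.Hydrophobicity.8` exists, and $w = 0.05$ is
  the customary weight. Both are configurable, and both limits
  $\lambda \to 0$ and $w \to 0$ reduce the composition part exactly to
  AAC (a property the tests assert).

Sequence validation is strict: residues outside the twenty-letter alphabet
are an error, never silently dropped, because every composition
denominator assumes all residues are counted. Whole records can be
excluded with `drop_invalid = TRUE`.

## Feature ranking

`rank_features()` scores feature $i$ as

$$\mathrm{score}_i = \left| r(x_i, y) \right| +
  \frac{1}{d-1} \sum_{j \ne i} \lVert u_i - u_j \rVert_2,$$

absolute Pearson correlation with the binary label (equal to the
point-biserial correlation) plus the mean Euclidean distance to the other
features. The distance is computed on columns that are z-scored and then
scaled to unit norm, so $\lVert u_i - u_j \rVert = \sqrt{2(1 - r_{ij})}
\in [0, 2]$. This scaling is a deliberate numerical choice: raw z-score
distances grow with $\sqrt{n}$ and would drown the correlation term, while
on the unit sphere both components are commensurate and the equal-weight
sum is meaningful. Zero-variance features get relevance 0 and a zero
vector (not an error), so rankings stay total on degenerate subsets. Ties
break by descending score then lexicographic feature name — deterministic
across platforms. Alternative scorers are pluggable (`anova_f` relevance,
mapped to the correlation scale $\sqrt{F/(F+n-2)}$; `cosine` and
`tanimoto` distances) and the scorer used is recorded on the result.

The exact internals of the ranking tool this procedure emulates are not
published; what `acpselect` guarantees is the *procedure* — rank once,
evaluate nested prefixes, read subsets off the curve — with a fully
specified, reproducible composite score.

## Incremental curves and subset extraction

`incremental_curve()` fixes one stratified fold assignment from the seed
and evaluates the top-1 through top-$d$ ranked subsets with the same
folds. Consequences worth knowing:

* the curve point at $m = d$ is identical to a direct `cross_validate()`
  with the same seed (asserted in the tests), because fitted classifiers
  canonicalize feature-column order internally;
* the whole curve is bit-identical under a fixed seed.

`select_best()` returns the smallest F-score-maximizing dimension (ties to
the smaller dimension — with equal scores, prefer fewer features).
`knee_points()` returns the features at dimensions where the F-score gain
over the previous dimension exceeds `min_gain`, with $F(0) = 0$, so the
first feature counts as a slope point whenever it alone yields more than
`min_gain`. The separation threshold for slope points is not a canonical
number; the default `min_gain = 0.01` (absolute F-score) is configurable
and recorded on the output. `iterate_reduction()` loops rank → curve →
best-subset on the survivors until the dimension stops shrinking (cap
`max_iter = 10`): each round re-ranks within the reduced set, which is how
a merged many-encoder table is squeezed to a compact model in several
rounds. `greedy_select()` implements sequential forward selection by CV
F-score as the comparison method; forward-by-F-score is one reasonable
reading of "greedy" here, and it is documented as an assumption, not a
reproduction of any specific tool.

## Evaluation protocol

`cross_validate()` uses seeded stratified folds (per-class shuffle dealt
round-robin) and the **pooled** protocol: out-of-fold predictions from all
folds are pooled into one confusion table and Sn, Sp, Acc, MCC and F-score
are computed once. Pooling reproduces the single headline numbers that ACP
tools report; per-fold metrics are kept in `tidy()` for dispersion
diagnostics. Degenerate denominators follow total conventions — MCC 0 when
its denominator vanishes, F-score 0 when precision + recall is 0 — so
selection curves are defined even on useless subsets.

The F-score is the positive-class F1 by default. Published ACP tables
sometimes show F ≈ Acc, a pattern more consistent with a support-weighted
two-class average; `fscore = "weighted"` computes that variant. Neither
convention is asserted as "the" published one.

Classifiers: a seeded 100-tree probability forest (`ranger`, single
thread) on raw features; an RBF-SVM (libSVM via `e1071`) on features
standardized with training-fold means and standard deviations;
`grid_search_svm()` searches the customary powers-of-two grid
($c \in 2^{-5}..2^{15}$, $g \in 2^{-15}..2^{3}$, step $2^2$), maximizing
pooled CV accuracy with ties to smaller $c$ then smaller $g$ — the grid
contains the classic ACP operating point $c = 2^{13} = 8192$,
$g = 2^{-11} \approx 4.88 \times 10^{-4}$. A majority-vote ensemble over a
configurable member list is provided as a simple selective-ensemble
stand-in; it is labeled as a plain majority vote in all outputs, and an
even-member tie resolves to the negative class (a strict majority is
required to call a peptide anticancer). `train_final()` + `save_model()` /
`load_model()` bundle model, feature manifest, standardization parameters,
spec and seed; predictions are asserted identical across the round trip.

## The synthetic generator

`simulate_peptides()` emulates the benchmark's shape, not its biology:
lengths uniform on 5–30 (the typical ACP length range), class sizes
defaulting to the 138:206 imbalance, residues sampled independently.
Negatives are uniform over the twenty residues; positives draw from

$$p_r = \frac{1/20 + b\,[r \in T]/|T|}{1 + b}$$

with tilt set $T$ (default {K, R, L, G, C} — the residues whose
composition and content are the classic ACP indicators) and bias $b$. At
$b = 0$ the classes are exchangeable by construction; at $b = 2$ three
quarters of positive-class residue mass sits on the tilt set, a strong but
not trivial signal. An optional motif mode plants a gapped residue pair
(default G…L at gap 4) at a random position in each positive, the one
positional signal — needed to exercise the k-spaced pair encoders, which
composition bias alone cannot.

What the generator does **not** emulate: real amino-acid background
frequencies, positional and autocorrelation structure, shared evolutionary
ancestry or sequence redundancy (no CD-HIT-like similarity structure), and
any genuine physicochemistry of membrane activity. Passing
selection-recovery tests on this generator therefore demonstrates that the
pipeline recovers *planted composition signal under benchmark-shaped
imbalance* — it does not certify real-data accuracy, which depends on an
external benchmark.

`planted_truth()` returns the ground-truth informative feature names (the
AAC features of the tilt residues, plus the motif pair feature when
planted), and `add_noise_features()` appends iid standard-normal
distractor columns — the controlled setting for selection-recovery
experiments, where encoder-derived columns would themselves carry
composition signal.

## Problem sizes and numerical choices

The test suite and examples run at deliberately moderate sizes chosen as
realistic for this problem class: selection recovery at $n = 344$
(138:206) with bias 2 and 5 planted features among 100 noise distractors,
evaluated with 5-fold CV and 100-tree forests over 10 generator seeds;
null calibration at $n = 200$ balanced with 10-fold CV over 20 seeds
(balanced, so the majority-class rate 0.5 is the exact null target for a
label-independent feature set); the end-to-end example at $n = 200$ with
three encoder families. Seeds are explicit arguments everywhere
randomness enters (generator, fold assignment, forest), and every pipeline
stage is asserted bit-identical under a fixed seed.

Other numerical conventions, collected: CKSAAP denominator $N-k-1$ per
gap; CT frequency normalization by default; CTDD zero-fill for absent
groups; pseudo-AAC scales standardized with population variance;
zero-variance relevance 0; MCC/F degenerate-denominator zeros; all
tie-breaks lexicographic after score.

## Known limitations

* The composite ranking is a faithful, documented max-relevance–
  max-distance score, but no claim is made that it reproduces any specific
  tool's internal ranking values; intermediate dimensions of iterated
  reduction depend on those internals and on the data.
* The greedy baseline is forward selection only; no backward elimination
  or stochastic wrappers.
* The majority-vote ensemble is not a clustering-based selective ensemble;
  it is a deliberately simple reference point.
* Encoder length preconditions are hard errors by default (DPC $N \ge 2$,
  TPC/CT $N \ge 3$, CKSAAP $N \ge k_{max}+2$, PAAC/APAAC
  $N \ge \lambda+1$); dataset-level encoding offers explicit record
  dropping, never silent residue skipping.
* Real-benchmark headline numbers require the external benchmark FASTA
  files; nothing in the package downloads data.
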