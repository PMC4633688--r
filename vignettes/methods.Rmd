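---
title: "Two-stage NMF-based feature selection for ordinal symptom data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage NMF-based feature selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical questionnaire studies of hepatocellular carcinoma (HCC) staging
record, for each patient, dozens of symptoms coded as nonnegative
integers — binary presence/absence or ordinal severities in 0..3, where 0
means "not positive" — together with a clinical stage label (three
phases, each with A/B substages). Such symptom sets are assembled by
clinicians for coverage, not parsimony: some items are almost never
positive in any stage (irrelevant to stratification), and some groups of
items measure nearly the same clinical phenomenon (redundant). Both kinds
inflate the feature space and degrade downstream classifiers.

`nmfselect` implements a two-stage *filter* feature-selection procedure
for such sample-by-symptom matrices:

1. **Irrelevance screening.** For each symptom and each clinical stratum,
   compute the positive frequency (fraction of the stratum's patients
   with a value > 0). A symptom whose frequency is strictly below a
   threshold (default 10%) in *every* stratum is removed.
2. **Redundancy compression.** Factorize a class- and sex-balanced
   representative subsample by Kullback–Leibler nonnegative matrix
   factorization, X ≈ WH with W ≥ 0 (symptoms × rank) and H ≥ 0
   (rank × samples). Because x_i ≈ w_i H, symptoms whose basis rows w_i
   are simultaneously *close* (distance) and *proportional*
   (correlation) have near-identical profiles over the whole sample
   space. Pairs clearing a threshold θ on both similarities within one
   basis are linked; connected components of size ≥ 2 form redundant
   groups, and each group is replaced by a single *mixed feature*.

The selected subset (kept originals + mixed features) is scored with a
least-squares SVM (RBF kernel, one-vs-rest, grid-searched σ² and γ under
stratified 5-fold cross-validation).

## Models and statistics

**KL-NMF.** The loss is the generalized Kullback–Leibler divergence
D(X‖WH) = Σ X log(X/WH) − X + WH with 0·log 0 = 0, minimized by the
Lee–Seung multiplicative updates, which provably never increase the
objective. Optional penalties R(W, H) = λ_w·F1 + λ_h·F2 are available:
F1(W) = ½ Σ (W_ij − c)² (Tikhonov smoothing toward a constant c) and
F2(H) = ½ Σ_rows (‖h‖₂² − α²‖h‖₁²) (a sparsity-shaping term). No update
rules or values for c, α or the λ's are prescribed for these penalties,
so the defaults are λ_w = λ_h = 0 (plain Lee–Seung, for which every
monotonicity guarantee holds) and, when enabled, the penalties enter as
gradient-derived multiplicative corrections with entries floored at
1e-12 — documented as a heuristic. Two quirks of the F2 form are worth
noting: it is summed over *rows* of H (deliberately, although ".j"
notation usually denotes columns), and for α > 1 it rewards rather than
penalizes L1 mass; sensible α lie in [0, 1].

**Initialization and stopping.** W and H start i.i.d. uniform(0, 1],
jointly rescaled so mean(WH) = mean(X); iteration stops when the relative
objective change drops below `tol` (default 1e-6) or at `max_iter`
(default 2000). Everything is seeded; a fit is a pure function of
(X, config).

**Rank selection.** For each rank in 2..7 the factorization is restarted
(default 30 times); samples are clustered by the argmax of their H
column, the run-averaged connectivity matrix is the consensus, and its
cophenetic correlation (average-linkage, against 1 − consensus) measures
stability. The chosen rank is the smallest r whose cophenetic value
decreases at r + 1; the residual-sum-of-squares curve's inflection
(first sign change of the discrete second difference) is computed as a
second opinion. When the cophenetic rule is inconclusive the RSS rule
decides, and when both are inconclusive the survey falls back to the
cophenetic maximum, flagged as such. Ties in argmax assignments break to
the smallest index; constant dissimilarity is defined as cophenetic 1;
negative cophenetic correlations are clipped to 0.

**Similarity of basis rows.** With d²(i, j) the squared Euclidean
distance between rows of W and MaxD its maximum over all pairs,
sim_dist = 1 − d²/MaxD, and sim_corr is row-wise Pearson correlation
(each row centered by its own mean; a shared grand mean would not be
standard Pearson and is not offered). The combined SMX is their
arithmetic mean. The default grouping rule is the dual condition
sim_dist ≥ θ AND sim_corr ≥ θ (this is what the reported experiments
used); thresholding SMX > θ is available as an option. Edges are
restricted to features sharing a dominant basis (argmax of the W row) by
default. Groups are connected components — the weakest assumption
consistent with "screening redundant features by groups"; no clique or
centroid condition is imposed.

**Mixed features.** A group is replaced either by the elementwise mean
of its member columns (default — deterministic and reproducible) or by a
uniformly chosen member (the chosen member is recorded so the feature can
be recomputed exactly on held-out data). Ids follow the `M<basis><ordinal>`
scheme. The stated procedure is ambiguous about which strategy was used
(the prose points at the random-member formula while the numbering
points at the mean); the mean is the default here.

**LS-SVM.** Binary machines solve the standard Suykens dual system
`[[0, yᵀ], [y, Ω + I/γ]]·[b; α] = [0; 1]` with Ω_ij = y_i y_j K(x_i, x_j)
and K(x, y) = exp(−‖x−y‖²/σ²); decision value f(x) = Σ α_i y_i K(x_i, x) + b.
One system per class (one-vs-rest), prediction by argmax with ties to
the smallest class. Among multiclass schemes, one-vs-rest is the
simplest argmax-consistent choice and is the one implemented
(one-vs-one is not). The grid uses σ² = 10^a, γ = 10^b with 24 a-levels
from −1 in steps of 0.25 and 25 b-levels from −1 in steps of 0.2 (600
pairs); the nominal ranges a ∈ [−1, 5], b ∈ [−1, 4] would give one extra
level each, so the default grid drops the final endpoint of each range
to keep the 600-pair bookkeeping, and the full-endpoint grid is
available via `default_grid(full = TRUE)`. CV folds are stratified by
class — a design choice for stability of small classes — and dealt
deterministically from a seed.

## Screening granularity

The screening rule is applied per coarse clinical stage (three strata) by
default: the rule is about rarity "in each clinical stage", and substage
strata can be as small as 19 patients, where a 10% frequency estimate has
a standard error near 7% — screening there flags symptoms by sampling
noise. `positive_frequencies()` computes either granularity, so
substage-level frequency tables (the layout clinicians usually inspect)
remain available.

## Representative sampling

The balanced subsample ("120 representatives, 40 per stage, 20:20 by
sex") is obtained by ranking each (stage, sex) cell's samples by
Euclidean distance to their *stage centroid* (the mean symptom vector of
the stage) and taking the closest. An equivalent framing queries a KNN
model built on the labeled cohort with large K at each class centroid;
centroid-distance ranking implements that directly, is deterministic
(distance ties break by sample id), and leaves no free K parameter.

## The synthetic world

No patient-level data is distributed, so every experiment runs on a
generator with planted ground truth. Its defaults state one fixed world
emulating the reference cohort's composition:

* 407 patients in stages 82/195/130; substage-A fractions and male
  fractions chosen so the rounded counts reproduce the tabulated
  composition exactly (45/37, 60/135, 111/19 substages; 60/165/105
  males).
* 57 symptoms: 33 standalone informative, 16 redundant in 6 groups of
  sizes 3, 2, 2, 5, 2, 2 (each group one source pattern plus copies,
  two groups per stage), and 8 irrelevant.
* Informative patterns: each has an affinity stage; its peak positive
  probability is log-uniform in [0.2, 0.85] (low-frequency symptoms as
  common as high-frequency ones — questionnaire cohorts of this kind
  show positive frequencies from ~3% to >50%), off-stage probabilities
  a U(0, 0.8) fraction of the
  peak; 40% of symptoms binary, the rest ordinal 0..3 with
  truncated-geometric severities (decay 0.5).
* Irrelevant symptoms: per-stage positive probability U(0.01, 0.05) —
  strictly below threshold − margin, mirroring the screening margin the
  recovery experiments assume.
* Patient burden: a log-normal (σ = 0.4) per-patient factor enters each
  symptom's positivity as an exposure multiplier with a per-symptom
  loading exponent U(0.3, 1.7). Without it the matrix is exactly rank 3
  in expectation (conditional independence given stage), a degenerate
  geometry no real questionnaire exhibits.
* Redundant copies: each entry of a copy is perturbed one severity level
  up or down with probability ε = 0.02, clipped to the valid range.
* Identifiability margin: distinct same-stage patterns are rejection
  sampled so that any two differ in expected-profile correlation
  (≤ 0.93) or squared distance (≥ 7% of the maximal pairwise distance).
  Without such a margin "planted redundancy" is ill-defined — see below.

What a green test on this world does establish: the pipeline's stages
compute their stated quantities, planted irrelevance is recovered at the
stated margins, planted copies are always grouped together (pairwise
recall ≈ 1), and rank selection recovers planted block structure. What it
does not establish: performance on real questionnaire data, whose
dependence structure, missingness handling and symptom semantics the
generator does not model.

## Identifiability limits of the redundancy measure

A structural property of the method matters for interpreting results at
the reference settings (rank 3, θ = 0.95, dual rule): basis rows are
r-vectors, and for r = 3 their centered (Pearson) geometry lives on a
circle, where at most ~360°/18° ≈ 20 directions are pairwise below a 0.95
correlation — and fitted KL-NMF solutions are sparse and near-axis, which
collapses within-basis correlations to ≈ 1 regardless of profile
differences (confirmed against an independent multiplicative-update
implementation, which finds the same optima). The dual rule then reduces
to the MaxD-normalized distance, whose θ = 0.95 ball has radius
≈ 0.32 × (largest row norm): only ~2–3 distinguishable magnitude levels
per basis. With ~16 same-basis symptoms, false links are therefore
unavoidable, and connected components merge them transitively. In the
test suite this appears as an honestly failing acceptance criterion on
the 57-symptom preset (pairwise grouping precision ~0.15 at rank 3,
against a 0.9 bar) and a passing one on a minimal identifiable fixture
(one base feature plus one copy-group per basis at a 6:1 magnitude
ratio). The same defect propagates to the subset-vs-full-set accuracy
comparison: over-merged groups average away ~30 of 49 features, and the
compressed subset scores slightly below the full set — the same
direction of effect that aggressive grouping (lower θ) produces when
grouping becomes aggressive. Practical advice for users: on data with
more than a handful of features per basis, inspect group sizes, raise θ
toward 1, or use the SMX rule with a stricter threshold before trusting
the compression.

## Numerical choices and degenerate inputs

* Multiplicative updates floor every factor entry at 1e-12 (entries at
  exactly zero cannot revive under multiplicative updates).
* `kl_divergence` returns `Inf` when the fit is zero where data is
  positive; `factorize` rejects all-zero matrices and non-finite
  objectives (with the iteration index).
* `sim_dist_matrix` refuses geometry where all rows coincide
  (MaxD = 0); constant rows make Pearson correlation undefined — they
  are flagged, warned about and excluded from grouping.
* Distance and argmax ties break deterministically (sample id order,
  smallest index).
* The LS-SVM solve reports a condition estimate when the KKT system is
  singular.
* All randomness is scoped: library calls never disturb the caller's
  RNG state, and one master seed derives per-stage seeds by fixed
  offsets so pipeline stages can be re-run independently.

## Runtime scaling in the test suite

The acceptance experiments state 30 restarts per rank over ranks 2..7 and
ten replicate seeds; to keep the suite inside its budget the *inner NMF
iteration caps* are reduced there (max_iter 300, tol 1e-4) — consensus
cluster assignments stabilize long before tight objective convergence —
and the LS-SVM validation grid in the end-to-end experiments uses integer
exponents. World parameters, thresholds, seed counts and pass bars are
never scaled.

## Known limitations

* Missing values are rejected, not imputed (the target data has none).
* The regularized update rules are heuristic (see above); guarantees are
  asserted only for λ = 0.
* One-vs-one multiclass, probabilistic outputs and sparse LS-SVM
  variants are out of scope, as are reimplementations of ReliefF, mRMR
  and Elastic Net baselines.
* The redundancy measure's capacity limits at small rank are inherent to
  thresholding basis-row similarities; see "Identifiability limits".
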