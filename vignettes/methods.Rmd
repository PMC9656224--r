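---
title: "Graph-theoretic EEG connectivity and peripheral-signal fusion for emotion recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`emograph` implements a multimodal pipeline for binary classification of
emotional *valence* (pleasantness) and *arousal* (intensity) from
physiological recordings. The data model mirrors the common affective-
computing protocol: each subject watches a set of one-minute stimuli
(trials), EEG and up to eight peripheral channels (EOG, EMG, galvanic skin
response, respiration, plethysmograph, temperature) are recorded at a
common rate (128 Hz after resampling, in the datasets this layout
emulates), and the subject self-reports valence and arousal on a
continuous 1–9 scale. Ratings are dichotomized at 4.5 — `low` for ratings
$\le 4.5$, `high` above — at labelling time, so raw and binary labels both
remain available.

Analysis is windowed: 4 s windows advanced in 2 s steps, each window
inheriting its trial's ratings. A trailing remainder shorter than one
window is discarded, so a trial of $T$ seconds yields
$\lfloor (T-4)/2 \rfloor + 1$ windows.

Per window, two feature blocks are extracted and fused by concatenation:

1. **Peripheral statistics** — 12 time-domain descriptors per peripheral
   channel (mean, population variance and standard deviation, max, min,
   skewness, excess kurtosis, 25/50/75 % quantiles, zero-crossing rate of
   the mean-centred signal, approximate entropy). Eight channels give 96
   features.
2. **EEG graph measures** — pairwise mutual information between all EEG
   electrode pairs forms a complete weighted functional-connectivity
   graph per window; five global measures (characteristic path length,
   global efficiency, transitivity, modularity, density) and four
   node-level measures (clustering coefficient, local efficiency,
   betweenness centrality, degree centrality) are computed from it. With
   the 14-channel wearable-headset montage this yields $5 + 4\cdot14 = 61$
   features (157 fused); with a 32-channel research montage,
   $5 + 4\cdot32 = 133$ (229 fused).

A genetic-algorithm wrapper can select a feature subset using classifier
accuracy as fitness, and four classifiers are available: linear SVM,
random forest, gradient boosting, and a small 1-D CNN. Evaluation follows
two protocols: *subject-dependent* (per-subject stratified 85/15 split)
and *subject-independent* (leave-one-subject-out cross-validation, LOOCV).

### A note on feature-count arithmetic

The study this design follows lists local measures for 32 electrodes
(giving $96 + 5 + 128 = 229$ features) while stating that only the 14
wearable-montage channels were used (giving 157), and prints a total of
224. The package takes no side: the graph-block length is determined by
the channel selection actually applied (`5 + 4n`), and both montages are
exercised in the tests.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `window_s`, `step_s` | 4 s, 2 s | stated analysis windowing |
| EEG subset | the Emotiv 14 | stated montage; overridable |
| MI `bins` | 8 | equal-width histogram plug-in; see below |
| ApEn `m`, `r` | 2, 0.2·sd | field-standard regularity settings |
| GA | 200 gen, pop 100, 10 parents, pool 4, 3 mutations | stated parameter block |
| `fitness_split` | 0.15 | mirrors the 85/15 protocol split |
| `fitness_reps` | 1 | see "GA fitness granularity" |
| CNN | filters 32/64/128, kernel 3, pool 2, dense 64, Adam 1e-3, BCE | stated 3-block shape; widths conventional |
| SVM / RF / XGB | linear, C-like λ=1e-4 / 500 trees / 100 rounds, depth 3, η=0.1 | no hyperparameters are stated; conventional defaults |

## Numerical and estimator choices

**Mutual information.** No estimator variant, bin rule or logarithm base
is stated for the connectivity step. The package uses the equal-width
joint-histogram plug-in estimator in bits with 8 bins per variable over
each signal's $[\min,\max]$ — deterministic, adequate for 512-sample
windows, and invariant under affine rescaling of either input (edges
scale with the data). Degenerate (constant) inputs have zero-entropy
marginals and return 0. The estimate is clipped at 0 against round-off.
No thresholding, binarization or normalization is applied to the
adjacency matrix: all downstream measures use weighted formulas on the
complete graph.

**Weight-to-length mapping.** Path-based measures traverse an edge of
weight $w$ at length $1/w$, the standard brain-connectivity convention
(stronger coupling = shorter path); zero weight means no edge.
Betweenness is normalized by $(n-1)(n-2)$ (ordered pairs excluding the
node) so values are comparable across montage sizes. Degree centrality is
node strength $s_i=\sum_j w_{ij}$: on a complete weighted graph a literal
edge count is the constant $n-1$ and carries no information. Clustering
and transitivity use the Onnela geometric-mean triangle intensity on
max-normalized weights, which reduces exactly to the classical binary
coefficients on 0/1 graphs. Density follows the literal stated definition
— the *sum of all weights* — not the edge-fraction density of binary
graph theory.

**Modularity.** Newman's weighted modularity is maximized by a
deterministic greedy agglomeration (merge the community pair with the
best gain until none is positive) followed by single-node local-moving
refinement. The single-community partition ($Q=0$) is always a candidate,
so the result is nonnegative; determinism makes feature extraction
reproducible without seed bookkeeping. On exhaustive partition search
over graphs of up to 8 nodes the detector stays within 0.05 of the
optimum (usually equal) in the test suite.

**Approximate entropy.** $\mathrm{ApEn}(m,r)=\Phi_m(r)-\Phi_{m+1}(r)$
with self-matches included, computed in compiled code and checked to
1e-12 against an independent $O(N^2)$ definition-level implementation.
Constant signals return 0 by convention. A strictly periodic alternating
signal is *almost* 0: the finite template counts at $m{=}2$ (50/49
occurrences of the two template types) leave an edge effect of order
$10^{-5}$, which both implementation and oracle reproduce.

**ZCR.** Computed on the mean-centred signal (temperature-like channels
carry DC offsets that would otherwise pin ZCR at 0); exact zeros after
centring inherit the previous nonzero sign, so grazing the mean is not a
crossing.

**Moments.** Population (divide-by-$N$) variance and standard deviation,
excess kurtosis, and type-7 (linear-interpolation) quantiles. At the
512-sample windows the pipeline uses, the sample/population difference is
immaterial; the convention is simply fixed. The listed "25/50/75 %
quantile range" features are read as the three quantile values
themselves: an inter-quantile range would collapse three listed features
into fewer than three numbers.

## Learners

No machine-learning library is assumed: all four classifiers are
implemented in the package and are deterministic given their seed.

* **SVM** — linear soft-margin, primal hinge loss with $L_2$ penalty,
  full-batch subgradient descent on standardized inputs (statistics
  fitted on training rows only). A linear rather than RBF machine is a
  deliberate narrowing: no kernel-SVM solver is available in the target
  environment, the fused features are near-linearly separable in the
  planted-effect regime, and a deterministic primal solver keeps GA
  fitness evaluation cheap and exactly reproducible.
* **Random forest** — probability forest of CART trees grown in C++
  (variance-reduction splits, which are proportional to Gini reduction
  for 0/1 responses), bootstrap + $\sqrt{p}$ feature subsampling,
  averaged votes.
* **Gradient boosting** — logistic-loss boosting of depth-3 trees with
  Newton leaf values and shrinkage 0.1, the conventional XGBoost-style
  configuration.
* **1-D CNN** — exactly three conv(ReLU)+max-pool blocks (filters
  32/64/128, kernel 3, pool 2), dense-64 head, sigmoid output, binary
  cross-entropy, Adam; the feature vector is treated as a length-$p$
  sequence with one channel. Implemented with explicit
  im2col/col2im matrix algebra; seeded init and shuffling make training
  bit-reproducible.

## GA fitness granularity

The stated GA design scores a chromosome by classifier accuracy on a
single inner 85/15 stratified split. A single 15 % split of a few hundred
windows resolves accuracy only to ~1/45, which is far coarser than the
per-feature differences wrapper selection must detect; fitness then
saturates and the elite chromosome is whichever early mask got lucky.
`GAConfig$fitness_reps` (default 1, the literal design) lets the fitness
average over several independently drawn inner splits; the selection
benchmark in the test suite uses 3. The inner split(s) are drawn once per
run, so every chromosome faces identical data and the search is exactly
reproducible; elitism carries the best chromosome forward, making the
best-fitness trace provably non-decreasing.

## What the synthetic generator emulates — and what it does not

`generator_spec()` produces datasets with the emulated shape (subjects ×
trials × channels × samples at 128 Hz, one-minute trials, ratings in
1–9) and *planted, class-dependent structure*:

* a designated EEG channel subset (default 4 channels) shares a latent
  band-limited oscillation whose mixing weight is 0.1 for low-class
  trials and 0.1 + `coupling_effect` (default 0.8 total) for high-class
  trials, so MI connectivity — and hence the graph features — separates
  the classes with controllable effect size;
* peripheral channels are AR(1) noise whose mean shifts by
  `peripheral_effect` (default 2) standard deviations between classes,
  with a mild class-dependent scale change, so the windowed statistics
  are informative;
* ratings are drawn uniformly from [1, 4] (low) or [5, 9] (high),
  exercising the 4.5 cut unambiguously;
* `mechanism_mode = "shared"` uses identical effect directions for all
  subjects (cross-subject transfer learnable); `"idiosyncratic"`
  randomizes directions per subject, reproducing qualitatively the
  observation that subject-independent models underperform
  subject-dependent ones.

Latent sources are sums of random-phase sinusoids rather than white
noise, so MI estimation operates on autocorrelated signals as it would on
real EEG. The generator does **not** attempt realistic EEG spectra,
volume conduction, artifacts, non-stationarity, or genuine physiology in
the peripheral channels. A green pipeline test therefore establishes that
the estimators, graph measures, selection and protocols are implemented
correctly and can recover planted structure — not that the method attains
any particular accuracy on real recordings, which live behind gated
access and are out of scope here.

Test fixtures scale the generator down (shorter trials, 64 Hz, fewer
trials) purely for runtime; effect sizes and all estimator settings are
the defaults above.

## Degenerate inputs and error policy

Trials shorter than one window, unknown channel labels, out-of-range
ratings, malformed recording files, non-finite features, and single-class
training sets all raise errors naming the offending unit; they are never
silently skipped. The one deliberate exception: in the subject-dependent
protocol a subject whose windows carry a single class is excluded *with a
warning*, since other subjects' reports remain valid. All-zero GA
chromosomes are repaired by activating one random gene. Disconnected
graphs are an error for characteristic path length (undefined) but valid
for global efficiency ($1/\infty = 0$).

## Known limitations

* The subject-dependent split is, by default, at window level: windows of
  one trial can land on both sides, which is optimistic when windows
  overlap. The literal protocol is the default; `group_by_trial = TRUE`
  provides the conservative variant.
* Whether the original GA consumed the final test split or an inner split
  is unstated; the leak-free inner-split reading is implemented.
* The gated source dataset's own preprocessing (artifact removal,
  band-pass) is out of scope; the loader consumes preprocessed arrays.
* The linear SVM substitutes for an unspecified (possibly kernel) SVM;
  RF/XGB/CNN hyperparameters are conventional defaults, not reproduced
  settings.
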