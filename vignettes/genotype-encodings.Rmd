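---
title: "Genotype encodings for genomic prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype encodings for genomic prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(encodeGP)
```

## The problem

Genomic prediction regresses a quantitative trait on thousands of biallelic
SNP genotypes at once.  Each genotype is a three-level categorical variable
— major-allele homozygote, heterozygote, minor-allele homozygote — that must
be turned into a number before any regression can run.  The near-universal
choice is the *ordinal* coding 0/1/2 (minor-allele dosage), which treats the
categories as equally spaced and codes every marker identically.  `encodeGP`
treats the coding itself as a modeling decision: it implements a family of
*trait-aware* encodings, the machinery to fit them without test-set leakage,
an rrBLUP predictor, and diagnostics that probe *why* one encoding
out-predicts another.

## The encodings

Write `E(i, g)` for the encoded value of category `g ∈ {0, 1, 2}` at marker
`i`, and `Ave(trait | i, g)` for the mean training trait among samples with
category `g` at marker `i`.

* **Ordinal**: `E(i, ·) = (0, 1, 2)` (or `(-1, 0, 1)`), identical at every
  marker.  Order-preserving, but blind to the data.
* **Ordinal flipped**: ordinal, with categories 0 and 2 swapped at any
  marker whose training correlation with the trait is negative, so all
  features point the same way.
* **Target-based**: `E(i, g) = Ave(trait | i, g)` — classic target encoding
  of a categorical feature.  Fully flexible per marker, but the heterozygote
  value may fall outside the two homozygote values, scrambling the category
  order.
* **Hybrid one**: homozygotes target-encoded; heterozygote set to the
  overall training-trait mean.
* **Hybrid two**: homozygotes target-encoded; heterozygote set to the
  midpoint `(E(i,0) + E(i,2))/2`.

A category never seen in training falls back to the overall training mean
(the no-information value); hybrid two takes its midpoint after that
substitution, so its order guarantee survives sparse data.  Monomorphic
markers collapse to a constant column under every trait-aware scheme.
Missing genotypes are imputed at transform time with the marker's mean
encoded value over the training rows, so downstream predictors never see
`NA`.

### What is, and is not, guaranteed about category order

Hybrid two's heterozygote is between the homozygote values *by
construction*, exactly, always.  Hybrid one's heterozygote — the overall
mean — is a weighted mean of the *three* per-category means, so it is
guaranteed to lie within their range, but **not** within the narrower
interval `[E(i,0), E(i,2)]`: whenever the raw heterozygote category mean
falls outside that interval (which happens routinely at weak-signal markers
— among three noisy means, the middle-labeled one lands outside the other
two with probability 2/3), the overall mean can be dragged outside too.  In
simulation roughly a third of polymorphic markers violate the strict
interval for hybrid one, at every dominance level we generate.  The package
therefore asserts the strict order property only for hybrid two and the
range property for hybrid one; claims that hybrid one preserves category
order unconditionally should be read as holding only when the heterozygote
mean is itself order-consistent.

### Pairwise epistasis grids

For a marker pair, the nine genotype combinations form a 3×3 grid.  Both
hybrid grids put the mean trait of each double-homozygote cell at the four
corners.  Hybrid one fills an edge cell (e.g. heterozygous at `i`, 0 at `j`)
with the marginal mean over the fixed category, and the center with the
overall mean.  Hybrid two fills each edge with the mean of its two adjacent
corners and the center with the mean of the four edges, which keeps every
synthesized cell inside the range of its neighbours.  (A published variant
of these formulas wraps the corner averages in a further trait-average,
which is not well-formed — an encoded value appears where a genotype
category belongs; we use the direct arithmetic means, consistent with the
single-marker midpoint rule.)  Product features `X_i * X_j` of any encoded
matrix are available as the classical alternative, and pair selection (all
pairs under a cap, an explicit list, or all pairs among the `t` markers most
correlated with the trait, default `t = 50`) is re-run inside each training
fold.

## The predictor

rrBLUP fits `y = 1·b0 + X·b + e` with `b ~ N(0, σβ² I)`,
`e ~ N(0, σe² I)`.  The marker effects are the ridge solution with penalty
`λ = σe²/σβ²` (unscaled convention: `RSS + λ‖b‖²`; a `1/(2l)` factor in
front of the loss only reparametrizes `λ`).  The variance components are
estimated by REML: after absorbing the intercept by centering, the kernel
`XcXc'` is eigendecomposed **once**; the restricted log-likelihood is then a
scalar function of `λ`, minimized by a bounded search over
`log10(λ) ∈ [-8, 8]` at relative tolerance `1e-6`.  Hitting either bound
sets a `boundary` flag (a noiseless trait drives `λ` to the lower bound, as
it should).  A closed-form `ridge_solve()` provides the independent oracle:
BLUP effects at the estimated `λ` agree with it to below `1e-8` in the test
suite.  The ε-SVR predictor (sigmoid kernel by default, `C = 1`,
`ε = 0.1`, `γ = 1/m`; none of these were prescribed, so they follow the
common library defaults) standardizes features on the training fold and
delegates the quadratic program to `e1071::svm`.

## Leakage-safe evaluation

Trait-aware encodings are fitted *per training fold* and applied unchanged
to the held-out fold, as is the allele-orientation decision (swap categories
so that "2" counts the minor allele, judged on training rows only, ties at
frequency 0.5 keep the input orientation).  `cross_validate()` shares one
fold assignment (seeded shuffle, then contiguous blocks differing by at most
one sample) across all requested encodings so method contrasts are not fold
noise, and reports the arithmetic mean of per-fold squared Pearson
correlations, the field's standard accuracy metric.  The test suite asserts
bitwise that perturbing held-out trait values changes no prediction.

## Diagnostics

Two summaries probe an encoding's quality independently of any predictor.

*Top-k absolute correlation* (default k = 100): mean `|r|` of the k encoded
markers most correlated with the trait.  Higher means individually more
informative features.  Because `|r|` is invariant to per-marker affine maps
and hybrid two's column is affine in the ordinal column
(`E(g) = E0 + g·(E2-E0)/2`), hybrid two scores *identically* to ordinal
here; only target and hybrid one can genuinely differ.

*Within-group distance*: samples are discretized into low/mid/high trait
groups by the trait z-score thresholded at ±1; encoded columns are
standardized to z-scores; all pairwise Euclidean distances between samples
sharing a group are pooled over the three groups and averaged.  Encodings
that keep same-trait samples close should predict better.  Population
(divide-by-n) moments are used in both standardizations, and pairs are
pooled across groups rather than averaged per group.  Two printed variants
of these formulas divide by `δ²` or square the deviation; both would break
the affine invariance that makes scales comparable across encodings, so the
standard z-score is used for both.  The same affine argument as above makes
hybrid two's distance *exactly* equal ordinal's — which the tests assert —
so this diagnostic separates order-breaking (target) from order-keeping
encodings but cannot separate hybrid two from ordinal.  Which direction the
target-vs-hybrid gap takes is architecture-dependent: with the standard
z-score, a rare category with an extreme target encoding becomes an outlier
that *compresses* the common categories after variance normalization, and
target's distance can come out below hybrid two's; squared-deviation
normalizations amplify the same outliers instead.  The suite records the
observed direction without asserting it.

## The synthetic generator

`sim_config()` draws unlinked markers in Hardy–Weinberg proportions with
minor-allele frequency uniform on `maf_range`, and builds the trait from
*per-category genotypic values* at causal markers: `(v0, v1, v2) =
(-a, d, +a)` with `a ~ N(0, additive_scale²)` (made all-positive when
`sign_mixing = FALSE`), and a heterozygote deviation
`d ~ N(0, (dominance_scale·additive_scale)²)` at a `dominance_degree`
fraction of causal markers.  Optional epistatic pairs contribute a full 3×3
grid of `N(0, epistasis_scale²)` cell values.  Noise is scaled so the
genetic share of trait variance hits `h²`.  Parameterizing signal as
category means (not dosage coefficients) lets one knob sweep from "ordinal
is optimal" (pure additive) to "per-marker encodings are needed"
(dominance, heterogeneous effects).

Defaults — `n = 300`, `m = 200`, 60 causal markers, `maf_range =
(0.05, 0.5)` (the conventional MAF ≥ 5 % inclusion threshold), dominance at
half the causal markers with deviation scale equal to the additive scale,
mixed signs, `h² = 0.6` — define the package's benchmark architecture, used
as-is by `scripts/acceptance.R`.

What the generator does *not* emulate: linkage disequilibrium (markers are
independent), population structure and relatedness, inbred panels (where
heterozygotes are rare and homozygote means are estimated from most of the
data), and genotyping error.  Passing benchmarks here therefore shows the
machinery is correct and leakage-free, not that any encoding will win on a
particular real dataset.

### When does a hybrid encoding beat ordinal — and when not

For a *linear, sign-agnostic* predictor like rrBLUP, flipping or mixing
effect signs is absorbed by the coefficients, and hybrid two's column is
ordinal's column rescaled per marker by `|E2 - E0|/2 ≈ |effect|`.  Its
entire advantage is therefore *adaptive shrinkage*: large-effect markers get
large-variance columns and effectively smaller penalties.  That helps
exactly when the homozygote group means are estimated with adequate
signal-to-noise — oligogenic architectures, common alleles, large training
folds.  Under the default benchmark the rare end of the MAF range leaves
minor-homozygote classes with a handful of training samples; their noisy
means hand random leverage to null markers, and hybrid two does **not**
reliably beat ordinal (the acceptance suite reports the win count rather
than hiding it), while the fully flexible target encoding — whose
heterozygote value carries real information under dominance — does.  In the
purely additive limit all encodings perform alike, as they must.

## Numerical choices

* Pearson correlation with any zero-variance vector is defined as 0
  (flip decisions, ranking, `pearson_r2` with constant predictions).
* A constant *observed* test vector makes r² undefined: the fold is
  recorded as `NA` and excluded from the mean, with a warning.
* Allele-frequency tie at exactly 0.5: keep the input orientation.
* Ranking ties (top-k, top-t): earlier marker wins, for determinism.
* `λ = 0` with a rank-deficient design is an explicit error in
  `ridge_solve`; REML never requests it.
* All serialization uses `%.17g`, so fitted objects round-trip through
  text bit-exactly.
* Every random draw goes through `with_seed()`, which restores the
  caller's RNG state; identical seeds give identical outputs everywhere,
  including the command line.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path with comfortable statistical margins: toys of 6–9
samples for exact hand-checked values; 1000-marker sweeps for order
properties; `n = 200, m = 400` with 20 replicates for REML recovery
(median `λ̂` within a factor of 2 of the truth 100); and the default
benchmark with 10 replicates for the encoding comparison.  The full
acceptance run completes in well under a minute.

## Known limitations

* Hybrid one's strict order claim fails at weak-signal markers (above);
  the package documents and measures this rather than enforcing it.
* No LD or population structure in the generator; CV folds are random,
  so family-structured data would need grouped folds the package does not
  provide.
* The epistasis grids are fitted per pair in a loop; at the default
  `top_t = 50` (1 225 pairs) this is instant, but all-pairs on tens of
  thousands of markers is out of scope by design (the cap enforces this).
* SVR hyperparameters are not tuned; the wrapper exists to compare
  encodings under a fixed nonlinear predictor, not to maximize accuracy.
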