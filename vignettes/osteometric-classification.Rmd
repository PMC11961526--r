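---
title: "Size, shape, and regularized discriminants for reindeer osteometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size, shape, and regularized discriminants for reindeer osteometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteorda)
```

## The problem

Zooarchaeologists working on Fennoscandian reindeer (*Rangifer tarandus*)
face a classification problem with seven intergrading groups: castrated,
intact male, and female domestic reindeer, male and female wild mountain
reindeer (all *R. t. tarandus*), and male and female wild forest reindeer
(*R. t. fennicus*). The groups differ in overall skeletal size, in bone
proportions (forest reindeer are longer-legged and more gracile; females
have slimmer diaphyses than males of the same type), and in the specific
signature of castration, which — when performed before osteological
maturity at roughly 4.5 years — suppresses breadth, depth, and
circumference growth much more than length growth. Archaeological material
is additionally fragmentary, so any usable method must work on proximal
ends, distal ends, or shaft fragments alone.

`osteorda` implements the analysis chain for this problem: a measurement
registry with bone-region tags, inclusion and deduplication filters, the
classical slenderness indices, the Mosimann size/shape decomposition, and
a from-scratch regularized discriminant analysis (RDA) with stratified
splitting and cross-validated hyperparameter tuning — together with a
synthetic assemblage generator that encodes the biological structure the
analyses assume, so the whole pipeline is testable without access to any
museum collection.

## Size and shape

For a specimen with measurements $V_1, \dots, V_n$ (all in mm), the
isometric size index is

$$\mathrm{IS} = \frac{1}{n}\sum_{v=1}^{n} \log V_v,$$

and the log shape ratios are $\mathrm{LSR}_v = \log V_v - \mathrm{IS}$.
Logs are natural logarithms throughout; any other base would rescale both
quantities by a common constant, which the scale-equivariance tests
document (`isize(c * v) == isize(v) + log(c)` exactly). The LSR vector
sums to zero by construction, so one component is redundant:
`size_shape_features()` drops the last variable's LSR (registry order)
and records which code was dropped. The alternative — keeping all
components and absorbing the singularity with identity shrinkage — is
available via `drop_policy = "none"`, but drop-one is the default because
it keeps the feature covariance honestly full-rank regardless of the
regularization chosen. iSize is always computed over exactly the
variable subset under analysis (only the shaft codes in a shaft-fragment
analysis), never over whatever a specimen happens to preserve.

The Mennerich indices are the classical two-measurement shape ratios:
index 1 is $\mathrm{SD} \times 100 / \mathrm{GL}$ (smallest diaphysis
breadth over greatest length) and index 3 is
$\mathrm{Bd} / \mathrm{GL} \times 100$ (distal breadth over greatest
length). Both are dimensionless and scale-invariant. `build_scatter()`
pairs an index or a raw measurement with a second axis; cluster
separation in such plots is judged visually in practice, so the
quantitative bounding-box overlap score in
`scatter_overlap_diagnostic()` is explicitly labelled a non-canonical
batch-screening aid.

## The classifier

RDA is a Gaussian discriminant whose class covariances are doubly
regularized (the Friedman parameterization):

$$\Sigma_k(\lambda) = (1 - \lambda)\,\hat\Sigma_k + \lambda\,\hat\Sigma_{\text{pooled}},
\qquad
\Sigma_k(\lambda, \gamma) = (1 - \gamma)\,\Sigma_k(\lambda)
 + \gamma\,\frac{\operatorname{tr}\Sigma_k(\lambda)}{p}\,I.$$

$\lambda = 0, \gamma = 0$ is QDA, $\lambda = 1, \gamma = 0$ is LDA, and
$\gamma = 1$ gives spherical covariances (nearest-mean-like behaviour).
Classification maximizes
$d_k(x) = -\tfrac12 \log\det\Sigma_k - \tfrac12 (x-\mu_k)^\top
\Sigma_k^{-1} (x-\mu_k) + \log\pi_k$, with ties broken to the lowest
class index and posteriors obtained by softmax of the scores. Priors are
empirical by default because group sizes in real assemblages are very
unequal; uniform priors are a flag away.

The tuning grid is $\lambda \in \{0, .25, .5, .75, 1\} \times \gamma \in
\{0, .1, .25, .5, 1\}$, evaluated by stratified tenfold cross-validation
and scored by balanced accuracy (the unweighted mean of per-class
recalls, the imbalance-robust headline metric; accuracy and macro F1 are
recorded alongside). Ties prefer larger $\lambda$, then larger $\gamma$ —
more regularization, never less, when the data cannot distinguish.

Splitting is 80/20, stratified by class and sex, with per-stratum test
counts computed by round-half-up and floored at one test member for
strata of five or more. Strata below five contribute train-only with a
warning: a "test set" of one specimen from a three-animal group measures
nothing, and tiny groups (the wild-male problem) are better used to
inform training than to produce noise metrics. All randomness — split,
fold assignment, tuning — derives from one top-level seed through named
substreams, so a report is byte-reproducible from its seed.

### Numerical choices

Covariance factorizations go through Cholesky decomposition; a relative
pivot check (smallest diagonal of the factor below $10^{-6}$ of the
largest) treats near-collinear covariances as singular and raises an
error that points to $\gamma > 0$ or the drop-one shape policy, rather
than returning garbage quietly. Posterior softmax subtracts the row
maximum before exponentiating. Per-class F1 is defined as 0 when
precision and recall are both zero; balanced accuracy ignores classes
with no support in the partition under evaluation.

## The synthetic assemblage generator

The generator is a first-class module, not a test fixture: it encodes
the study conditions as a log-normal measurement model, and every
downstream guarantee is demonstrated against it.

Log-measurements for each group and element are multivariate normal with

* a **baseline** log-mean per variable — round magnitudes by axis class
  (element-specific lengths around 200–300 mm, epiphyseal
  breadths/depths around 45 mm, shaft dimensions around 25 mm,
  circumferences around 80 mm). These are configuration for realistic
  ratios, not biological claims.
* a **group size offset** $\delta_g$ added to every variable, so group
  iSize differences equal $\delta$ differences exactly — which is what
  makes parameter recovery analytically checkable. The defaults decrease
  strictly in the order: fennicus male (0.14), domestic male (0.10),
  domestic castrate (0.075), fennicus female (0.045), wild male (0.02),
  domestic female (0), wild female (−0.03) — the size ranking reported
  for these seven groups, with castrates between intact males and
  females.
* a **gracility contrast**: a zero-sum vector (positive on lengths,
  negative on shaft variables) scaled by 0.025 for forest reindeer and
  0.015 for females. This makes fennicus ME1-slenderer than tarandus at
  equal size and dimorphism stronger in the diaphysis than in lengths.
* a **castration deficit** subtracted from the intact-male mean, scaled
  per variable by the length-sparing factor (default 0.25) on
  length-class variables and 1 elsewhere, its magnitude calibrated so
  the castrate group's expected iSize equals its configured $\delta$.
  With sparing 1 lengths suffer the full deficit; with sparing 0 they
  match intact males exactly.
* an **equicorrelated covariance**: common correlation $\rho = 0.55$
  between log-measurements and per-variable log-sd by axis class
  (lengths 0.030; breadths/depths 0.055; circumferences 0.050) —
  coefficients of variation of 3–6%, the within-group magnitude typical
  of adult ungulate long-bone measurements.

Fragmentation is region-atomic: a fragmented record survives as exactly
one region (proximal, distal, or shaft) and loses everything else,
including whole-bone lengths — mirroring marrow-split archaeological
material and the region-wise analysis units.

What the generator does **not** emulate: instrument rounding hierarchies
(0.1 mm calipers vs 1 mm boxes), inter- and intra-observer error,
pathology, nutrition- or cohort-driven size shifts, hybrids, and
measurement-level (non-region) missingness. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
log-normal structure — not that real assemblages satisfy that structure.

```{r example}
params <- synth_params(n_per_group = 25, seed = 42)
tab <- simulate_assemblage(params)
tab <- apply_inclusion_rules(dedupe_sides(tab))$kept
report <- suppressWarnings(run_ecotype_experiment(
  tab, elements = c("femur", "radioulna"), subsets = c("all", "shaft"),
  seed = 42
))
report[, c("element", "subset_id", "partition", "n",
           "accuracy", "balanced_accuracy", "macro_f1", "lambda", "gamma")]
```

## Design decisions worth recording

**Ecotype/variety target.** The main classification task uses three
classes — domestic tarandus, wild tarandus, fennicus — because
"ecotype/variety" names exactly that partition; a two-class
tarandus-vs-fennicus mode exists (`n_classes = 2`) since ecotype alone
is also a defensible reading. The pelvis and the wild-male group are
excluded from classification by default (tiny sample, different
measurement geometry), both overridable.

**Percent difference.** The convention is asymmetric,
$100\,(\bar x_A - \bar x_B)/\bar x_B$, with the second argument the
reference group, because group comparisons in this literature are
phrased against a reference; a symmetric variant (mean denominator) is
available by flag. Neither convention is claimed as "the" published one.

**Castration-age cutoff.** "4,5 years" is read as 4.5 (decimal comma)
and the rule is strict: castration at exactly 4.5 years is excluded,
since that age marks the completion of epiphyseal fusion, after which
castration leaves no osteometric trace.

**The one-vs-rest null.** A subtle point the castrate-detection tests
make explicit: with zero castration effect but realistic group size
structure, one-vs-rest balanced accuracy is genuinely *above* chance
(≈68% in our simulations), because castrates then sit exactly on the
domestic-male region of a heterogeneous "rest" mixture, and the
single-Gaussian rest model hands that region to the castrate class.
Chance is only the correct null when the castrate label is exchangeable
with the rest — so the null simulation uses a homogeneous assemblage.
The practical moral is the confounding the field already knows: apparent
"castrate detection" in a structured assemblage may be group-position
detection unless the effect's axis-class signature (breadth-heavy,
length-spared) is verified, e.g. by comparing shaft-subset against
length-subset detection, which is exactly the power contrast the
acceptance checks compute.

**Problem sizes.** The simulation-backed checks use 20 seeds for
medians, 8–10 seeds for means, 30–40 specimens per group for
classification experiments, and up to 10,000 per group for moment
checks — sizes at which the Monte-Carlo error bars quoted in the tests
are comfortably below the effects being asserted, while the whole suite
runs in about a minute.

## Limitations

The registry's 99 measurement definitions and its region memberships are
a plausible enumeration sufficient for type-checking and region
subsetting; applications to real data should load their own registry and
explicit per-subset code lists where an authoritative protocol exists.
Hyperparameter selection replicates a *procedure* (stratified split,
tenfold CV, balanced-accuracy selection), not any particular published
model fit, whose split seed and tuner internals are unknowable; published
per-element classification tables are therefore reproducible only in
distribution. Classification quality claims transfer to archaeological
material only to the extent that the log-normal, equicorrelated,
region-atomic world of the generator resembles it.
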