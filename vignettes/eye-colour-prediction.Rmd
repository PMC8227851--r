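---
title: "Eye-colour prediction from SNP panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eye-colour prediction from SNP panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ec11)
```

# The problem

Forensic DNA phenotyping predicts externally visible characteristics from a
crime-scene genotype. For eye colour in Europeans, most of the signal sits in
a single HERC2 SNP, rs12913832, in the OCA2 promoter region: GG homozygotes
are almost always blue-eyed, A-allele carriers almost always brown-eyed.
Modifier variants in OCA2, SLC45A2, TYRP1, SLC24A4 and TYR explain part of
the residue — notably two rare OCA2 variants (rs121918166, rs74653330) that
shift rs12913832:AG carriers towards blue.

This package implements a complete, testable version of that analysis:

1. a quantitative phenotype (the PIE-score) with its transform and two
   categorisation systems;
2. a resampled multi-model variable-importance ranking used to select a
   small prediction panel from a candidate set of 44 variants;
3. leave-one-out cross-validated (LOOCV) prediction models under three
   reporting systems, with the matching error measures;
4. a forensic reporting layer: probability thresholds, sensitivity and
   specificity, genotype-space enumeration, and likelihood ratios;
5. a synthetic-cohort generator, because the underlying human cohorts
   (757 Europeans for discovery; 523 Norwegians for modelling) are not
   publicly deposited.

# Phenotype: the PIE-score and its transform

The pixel index of the eye (PIE) summarises an iris photograph as
$r = (b - w)/(b + w)$ over its classified blue ($b$) and brown ($w$) pixels,
so $r \in [-1, 1]$ with 1 fully blue and $-1$ fully brown. Pixel
classification itself is out of scope; `pie_from_pixel_counts()` starts from
given counts.

Quantitative modelling uses the transformed score

$$y = \mathrm{logit}(0.5 + 0.499\,r),$$

which maps $[-1, 1]$ to $[\mathrm{logit}(0.001), \mathrm{logit}(0.999)]
\approx [-6.91, 6.91]$. The 0.499 factor keeps the transform finite at the
endpoints. The natural logarithm is used. `inverse_transform()` maps any
real back to a PIE-score; beyond the transformed endpoints the raw inverse
would overshoot $\pm 1$ by at most $1/499$, so it saturates there — the
round-trip on $[-1, 1]$ is exact to machine precision.

Categories partition the PIE range with closed boundaries and no tolerance:

* two-category: blue iff $r > 0.2$, otherwise brown;
* three-category: blue iff $r > 0.8$; intermediate iff $-0.5 \le r \le 0.8$;
  brown iff $r < -0.5$.

# Genotype encoding

Raw calls are unordered allele pairs (`"AG"` ≡ `"GA"`; indel alleles are
full strings such as `"TCT-"`). No strand flipping is attempted: a call
whose alleles are not the declared pair is an error, never a silent
complement. Panels assign each variable one coding:

* additive — minor-allele count, 0/1/2. Minor alleles are determined from
  the supplied cohort's allele frequencies; a tie at exactly 0.5 is broken
  by the lexicographically smaller allele, and the resolved map is stored on
  the coded matrix so encodings are reproducible across data sets.
* dominant (rs12913832) — AA and AG code 0, GG codes 1.
* carrier — indicator of at least one minor allele, used for rare variants.
* combined — sum of minor-allele counts over constituent variants, capped
  at 2. This is used for the rare OCA2 pair in the 44-variant *ranking*
  panel only.

In the EC11 *prediction* panel the two rare OCA2 variants are instead kept
as separate carrier-coded 0/1 variables. That choice is forced by the
published size of the EC11 genotype space: $52{,}488 = 2^3 \cdot 3^8$ admits
exactly three binary variables (dominant rs12913832 plus two carriers) and
eight additive ones. A combined 0–2 variable would give $3^9 \cdot 2$
combinations instead.

Samples with any missing panel call are dropped by default (prediction
modelling uses complete profiles); mean imputation is available for
exploratory work.

# Variable ranking and selection

The selection procedure repeatedly splits the cohort into a training set of
$\mathrm{round}(2n/3)$ samples and a test set of the rest (100 replicates by
default). A draw that leaves any *coded* variable fixed in the training set
is discarded and redrawn — "fixed" is judged on the coded scale because that
is what enters the models. On each training set seven models are fitted:

| response | models |
|---|---|
| quantitative ($y$) | LASSO (main effects), LASSO (+rs12913832 interactions), regression tree |
| two-category | LASSO (binomial, main), LASSO (binomial, +interactions), classification tree |
| three-category | classification tree |

LASSO fits standardise predictors to unit SD, follow a log-spaced 100-value
penalty path (minimum ratio $10^{-4}$), and choose the penalty by 10-fold
cross-validation with the one-standard-error rule: the most regularised
model within one SE of the minimum CV error. The interaction design adds
$g_j \cdot g_{\text{rs12913832}}$ columns for every $j$ with all main
effects retained, so the hierarchical principle holds by construction. A
LASSO variable's raw importance is its absolute standardised coefficient;
an interaction coefficient is credited to **both** partners (a flag
restricts credit to the non-rs12913832 partner). Trees are CART fits
(cp 0.01, minsplit 20, maxdepth 30) with variance or Gini splits; competitor
and surrogate splits are disabled, so a variable's importance is exactly the
impurity decrease over its primary splits — surrogate-based importance is a
deliberate deviation from rpart's default accounting.

Within each (replicate, model) cell, raw importances are standardised to
sum to one (all-zero fits stay zero). The mean over all cells ranks the
variables, and `select_top()` keeps those with mean importance at or above
0.3%. Test-set errors are computed and stored per replicate but never used
for selection.

Two empirical notes. First, under a strong dominant rs12913832 effect the
procedure is very stable: rank 1 with a dominant share of mean importance
across seeds. Second, under a pure-noise phenotype the LASSO cells are
empty (the 1-SE rule keeps the intercept-only model) but classification
trees still split on noise in a substantial share of replicates at
cp = 0.01; a single nonzero cell among $R \times 7$ contributes
$\approx 1/(7R)$ mean importance, which exceeds 0.3% at practical $R$. The
0.3% cutoff therefore does not act as a null-calibrated threshold for the
tree models, and the package makes no such claim.

# Prediction models and LOOCV

For a given panel and reporting system the prediction models are:

* quantitative — least squares on $y$ (errors reported as mean squared
  error on the transformed scale, the scale the model fits; predicted
  PIE-scores pass back through the inverse transform);
* two-category — binomial logistic regression, blue = 1;
* three-category — multinomial logistic regression over
  blue/intermediate/brown.

The logistic fits are Newton/IRLS with a tiny L2 ridge ($10^{-6}$) on slope
coefficients (never intercepts), which guarantees finite estimates under
perfect separation — routine with an 11-variable panel and a phenotype
dominated by one SNP. The ridge is togglable (`ridge = 0` gives the MLE)
and the fits agree with `glm()`/`nnet::multinom()` away from separation.
Convergence is declared at gradient max-norm $10^{-8}$, with step-halving
and at most 200 iterations. The multinomial baseline is the last category
present in the training data; a category absent from training is pinned at
a large negative intercept so its probability stays at zero. The
rs12913832-only three-category model is fitted exactly like the others even
though its single two-level predictor cannot separate three categories.

LOOCV refits the model $n$ times, leaving out one sample each time; every
prediction is out of sample. Genotype coding (the minor-allele map) comes
from the full cohort — coding is data preparation, not model fitting — and
only the fit is cross-validated. Errors are per-sample means:

* quantitative: $\frac1n \sum (y^{\text{pred}}_i - y_i)^2$;
* two-category: $\frac1n \sum -\log p_i(\text{truth}_i)$ (log-loss);
* three-category: the Kullback–Leibler divergence from the one-hot observed
  distribution, which reduces to the same $-\log p$ form.

Means (not sums) are used so error magnitudes are comparable across cohort
sizes. Probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ before logs;
clip counts are recorded on the result.

# Forensic reporting

`call_category()` applies a policy: `pmax` calls the most probable category
outright; a threshold $t$ calls it only when $\max(p) \ge t$ (0.5 and 0.7
are the conventional choices), otherwise the call is inconclusive. An exact
tie at the maximum is always inconclusive. `report()` tabulates percent
correct / incorrect / inconclusive over all samples (they sum to 100
exactly) and one-vs-rest sensitivity and specificity per category over the
conclusive calls, with `NA` when nothing conclusive remains.

`enumerate_genotype_space()` expands every coded genotype combination of a
panel — 729 for six additive SNPs, 52,488 for the EC11 coding — and, given
a fitted categorical model, reports each category's reachable share and
maximum attainable probability. This quantifies a structural property of
three-category reporting: the intermediate category occupies a small,
model-dependent corner of genotype space.

`likelihood_ratio()` supports two-category weight-of-evidence reporting:
$LR = P(\text{genotype} \mid \text{brown}) / P(\text{genotype} \mid
\text{blue})$, estimated from conditional genotype frequencies. Optional
add-0.5 smoothing handles genotypes unobserved in one class; whether the
published ratios used smoothing is not stated, so both modes exist and the
unsmoothed mode errors loudly on a zero denominator.

# The synthetic-cohort generator

The generator exists because the human cohorts are unavailable. It draws,
per variant, independent Hardy–Weinberg genotypes
($(1-q)^2, 2q(1-q), q^2$) at the published allele frequencies (packaged in
`variant_table()`; frequencies printed as "<0.01" are stored as 0.005, the
interval midpoint). Phenotypes follow a linear model on the transformed
scale,

$$y_i = \beta_0 + \textstyle\sum_j \beta_j g_{ij} +
\sum_j \gamma_j\, g_{i,\text{rs12913832}}\, g_{ij} + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

with $r_i$ recovered through the inverse transform. This family was chosen
deliberately: it is exactly the model family the selection stage fits, so
parameter recovery is a meaningful test of the machinery rather than of a
mismatch between generator and model.

The packaged `paper_like_config()` defaults are synthetic constants, not
biological estimates: a dominant rs12913832 effect of $+6$ on the
transformed scale against an intercept of $-1.5$, a $+4$ blue-shifting
effect of the rare OCA2 variants cancelled in GG homozygotes by a $-4$
interaction, small ($|\beta| \le 0.6$) modifier effects, and $\sigma = 2$.
They were calibrated once, against coarse published marginals only (a
two-category blue fraction around 60–70% and two-category LOOCV accuracy
near 0.9), and are not revisited. With them, the model-set configuration
reproduces the expected structure: blue fraction near 70%, LOOCV error
ordering EC11 ≤ IrisPlex ≤ rs12913832-only, and rank-1 recovery of
rs12913832 with a dominant importance share.

What the generator does **not** emulate: linkage disequilibrium (variants
are independent; an optional tag-block copies one variant's alleles with
probability $\sqrt{r^2}$ to mimic a tagged haploblock, off by default),
population substructure (the published cohorts mix Scandinavians and
Italians, with two variants out of HWE in the real discovery data — users
can emulate strata by editing a panel's `var_freq` column), genotyping
error, and missingness. Passing tests on synthetic cohorts therefore
demonstrate correctness of the *procedures*, not real-world predictive
accuracy.

# Numerical and design choices

* Reproducibility: every stochastic function takes a seed; replicate-level
  substreams are derived from a master seed with a fixed integer recurrence,
  so replicates are individually reproducible and independent of row order
  (samples are canonically sorted before splitting). Identical
  configurations yield bitwise-identical cohorts and pipeline artefacts
  (md5-checksummed in the run manifest).
* Splits that would fix a coded variable are redrawn up to 10,000 times,
  then fail naming the offending variable; a globally fixed variable fails
  immediately.
* Ranking replicates abort on any model-fit error (e.g. a single-class
  training response); more than 10% aborted replicates abort the run.
* Degenerate inputs: an empty cohort is a valid object; a constant response
  yields a root-only tree with zero importances (not an error); monomorphic
  HWE tables return p = 1.
* Test problem sizes: the suite exercises ranking recovery at the discovery
  size (n = 750) with 20 replicates across 20 seeds, LOOCV oracle
  equivalence at n = 30, and frequency/HWE recovery at n = 10,000 — sizes
  chosen to make the statistical assertions sharp while keeping the suite
  quick to run.

# Limitations

* LD $r^2$ is the squared Pearson correlation of genotype dosages
  (composite LD), not haplotype-EM $r^2$; the two differ away from HWE.
* The ranking's importance scale mixes LASSO coefficients and tree impurity
  decreases; only the within-cell standardised shares are comparable, and
  no p-value calibration is attempted.
* The IrisPlex web tool's coefficients are not published; all comparisons
  here use locally fitted models on the same cohort.
* Effect sizes in the generator are explicitly synthetic; nothing in the
  package should be read as an estimate of real genotype–phenotype
  parameters.

# A short end-to-end run

```{r pipeline, eval = FALSE}
cfg <- list(
  seed = 17, out_dir = tempfile("run"),
  simulate = list(n = 523, set = "model"),
  rank = list(panel = "ec11", reps = 20),
  predict = list(panel = "ec11", system = "three_category"),
  report = list(policies = list("pmax", 0.5, 0.7))
)
manifest <- run_pipeline(cfg)
```

The same run is available from a shell through the packaged wrapper
(`inst/cli/ec11.R run --config config.yaml`); example configurations ship
in `inst/extdata/`.
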