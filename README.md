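# ec11 — eye-colour prediction from small SNP panels

`ec11` is an R package for forensic eye-colour prediction and for the
methodology around building such predictors. It is aimed at forensic
geneticists and statistical-genetics researchers who want a reproducible,
fully tested implementation of:

* the **PIE-score** phenotype — the pixel index of the eye,
  `r = (blue − brown) / (blue + brown)` over an iris photograph's classified
  pixels, in `[-1, 1]` — with its modelling transform
  `y = logit(0.5 + 0.499 r)` and the two-category (blue/brown at
  `r > 0.2`) and three-category (blue / intermediate / brown at
  `r > 0.8` and `r < −0.5`) reporting systems;
* **genotype encoding** for named panels — additive (minor-allele count),
  dominant (rs12913832: AA/AG → 0, GG → 1), carrier and combined codings —
  with built-in EC11 (11 variables), IrisPlex (6 SNPs) and
  rs12913832-only panels, plus a 44-variant ranking panel with published
  allele frequencies;
* the **variable-selection procedure**: 100× repeated 2/3–1/3 resampling,
  seven models per split (gaussian/binomial LASSOs with and without
  rs12913832 interactions via the 10-fold CV one-standard-error rule, and
  CART trees), per-model importances standardised to sum to one, mean
  importance ranking, and a 0.3% selection cutoff;
* **LOOCV prediction models** per reporting system — linear regression on
  the transformed scale, ridge-stabilised binomial and multinomial logistic
  regression — scored by mean squared error, log-loss, and mean
  Kullback–Leibler divergence (`−log p` of the observed category);
* the **forensic reporting layer**: pmax/0.5/0.7 call policies with
  inconclusive handling, sensitivity/specificity tables, genotype-space
  enumeration (729 IrisPlex and 52,488 EC11 coded combinations), and
  two-category likelihood ratios `P(genotype | brown) / P(genotype | blue)`;
* a **synthetic-cohort generator** (Hardy–Weinberg genotypes at published
  frequencies; phenotypes from a configurable linear model with
  rs12913832-interaction terms on the transformed scale), since the original
  human cohorts are not publicly deposited.

Everything is tidyverse-shaped: functions take data frames or cohort objects
first and return tibbles, fitted objects have `tidy()`/`glance()` methods,
and result types have `autoplot()` methods.

## Worked example

Simulate a Norwegian-style model cohort, cross-validate the EC11
two-category model, and report with a 0.7 probability threshold:

```r
library(ec11)

cht <- simulate_cohort(paper_like_config(n = 523, seed = 17, set = "model"))
table(categorise_pie(cht$phenotypes$pie_score, "three_category"))
#>         blue intermediate        brown
#>          316          109           98

res <- loocv_predict(cht, panel_ec11(), "two_category")
glance(res)
#> # A tibble: 1 × 5
#>   system       panel     n error n_clipped
#>   <chr>        <chr> <int> <dbl>     <int>
#> 1 two_category EC11    523 0.247         0

report(res, call_policy(0.7))
#> <ec_report> two_category, panel EC11, policy p >= 0.7, n = 523
#> # A tibble: 3 × 3
#>   outcome      count percent
#>   <chr>        <int>   <dbl>
#> 1 correct        477   91.2
#> 2 incorrect       35    6.69
#> 3 inconclusive    11    2.10
#> # A tibble: 2 × 3
#>   category sensitivity specificity
#>   <chr>          <dbl>       <dbl>
#> 1 blue           0.935       0.923
#> 2 brown          0.923       0.935
```

The LOOCV `error` (0.247) is the mean out-of-sample log-loss of the
blue-vs-brown classifier; the report shows that at a 0.7 threshold 91% of
calls are correct and 2% are withheld as inconclusive. Likelihood ratios
for single-genotype weight-of-evidence reporting:

```r
likelihood_ratio(cht, "rs12913832", smoothing = TRUE)
#> # A tibble: 3 × 6
#>   genotype      lr n_brown n_blue freq_brown freq_blue
#>   <chr>      <dbl>   <int>  <int>      <dbl>     <dbl>
#> 1 AA       25.8         15      1     0.103    0.00399
#> 2 AG        9.27       124     33     0.827    0.0892
#> 3 GG       0.0769       10    340     0.0698   0.907
```

i.e. on this cohort a GG genotype is ~13× more likely under "blue-eyed"
than under "brown-eyed", while AA favours brown strongly.

Variable ranking on a discovery-style cohort:

```r
disc <- simulate_cohort(paper_like_config(n = 757, seed = 1, set = "discovery"))
imp  <- rank_variants(disc, panel_discovery44(), n_reps = 100, seed = 1)
select_top(imp, cutoff = 0.003)   # variables with mean importance >= 0.3%
autoplot(imp)
```

An end-to-end simulate → rank → predict → report run with provenance is
`run_pipeline()` (or `inst/cli/ec11.R run --config run.yaml`; example
configs in `inst/extdata/`). See the vignette
`vignettes/eye-colour-prediction.Rmd` for the models, assumptions and
numerical choices.

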