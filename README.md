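# polyfc

Coordination and subclass modeling of polyfunctional antibody responses.

HIV elite controllers suppress viremia without therapy, and their humoral
immunity is distinctive not in the *magnitude* of any single antibody
effector function but in how *coordinated* those functions are: subjects
whose IgG recruits ADCC also recruit phagocytosis, complement deposition and
NK-cell activation. `polyfc` implements the complete analysis pipeline for
that question over per-subject panels of seven Fc-effector readouts (ADCC,
ADCP, ADCD, ADNP, NK CD107a/IFN-γ/MIP-1β) and five gp120-specific titer
measurements (total IgG, IgG1–IgG4), across four subject groups: elite
controllers (EC), viremic controllers (VC), chronic treated (CT) and chronic
untreated (CU).

It is written for immunologists and biostatisticians doing systems serology:
every user-facing function takes a cohort table (a tibble, one row per
subject) and returns a tibble, so stages compose with the pipe.

## What it computes

* **Coordination statistic** — within each group, Spearman's rank correlation
  for all C(7,2) = 21 pairs of effector functions; the per-group
  distributions of coefficients are compared with a Friedman rank test over
  the 21 function-pair blocks plus Dunn's post-hoc comparisons
  (Bonferroni-adjusted), binned by strength, and exported as per-group
  correlation matrices with unadjusted p-values.
* **Subclass landscape** — positivity prevalence per group and subclass
  (fixed or control-derived mean + 3 SD thresholds), the 5×5 subclass
  co-induction correlation matrix, and Kruskal–Wallis + Dunn level
  comparisons per measurement.
* **Titer–function landscape** — per-group 5×7 titer-vs-function Spearman
  matrices and the pooled 4×7 matrix of *relative* levels
  (subclass MFI / total IgG MFI) against function.
* **Polyfunctionality classifier** — subjects are labeled polyfunctional
  when above the cohort-wide median in ≥ 2 of the 7 functions; an
  L2-penalized (ridge, elastic-net α = 0) logistic model on the five titer
  features is evaluated with 250 iterations of stratified 5-fold
  cross-validation against a permuted-label null, reporting balanced
  accuracy (sensitivity + specificity)/2, a Welch test between arms, and
  mean standardized coefficient weights with sign stability. The ridge
  objective is `mean(-loglik) + λ‖β‖²/2` with the penalty chosen by inner
  5-fold cross-validation on a 50-point log grid; the Newton solver lives in
  compiled code.
* **Synthetic cohort generator** — a Gaussian-copula / shared-factor model
  reproducing the statistical structure the analysis assumes (group sizes
  50/64/45/38, group-dependent coordination, IgG1↔IgG3 and IgG2↔IgG4
  co-induction, group-dependent subclass skewing and positivity, and planted
  subclass→function effects), so the full pipeline runs and is testable with
  no external data.

## Worked example

```r
library(polyfc)

cohort <- simulate_cohort(cohort_config(seed = 7))
group_sizes(cohort)
#> EC VC CT CU
#> 50 64 45 38

corr  <- pairwise_function_correlations(cohort)
compare_group_coordination(corr)
#> Coordination comparison (Friedman / Dunn on 21 function-pair blocks)
#>   chi-squared = 55.229, df = 3, p = 6.14e-12
#>   mean block rank (higher = more coordinated):
#>   EC   CT   CU   VC
#> 3.90 3.10 1.67 1.33
#>   pairwise (Dunn, Bonferroni-adjusted):
#>  group_a group_b statistic  p_value adjusted_p
#>       EC      VC     6.454 1.09e-10   6.53e-10
#>       EC      CT     2.032 4.22e-02   2.53e-01
#>       EC      CU     5.618 1.94e-08   1.16e-07
#>       ...
```

The elite-controller group ranks as the most functionally coordinated, and
its advantage over the viremic groups is significant after adjustment —
coordination, not raw magnitude, separates the groups.

```r
run <- polyfunction_model(cohort, iterations = 250, seed = 7)
run
#> Polyfunctionality classification (197 subjects, 132 polyfunctional)
#>   true:     balanced accuracy 0.797 +/- 0.012
#>   permuted: balanced accuracy 0.500 +/- 0.005
#>   difference 0.297, welch_t p = 0
tidy(run)
#> # A tibble: 5 × 4
#>   feature   mean_weight  sign stability
#>   <chr>           <dbl> <dbl>     <dbl>
#> 1 IgG_total      0.0264     1     0.528
#> 2 IgG1           0.811      1     1
#> 3 IgG2          -0.228     -1     1
#> 4 IgG3           1.45       1     1
#> 5 IgG4          -0.372     -1     1
```

The subclass titers predict polyfunctional status far better than the
permuted-label control, with IgG1/IgG3 contributing positively and
IgG2/IgG4 negatively — subclass quality, not just quantity, drives the
functional profile. `glance(run)` returns the one-row summary,
`autoplot(run)` the accuracy distributions and coefficient weights.

The whole pipeline (per-function ANOVA/Tukey group comparisons,
coordination, subclass landscape, titer–function matrices, classifier,
TSV/JSON outputs and a markdown report) runs as one call:

```r
run_all(pipeline_config(seed = 7), "results/full")
```

or from a shell via `inst/scripts/run_pipeline.R`.

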