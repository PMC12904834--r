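# grivus

Dose–time–response surface modelling and growth-rate-normalised drug
response scoring for live-cell imaging screens.

## The problem

Live-cell imaging screens count cells in every well every few hours for
days, yet drug response is still usually summarised by endpoint metrics
— IC50, Emax, or the area under a single-time-point dose–response curve
— which discard the kinetics and are confounded by how fast the cell
line happens to divide. `grivus` fits a single surface to the whole
dose–time–count table of each cell line–drug pair, scores it with a
growth-rate-normalised volume, and extrapolates long-horizon response
from short incubation windows. It is aimed at anyone analysing
Incucyte-style count exports: screening cores, pharmacology labs, and
method developers.

## The model

For log10 concentration *d* (µM) and time *t* (hours), the surface is a
4-parameter logistic in dose whose asymptotes travel along logistic
growth curves in time:

```
f(d, t) = (α(t) − δ(t)) / (1 + 10^(β(t)·(d − kγ))) + δ(t)

α(t) = aα·2^(kα·t) / ((aα − 1) + 2^(kα·t))      untreated growth
δ(t) = aδ·2^(kδ·t) / ((aδ − 1) + 2^(kδ·t))      growth at saturating dose
β(t) = kβ·|α(t) − δ(t)|                          time-varying steepness
```

Counts are normalised to 1 at *t* = 0, so f(d, 0) ≡ 1; the 0 µM vehicle
control is the d → −∞ limit, i.e. α(t); kγ is the log10 IC50. The six
parameters (kα, aα, kδ, aδ, kβ, kγ) are estimated by bounded nonlinear
least squares on relative errors, with fit quality reported as MAPE.

**GRIVUS** (growth-rate-inhibition volume under the surface) integrates
not f but the rescaled surface f′ in which both growth exponents are
expressed relative to the faster rate — removing division-rate
confounding the way GR metrics do for dose–response curves — using an
averaged upper/lower cuboid sum on a 100 × 100 grid, and normalises by
the "unaffected" volume of the dose-constant control surface α′(t).
For an inhibitor the normalised score is in (0, 1]; 1 means no effect.

Fitting on a truncated window (say 72 h) and evaluating the trained
surface over the full horizon predicts the 120-h GRIVUS before the
experiment gets there; agreement between series is quantified with
Lin's concordance correlation coefficient plus a percentile bootstrap
interval.

## A worked example

Simulate a 4-pair cohort under the default screen layout (six doses
0–10 µM, images every 3 h for 120 h, three replicate wells, 5%
multiplicative noise), fit, score, and extrapolate:

```r
library(grivus)
library(dplyr)

spec <- synthetic_spec(n_pairs = 4, seed = 7)
sim <- simulate_cohort(spec)

fits <- fit_dose_time(sim$counts)
scored <- grivus_scores(fits)
scored %>% select(drug, k_alpha, k_gamma, mape_percent, grivus_normalized)
#> # A tibble: 4 × 5
#>   drug   k_alpha k_gamma mape_percent grivus_normalized
#>   <chr>    <dbl>   <dbl>        <dbl>             <dbl>
#> 1 drug01  0.0500   0.418         3.91             0.826
#> 2 drug02  0.0428  -0.936         3.98             0.541
#> 3 drug03  0.0411   0.594         4.01             0.887
#> 4 drug04  0.0349  -1.19          3.89             0.443
```

Per pair: the fitted untreated growth rate (`k_alpha`, 1/h — 0.035–0.05
is a 20–40 h doubling time), log10 IC50 (`k_gamma`), the fit MAPE in
percent, and the normalised GRIVUS (drug04 is the strongest responder
here, drug03 the weakest).

```r
preds <- predict_grivus(sim$counts, t_train = 72, t_horizon = 120)
preds %>% select(drug, mape_holdout_percent, grivus_at_train,
                 grivus_predicted, grivus_measured)
#> # A tibble: 4 × 5
#>   drug   mape_holdout_percent grivus_at_train grivus_predicted grivus_measured
#>   <chr>                 <dbl>           <dbl>            <dbl>           <dbl>
#> 1 drug01                 4.23           0.819            0.823           0.826
#> 2 drug02                 4.82           0.512            0.511           0.541
#> 3 drug03                 4.06           0.920            0.927           0.887
#> 4 drug04                 4.35           0.429            0.429           0.443
concordance(preds$grivus_measured, preds$grivus_predicted, seed = 1)
#> CCC = 0.9914 [95% CI 0.8107, 0.9989], PCC = 0.9971 (n = 4, 100 bootstrap reps)
```

Surfaces trained on the first 72 h predict the 120-h score of the fresh
full-window fit (`grivus_measured`) to within a few percent, at a
holdout MAPE comparable to the full fit's own error.

`autoplot(fits$fit[[1]])` draws measured counts and fitted curves per
dose; `plot_surface(fits$fit[[1]]$params, dom)` renders the surface as
a heatmap. `read_counts()` / `run_pipeline()` handle CSV plate exports
end-to-end, and `exec/grivus` exposes `fit`, `grivus`, `predict`,
`simulate` and `concordance` subcommands for shell use.

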