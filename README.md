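# spermophagy

Penalized logistic modelling of in vitro sperm phagocytosis
("spermophagy") by polymorphonuclear neutrophils as a function of bovine
oviductal fluid components (BOFCs): serum albumin (BSA), luteinizing
hormone (LH), oviductal epithelial cell (BOEC) co-culture, angiotensin II
(ANGII), prostaglandin E2 (PGE2), alpha-1 acid glycoprotein (AGP) and
endothelin-1 (EDN-1).

The package is for reproductive-biology and biostatistics researchers who
want to (re)analyse dose-response phagocytosis data of this kind: fit the
model, compare the plain and penalized fits, decide which components
matter, and predict the effect of dose combinations that were never run
in the lab.

## The model

Observed spermophagy SP (a phagocytosis ratio relative to control,
roughly 0.2–1.4) is mapped onto (0, 1) by `RP = 0.2 + (1.4 − SP)/2` and
modelled with a logistic regression on the seven component doses,

```
p = exp(f)/(1 + exp(f)),   f = β₀ + β₁·BSA + β₂·LH + β₃·BOEC + β₄·ANGII
                               + β₅·PGE2 + β₆·AGP + β₇·EDN1
```

fitted by maximizing the ridge-penalized quasi-log-likelihood

```
M(β) = Σᵢ [ yᵢ ln pᵢ + (1 − yᵢ) ln(1 − pᵢ) ] − λ‖β‖²
```

with the iterative gradient-ascent scheme
`β(k+1) = β(k) + α(k) ∇M(β(k))`, whose step size is adapted dynamically
(`α(k+1) = δ(k) α(k)`, δ derived from the ratio of consecutive update
norms).  λ = 0 is the plain logistic fit (LR); λ > 0 the penalized fit
(ALR).  Model comparison uses RMSE, MAE, Nash–Sutcliffe efficiency,
Willmott's index of agreement and AIC; variable removal uses the Murtaugh
ΔAIC–chi-square equivalence.  The methods vignette
(`vignettes/spermophagy-modelling.Rmd`) documents every convention and
numerical choice.

## Worked example

```r
library(spermophagy)
library(dplyr)

# synthetic five-study dose-response data with the experimental structure
obs <- simulate_observations(default_table2_config(seed = 1))

# scan the penalty grid and take the selected fit
scan <- penalty_scan(obs, standardize = TRUE)
select(scan, -fits)
#> # A tibble: 8 × 8
#>   lambda    ef     d   rmse    mae   aic converged selected
#>    <dbl> <dbl> <dbl>  <dbl>  <dbl> <dbl> <lgl>     <lgl>
#> 1   0.25 0.782 0.934 0.0397 0.0302  92.1 TRUE      TRUE
#> 2   0.5  0.779 0.931 0.0400 0.0306  92.2 TRUE      FALSE
#> ...
#> 8   2    0.741 0.907 0.0434 0.0342  92.4 TRUE      FALSE

alr <- scan$fits[[which(scan$selected)]]
alr
#> Penalized logistic spermophagy model (lambda = 0.25)
#>   converged after 817 iterations (n = 56)
#>   penalized objective M(beta*) = -38.07285, AIC = 92.1457
#>   coefficients (raw dose scale):
#> (Intercept)         bsa          lh        boec       angii        pge2
#>   -0.297176    0.000101    0.048403    0.239085   -0.029881    0.002246
#>         agp        edn1
#>    0.005857    0.000203
```

The scan reports, per penalty value, the training-set efficiency (`ef`),
agreement (`d`), errors and AIC; the selected row maximizes `ef` with AIC
as tie-break.  The fitted slopes are per dose unit: here every component
except ANGII gets a positive slope, i.e. reduces predicted spermophagy,
and ANGII's negative slope means it increases it — the pattern the
generating model encodes.

Evaluating the bundled 15-row literature validation table (phagocytosis
observations against the reference predictions of both models):

```r
fx <- validation_fixture()
bind_rows(
  mutate(fit_statistics(fx$phagocytosis, fx$alr_ref), model = "ALR"),
  mutate(fit_statistics(fx$phagocytosis, fx$lr_ref),  model = "LR")) %>%
  relocate(model)
#> # A tibble: 2 × 10
#>   model  rmse   mae   nse     d   aic tot_pred mean_pred sd_pred     n
#> 1 ALR   0.132 0.103 0.758 0.920    NA     13.7     0.915   0.211    15
#> 2 LR    0.207 0.163 0.403 0.758    NA     13.2     0.879   0.188    15
```

The penalized model's validation RMSE (0.132 vs 0.207) is about 36%
lower than the plain fit's, with better agreement on every statistic.
Combination effects and the factor classification follow directly from a
fitted coefficient vector:

```r
classify_factors(combination_report(coef(alr)))
#> # A tibble: 7 × 4
#>   factor mean_reduction  rank class
#> 1 pge2            53.5      1     1
#> 2 agp             45.2      2     2
#> ...
#> 7 angii            6.95     7     3
```

`mean_reduction` is the mean percent reduction of predicted spermophagy
over all single and pairwise dose combinations containing the factor (at
maximum experimental doses); classes partition the ranking at its largest
gaps.

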