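# cliffcensus

Population censuses of plants on inaccessible rocky cliffs are done through
a telescope: the wall is photographed, rectified, overlaid with a 10 m ×
10 m grid, and the individuals distinguishable in each grid cell — the
*visual units* — are counted. `cliffcensus` implements the statistics that
turn such grid-cell counts into population estimates, for botanists and
conservation monitors working on rupicolous flora or in any environment
where exhaustive counts are impractical:

* **Observer correction factors (CF).** Paired counts of 30–40 calibration
  areas at survey (20×) and high (60×, or true count) magnification give
  per-area ratios $r_j = \text{precise}_j / \text{visual units}_j$; the CF
  is their mean (Shapiro–Wilk-checked), and multiplies per-cell visual
  units to give individuals.
* **Count-distribution fitting.** Per-cell counts are fitted by maximum
  likelihood to Geometric, Poisson and Negative Binomial models
  ($\hat\lambda = \bar x$; $\hat p = 1/(1+\bar x)$; $(\hat r, \hat\mu)$
  with $\hat\mu = \bar x$ and $\hat r$ by profile likelihood), compared by
  χ² goodness of fit and ranked by AIC/BIC, with CDF/PP/QQ diagnostics.
* **Minimum sampling effort.** Grid cells are subsampled at random without
  replacement at fractions 90% → 5% (step 5%, 25 replicates each); each
  subsample is expanded to a total $\widehat T = N \hat\mu \widehat{CF}$
  and wrapped in two 95% confidence intervals — a log-normal
  maximum-likelihood (ML) interval and a simple-bootstrap (SB) percentile
  interval from 10,000 resamples. The summary recommends the method with
  the smaller error bar and the smallest fraction whose interval is still
  acceptably tight, i.e. the minimum effort a field campaign needs.
* **Synthetic data.** A generator with known ground truth (counts, true CF,
  true total) so the whole pipeline is testable without field data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on results, plus a thin
`cliffcensus` command-line script (`exec/cliffcensus`) with subcommands
`cf` / `fit` / `effort` / `simulate`.

## Worked example

A synthetic 147-cell wall with clumped counts (negative binomial, r = 1.5,
μ = 4) and an observer who resolves two of every three plants (true CF 1.5):

```r
library(cliffcensus)

scn    <- synthetic_scenario(seed = 42)
census <- simulate_census(scn)
pairs  <- simulate_calibration_pairs(scn)

cf <- estimate_cf(pairs)
#> <correction_factor> CF = 1.5322 (sd 0.1417, n = 35)
#>   reciprocal (20x/60x orientation): 0.6527
#>   Shapiro-Wilk p = 0.02598

compare_count_models(census)[, c("rank", "family", "aic", "bic", "gof_p")]
#>    rank family      aic   bic    gof_p
#> 1     1 nbinom     699.  705. 2.49e- 2
#> 2     2 geometric  701.  704. 9.98e- 3
#> 3     3 poisson    828.  831. 2.27e-18
```

The estimated CF (1.53) recovers the true 1.5 within its standard error,
and AIC picks the generating negative binomial (the Poisson is far behind:
the wall is overdispersed). Now the effort analysis:

```r
design  <- effort_design(seed = 42)       # 0.90..0.05, 25 reps, B = 10,000
records <- run_effort_analysis(census, design, family = "auto", cf = cf)
summarize_effort(records)
#> <effort_summary> census total 783.0
#>   recommended method: SB; recommended fraction: none qualifies
#>    fraction mean_estimate ml_width_mean sb_width_mean ml_coverage sb_coverage
#>  1     0.9           784.          266.          247.        1           1
#>  8     0.55          785.          337.          315.        1           1
#> 14     0.25          814.          520.          476.        0.96        1
#> 18     0.05          844.         1298.          979.        0.92        0.92
```

(rows abridged). Read it as the field protocol does: the mean estimate
stays on the census total (783 corrected individuals) down to very small
fractions, both intervals widen as effort drops, SB is consistently the
tighter method here, and coverage of the full-census total stays at or
above 92% everywhere. No fraction meets the default 15% relative-half-width
dial on this strongly clumped wall — an honest "this wall needs most of the
grid (or looser precision) " answer; `summarize_effort(records, hw_tol = 0.25)`
relaxes the dial. `autoplot(records)` draws the CI boxplots per fraction
with the census total as a red reference line, and
`plot_effort_fraction(records, 0.55)` the detail view at one fraction.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package end to end on the synthetic wall — generate
census and calibration pairs, estimate the CF, select the count model by
AIC, and run the full subsampling design with both CI methods — logging a
short summary and writing the results JSON to `--out`. All randomness
derives from `--seed`.
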