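---
title: "Estimating cliff-plant populations from partial grid censuses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cliff-plant populations from partial grid censuses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliffcensus)
```

## The problem

Rupicolous (rock-dwelling) plants on vertical cliff walls cannot be censused
by walking transects. The standard workaround is optical: photograph the
wall, rectify the image so distances are real, overlay a square grid
(10 m × 10 m cells by default), and count through a telescope the number of
individuals distinguishable in each cell — the *visual units*. Cells at the
image border that contain only a sliver of rock are excluded to avoid edge
bias. Two statistical questions then arise, and this package answers both:

1. **Observer calibration.** A visual unit is not an individual: at survey
   magnification plants merge and hide. A *correction factor* (CF) converts
   visual units into individuals.
2. **Minimum sampling effort.** Weather windows on high cliffs are short.
   If only a fraction of the grid cells can be censused, how small can that
   fraction be while the population-total estimate remains accurate and its
   confidence interval acceptably tight?

## Observer correction factor

For 30–40 easily delimited areas, the observer counts twice: once at the
survey magnification (20×, giving visual units) and once either at higher
magnification (60×) or exhaustively where the area is accessible. For area
$j$ the ratio

$$ r_j = \frac{\text{precise count}_j}{\text{visual units}_j} $$

is the local conversion factor, and the CF is the arithmetic mean
$\widehat{CF} = \bar r$. Before averaging, the ratios are checked for
compatibility with a normal distribution (Shapiro–Wilk at $\alpha = 0.05$);
a failure produces a warning, not an error, because no alternative estimator
is prescribed for this protocol — a trimmed-mean option exists but is off by
default. The CF is observer- and year-specific; `apply_cf()` warns when the
labels do not match.

**Orientation.** The two counts can be divided either way. We define the CF
as precise/visual-unit — the multiplier applied to visual units — because it
is the only orientation under which "multiply the average by the per-cell
visual units" yields individuals. The reciprocal (the 20×/60× shrink
factor) is reported alongside for traceability. Pairs with a zero
visual-unit count leave the ratio undefined and are rejected (or dropped
with a warning in batch mode).

## Count models for per-cell visual units

Per-cell counts are fitted by maximum likelihood to three candidate
families on support $\{0, 1, 2, \dots\}$:

| family | parameters | MLE | mean | variance |
|---|---|---|---|---|
| Poisson | $\lambda$ | $\hat\lambda = \bar x$ | $\lambda$ | $\lambda$ |
| geometric | $p$ | $\hat p = 1/(1+\bar x)$ | $(1-p)/p$ | $(1-p)/p^2$ |
| negative binomial | $(r, \mu)$ | $\hat\mu = \bar x$, $\hat r$ numeric | $\mu$ | $\mu + \mu^2/r$ |

The geometric support convention matters: we count failures starting at 0
(R's `dgeom`), so $\hat p = 1/(1+\bar x)$; the shifted variant would change
the estimate. The negative binomial uses the (size, mean)
parameterization; `nb_mu_to_prob()` converts. Its mean MLE is the sample
mean exactly, so the dispersion $r$ is found by maximising the profile
log-likelihood in $\log r$ with `optimize()` (tolerance $10^{-10}$) over
$\log r \in [-12, 15]$. When the sample variance does not exceed the mean
the optimum sits at the upper boundary — the fit is then numerically a
Poisson and is returned with `boundary = TRUE` rather than as an error.

A key identity used throughout: **all three fitted model means equal the
sample mean.** This makes the expansion estimator below family-independent
at the point-estimate level and is asserted as a cross-family test.

### Model choice

Families are ranked ascending by AIC ($2k - 2\ell$), ties broken by BIC
($k\ln n - 2\ell$), then by fewer parameters, so that when the negative
binomial collapses onto the Poisson boundary the one-parameter model wins.
A $\chi^2$ goodness-of-fit test accompanies the ranking: count classes
$0, 1, 2, \dots$ with the open upper tail as top class, pooled so every
expected frequency reaches 5 (the classical floor; the protocol itself
states no binning rule). The top class is the largest tail cut whose
expected frequency still reaches the floor, so classes may extend past the
largest observed count; any remaining deficient class is merged with its
upper neighbour, keeping classes contiguous. Degrees of freedom are
(bins − 1 − parameters), floored at 1, and a result built on ≤ 2 bins
carries a low-resolution flag. A goodness-of-fit rejection flags a family
but does not veto the AIC ranking — the interaction of the two criteria is
left to the analyst, and both are reported.

### Graphical diagnostics

`diagnostic_series()`/`autoplot()` reproduce the usual four panels:
observed vs fitted probability mass, empirical vs theoretical CDF, PP and
QQ plots. The plotting position is Hazen's $(i - 0.5)/n$ (no convention is
prescribed by the protocol); the discrete theoretical quantile at $p$ is
the smallest support point whose CDF reaches $p$. Because counts are
discrete, PP points sweep each tie block vertically while the theoretical
CDF stays fixed; closeness to the identity line should therefore be judged
at the top of each block (the empirical CDF), which is what the package's
tests assert.

## Minimum-effort analysis

### The expansion estimator

Let $N$ be the number of included cells, $s$ a simple random sample without
replacement of $n = \mathrm{round}(fN)$ cells (round half up, minimum 1) at
sampling fraction $f$. The chosen family is fitted to the sampled counts and
the population total is estimated by

$$ \widehat T = N \cdot \hat\mu_{\text{fit}} \cdot \widehat{CF}. $$

The protocol never writes this formula; it is the only estimator consistent
with both the distribution-fitting step and the requirement that full
sampling reproduce the census total exactly (which it does, because
$\hat\mu_{\text{fit}} = \bar x_s$). The best-fitting family is selected once
on the full census and held fixed across subsamples; per-subsample
re-selection exists behind `refit_family = TRUE`.

### Confidence intervals

Two interval methods are attached to every subsample, and the analyst picks
the one with the smaller error bar:

**Maximum likelihood (ML).** A log-normal approximation: with
$s_{\log} = \mathrm{SE}(\hat\mu)/\hat\mu$ and
$\mathrm{SE}(\hat\mu) = \sqrt{\widehat{\mathrm{Var}}_{\text{model}}/n}$
(the fitted family's variance at the MLE, i.e. the observed-information
variance of the mean, delta-method transferred to the log scale),

$$ \left( \widehat T e^{-z_{1-\alpha/2} s_{\log}},\;
         \widehat T e^{+z_{1-\alpha/2} s_{\log}} \right). $$

The interval is asymmetric around $\widehat T$ with
$\text{high}/\widehat T = \widehat T/\text{low}$. A zero estimate is
undefined on the log scale and returns a degenerate $(0, 0)$ with a
warning. The exact variance formula behind the protocol's one-line
description is not published; this construction is validated by its own
coverage simulation (see below).

**Simple bootstrap (SB).** The sampled cells are resampled *with
replacement* $B$ times (default $B = 10{,}000$), the expanded total is
recomputed on each resample, and the interval is the
$(\alpha/2, 1-\alpha/2)$ percentile pair. Since every fitted mean equals
the resample mean, each bootstrap total is $N \bar x^* \widehat{CF}$, which
the implementation computes vectorised. The percentile interval is the
plainest reading of "simple bootstrap"; BCa is deliberately not used.

### Design and reproducibility

The default `effort_design()` mirrors the field protocol: fractions 0.90
down to 0.05 in steps of 0.05 (18 fractions), 25 random subsamples per
fraction, $B = 10{,}000$, $\alpha = 0.05$ — 450 records per run. Every
(fraction, replicate) pair gets its own RNG stream derived deterministically
from the root seed, so any record can be reproduced in isolation and two
runs with the same design are byte-identical.

### Summaries and the recommendation

`summarize_effort()` aggregates per fraction: mean estimate, mean/min/max of
each CI bound, mean CI width and the fraction of replicates whose interval
covers the full-census total. The protocol chooses the minimum effort
visually from boxplots; to make that reproducible the package adds two
explicit dials, with the graphical route still available via `autoplot()`:

* `hw_tol` (default 0.15): the largest acceptable mean relative CI
  half-width. 15% mirrors the precision commonly accepted in rare-plant
  monitoring.
* `coverage_floor` (default 0.90): the smallest acceptable coverage of the
  full-census total.

The recommended method is the one with the smaller mean width (at a
user-chosen fraction of interest, or averaged over all fractions), and the
recommended fraction is the smallest one meeting both dials under that
method. On strongly overdispersed walls no fraction may qualify at the
defaults — an honest "sample more of the wall" answer, reported as `NA`.

## What the synthetic generator emulates — and what it does not

`synthetic_scenario()` states one simulated world: a wall of
`n_cells = 147` cells (a ~1470 m² wall at 10 m × 10 m resolution, though at
that cell size such an area strictly holds ~15 cells; 147 keeps the grid
large enough for distribution fitting while staying in the scale of the
motivating case), per-cell counts i.i.d. from a stated family (default
negative binomial, $r = 1.5$, $\mu = 4$ — clumped, as cliff vegetation on
ledges and cracks typically is), a true CF of 1.5 (the observer resolves
two of every three individuals) with 10% multiplicative Gaussian noise on
the low-magnification counts, and 35 calibration areas, inside the 30–40
band of the protocol. Counts are **independent across cells**: the
generator does not emulate spatial autocorrelation, phenology, or
distance-dependent detectability. A green end-to-end test therefore
establishes that the estimators and intervals behave as designed under
i.i.d. clumped counts — not that a real wall satisfies those assumptions.

Two ground-truth totals accompany every simulated census: the realized sum
of the generated counts (`census_total`) and the process-level expected
total $N \cdot E[X]$ (`true_total`). Coverage simulations target the
latter: the model-based intervals make no finite-population correction, so
against the realized total of one fixed census under without-replacement
subsampling they are conservative (empirically ≈ 0.99 at 50% sampling
rather than 0.95). This is a feature for field use — the reported intervals
err on the safe side for the wall actually in front of the observer — but
the nominal-level checks must be made against the process total.

## Numerical choices, edge cases

* Counts are stored as integers and never overwritten; CF-corrected values
  are real-valued and kept in a separate column.
* Subsample sizes use round-half-up with a floor of one cell.
* All-zero subsamples yield a zero estimate with a warning and a degenerate
  ML interval; the SB interval of any constant subsample is zero-width.
* The ML interval is zero-width only when the fitted model variance is
  zero (all-zero data); for constant nonzero counts the model-based
  standard error is positive by construction.
* Bootstrap percentiles use R's default quantile type; at $B = 10{,}000$
  two runs of the same subsample differ by well under 2% in either bound.
* Edge-cell exclusion is by explicit id list; the optional
  `rock_fraction` threshold is a convenience addition, off by default,
  since the field protocol removes edge cells by visual judgment.

## Limitations

* No spatial statistics: grid geometry is metadata, and stratified or
  adaptive subsampling designs are out of scope.
* No zero-inflated or spatially correlated count models.
* The ML interval is an interpretation of a one-line protocol description;
  it is validated by coverage simulation, not against a published formula.
* The CF model assumes a single multiplicative observer bias per
  observer-year; distance-dependent detectability is field protocol, not
  computation.
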