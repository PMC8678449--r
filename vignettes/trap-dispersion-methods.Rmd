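---
title: "Dispersion statistics and experimental design for insect trap counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersion statistics and experimental design for insect trap counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapdisp)
```

`trapdisp` implements the statistical workflow behind designing surveys and
field-efficacy experiments for strongly aggregated insect populations, with
spotted lanternfly (*Lycorma delicatula*) nymphs on sticky-band tree traps
as the motivating system. This vignette explains the models, the tunable
parameters and their defaults, the synthetic-data generator used for
testing, and the numerical and design choices made where several defensible
options existed.

## Dispersion statistics

A trap-count sample over $n$ sampling units (traps, or 1{,}000 cm$^2$ of
trap surface) with mean density $\bar{x}$ and sample variance $s^2$
($n-1$ denominator) is summarized by Lloyd's **mean crowding**

$$m^* = \bar{x} + \left(\frac{s^2}{\bar{x}} - 1\right),$$

the mean number of other individuals sharing a unit with a randomly chosen
individual, and the **index of dispersion** $I = s^2/\bar{x}$. Under a
Poisson (random) spatial pattern $E[s^2] = \bar{x}$, so $I = 1$ and
$m^* = \bar{x}$; for a negative binomial with size $k$,
$m^* = m(1 + 1/k)$ exactly at the distribution level. Randomness is tested
with

$$\chi^2 = I\,(n - 1),$$

compared to the $\alpha/2$ and $1-\alpha/2$ quantiles of $\chi^2_{n-1}$:
below the lower limit is classified *uniform*, above the upper limit
*aggregated*, otherwise *random*. The classification level defaults to a
two-sided $\alpha = 0.05$; the level is a parameter because the convention
is not universal. The sample variance uses the $n-1$ denominator
throughout — the choice under which the Poisson identity $E[I] = 1$ holds
and the standard one for $m^*$.

Counts can be analyzed per trap or per 1{,}000 cm$^2$ of trap area. The
trap area of a sticky band follows the band geometry: the foam spacer that
stands the film off the bark is added **once** to the trunk diameter
before computing the circumference,

$$A = \pi\,(\mathrm{DBH} + \mathrm{foam}) \times \mathrm{band\ width},$$

a literal reading of "adding the spacer width to the diameter"; a
configurable alternative (adding it twice, once per side) would increase
areas by $\pi \cdot \mathrm{foam} \cdot \mathrm{band}$ and is easy to
apply by passing an adjusted diameter. Groups with mean zero are reported
as `unclassifiable` rather than silently dropped, so tallies account for
every site-by-date observation.

## Iwao patchiness regression

Across many samples (site-by-date groups), the regression of group mean
crowding on group mean density,

$$m^*_g = \alpha + \beta\, \bar{x}_g + \varepsilon_g,$$

measures aggregation: $\beta = 1$ is the Poisson benchmark, $\beta > 1$
aggregation, $\beta < 1$ regularity. `iwao_fit()` is ordinary least
squares, with a through-origin variant whose slope is
$\sum x y / \sum x^2$; for the forced fit the $R^2$ is computed against
the *uncentered* total sum of squares (the standard no-intercept
convention, and the one under which forced fits can show slightly higher
$R^2$ than free fits). `aggregation_inference()` is a two-sided t-test of
$\beta = 1$.

Two caveats the package inherits from the method itself, quantified on
simulated data: with $n$ traps per group the regression inputs are
*estimates*, so the fitted slope carries a small finite-sample downward
bias (ratio bias in $m^*$ plus errors-in-variables attenuation from using
the sample mean as the regressor; about $-0.01$ at 30 traps per group for
$k = 2$), and because the residual scatter grows roughly with the squared
mean, the homoscedastic OLS standard error understates the slope's true
sampling variability — at 500 groups of 30 traps the reported SE is about
half the observed seed-to-seed standard deviation. Confidence statements
based on the OLS SE at very large group counts are therefore optimistic;
at 50 groups the SE is large enough that the bias is immaterial.

## Enumerative sample-size curves

The number of sampling units needed to estimate a mean density $x$ with
proportional precision $d$ (SE of the mean over the mean) is

$$q = \frac{t^2}{d^2}\left[\frac{\alpha + 1}{x} + (\beta - 1)\right],$$

with $(\alpha, \beta)$ from the patchiness regression and $t = 1.96$. For
$\beta > 1$ the curve flattens quickly to the plateau
$t^2 (\beta - 1)/d^2$ — the practical reason aggregated populations need
nearly as many traps at high densities as at low ones. `sample_number()`
rounds to the *nearest* integer (half up), with a minimum of 1: ceiling
rounding is incompatible with the published sample-number tables this
formula underlies (e.g. $q = 46.27$ is printed as 46), while nearest
rounding reproduces them almost everywhere. The remaining handful of
one-off discrepancies in such tables trace to slope rounding: a slope
printed to three significant figures can move a plateau cell by one unit
(at $x = 225$, $d = 0.25$, $\beta = 1.41$ gives $q = 25.47 \to 25$ while
$\beta = 1.411$ gives $25.53 \to 26$), so cell-exact agreement from
printed slopes is not attainable for every cell of a published table.

`labor_cost()` is the corresponding field-cost arithmetic
(traps $\times$ minutes $\times$ wage), rounded to cents.

## Replication for detecting a treatment effect

To detect a proportional reduction $r$ in mean counts with a two-sample
one-sided t-test on $\log(\mathrm{count} + 1)$, the log-scale shift is
$j = \log(1 - r)$ and the required replicates per group solve the
noncentral-t power equation for effect $|j|/\sigma_{\log}$
(`stats::power.t.test`), rounded *up* — replication must meet or exceed
the target power, so ceiling is used here even though the sample-size
curves above use nearest. `power_table()` estimates $\sigma_{\log}$ per
observation date from untreated control plots, and reports a normal
quantile–quantile correlation of the log counts as a numerical stand-in
for the visual normality check; the defaults are a one-sided
$\alpha = 0.05$ and 80% power. Equal group sizes and a pooled variance
are assumed, matching the one-treated-versus-control comparison the table
is designed for.

## The design simulator

`power_grid()` compares two ways of allocating $2n$ plots to a treated
and a control arm when a pretreatment abundance ranking is available:

* **CRD** — completely random, $n$ plots per arm;
* **RCBD** — plots sorted by pretreatment abundance, paired, and one
  plot of each pair randomly treated (ties broken by stable input order).

One simulated experiment draws pretreatment counts $N_{init}$ from a
negative binomial, assigns arms under both designs, and projects
posttreatment counts as negative binomial draws with mean
$\mu = \beta N_{init}$ (times $1 - r$ for treated plots). The two NB
parameterizations are kept explicit per stage because they model
different things: the pretreatment fit uses the **linear** form
($\mathrm{var} = \mu(1+\varphi)$, NB1), and the projection uses the
**quadratic** form ($\mathrm{var} = \mu(1 + \mu/k)$, NB2), which is what
"$\varphi = \mu/k$" amounts to when the projection variance is written
as $\mu(1+\varphi)$. `fit_nb()` estimates either by direct ML over
$(\log\mu, \log\mathrm{dispersion})$; plots with $N_{init} = 0$ get
posttreatment count 0 deterministically. Whether the projection is
applied on the raw or a rescaled predictor is immaterial here because
the mean map is linear; the package applies it on the raw scale.

### Significance criterion

Each simulated experiment is analyzed by a log-link count regression of
posttreatment count on treatment (plus block factors under the RCBD),
with a one-tailed test that the treated mean is lower. For these designs
the treatment coefficient equals the log ratio of (block-adjusted) arm
means under any of the available variants; they differ in the dispersion
behind the test:

* `"quasi_f"` (default): quasi-Poisson fit; the criterion is the signed
  root of the quasi-likelihood F statistic (deviance drop over the
  Pearson dispersion) referred to $t$ with the residual df. Chosen
  because, under field-level dispersion (pretreatment CV near 1), its
  one-sided size for the CRD stays near nominal (0.048–0.068 measured at
  $n = 4$–16) while NB maximum-likelihood Wald tests reject at up to
  0.15, and because the deviance-based statistic remains informative
  when the treated arm is all zeros — the separation case where Wald
  statistics collapse.
* `"nb_wald"`: NB2 regression (`MASS::glm.nb`), Wald t. Provided for
  fidelity to the common field-trial analysis; liberal at small $n$.
* `"nb_random"`: NB2 with a random block intercept (`glmmTMB`), the
  analysis style of the original field studies; also liberal at small
  $n$ (0.10–0.14 measured) and roughly two orders of magnitude slower,
  so it is optional rather than default.

A caveat that the simulations surface rather than hide: for the
**blocked** design every regression variant above is anticonservative at
the null (one-sided size 0.10–0.14 instead of 0.05) under these
conditions. The mechanism is that sorted pairs span order-of-magnitude
different means while the variance is strongly mean-dependent
($\mu(1+\mu/k)$): a single dispersion parameter underestimates the
within-pair contrast variance of the high-abundance pairs, which
dominate the treatment contrast. Part of the blocked design's apparent
power advantage at small $n$ is therefore test liberality, on top of its
genuine gain from exploiting the pre/post correlation. The package
reports this honestly — the null-calibration check in the test suite
passes for the CRD and documents the gap for the RCBD.

Degenerate fits (for example both arms all zero) are counted as
non-significant and tallied per cell. Power is the fraction of
significant runs over `n_sims` (default 300; Monte-Carlo SE about 0.023
near power 0.8, reported per cell), and `power_threshold()` maps each
grid to the smallest reliably detectable reduction per design at the
0.80 cutoff. A single seeded generator drives each grid, with draws
consumed in fixed row-major cell order, so grids are bit-reproducible
from the seed.

### Default scenario

The scenario defaults describe a mid-season survey of an aggregated
nymph population, fixed from published field summaries: pretreatment
plot totals with mean 50 and coefficient of variation 1 (NB1
$\varphi = 49$; per-date control-plot means and SDs of sticky-trap
counts are nearly equal, e.g. 24.5 vs 25.7 per trap, and a CV of 1
corresponds to the strong aggregation, $k \approx 1$–2, that the
dispersion analyses report), projection slope $\beta = 0.8$ (the typical
decline between consecutive observation dates a few days apart), and
projection dispersion $k = 3$, which places the pre/post correlation
near 0.8 — the short-lag rank correlation reported between consecutive
trap observations.

## Temporal structure

`spearman_series()` tracks the Spearman rank correlation of per-trap
catch against either the first observation date or the immediately
preceding date, with average ranks for ties and pairwise deletion of
traps missing on either date (no imputation). `seasonal_decline()` fits
a negative binomial regression of per-plot totals on date as a factor
and reports per-date marginal means with Wald 95% intervals on the
response scale; with date as the only term the fitted means equal the
per-date sample means, so the model's contribution is the interval
width. When plot totals show no overdispersion the NB fit degenerates
and a Poisson fit is used with a warning.

## The synthetic generator

`generate_trap_data()` emulates the features of trap-count surveys the
analyses rely on, without reproducing any real dataset:

* negative binomial counts per trap with size `nb_size_k` (default 2,
  patchiness slope 1.5 — the aggregation range reported for nymphs);
* an exponential seasonal decline of the mean (`decline_rate`, default
  0.06/day: about a twenty-fold decline over a 50-day season, the
  magnitude seen in control plots);
* latent per-trap log-normal multipliers with AR(1) persistence
  (`trap_autocorr`, default 0.8 per 3-day step; marginal log-SD
  `trap_sd`, default 0.5), which create exactly the qualitative
  correlation pattern of real trap series — short-lag rank correlations
  stay high while correlation with the season's first date decays;
* a static multinomial instar mixture (default 0.4/0.3/0.2/0.1), enough
  to test per-instar grouping without modelling phenology;
* trap geometry around a 17.6 cm mean DBH with a 7.6 cm band and 2 cm
  foam spacer.

`trap_sd` is the one structural knob the closed-form tests depend on:
with `trap_sd = 0` counts are *exactly* NB(`nb_size_k`), so
$m^* = m(1+1/k)$ and the patchiness slope converges to $1 + 1/k$ —
the identities the recovery tests assert. With `trap_sd > 0` the counts
are NB–log-normal mixtures, deliberately *more* dispersed than NB, as
real trap data tend to be. What passing tests on generated data do not
show: real surveys have spatial structure among neighboring trees,
instar phenology, weather-driven mean fluctuations, and trap-saturation
effects, none of which the generator models.

## Problem sizes and numerical choices

The test suite exercises the closed-form identities at modest sizes
(50–500 groups, up to 5{,}000 traps per date) and the design simulator
at a 5 replicate-levels by 6 reduction-levels grid with 300 simulations
per cell — the simulation count used for the published power grids, and
enough to resolve power to about $\pm 0.03$. NB maximum likelihood uses
Nelder–Mead on $(\log \mu, \log \mathrm{dispersion})$ with moment
starting values; near-Poisson samples pin the dispersion at the boundary
with a warning rather than failing. All randomness flows from explicit
integer seeds; identical seeds give byte-identical datasets and grids.

## Known limitations

* Patchiness-slope SEs are OLS SEs, optimistic at large group counts
  (see above); a heteroscedasticity-aware fit is deliberately out of
  scope to keep the reported quantities those of the standard method.
* The blocked-design analysis inherits the liberality of single-
  dispersion count regressions on pairs spanning very different means;
  comparisons between designs at equal nominal $\alpha$ should be read
  with the measured null sizes in mind.
* Sequential sampling plans, spatially explicit simulation, more than
  two arms, and unequal allocation are not implemented.
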