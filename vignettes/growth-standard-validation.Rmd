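---
title: "Validating canine growth standards: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating canine growth standards: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupgrowth)
```

## The problem

Weight-for-age growth standards give veterinarians the same tool that
paediatric growth charts give physicians: a set of centile curves
against which an individual's growth can be tracked. Before such
standards can be recommended for clinical use they need validation
evidence — that healthy dogs track their centiles, that dogs becoming
overweight or underweight drift visibly across centile lines, and that
disease is reflected in the trajectories. This package implements
that validation pipeline for longitudinal canine bodyweight records:
z-score conversion against sex- and size-class-specific standards,
cohort cleaning, centile-line-crossing statistics, population median
trajectory models, and group comparisons. Because the clinical and
colony datasets such analyses run on are proprietary, the package
ships a synthetic-cohort generator that reproduces their statistical
structure, so every stage is exercised end to end by code alone.

## Growth standards and the LMS representation

A standard is stored per sex and adult size class (I: under 6.5 kg,
II: 6.5 to under 9 kg, III: 9 to under 15 kg, IV: 15 to under 30 kg,
V: 30 to under 40 kg; intervals closed on the left) as age-gridded
LMS parameters: Box-Cox power $L$, median $M$ (kg) and coefficient of
variation $S$. The z-score of weight $w$ at age $t$ is

$$z = \frac{(w/M(t))^{L(t)} - 1}{L(t)\,S(t)} \quad (L \ne 0), \qquad
  z = \frac{\log(w/M(t))}{S(t)} \quad (L = 0),$$

with the exact inverse $w = M(1 + LSz)^{1/L}$ used to draw centile
curves and to synthesize weights. The LMS form was chosen because it
is the canonical parameterization of centile standards (it underlies
the WHO child standards), supports exact two-way conversion, and is
the minimal family capturing age-varying skewness. Standards built
from four-parameter distributions with kurtosis beyond LMS are out of
scope; for such references LMS z-scores are an approximation in the
far tails.

Between grid ages, $M$ is interpolated with a monotone
piecewise-cubic (Fritsch–Carlson) rule — median growth must not
overshoot or dip between grid points — and $L$, $S$ linearly. Ages
outside the grid are an error, never an extrapolation: the standards
are defined only for the growth phase. Ages are decimal years
throughout, with 1 year = 52.1775 weeks applied only at I/O.

The default chart uses the nine-centile set 0.4, 2, 9, 25, 50, 75,
91, 98, 99.6 percent, whose lines are equally spaced two-thirds of a
z-score apart; the band between adjacent lines is one "channel".

## Cleaning

Cleaning runs per sex-by-size-class stratum, in a fixed order:

1. **Size-class assignment.** Pedigree dogs map through a
   user-supplied breed table; mixed-breed dogs are classed by final
   adult weight, or excluded when none is recorded (or when it is 40
   kg or more, above the charted range).
2. **Eligibility.** Clinic mode requires at least 4 weights, spanning
   at least 3 months, between 12 weeks and 2 years of age; colony
   mode requires a single weight between 0.20 and 2.25 years.
3. **Population outliers.** Weights are binned into 40 equal-width
   age categories; per bin we compute the median and Tukey
   box-whisker statistics (type-7 quartiles; whiskers at the most
   extreme datum within 1.5 interquartile ranges of the quartiles —
   the exploratory-data-analysis convention, and the default of
   mainstream statistical software). Three loess curves (tricube
   weights, span 0.5 over the bin mid-ages, sparse bins down-weighted
   by $\sqrt{n}$) are fitted: through the medians, and through the
   median plus/minus 150 percent of the respective whisker length,
   whisker lengths measured from the median so the two bounds can be
   asymmetric. A record strictly outside the smoothed bounds at its
   age (linear interpolation between bin mids) is flagged; a record
   exactly on a bound is kept.
4. **Individual gross outliers.** Within each dog's z-score series, a
   visit whose z deviates from the median z of its nearest neighbours
   (up to 2 on each side, clipped at the ends) by more than
   $\tau = 1.5$ z is flagged. 1.5 z is more than two channel widths
   of instantaneous jump — physiologically implausible between
   adjacent visits — while smooth drifts of several channels over the
   growth phase pass untouched. The rule needs at least 3 visits.
5. **Extreme trajectories.** A dog whose kept visits lie entirely
   above the 99.6 percent centile or entirely below the 0.4 percent
   centile is excluded: the most plausible explanation is a
   misidentified breed, i.e. the wrong chart.

Every record ends in exactly one state (kept, population outlier,
individual outlier, or belonging to an excluded dog), and the
cleaning report reconciles all counts.

Two properties of this procedure are worth knowing. First, because
the LMS transform is convex in weight, the Tukey fence computed in
kilograms maps to an asymmetric band on the z scale — roughly
$+2.4\sigma$ above and $-3.3\sigma$ below the median for a cohort
with z spread $\sigma$. The population stage therefore always trims
the extreme upper tail (about 0.5–1 percent) of a widely spread but
perfectly clean cohort; that is inherent to box-whisker bounds, not a
defect, and it is why the package's consistency checks assert zero
*individual-level* flags and zero crossings on noiseless cohorts
rather than zero flags of any kind. Second, bin statistics need
support: with fewer than about 50 records per bin the whisker
estimates are noisy enough to move the bounds materially. Strata
with fewer than `min_stratum_records` (default 50) records skip the
population stage entirely with a warning — estimating population
bounds from a handful of dogs would be meaningless — and strata whose
usable bins number fewer than 4 do the same. The package's
validation cohorts therefore simulate 1,000 dogs within a single
stratum (about 200 records per bin), emulating the data density the
procedure is designed for, rather than spreading them thinly across
all ten sex-by-class strata.

The smoothing span (0.5) and the choice to smooth all three curves
(medians and both bound curves) are configurable; the underlying
procedure is usually described too tersely to pin either down, and
these defaults are documented as interpretation.

## Centile-line crossings

For each dog the starting point is the first kept visit's z-score
$z_1$. The upward count is the maximum over subsequent visits $j$ of
the number of chart lines lying strictly between $z_1$ and $z_j$
(above it); the downward count is symmetric; the total is the larger
of the two — the crossing count at the most differential point away
from the start. Strict inequalities encode the tie rule: a visit
sitting exactly on a line has reached it, not crossed it. Up and
down are counted independently (a dog can cross both ways), matching
the separate columns of crossing frequency tables, and counts are
binned as 0, 1, 2, more-than-2. Dogs with fewer than 2 usable visits
are reported unscorable rather than zero-crossing, to avoid biasing
the 0 bin. Counted from a fixed starting point, "max over visits of
lines crossed" and "lines crossed at the single most distant visit"
coincide, so the ambiguity between those two readings is immaterial.

The per-dog net count $d = \text{up} - \text{down}$ is compared
across groups with a one-way ANOVA and Tukey honest-significant-
difference contrasts; when several crossing tables are analysed in
one run a family-level Bonferroni factor can be applied on top.

## Median z trajectories: penalized B-splines with scaled-t errors

The population median z-score as a function of age is modelled as

$$z_i = \mu(t_i) + \varepsilon_i, \qquad
  \varepsilon_i \sim \sigma\, t_\nu, \qquad
  \mu(t) = \sum_k \beta_k B_k(t),$$

with $B_k$ a cubic B-spline basis on 20 equally spaced interior knots
(knots extended beyond the boundary in the Eilers–Marx fashion, so
the penalty null space maps exactly onto straight lines) and a
second-order difference penalty $\lambda \sum_k (\Delta^2\beta_k)^2$
— a P-spline. Heavy-tailed scaled-t errors make the fitted location
a robust, median-like centre: stray extreme z-scores that survive
cleaning do not drag the curve. Fitting is iteratively reweighted
penalized least squares with the t weight function
$w_i = (\nu+1)/(\nu + r_i^2/\sigma^2)$, an EM update for $\sigma$,
convergence when coefficients move less than $10^{-6}$ (at most 200
iterations). The t degrees of freedom $\nu$ are profiled over the
grid $\{3,4,5,6,8,10,15,20,30,\infty\}$ — stable at these sample
sizes, with $\infty$ recovering the Gaussian fit — and the smoothing
parameter minimises the Schwarz Bayes Criterion

$$\mathrm{SBC} = -2\,\log L + \log(n)\,(\mathrm{edf} + 2),$$

over a 40-point log-spaced $\lambda$ grid, where edf is the trace of
the smoother matrix and the 2 counts $(\sigma, \nu)$. The search
runs a Gaussian $\lambda$ scan, profiles $\nu$ at its optimum, then
rescans $\lambda$ at the chosen $\nu$ with warm starts. Strata
(groups, size classes) can be fitted as separate smooths (the
interaction case) or as a shared smooth with additive unpenalized
offsets. An optional age truncation (1.15 years in the colony
preset, where older data run thin) restricts the fit domain. Only
the location is smoothed; modelling the scale or shape parameters as
functions of age is deliberately out of scope, since the analyses
report median curves.

Model fit is assessed with normalized quantile residuals
$r_q = \Phi^{-1}(F_t(r/\sigma; \nu))$, which are standard normal
under a correct model: worm plots (detrended QQ series per age panel
with a 95 percent pointwise envelope; a panel-wide slope signals
misfit scale, curvature signals skewness) and Q statistics (per age
bin, z-statistics for the mean, variance via the Wilson–Hilferty
transform, skewness via D'Agostino, kurtosis via Anscombe–Glynn;
each moment's bin statistics aggregate as $Q = \sum_g z_g^2$ against
$\chi^2$ with one degree of freedom per bin). The kurtosis
transform is the least accurate below about 20 residuals per bin, so
the calibration checks use bins of 100.

## Group means: random-intercept mixed model

Mean z-scores are compared across groups with
$z_{ij} = \beta_{g(i)} + u_i + \epsilon_{ij}$,
$u_i \sim N(0, \sigma_u^2)$ (dog as a random factor), fitted by
REML, with all pairwise Tukey-adjusted contrasts on
Satterthwaite-approximated degrees of freedom (documented as
approximate; with a single record per dog the random intercept is
unidentifiable and the model collapses, exactly, to the one-way
ANOVA with Tukey contrasts, tagged `tukey_anova`). A boundary
estimate $\hat\sigma_u = 0$ triggers a warning and conservative
degrees of freedom.

## The synthetic-data generator

The generator works on the z scale so profiles are size-class
invariant. A dog draws a starting z from $N(\mu_0, \sigma_0^2)$
(default $\sigma_0 = 1$: the cohort matches the reference
population's spread), visit ages on an even grid over its age window
with uniform jitter, a stationary AR(1) visit-noise series (default
$\rho = 0.6$, $\sigma_v = 0.25$ z), and a drift — none, linear in
age, or saturating — scaled to a terminal displacement $\Delta z$ at
age 2. Weights come through the inverse LMS transform of a
synthetic standard whose median is a Gompertz curve
$M(t) = A e^{-b e^{-kt}}$ reaching 99 percent of adult weight $A$ by
age 2 (growth rate $k$ decreasing with size class), with $S$ falling
from 0.18 to 0.10 over the grid and constant $L = -0.2$ (mild right
skew typical of bodyweight).

The preset profiles encode the growth patterns the analyses look
for: healthy (no drift), overweight $\Delta = +1.4$ z, obese
$\Delta = +2.2$ z, underweight $\Delta = -1.2$ z, retarded growth
(start $-0.8$ z, shallow saturating fall), nutritional
osteodystrophy (start $-1.4$ z, falling a further 1.0 z),
accelerated growth (start $+0.4$ z, $\Delta = +0.5$), and feeding
planes at 118, 100 and 88 percent of optimal intake mapped to
$\Delta = +1.3, 0, -0.7$ z over a first-year window. These were
chosen once to mirror the described clinical patterns qualitatively
— one channel is 2/3 z, so the obese preset crosses about three
lines — not to reproduce any printed percentage. With the defaults,
healthy cohorts are dominated by 0–1 line crossings, and the AR(1)
noise keeps visit-to-visit jitter well below the gross-outlier
threshold.

Contamination injection perturbs a random subset of records with the
error kinds weight data actually exhibit — doubling, halving, pounds
entered as kilograms (×0.4536), decimal shifts (×10, ×0.1) — and
returns a truth table, making the cleaning sensitivity and
false-positive rate self-scoring. Cohort simulation derives a
substream seed per dog from the global seed by counter, so enlarging
a cohort never reshuffles the dogs already generated.

What the generator does **not** emulate: breed demographics, neutering
effects, seasonal visit patterns, age-dependent heteroscedasticity of
the visit noise, and informative visit timing (sick dogs visiting more
often). Passing recovery tests on these cohorts shows the pipeline's
statistical machinery is correct at realistic densities; it does not
certify performance on any particular clinical database.

## Validation problem sizes

The test suite and the acceptance script rerun every stage from
scratch at these scales, chosen to make the Monte Carlo noise small
relative to each tolerance while keeping a full run in minutes:
1,000 random parameter draws for the LMS round trip (tolerance
$10^{-9}$); 1,000 random trajectories against a brute-force
(visit × line) crossing oracle (exact); a 1,000-dog single-stratum
cohort with 2 percent injected contamination (sensitivity at least
0.95, false-positive rate at most 0.02); 500 dogs per group at
drifts $\{+1.33, 0, -0.67\}$ z for curve recovery within 0.15 z over
0.3–2.0 years; 500 replicates of 30 dogs × 10 visits per group
($\sigma_u = 0.5$, $\sigma_e = 0.3$, true difference 1.0 z) for
Tukey interval coverage in [0.93, 0.97] and mean bias at most
0.03 z; and 1,000 null replicates for the Q-test and ANOVA
calibration (rejection within Monte Carlo error of 0.05).

## Known limitations

* The gross-outlier rule for individual curves and the exact loess
  span are interpretations of a tersely described procedure; both are
  configurable and their defaults documented above.
* The upper population bound sits nearer the median (on the z scale)
  than the lower one, a consequence of computing symmetric-in-kg
  fences on a right-skewed weight distribution.
* The trajectory model smooths location only; σ and ν are global per
  fit.
* Mixed-model degrees of freedom are Satterthwaite approximations;
  with very few dogs per group the Tukey intervals are approximate.
* Synthetic standards are stand-ins with plausible shapes, not
  estimates from any reference population.

## A worked example

```{r example, eval = FALSE}
standards <- make_standard_set(seed = 11)
cohort <- simulate_cohort(standards["male.III"], default_profiles(),
                          c(healthy = 0.6, obese = 0.4),
                          n_dogs = 400, seed = 1)
cleaned <- clean_dataset(cohort$records, standards, mode = "clinic")
crossings <- cohort_crossings(cleaned$clean, centile_chart(),
                              group_col = "group")
tabulate_crossings(crossings)
fits <- fit_z_curve(cleaned$clean, by = "group")
predict_median(fits$obese, c(0.5, 1.0, 1.5, 2.0))
mixed_model_compare(cleaned$clean, "group")$contrasts
```
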