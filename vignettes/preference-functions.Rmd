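---
title: "Preference functions from repeated shelter-choice trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preference functions from repeated shelter-choice trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellprefs)
```

## The problem

Shell-dwelling cichlids such as *Neolamprologus multifasciatus* occupy empty
gastropod shells as shelters and brood chambers. Because the structural
attributes of natural shells — overall size, shell length, aperture width —
grow in or near isometry, they are tightly correlated in the wild, and
observational data cannot tell which attribute actually drives shelter
choice. The experimental answer is to offer each fish an ordered array of
replica shells in which a single attribute is varied (seven levels at
−3 … +3 population s.d. around the wild mean, one manipulated attribute per
task) across repeated trials, and to estimate each individual's *preference
function*: a curve mapping the attribute value to its attractiveness.

`shellprefs` implements the full analysis chain for such experiments:
per-individual spline preference curves, the traits *peak*, *strength* and
*tolerance* extracted from them, a simulated random-choice null
distribution that serves as the reference group, heteroscedastic group
models with Dunnett-type and all-pairs contrasts, and a binomial logistic
model for binary (shell-chirality) choice tasks. Because per-fish raw data
of such experiments are typically not deposited, the package also contains
a first-class synthetic-data generator that emulates the study conditions,
so every stage runs, and is tested, without any external data.

## Preference curves and traits

Each fish contributes a vector of choice counts over the $k = 7$ ordered
stimulus levels (a fish is included only if it successfully chose a shell
in at least three trials; fish with fewer successful choices are excluded,
not fitted). The curve is a penalized cubic regression spline (a Gaussian
generalized additive model of counts on level, fitted with `mgcv`),
evaluated on a uniform 501-point grid over the level range, with negative
fitted values clipped to zero since attractiveness is estimated from
non-negative counts.

**Smoothing policy.** The default applies one common penalty
(`sp = 0.5`, giving roughly five effective degrees of freedom at seven
levels) to every individual. We initially selected the penalty per curve
by GCV, constrained to effective degrees of freedom in $[2, k-1]$, but
with only seven observations GCV is erratic in a way that matters
scientifically: it smooths a single-level count spike (the signature of a
sharp preference) almost to a straight line while barely smoothing diffuse
counts, so the extracted strength of a sharp chooser could fall *below*
that of an indifferent one. A common penalty — the way PFunc-style
analyses apply one smoothing setting across all splines — makes the fitted
flexibility identical across individuals and across the random-choice
null, restoring monotonicity: in simulations, increasing choice sharpness
strictly increases mean strength and decreases mean tolerance.
Per-curve GCV (with the edf constraint and a smoothing-parameter window of
$[0.05, 5]$) and fully explicit penalties remain available through the
`smoothing` argument; a very large explicit penalty reproduces the
least-squares straight line through the counts.

The three traits are:

* **peak** — the grid argmax of the curve. Ties (heights within $10^{-9}$
  of the maximum, e.g. a flat curve or a plateau) are broken by the
  midpoint of the tying set, so a flat curve peaks at the centre of the
  range. Deterministic and symmetric.
* **strength** — $(h_{\max} - \bar h)/\bar h$ with $\bar h$ the grid-mean
  height: a scale-invariant measure of how sharply attractiveness falls
  away from the peak. Zero for a flat (or zero) curve; unchanged when all
  counts are multiplied by a constant. Absolute values are specific to
  this operationalization — only comparisons against the matched
  random-choice null are meaningful, which is how the trait is used.
* **tolerance** — the width of the level range where the curve stays at or
  above a fraction (default one half) of peak height, measured on the grid
  with linear interpolation at threshold crossings. The *broad* definition
  (default) sums all such regions; *strict* takes the contiguous region
  containing the peak, so strict ≤ broad always. A flat or zero curve has
  tolerance equal to the full range (6 s.d. for levels −3 … +3).

The flat-curve conventions (peak at the range midpoint, strength 0,
tolerance equal to the full range) make the random-choice null
well-defined even for degenerate fits.

## The random-choice null

Whether observed traits are non-random is judged against a simulated
reference: 1000 replicates of a fish making four uniform random choices
among the seven options, each replicate fitted and measured exactly like a
real fish (`simulate_random_traits()`). Null replicates always make
exactly four successful choices — the no-choice process is not part of the
null. The null peak distribution is symmetric about the centre of the
range; its mean and skewness are monitored by the tests.

Two comparison routes are provided. The parametric route enters the null
replicates as independent rows of a `RANDOM` reference group in the group
models below. The nonparametric companion (`empirical_comparison()`)
bootstrap-resamples the null into groups of the observed size and reports
an add-one-corrected empirical p-value, never exactly zero at finite
resamples.

## Group models and contrasts

`fit_group_model()` fits a trait against the choice-task factor (plus,
optionally, mean-centred body size and the task × size interaction) with
either a pooled residual variance (`lm`) or one residual variance per task
(`nlme::gls` with `varIdent`), on the identity or ln scale. Estimation is
REML by default: with two groups and per-group variances the squared
t-statistic of the group term then equals the Welch two-sample statistic
exactly, an identity the tests assert at $10^{-6}$. Likelihood-ratio tests
require ML fits and `lrt()` refuses REML inputs. When the interaction is
requested it is screened by an ML likelihood-ratio test and dropped when
non-significant. The pipeline chooses the variance structure with a
Brown-Forsythe (median-based Levene) test on each trait at the 5% level;
degenerate small groups (zero within-group variance) that defeat the
variance model fall back to the pooled fit with a logged message.

Dunnett-type many-to-one contrasts of every task against the `RANDOM`
group — and Tukey-style all-pairs contrasts among tasks — use a
single-step max-|t| adjustment computed by Monte Carlo: contrast
statistics are sampled from their joint distribution (correlation from the
model's coefficient covariance), and the adjusted p-value of a contrast is
the probability that the family-wise maximum absolute statistic exceeds
its observed value. When the fit has finite residual degrees of freedom
the normal draws are scaled by a shared chi-square factor (i.e. Monte
Carlo over the multivariate t rather than the multivariate normal); with
small per-group samples the pure-normal version is anticonservative, and
with the scaling the family-wise error rate under a simulated global null
is 0.05 within Monte-Carlo error (asserted by the tests at ±0.01 with
$10^4$ replicates). Adjusted p-values are clamped to be at least the raw
ones. `multcomp::glht` serves as an independent oracle in the test suite,
never as the implementation.

The binary chirality task is modelled by a grouped binomial logistic
regression fitted with a hand-written Newton–Raphson
(`fit_binary_logit()`), with Wald standard errors from the inverse
information. The intercept-only MLE has the closed form $\ln(s/f)$ with
s.e. $\sqrt{1/s + 1/f}$, and the two-group coefficient is the log odds
ratio; the Newton fit reproduces both to $10^{-6}$ and `stats::glm` is the
independent cross-check. On the published choice counts (16/20 choosing
females and 12/14 choosing males took the right-coiled replica) the
intercept-only fit gives $1.54 \pm 0.45$, $z = 3.42$, and the sex model a
coefficient of magnitude $0.41 \pm 0.95$, $z = 0.43$; the sex coefficient
is reported relative to the female reference level and compared by
magnitude, since coding conventions differ.

## What the synthetic generator emulates

The generator reproduces the study conditions so that the pipeline's
behavior can be verified end to end:

* **Wild shells** (`generate_shell_population()`): 113 shells whose length
  is log-normal with mean 43.2 mm and s.d. 5.8 mm; log width and log
  aperture are slope-1 (isometric) affine functions of log length plus
  independent multiplicative noise, with offsets calibrated so the width
  and aperture means are 32.3 mm and 15.0 mm. The default noise is 1%
  (`isometry_noise = 0.01`). This value is deliberately small: with noise
  attached to width and aperture only, the width–aperture OLS slope is
  attenuated by $\sigma^2/(\sigma^2 + \tau^2)$, and a $\tau$ large enough
  to pull the first principal component down to the ~90% observed in wild
  samples would make that slope's 95% CI exclude 1 at $n = 113$ —
  contradicting the observed isometry. We prioritize isometry (all slopes
  statistically indistinguishable from 1) and accept a higher PC1 fraction
  (~99%) than wild data show; the PC1 check is a lower bound (≥ 0.85),
  not an exact target.
* **Choice trials** (`generate_choice_dataset()`): four tasks × (10 males
  + 10 females) × 4 trials. Body sizes are normal, 36.5 ± 4.5 mm (males)
  and 30.1 ± 2.4 mm (females), truncated at 0.1 mm (a negligible
  correction at these parameters). The latent preference is a
  Gaussian-bump utility $u(x) = -((x-\mu)/\omega)^2$ turned into choice
  probabilities by a softmax with sharpness $\beta$; trials end with no
  choice with probability 0.1, independent of the stimulus levels (no
  dependence is documented). This minimal family produces flat
  ($\beta = 0$), closed ($\mu$ inside the range) and open-ended
  ($\mu \geq +3$) preferences. The per-task defaults
  (`default_task_preferences()`) encode strong open-ended preferences for
  size and intactness, an intermediate one for length and a weak broad one
  for aperture width, mirroring the qualitative ordering reported across
  such tasks.
* **Chirality data** (`generate_chirality_dataset()`): Bernoulli
  two-choice outcomes per sex, defaults calibrated to 16/20 (females) and
  12/14 (males) right-coiled choices with a 30% male no-choice rate.

What the generator does *not* emulate: social-stimulus effects, tank
geometry, digging behaviour, choice latency within the 20-hour window,
position effects (shell positions were randomized between trials), or any
dependence of no-choice on the offered levels. Passing tests therefore
demonstrate that the estimators behave correctly under the stated
stochastic model, not that real fish obey that model.

## Numerical choices and conventions

* Quartiles in morphometric summaries use the linear-interpolation
  convention (`quantile` type 7), documented because published summary
  tables rarely state one.
* The curve grid has 501 points; doubling it moves every trait by less
  than one coarse grid step (tested).
* The edf cap $k - 1$ is enforced, when a tiny level count would allow
  interpolation, by increasing the penalty until the cap is met.
* Monte-Carlo sizes default to $10^5$ draws for contrast adjustment and
  $10^4$ bootstrap resamples for empirical p-values; both are seeded and
  configurable.
* Every stochastic stage of `run_pipeline()` derives its own sub-seed from
  one master seed (kept within 32-bit integer range), and the run manifest
  records all seeds plus an MD5 checksum per output file, so a single
  integer reproduces the entire run byte-for-byte.
* Problem sizes used by the test-suite calibration experiments — 1000 null
  replicates, cohorts of 200 fish for recovery, $10^4$ replicates for the
  family-wise-error calibration — were chosen as the smallest sizes at
  which the Monte-Carlo error is comfortably below the tolerance being
  asserted.

## Known limitations

* Strength and tolerance values are specific to this package's
  operationalization and smoothing policy; they are not numerically
  interchangeable with PFunc's internal scales. Comparisons against the
  matched random-choice null (fitted with the same policy) are the
  meaningful quantities.
* The per-group variance model estimates one variance per task level only;
  no other variance structures are exposed.
* The Dunnett adjustment uses a single shared chi-square scale across
  contrasts, an approximation when group variances differ (exact for the
  pooled model).
* Exact replication of published per-task trait means is out of reach by
  design: the per-fish data behind them are not deposited, so the package
  validates machinery (closed forms, calibration, direction and sign
  patterns) rather than reproducing those tables.

## A minimal worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
run <- run_pipeline(cfg, out_dir = "shellprefs-run")
run$contrasts$peak$dunnett       # each task vs the random-choice group
run$chirality$overall            # pooled right- vs left-coiled preference
```
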