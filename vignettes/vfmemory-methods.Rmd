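---
title: "Methods: source-monitoring memory by vertical visual field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-monitoring memory by vertical visual field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfmemory)
```

## The scientific problem

`vfmemory` analyzes source-monitoring experiments in which everyday objects
are encoded in the upper or lower visual field and memory is probed in two
steps: an old/new judgment (item memory) and, after an "old" answer, an
up/down judgment about where the object had appeared (spatial, or source,
memory). The standard design has two groups (young and older adults, 25 and
20 participants), eight blocks, and per participant 80 up-old, 80 down-old,
and 80 new test trials. The package covers the full analysis chain:
eye-tracking quality control, Pr discrimination indices, a dual-process
source-item multinomial processing tree (MPT) fitted by maximum likelihood
and by latent-trait hierarchical Bayes, and kinetic-perimetry hemifield
geometry summarized by the vertical meridian asymmetry (VMA) index.

## Discrimination indices

Item Pr is the Snodgrass–Corwin index, hit rate minus false-alarm rate.
Source Pr is (correct − incorrect source judgments) / 160, where 160 =
8 blocks × 20 re-presented objects is the number of source prompts a
perfect item-memory performer would face; the fixed denominator prevents a
conservative responder (who answers "new" often and therefore sees few
source prompts) from being advantaged. The constant is exposed through
`source_trials_total()` and overridable for other designs.

Two counting conventions are deliberate and tested:

* Hit/FA/CR rates use **all presented trials** of the relevant type as
  denominator, so missed trials depress the rate rather than being dropped
  (which is why FA + CR need not sum to 100%).
* Source correct/incorrect are counted only among true-old trials answered
  "old" with a source judgment — the only trials on which a source prompt
  exists.

Missed trials are excluded from MPT frequency tables and tallied in
`n_miss`: the tree has three answer categories and no "no response"
branch; misses are a separate phenomenon analyzed outside this package's
scope. A trial marked "old" without a source response is treated as
malformed input, not as a miss, because the task forces a source judgment
after every "old" answer.

## The source-item MPT

Responses from the three trial types (UP, DOWN, NEW trees) fall in three
categories (old&up, old&down, new). Six probabilities generate them:

| parameter | meaning |
|---|---|
| $S_{up}, S_{down}$ | recollection: item and its position retrieved jointly |
| $I_{up}, I_{down}$ | familiarity: item recognized after recollection fails |
| $o$ | guessing "old" with no memory signal |
| $g$ | guessing "up" when the source must be guessed |

For the UP tree:

$$P(\text{old\&up}) = S_{up} + (1-S_{up})I_{up}g + (1-S_{up})(1-I_{up})og$$
$$P(\text{old\&down}) = (1-S_{up})I_{up}(1-g) + (1-S_{up})(1-I_{up})o(1-g)$$
$$P(\text{new}) = (1-S_{up})(1-I_{up})(1-o)$$

the DOWN tree mirrors it (recollection leads to old&down; $g$ is still the
probability of guessing "up"), and the NEW tree is pure guessing:
$og$, $o(1-g)$, $1-o$.

One modelling choice deserves emphasis: **$g$ governs the source guess both
after familiarity succeeds and after an uninformed "old" guess.** A
narrower reading would attach $g$ only to the no-memory branch, but the
dual-process topology requires a source guess whenever the item is called
"old" without recollection of its position, and a single shared $g$ is the
conventional, identifiable choice. Likewise one $o$ and one $g$ are shared
across trees within a fit, and groups are fitted separately.

The model is just-identified (six free category probabilities, six
parameters), which yields two strong internal checks used throughout the
tests: the closed-form moment estimator (`moment_estimator()`, an algebraic
inversion of the observed proportions) must agree with the numeric MLE
(`fit_mle()`) to 1e-6 on interior optima, and $G^2$ at the MLE must vanish.

### Numerical choices in the MLE

Optimization runs on the logit scale with L-BFGS-B, probabilities clipped
at 1e-9 from the boundary to keep the likelihood finite, 10 seeded random
starts plus the moment estimate and any user start. Ties across starts
break by highest log-likelihood, then lowest parameter L2 norm. Because
the likelihood is extremely flat around a just-identified optimum, the
winning start is polished once with tight tolerances; without this, tied
starts can sit ~1e-6 apart in parameters. Boundary estimates (e.g. $o = 0$
when no "old" response ever occurs) are reported with a per-parameter
boundary flag rather than an error.

## Latent-trait hierarchical estimation

Participant $i$'s parameter $p$ obeys
$\theta_{ip} = \Phi(\mu_p + \beta_p x_i + \xi_p \eta_{ip})$ with
$\eta_i \sim \mathrm{MVN}(0, Q)$: individual parameters are correlated
probit-normal deviations around group means, the covariance of the
probit-scale effects being $\Sigma = \mathrm{diag}(\xi)\,Q\,\mathrm{diag}(\xi)$.
Priors are the common weakly-informative latent-trait defaults: standard
normal on $\mu_p$ (and on the optional covariate slope $\beta_p$; the
covariate, e.g. a 0/1 sex indicator, enters as an additive probit-scale
shift and is off by default in synthetic runs), scaled inverse-Wishart on
$\Sigma$ ($Q \sim \mathrm{IW}(I, P+1)$ with uniform(0, 10) scale factors
$\xi_p$, which keeps the $Q$ update conjugate while the scales absorb the
IW prior's variance bias).

Sampling is Metropolis-within-Gibbs, written for seeded, draw-for-draw
reproducibility:

* conjugate inverse-Wishart update for $Q$ given $\eta$ (via
  `stats::rWishart` on the precision);
* adaptive random-walk Metropolis for $\mu$, $\beta$, $\xi$ and $\eta$
  ($\eta$ updated component-wise but vectorized across participants, who
  are conditionally independent); proposal scales adapt toward 44%
  acceptance during burn-in only, so the post-burn-in chain is Markovian;
* at least two chains (chain $c$ seeded with `seed + c − 1`), since the
  convergence diagnostic is split R-hat on the probability-scale group
  means $\Phi(\mu_p)$, with < 1.05 the conventional bound. A fit failing
  the bound is returned flagged, never silently discarded.

Study-scale MCMC defaults are 50,000 iterations, 10,000 burn-in, thinning
10. All package tests and the analysis scripts run a reduced desk scale —
5,000 iterations, 1,000 burn-in, thinning 5, two chains — chosen so a full
two-group fit completes in well under a minute while still passing the
split R-hat bound on well-behaved synthetic cohorts.

### Posterior predictive checks

$T_1$ measures fit of mean category frequencies, $T_2$ fit of the
across-participant covariance of category frequencies. For each retained
draw, a replicate cohort is simulated from the individual-level parameters;
the statistic compares a dataset (observed or replicate) against its
posterior-expected value, and the p-value is the fraction of draws where
the replicate statistic is at least the observed one. The distance is the
summed squared deviation (for $T_2$, summed over all entries of the 9×9
covariance matrix, with the model-implied covariance computed as the
between-participant covariance of expected frequencies plus the mean
within-participant multinomial covariance). p-values above 0.05 are read
as adequate fit. The squared-deviation distance is this package's
documented choice; other distances would serve equally.

### Group differences

Group posteriors are estimated independently; differences (young minus
older) are computed per parameter by pairing probability-scale group-mean
draws after a seeded random shuffle — the pairing is arbitrary for
independent posteriors, and shuffling removes any accidental within-chain
alignment. Intervals are central (equal-tailed) 95% credible intervals;
the "credible" flag is set when the interval excludes zero. Draw-count
mismatches resolve by seeded subsampling of the longer set.

### Probit transforms in the tails

`probit()`/`inv_probit()` round-trip to ~1e-15 across (−6, 6) when the
probability is carried on the log scale (`log_p = TRUE`). On the raw
probability scale the upper tail is limited to ~1e-8 near +6 by the
spacing of double-precision numbers at $p \approx 1$ — an information
limit of the representation, not of the algorithm — and the property
tests assert exactly that structure.

## Gaze quality control

Fixations are detected with a velocity-threshold algorithm: symmetric-
difference velocities per axis, a robust median-based dispersion estimate
$\sqrt{\mathrm{median}(v^2) - \mathrm{median}(v)^2}$, and an elliptic
threshold at `lambda` (default 6) dispersions, the classic microsaccade
detector. Maximal non-saccadic runs become fixations; fixations under
100 ms are removed before anything else. Stability is graded with the
Fujii 2/4 method on fixation **centroids** (not raw samples), pooled
across encoding phases per participant: stable when ≥ 75% lie within 2°,
relatively unstable when not but ≥ 75% lie within 4°, unstable — and
excluded — when fewer than 75% lie within 4°. Boundaries are inclusive: a
distance of exactly the radius is inside, and exactly 75% meets the
criterion ("less than 75%" excludes strictly below). Exclusion depends
only on the 4° percentage, and the QC stage runs before any model sees
the data.

## Perimetry geometry

An isopter (polar points, one radius per meridian angle) becomes a polygon
by angle-sorting and linear closure; the polygon is clipped against the
horizontal meridian with intersection points inserted, and each hemifield
area comes from the shoelace formula. Unique sorted angles with
non-negative radii make the polygon star-shaped about fixation, hence
simple. Linear interpolation between sampled meridians is the documented
choice; its density-dependent error is tested against analytic shapes
(a circle sampled every 15° reproduces hemifield areas within 2%, an
ellipse sampled every 2° within 1%).

$\mathrm{VMA} = (A_{lower} - A_{upper}) / \mathrm{mean}(A_{lower},
A_{upper}) \times 100$, positive when the lower field is larger, bounded
in [−200, 200], undefined (flagged, never NaN) when both areas are zero.
VMA is computed per eye and per isopter; I1e charts are parsed but
excluded from the default analysis set (areas are analyzed for V1e, III1e,
II1e), and cross-eye aggregation is left to the caller since no single
combination rule is canonical.

## The synthetic-data generator

`gen_cohort()` emulates the study's statistical structure: per participant
a probit-scale latent vector drawn from the group multivariate normal
(default per-parameter SD 0.4, exchangeable correlation 0.2), mapped to
MPT parameters, then per-tree categorical draws, then an independent
Bernoulli miss process (default rate 0.02, configurable per group since
older adults miss more). Group-mean defaults follow the qualitative
empirical pattern — upper-field recollection reduced by 0.20 in the older
group, a smaller lower-field reduction, familiarity near-preserved, a
slightly lower "old"-guessing rate in older adults. The default guessing
rates ($o$ = 0.26/0.20) are set high enough that the NEW tree contains
ample "old" responses, keeping $g$ well identified in every synthetic
cohort; real cohorts with very low false-alarm rates identify $g$ less
sharply. Parameter-recovery runs use a smaller latent SD (0.2): at SD 0.4
a 25-participant cohort's realized mean deviates from the population mean
by up to ~0.07 on the probability scale, which would conflate cohort
sampling error with estimator error in a 0.10 recovery bound.

`gen_gaze()` builds 1000-Hz streams of still epochs (Gaussian jitter,
default 0.02°) joined by instantaneous jumps, visiting epoch centers in a
long-stride order so each jump is saccade-sized; epoch radii are chosen so
the centroid pattern classifies into the requested Fujii category under
the default detector settings. `gen_isopters()` scales lower-hemifield
radii and then calibrates that scale by bisection against the package's
own `hemifield_areas()`, so the achieved VMA matches the target through
the same polygonal pipeline that analyzes it (radial jitter included).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: reaction-time structure (placeholder lognormal
draws), item-identity effects and pre-experimental source expectations,
encoding-phase behavior, smooth pursuit or blinks in gaze, and
device-specific perimetry noise. Tests on synthetic data validate the
estimators' correctness and calibration, not the substantive findings.

## Problem sizes and limitations

Test and script sizes were chosen as the package's own desk scale: unit
tests use cohorts of 2–12 participants with 8–80 trials per tree; the
recovery run uses the full 25 + 20 design at 80 trials per tree with
5,000-iteration chains; law-of-large-numbers checks use single
participants with 10^5 trials; the coverage property uses 20 replications
of an 8-participant cohort. Known limitations: the sampler is a bespoke
random-walk scheme, adequate at these dimensions but slower-mixing than
gradient-based samplers for much larger cohorts; WAIC is not computed; the
aggregate extended MPT with explicit age×position difference parameters
and the mixed-model analyses of Pr, misses, and reaction times are outside
the package's scope.
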