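---
title: "Modelling moral cost-benefit decisions with a multi-attribute DDM"
author: "moralddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling moral cost-benefit decisions with a multi-attribute DDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralddm)
```

## The task and the model

The package targets two-alternative forced choices in which a *low* option
(fewer electric shocks, less money) competes with a *high* option (more
shocks, more money). Conditions vary the *source* of the money — dirty
(obtained by shocking another person) versus clean (obtained by shocking
oneself) — and its *destination* — personal profit versus a charitable
donation. The scientific question is *how* these moral features change
decisions: by changing the valuation of the options' attributes, or by
biasing the response before the attributes are even seen.

Decisions and response times are modelled jointly with a multi-attribute
drift-diffusion model (DDM). Evidence accumulates from a starting point
$z \cdot a$ between a lower boundary at 0 (choose low) and an upper boundary
at $a$ (choose high), with drift

$$v = \beta_m \,\Delta m + \beta_s \,\Delta s,$$

where $\Delta m$ (GBP) and $\Delta s$ (shock count) are the attribute
differences between the options. The observed RT is the boundary-crossing
time plus a non-decision time $T$. The diffusion coefficient is fixed at 1,
the usual identification convention, so $a$, $v$ and the drift weights are
expressed in diffusion-noise units. Typically $\beta_m > 0$ (money attracts
towards the high option) and $\beta_s < 0$ (shocks repel).

Competing accounts map onto parameter-condition structure:

* **naive** — no parameter varies by condition (baseline);
* **prosocial default** — the starting point $z$ varies by source: a
  pre-attribute bias against harmful choices for dirty money;
* **valuation conflict** — the drift weights vary by condition (by source in
  a one-factor design; by source and destination in the 2x2 design), i.e.
  the moral context re-weights the attributes themselves;
* **hybrid** — valuation-conflict drift weights *plus* source-specific
  starting points.

A modelling decision worth making explicit: the starting point is a free
parameter only in specifications that split it by condition. In the other
members of the family it is fixed at the unbiased midpoint $z = 0.5$, so the
naive baseline has exactly four parameters per subject ($a$, $T$,
$\beta_m$, $\beta_s$). This keeps the baseline genuinely naive and makes the
prosocial-default model a pure "bias" account.

## Trial generation

Trials are constructed to be diagnostic: each trial is matched to the
indifference point of a simulated agent with harm aversion $\kappa \in
[0, 1]$, whose net value for the high option we take as
$(1-\kappa)\Delta m - \kappa\Delta s$. The published procedure states the
matching but not the agent's utility; this linear trade-off is the standard
parameterisation for this task family (a single coefficient pricing shocks
against money) and is documented here as a package choice. For each
$\kappa$ on an equidistant grid over $[0,1]$ (endpoints included, one trial
per grid point), 1000 candidate $(\Delta s, \Delta m)$ pairs are drawn
($\Delta s$ uniform integer 1–20; $\Delta m$ uniform in $[0.1, 19.9]$,
rounded to 10 pence as display currency), and the candidate minimising the
absolute indifference gap is selected, ties broken by candidate order so a
seed fully reproduces the set. Low-option values are then drawn uniformly
subject to the option bounds (0–20 shocks, £0–20; the judged-decision
variant requires at least 1 shock and £0.10, which also rules out
$\Delta s = 20$ there). Because different $\kappa$ agents are indifferent at
very different $\Delta m / \Delta s$ ratios, the resulting sets leave the
two attributes nearly uncorrelated — `check_attribute_independence()`
reports the Pearson correlation, and the test suite checks that the median
absolute correlation across regenerated 42-trial sets stays below 0.2 —
which is what makes the two drift weights separately identifiable.

## Likelihood and numerics

The likelihood of a response is the Wiener first-passage density of the
boundary actually hit, evaluated at `rt - t0`, with the drift recomputed per
trial from its attributes and condition. The density is computed by the
classical dual series: a small-time expansion and a large-time
(eigenfunction) expansion, choosing whichever needs fewer terms, with
truncation error bounded at 1e-10 per evaluation. Responses at or below the
non-decision time contribute $-\infty$ and are counted, not dropped. The
closed-form absorption probability
$p_\mathrm{upper} = (1 - e^{-2vza})/(1 - e^{-2va})$ is implemented with
`expm1` and is continuous through $v = 0$; it serves as an analytic oracle
for the simulator in the tests.

The simulator exploits the fact that increments of a constant-drift
diffusion are exactly Gaussian: endpoints are sampled exactly at any step
size, and a Brownian-bridge test catches within-step boundary crossings.
Choice frequencies are therefore unbiased for any `dt`; the step size only
sets the resolution of the recorded crossing time (mid-step imputation,
error $O(dt)$) and the probability of an undetected double crossing
($\sim e^{-2a^2/dt}$, negligible at the defaults). The default `dt` is 1 ms;
large Monte-Carlo checks use 5 ms, where the RT coarseness is irrelevant and
the choice frequencies remain exact. Simulated trials whose RT would exceed
the 6 s response window are redrawn, mirroring a task deadline whose missed
trials are re-presented until answered; the likelihood does not truncate at
6 s because at fitted parameters the mass beyond the window is negligible.

## Hierarchical estimation

Each sampled parameter label (boundary, non-decision time, and every
condition cell of the starting point and drift weights the specification
splits) gets a group location and a group scale; subject values are normal
around the location, truncated to the parameter's support. Priors are
deliberately non-informative: uniform over wide supports —
$a \sim U(0.3, 6)$, $z \sim U(0.05, 0.95)$, $T \sim U(0.05, 1.5)$ s,
$\beta_m, \beta_s \sim U(-3, 3)$ per pound / per shock, group scales
$\sim U(0.01, 3)$. The supports generously cover fitted ranges for this task
class while keeping the posterior proper; the truncated-normal group model
realises partial pooling on bounded supports.

Sampling is Metropolis-within-Gibbs with random-walk proposals, implemented
in C++. Proposal scales are batch-adapted towards a 0.44 acceptance rate
during burn-in only, so the retained draws come from a fixed kernel.
Anything from two chains upwards can be run for within-fit diagnostics, and
`gelman_rubin()` computes the potential scale reduction across independent
runs (values near 1 indicate convergence; we treat 1.1 as the working
threshold). Trials faster than 200 ms are removed before fitting — such RTs
are incompatible with a decision process plus non-decision time and are the
standard exclusion for this model class. Sampler budgets in the examples and
tests (a few thousand iterations, 500–1000 burn-in) were chosen by checking
that group-location traces mix and R-hat stays near 1 at the study sizes
used; larger datasets may warrant more.

## Model comparison and inference

Three complementary criteria adjudicate between specifications. The DIC is
$\bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$, where $D$ is minus twice
the data log-likelihood and $\bar\theta$ the posterior mean of the
subject-level parameters on their sampling scale (the group parameters enter
only through them). Posterior-predictive mean squared errors re-simulate the
fitted dataset from random posterior draws and compare per-condition mean
harmful-choice proportions and mean RTs with the observed ones; the
published description does not pin down the exact summary the squared error
was taken over, and per-condition means are the package's reading — the
natural desk-checkable choice, and the one the self-consistency tests
exercise. `rank_models()` orders fits by DIC and flags when either MSE
ordering disagrees.

Posterior hypothesis summaries follow the sampled-coefficient conventions:
`posterior_probability()` (fraction of draws beyond a threshold, reported
two-sidedly where used as a test), `ratio_posterior()` (draw-wise ratios,
e.g. dirty/clean weight ratios, warning when the denominator crosses zero),
and `hdi()` (narrowest interval holding the stated mass; never wider than
the equal-tailed interval). Ratios are taken on raw coefficients: both shock
weights are negative, so dirty/clean shock-weight ratios are positive and
read the same way as money ratios. Reported "mean ratios" are means of the
ratio draws, not ratios of means.

## Blame judgments and the linkage

Third-party blame ratings (0 = extremely praiseworthy, 100 = extremely
blameworthy) of the harmful choice are modelled with a random-intercept
linear mixed model estimated by maximum likelihood (via `lme4`):

$$Blame = (\beta_0 + u_{0i}) + \beta_1 \Delta m + \beta_2 \Delta s +
\beta_3\, cond + \beta_4\, (cond \times \Delta m) +
\beta_5\, (cond \times \Delta s),$$

with condition dummy-coded profit = 1 so that $\beta_3 > 0$ means more blame
for profit-directed harm. Raters failing either attention check (a response
below the scale maximum) are excluded wholesale; predictors enter on their
natural scales (pounds, shocks), unstandardised, so slopes read as rating
points per unit.

The linkage between judgments and decisions compares, over a grid of offers,
the *gap in blame* $Blame_{profit} - Blame_{charity}$ (slope-only
predictions from per-condition fits, as the relative quantity of interest)
with the *temptation gap*, the same contrast on the drift-weighted value
$\beta_m \Delta m + \beta_s \Delta s$ using destination-specific weights
from the best-fitting decision model (averaged across source conditions,
since the contrast of interest is profit versus charity). "Each possible
combination" of offers is not enumerated in print; the default grid takes
$\Delta s \in \{1, \dots, 20\}$ and $\Delta m \in \{0.5, 1.0, \dots, 19.5\}$
and is configurable. `link_correlation()` reports the Pearson correlation of
the two gaps across the grid.

## Synthetic studies and what they do (and do not) show

`generate_choice_study()` builds complete studies with the designs the
analyses assume: a source-only design (102 base trials reused in both
source conditions, 204 decisions per subject, 28 subjects by default) and a
2x2 source-by-destination design (44 base trials, 176 decisions, 61
subjects, presented in blocks of 10 trials per condition). Subject
parameters are truncated-normal draws around configurable group means; the
defaults are demonstration values placed inside plausible fitted ranges
(e.g. a dirty/clean money-weight ratio near 0.85 in the one-factor design,
and 2x2 defaults in which the source effect falls on the money weight for
profit but on the shock weight for charity), not estimates of any dataset.
`generate_blame_study()` produces clipped-Gaussian ratings from the blame
model above (defaults $\beta_1 = -1.9$, $\beta_2 = 1.7$, rater-intercept SD
5, residual SD 10, intercept 45 so that mean ratings sit mid-scale and
clipping stays below 5% of ratings) plus two attention-check rows per rater.
Every generator is driven by named substreams of one seed and returns a
ground-truth manifest sufficient to re-simulate bit-identically.

These generators make the recovery tests meaningful: parameters are
recovered from data whose generating process *is* the fitted model. Real
data differ in ways the generators deliberately omit — RT contamination
beyond the 200 ms cut, attribute-dependent attention, inter-trial parameter
variability, slow drifts in caution — so passing recovery and
model-selection tests certifies the estimator and the comparison machinery,
not the substantive conclusions one would draw from any particular human
dataset.

## Degenerate inputs and edge behaviour

Out-of-range harm-aversion, empty candidate lists, zero-variance attributes,
missing condition factors, non-positive RTs, ratings outside the scale and
mismatched draw vectors raise errors naming the offence; RTs that look like
milliseconds are rejected rather than silently rescaled (an explicit
`rt_unit = "ms"` converts). Zero-variance paired differences make the paired
t undefined and error. A participant losing all trials to the 200 ms
exclusion triggers a warning, not an error. Ties in candidate selection
resolve to the lowest index; equal-width HDI candidates resolve to the first
(lowest) window.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the pipeline end to end at
sizes chosen to exercise the statistical properties while staying quick on a
single core: 20 subjects by 200 decisions for parameter recovery, 10
subjects by 100 decisions and five replicates per direction for
model-selection recovery, a million simulated paths for the analytic-oracle
check, and 60 raters for blame recovery. These sizes are the package's
choices for desk-scale verification; the same functions run unchanged at
full study sizes.

## Known limitations

No inter-trial variability parameters (the classic `sv`, `sz`, `st`
extensions) — the modelled family does not include them. No
attention-weighted drift, race or accumulator alternatives. The blame model
is a linear model of a bounded rating (generated accordingly, clipped
Gaussian); ordinal or beta regression is out of scope. The MCMC kernel is a
random-walk scheme: robust and dependency-free, but less efficient than
gradient-based samplers for very large designs — budget iterations
accordingly and check `gelman_rubin()` across runs.
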