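---
title: "Planning risk-prediction studies when the outcome is rare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning risk-prediction studies when the outcome is rare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowprev)
```

## The problem

Clinical prediction rules for rare outcomes — suicide is the motivating
example, with population risk usually below 1% — face two compounding
obstacles that no amount of modelling ingenuity removes:

1. **Sample size.** Detecting even a moderate relative risk for a binary
   risk factor requires observing enough outcome events, and at a 1%
   baseline risk events are scarce: thousands of subjects per candidate
   effect, tens of thousands when the factor is carried by a minority.
2. **Effect size.** A marker that reaches a positive predictive value
   (PPV) a clinician would call useful must, at low prevalence, carry a
   relative risk far beyond anything observed in practice. This is a
   mathematical property of the 2×2 distribution, not a shortcoming of any
   particular model.

`lowprev` turns both arguments into callable, simulatable calculations so
that a study team can see, before collecting data, what their design can
and cannot deliver.

## The model

Everything rests on the joint distribution of a binary marker (or risk
factor) $E$ and a binary outcome $D$. Write $p$ for prevalence
$P(D)$, $S$ for sensitivity $P(E \mid D)$, $f$ for the marker-positive
fraction $P(E)$, and $r_0$ for the baseline risk
$P(D \mid \bar E)$. Conditioning on the four cells gives the central
identity

$$\mathrm{RR} \;=\; \frac{P(D \mid E)}{P(D \mid \bar E)}
  \;=\; \frac{\mathrm{PPV} - pS}{p(1-S)},$$

implemented in `rr_from_predictive()`. Two consequences drive the
package's predictive-performance half:

* As $S \to 0$ the identity approaches its floor $\mathrm{RR} \to
  \mathrm{PPV}/p$: at $p = 1\%$, a PPV of 50% is unreachable below
  $\mathrm{RR} = 50$, and a PPV of 10% below $\mathrm{RR} = 10$;
  realistic sensitivities push the requirement higher still
  (`rr_sensitivity_curve()`).
* In likelihood-ratio terms, moving a 1% pre-test probability to 10%,
  25% or 50% requires $LR^+$ of 11, 33 and 99 (`required_lr()`), via the
  odds form of Bayes' theorem.

`scenario_from_predictive()` and `scenario_from_exposure()` complete the
full eight-field scenario ($p$, $S$, specificity, PPV, NPV, $f$, RR,
$LR^+$) from either parameterization, re-derive every redundant field and
refuse internally inconsistent input, naming the violated constraint. The
two parameterizations are connected by $f = Sp/\mathrm{PPV}$ and
$r_0 = p(1-S)/(1-f)$; the test suite verifies on a 1,000-point grid that
a round trip through either direction reproduces the inputs to $10^{-9}$
relative tolerance, and checks every closed form against brute-force
enumeration of the four joint cells.

## Sample size

`required_total_n()` sizes a cohort for the two-proportion comparison of
exposed risk $p_1 = r_0\,\mathrm{RR}$ against unexposed risk $p_2 = r_0$
with allocation ratio $k = (1-f)/f$. The default (`variant = "pooled"`)
is the classical pooled-variance normal approximation,

$$n_\text{exposed} = \frac{\left[z_{1-\alpha/2}\sqrt{(1+1/k)\,\bar p(1-\bar p)}
 + z_{1-\beta}\sqrt{p_1(1-p_1)+p_2(1-p_2)/k}\right]^2}{(p_1-p_2)^2},
 \qquad \bar p = f p_1 + (1-f) p_2,$$

with the exposed group rounded up first and the unexposed group derived
from the allocation ratio and rounded up — a conservative, reproducible
integerization. Two variants are provided for sensitivity analysis:
`"unpooled"` (both variance terms unpooled) and `"pooled_cc"` (the
continuity-corrected form, always at least as large as the pooled
result). The variant is recorded in every result object rather than
hidden, because published sample-size statements rarely say which variant
produced them; the pooled default reproduces the canonical
low-prevalence bounds (total $n = 6{,}206 > 5{,}000$ at
$r_0 = 1\%$, RR $= 2$, $f = 0.5$; $15{,}990 > 14{,}000$ at $f = 0.1$).

Significance is interpreted as two-sided $\alpha = 0.05$ — the
epidemiological default when sidedness is unstated. The companion test,
used by both `achieved_power()` and the simulator, is the two-sided
Pearson chi-square without continuity correction, which is algebraically
the pooled two-proportion $z$ test: sizing formula and rejection rule are
deliberately the same approximation, so the simulation validates the
formula actually implemented.

`min_detectable_rr()` inverts the calculation by bisection over
$\mathrm{RR} \in (1+10^{-6}, 100]$ to $10^{-6}$ relative tolerance;
relative risks above 100 are outside any plausible planning range, so a
design that cannot reach the target power anywhere below the cap is
reported as not achievable rather than extrapolated. Note that smallness
of the cohort alone does not make detection impossible: with a common
exposure and $r_0\,\mathrm{RR}$ near 1, even $n = 100$ has near-certain
power, because almost every exposed subject experiences the outcome.

`epv_limit()` implements the events-per-variable rule of thumb for model
development — at least 10 outcome events per candidate predictor — and
returns a feasibility verdict: 222 events support at most 22 predictors,
33 events at most 3.

## The simulator

`simulate_cohort()` draws the exposed count binomially with probability
$f$ from $n$ subjects (population sampling; `fixed_margins = TRUE` gives
the conditional design), then outcome counts binomially at risks
$r_0\,\mathrm{RR}$ and $r_0$. It emulates exactly the sampling model the
sizing formula assumes — independent subjects, a dichotomous exposure,
constant risks. It deliberately does *not* emulate features of real
cohort data such as correlated predictors, measurement error,
time-varying risk, censoring or clustering, so agreement between the
simulator and the closed forms demonstrates internal correctness of the
algebra and the sizing approximation, not performance on any real
dataset.

`empirical_power()` reports the rejection fraction of the pooled
chi-square across replicates, with a binomial Monte-Carlo standard error;
replicates with a degenerate margin (an empty arm, or no events at all)
cannot reject and are counted as non-rejections, with a logged message.
`empirical_predictive()` pools the 2×2 counts across replicates before
forming sensitivity, specificity, PPV, NPV, RR and $LR^+$ — per-replicate
ratios are undefined or wildly skewed when a 1%-prevalence replicate
contains a handful of events — and attaches delta-method standard errors
on the log scale for the two ratio estimates.

All randomness flows through R's global generator, seeded once per call
from the user's `seed` argument, and replicate draws are vectorized
binomials. This deviates from a substream-per-replicate design: the
property that matters — bit-for-bit reproducibility of every result from
`(inputs, seed)` — is guaranteed and tested, while substreams would only
buy parallel safety the package does not need and would force a scalar
loop.

### How well does the sizing formula hold up?

The test grid asserts that empirical power at the returned $n$ is within
three Monte-Carlo standard errors of the target and never materially
below it. At the canonical design ($r_0 = 1\%$, RR $= 2$, $f = 0.5$,
$n = 6{,}206$) exact enumeration of the binomial joint distribution puts
the true power of the chi-square test at 0.9068 against the 0.90 target,
while the exact test size at $n = 5{,}000$ under the null is 0.0490
against nominal 0.05: the pooled formula is mildly conservative at ~93
expected events (it buys slightly more power than requested), and the
test holds its level. A planning tool should err exactly this way.

## Numerical choices

* Probabilities are proportions in $[0,1]$ internally; the CLI accepts
  percentage strings (`"1%"`) and text output reports both scales,
  because planning conversations mix the two freely.
* $S = 1$ and specificity $= 1$ are domain errors, not infinities; a
  caller who wants the limit passes $1 - \epsilon$ explicitly. This
  keeps non-finite values from propagating silently.
* Scenario consistency checks compare at relative tolerance $10^{-9}$
  with an absolute floor of $10^{-12}$: all quantities are
  well-conditioned ratios of magnitude $O(1)$–$O(100)$.
* Curve grids default to $\mathrm{RR} \in [1.5, 5]$ step 0.1 and
  $S \in [0.05, 0.95]$ step 0.01 (open interval: the identity's
  endpoints are degenerate), covering the region where the planning
  argument bites; grid points that violate a domain constraint are
  skipped with a warning, never emitted as sentinel values.
* Monte-Carlo defaults in the test suite use 4,000–20,000 replicates of
  cohorts up to $10^5$–$10^6$ subjects — large enough that every
  three-standard-error check has meaningful resolution, small enough to
  run in seconds.

## Limitations

The package treats a single dichotomized marker against a binary outcome.
It says nothing about continuous risk scores, ROC analysis, calibration,
negative likelihood ratios for rule-out, survival outcomes, matched
designs, or development-sample criteria beyond the events-per-variable
heuristic. Those are different planning questions; the two computations
here are the ones that make low prevalence bite hardest, and they bound
what any more elaborate model can achieve.
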