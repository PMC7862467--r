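---
title: "Simulating and analysing cross-domain cognitive effort discounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing cross-domain cognitive effort discounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Cognitive motivation — the willingness to engage in effortful thinking — has
mostly been measured by self-report. Effort-discounting paradigms instead
infer it from revealed preferences: participants repeatedly choose between
redoing an easy task for a smaller reward and a harder task for a larger
one, and the money they forgo to avoid the harder task prices their
subjective cost of effort. `cogedkit` simulates this paradigm in two domains
— an N-back working-memory task (hard levels 2-, 3-, 4-back vs a 1-back
baseline) and speech-in-noise listening (−4, −8, −12 dB SNR vs 0 dB) — and
runs the Bayesian correlation analysis that asks whether effort costs in the
two domains share a common, domain-general trait, even after removing
ability- and performance-related variance.

Everything is exercised on synthetic cohorts, so the full pipeline is
testable without human data; the latent structure of the generator is the
structure the analysis assumes, which is exactly what makes parameter
recovery a meaningful test.

## The staircase and its fixed points

Each of the nine cells per domain (3 hard levels × base offers \$2, \$3,
\$4) runs a five-trial titration. Trial 1 offers equal amounts; the option
chosen there becomes the *titrated* side. After choice $k$ the titrated
offer moves by $\mathrm{base}/2^k$ — down if the titrated side was chosen
again, up (capped at base) if not. Two readings of the protocol required a
decision:

* **What counts as the five calibration trials.** The 45-trials-per-domain
  arithmetic (3 levels × 3 rewards × 5 trials) forces the initial
  equal-offer trial to be one of the five. The fifth choice still triggers
  a final half-step adjustment, and that post-adjustment offer is the
  indifference point. The alternative (indifference point read before the
  last adjustment) also converges; one reading simply had to be fixed, and
  the post-adjustment reading matches "the value of the titrated reward at
  the end of the task".
* **What happens when the fixed side is chosen.** Only the decreasing move
  is illustrated in descriptions of the task; a staircase that never moves
  back up cannot converge to interior indifference points, so the reverse
  move (same halved step, upward) is implemented.

With these rules the staircase is a five-step bisection: for any
deterministic threshold chooser with threshold $t$, the indifference point
lands within $\mathrm{base}/32$ of $t$ (verified exhaustively in the test
suite), and the attainable indifference points span
$[\mathrm{base}/32,\; 31\,\mathrm{base}/32]$. All amounts are dyadic
fractions of whole-dollar bases, hence exactly representable in floating
point — no cent rounding is ever needed.

## Subjective-value scoring

With first choice *easy* (the hard option is being discounted),
$SV = IP/\mathrm{base} \in (0, 1]$; with first choice *hard*,
$SV = (\mathrm{base} - IP)/\mathrm{base} + 1 \in [1, 2)$. Exhaustive
enumeration of all $2^5$ choice paths × 3 bases shows the attainable range
is $[1/32,\ 63/32]$, safely inside the registered 0–2 scale. Averaging for
the stage-1 analysis is over all nine cells; per-level means are kept as
well because the stage-2 model uses task level as a predictor, which
requires level-grain outcomes.

## The synthetic cohort

Per-participant proportional costs follow
$\mathrm{cost}_i(d, \ell) = \mu_{d\ell} + \sigma\,(a_d M_i + b\,\eta_{id})$
with $M_i$ the shared motivation factor, $a_d^2 = |\rho|$,
$b^2 = 1 - |\rho|$, so the cross-domain correlation of mean costs is
*exactly* the configured `cross_domain_rho` — making it a recoverable
ground truth rather than an emergent property. Defaults state the world
once:

* `level_cost_means` rise by 0.15 per load level (0.30/0.45/0.60 in both
  domains), mirroring the ≈0.15 drop in subjective value per level seen in
  pilot work, and centring costs in the band typical of effort
  discounting;
* `cost_sd = 0.2`, giving realistic between-person spread while keeping
  most costs inside (0, 1);
* `choice_temperature = 0` by default: agents are deterministic threshold
  choosers, so staircase error is bounded by the base/32 resolution and
  recovery tests isolate the analysis machinery. Positive temperatures add
  logistic choice noise for robustness experiments;
* covariates (d-prime, RT, intelligibility, three span totals, three
  reward-sensitivity scales) load on ability and reward latents that are
  *independent* of $M_i$; only the Need for Cognition score loads weakly
  (0.2) on $M_i$, echoing the anecdotal pilot association. Bounded scores
  are scaled-logistic transforms of normal predictors, rounded into their
  instrument ranges — a convention, not a distributional claim.

One shared seed derives a named stream per participant, so participant
`P0007` is identical in a cohort of 10 and a cohort of 10,000.

What the generator does *not* emulate: trial-level task behaviour (letters,
audio), learning or fatigue across the session, measurement error in the
staircase beyond choice noise, and any dependence of task performance on
motivation. A green recovery test therefore establishes that the analysis
recovers the latent structure the registration assumes — not that real
data satisfy that structure.

## Bayes factors for correlations

The likelihood is the exact sampling density of the Pearson correlation
under bivariate normality (a ${}_2F_1$ expression; the sample $r$ and $n$
are sufficient). The registered prior, "Cauchy ($\mu = 0$, $r = \sqrt2/2$)",
is improper on $(-1, 1)$ as stated, and is implemented as a zero-centred
Cauchy truncated to $(-1,1)$ and renormalised; a stretched-beta family
(`scale` = $\kappa$, with $\kappa = 1$ uniform) is provided because that is
what common Bayes-factor software actually uses for correlations. Both
families support a one-sided (positive) variant.

Numerics: the marginal likelihood is integrated on the Fisher-$z$ scale
(the $\tanh$ substitution tames the endpoints), split at the sample value
so adaptive quadrature cannot miss a narrow peak, and shifted by the
log-likelihood at the mode for overflow safety; relative tolerance 1e-8.
Posterior median, 95% credible interval and the density at $\rho = 0$ come
from a dense two-resolution grid on the same scale. Three independent
routes agree: adaptive quadrature, the Savage–Dickey density ratio (within
1% on a grid of cases), and a Monte-Carlo prior-draw estimator; the
stretched-beta case is additionally pinned to values computed once with an
independent implementation (pingouin's exact method) and frozen in the
tests.

The partial correlation residualises both vectors on the controls (with
intercept) and reduces $n$ by the number of controls, the standard
degrees-of-freedom bookkeeping for partial-correlation inference.

## Sequential design analysis

`simulate_sequential_design()` grows bivariate-normal samples from `n_min`
by `n_step`, stopping at the first interim where $BF_{10}$ crosses 10 (or
0.1), or at `n_max`. Because the two-sided $BF_{10}$ is an even, monotone
function of $|r|$ at fixed $n$ (a property the test suite asserts), the
simulator precomputes per-$n$ critical correlations by root-finding and
compares running correlations against those curves — thousands of times
faster than quadrature at every interim of every replicate, and
behaviourally identical. Terminal Bayes factors are evaluated afterwards
with a small cache keyed on (rounded $r$, $n$).

Two findings from this machinery shape how results should be read:

* Under the truncated-Cauchy prior, $BF_{10}(r = 0, n)$ only reaches 0.1
  beyond $n \approx 340$: with the registered ceiling of $N = 300$ the
  null boundary is *unreachable*, and every null-true replicate ends at
  the ceiling. The design-analysis defaults therefore leave the horizon
  effectively unbounded when the lower-boundary stopping distribution is
  of interest; the registered ceiling variant is available as
  `registered_design()`.
* The published planning medians for this design (112 to reach the upper
  boundary at $\rho = 0.3$; 140 to reach the lower at $\rho = 0$) could
  not be reproduced under any standard prior/settings combination we
  examined (truncated Cauchy, stretched-beta $\kappa = 1$, Fisher-$z$
  Cauchy; `n_min` 10 or 100). This package reports what its own, fully
  specified machinery computes — e.g. a median upper-boundary stop near 68
  under the truncated Cauchy with `n_min = 10`, step 1 — and the
  acceptance checks against the published medians are left failing rather
  than tuned.

## The three analysis stages

1. **Zero-order**: Bayesian correlation of the per-participant domain-mean
   subjective values.
2. **Performance-adjusted**: per domain, OLS of level-grain SV on task
   level (categorical) plus the domain's performance covariates (N-back:
   d-prime, mean RT; speech: intelligibility; speech RT is deliberately
   not a covariate), participant residuals averaged, then correlated. The
   participant×level grain is chosen because task level is itself listed
   as a covariate — the only reading that uses all listed covariates; a
   participant-mean grain is available via `grain = "participant"`.
3. **Trait-adjusted**: partial correlation of the stage-2 residuals
   controlling for the working-memory-capacity and reward-sensitivity
   z-score composites, implemented by further residualisation plus the
   effective-$n$ correction.

Residualisation is idempotent and inert to orthogonal covariates (both
tested at 1e-10), and constant covariate columns drop out rather than
tripping the collinearity check, so degenerate simulated worlds still
analyse cleanly.

Participants who chose one and the same option on *every* decision trial
(detectable from the SV table: uniform first choices with all indifference
points at the staircase floor) are flagged as possibly non-compliant, and
analyses are reported with and without them — mirroring the registration's
both-ways reporting rather than silently dropping anyone. Flagging on
uniform *first* choices alone would be wrong: every ordinarily
effort-averse responder first-chooses the easy option in all 18 cells and
then shows mixed choices during titration.

## Known limitations

* Posterior medians are shrinkage estimators: at $n = 150$ and $\rho =
  0.5$ the expected posterior median is ≈0.475 (≈1% attenuation of the
  sample $r$ from the staircase's base/32 resolution and cost clamping at
  the scale floor, plus ≈2.5% prior shrinkage). Recovery tests that demand
  unbiasedness at ±3 Monte-Carlo SE therefore fail by ~1–2% by design of
  the estimator, not by error; see the test suite's acceptance file.
* The generator draws covariates at the summary grain the analysis
  consumes; it cannot speak to trial-level exclusion rules.
* Sequential-design runtime is dominated by the boundary-curve
  precomputation (a few hundred root-finds); curves are reusable across
  simulations with the same prior and thresholds and should be shared.
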