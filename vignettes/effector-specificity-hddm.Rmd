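---
title: "Modelling effector specificity in perceptual learning with hierarchical drift-diffusion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling effector specificity in perceptual learning with hierarchical drift-diffusion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Visual perceptual learning — the slow improvement of a visual discrimination
with practice — is classically attributed to visual cortex. But every
discrimination task also maps a visual decision onto a motor act: a joystick
flick, a reach, a saccade. If part of the learned improvement lives in that
sensorimotor mapping, changing the *effector* after training should cost
performance even though the stimuli are unchanged. `vplddm` implements the
analysis pipeline for exactly this design: several training sessions with one
effector, then a transfer session with another, plus an untrained control
group that performs one block with each effector.

Two layers of analysis are provided:

1. **Behavioral layer** — signal-detection sensitivity $d'$ per subject and
   session (with the loglinear correction), repeated-measures ANOVAs with
   partial $\eta^2$, paired $t$-tests with Hedges' $g$, exact one-sided sign
   tests, and the Specificity Index
   $$ SI = \frac{d'_{\text{last}} - d'_{\text{transfer}}}
                {d'_{\text{last}} - d'_{\text{first}}}, $$
   where 0 means the learning gain fully survived the effector change and 1
   means it was fully specific to the trained effector.

2. **Process layer** — a hierarchical Bayesian drift-diffusion model (DDM)
   that decomposes each choice and reaction time into evidence accumulation
   rate $v$, boundary separation $a$, non-decision time $t_0$, and start-point
   bias $z$, so that learning and transfer effects can be located on specific
   components of the decision process.

## The drift-diffusion model and its likelihood

A trial is modelled as a Wiener process with drift $v$ and unit diffusion
coefficient starting at $z a$ between absorbing boundaries $0$ and $a$;
the reaction time is the first passage time plus $t_0$. Clockwise stimuli
accumulate at $+v$, counterclockwise at $-v$, and one drift is estimated for
both orientations together; by default the upper boundary codes clockwise
choices. Inter-trial variability parameters ($\eta$, $s_t$, $s_z$) are
deliberately excluded — estimating them well needs far more trials per
condition than this design provides.

The first-passage density is evaluated with the two complementary series
expansions (the small-time Gaussian-image series and the large-time sine
series), choosing per evaluation whichever needs fewer terms for a truncation
error below `err` (default `1e-7`). Densities are floored at `1e-12` before
logs; trials with `rt <= t0` hit that floor and are counted in a warning.
Both constants are exposed in the configuration. Closed forms used for
validation: the upper-boundary absorption probability
$(1 - e^{-2vaz})/(1 - e^{-2va})$ and the zero-drift mean decision time
$a^2 z (1-z)$.

The path sampler is an Euler–Maruyama walk with step `dt` (default
`1e-4` s) plus a Brownian-bridge crossing test between consecutive points;
the bridge test removes the $O(\sqrt{dt})$ first-passage discretization bias,
which would otherwise be visible at the $3$-standard-error level in a
$10^5$-trial calibration run.

## Model space and hierarchical estimation

The model space is declarative: strings like
`"v(ses*diff)_a(ses)_t(ses)_z(ses)"` state which parameters vary with which
factors (sessions, difficulty levels, both, or neither); omitting `z` fixes
the start point at 0.5. Drift varies by session and difficulty; $a$, $t_0$
and $z$ vary at most by session, since boundaries, encoding and response
bias have no reason to track randomly interleaved difficulty levels.

Estimation is by single-parameter Gaussian random-walk Metropolis updates
sweeping group-level then subject-level parameters — the algorithmic
regime of the widely used Python HDDM toolbox, which avoids gradient
derivations of the series density. Proposal scales adapt during burn-in toward a
0.2–0.5 acceptance rate and are frozen afterwards. The start point is
sampled on the logit scale, which keeps its $(0,1)$ support without
rejections.

Priors are weakly informative and bracket the plausible range of the task:
group means $v \sim N(2, 3^2)$, $a \sim N(1.5, 1^2)$ truncated above $0.1$,
$t_0 \sim N(0.4, 0.25^2)$ truncated at $0$,
$\mathrm{logit}(z) \sim N(0, 0.5^2)$; group SDs half-normal with scale 1
($v$), 0.3 ($a$, $t_0$), 0.25 (logit $z$); subject-level values normal
around the group means (truncated for $a$ and $t_0$, logit-normal for $z$).
With a single subject the hierarchy degenerates and the subject level
collapses onto the group means.

Desk-scale MCMC defaults are 4 chains of 3000 retained draws after 1000
burn-in sweeps; `full_scale = TRUE` restores the long regime (4 chains,
30,000 sweeps, 10,000 burn-in, thinning by 5). Four chains are pooled for
diagnostics; running the fitting algorithm "four times" is
treated as running four chains, which is the interpretation that makes the
between-chain variance of the Gelman-Rubin statistic meaningful.

Model comparison uses the conditional DIC (deviance evaluated at
subject-level parameters, $pD = \bar D - D(\bar\theta)$), matching the
toolbox convention; marginal DIC and WAIC/LOO are out of scope.
Convergence is checked with the classic Gelman-Rubin statistic (flags at
1.2, and 1.1 under strict conditions) and Geweke z-scores comparing the
first 10% of each chain against the last 50% split into 20 segments, with
segment-mean variances estimated by batch means (20 batches) — simpler than
spectral estimation, asymptotically equivalent, and deterministic. Because
all 20 z-scores share the same reference segment they are correlated within
a chain, so calibration statements are made pooled across chains.

## The synthetic cohort generator

The generator inverts the hierarchical model into a simulator of the
emulated experiment: 4 training sessions plus a transfer session, 220
trials per session — 20 per signed difficulty level at
$\pm\Delta \in \{0°, 0.31°, 0.56°, 1°, 1.77°, 3.16°\}$ — and a 1-s response
window; timed-out first-passage draws are redrawn (the experimental
protocol repeats timed-out trials), with cell counts conserved exactly. A
draw that fails ten redraws is emitted once with `timeout_redraws = 10` and
excluded by every downstream default filter.

Group-level truth and its defaults:

| parameter | meaning | default |
|---|---|---|
| $\beta_s$ | drift slope per session, $1/(\mathrm{s\,deg})$ | 0.55, 0.75, 0.9, 1.0 |
| $\gamma$ | drift–difficulty exponent | 1 (linear) |
| $a$ | boundary separation | 1.6 |
| $t_0$ | non-decision time (s) | 0.45 training / 0.31 transfer |
| $z$ | start point | 0.47 session 1, 0.5 later |
| $\rho$ | specificity factor | 0.3 |
| $\delta_t$ | transfer $t_0$ drop (s) | 0.14 |
| SDs | between-subject (on $\beta$, $a$, $t_0$, logit $z$) | 0.15, 0.15, 0.05, 0.15 |

Drift for session $s$ at difficulty $\Delta$ is $v = \beta_s \Delta^\gamma$.
The power law is a generator-side convenience only — the fitter estimates
one free drift per session-difficulty cell and never sees the law. The
transfer session removes a fraction $\rho$ of the acquired drift gain,
$v_{\text{transfer}} = v_{\text{first}} + (1-\rho)(v_{\text{last}} -
v_{\text{first}})$ per difficulty, and lowers $t_0$ by $\delta_t$ (saccades
are faster than hand responses), floored at 0.05 s. The magnitudes were
chosen once to be realistic for a trained orientation-discrimination
observer; the between-subject SDs produce the cohort heterogeneity a
hierarchical fit needs without drowning the session effects. The control
group draws both effector blocks from session-1 drifts (zero generating
drift difference) with the eye block's $t_0$ lowered by $\delta_t$, block
order counterbalanced.

Zero-difficulty trials are labelled `neutral`, never enter $d'$ (they have
no correct response), and are excluded from the DDM likelihood by default
with a configuration switch to include them at drift 0 — the original
pipeline's handling of these trials is not documented, so both options are
supported.

What the generator does **not** emulate: fixation breaks, feedback-driven
strategy shifts, fatigue within sessions, sequential dependencies, and any
non-stationarity within a session. Passing tests on this synthetic cohort
therefore demonstrate that the pipeline recovers what it assumes — not that
real data satisfy those assumptions.

## The response-window truncation bias, and how validation handles it

Redrawing timed-out trials means the generator samples reaction times from
the *truncated* first-passage distribution, while the likelihood —
deliberately, following standard HDDM practice — ignores the truncation.
Under the default truth and the 1-s window roughly a third of raw draws
exceed the window, and the fitted boundary separation is then biased low by
about 0.4 with non-decision time compensating; this is a property of the
censoring-blind likelihood, not of the sampler. The estimation-validation
studies (`recovery_study()` and `model_identification_study()`)
therefore run the same design without an effective deadline
(`response_window = 10` s via `recovery_design()`): there they validate
the estimator under its own assumptions, and at that setting the
group-level 95% credible intervals cover all 40 generating group values
with a maximum Gelman-Rubin statistic near 1.1. The behavioral specificity
study keeps the 1-s window, because $d'$ and the Specificity Index are
insensitive to RT truncation.

## Validation studies and problem sizes

The package validates itself end-to-end at sizes chosen to make each check
statistically meaningful on a single CPU:

- **Recovery** (`recovery_study()`): 8 subjects, 4 training sessions plus
  transfer, 100 trials per session (10 per signed nonzero level), full
  model, 4 chains × 3000 draws after 1000 burn-in; coverage of group-level
  95% credible intervals pooled over 5 cohorts.
- **Model identification** (`model_identification_study()`): cohorts
  generated with a genuine start-point bias $z = 0.42$; the bias model must
  beat the no-bias model on conditional DIC. 2 chains × 1500 draws after
  500 burn-in per model suffice for a DIC difference that is an order of
  magnitude larger than its run-to-run noise.
- **Specificity recovery** (`specificity_curve()`): 19-subject cohorts at
  the full 220-trial design; the median SI must track the generating
  $\rho$, with anchors at $\rho = 0$ and $1$. Two finite-sample properties
  of the SI deserve note. First, $d'$ saturation at easy difficulties makes
  the pooled-$d'$ median SI slightly convex in $\rho$. Second, the SI
  numerator $(d'_{\text{last}} - d'_{\text{transfer}})$ and denominator
  $(d'_{\text{last}} - d'_{\text{first}})$ share the measurement noise of
  $d'_{\text{last}}$, so their signs agree more often than chance even
  under full transfer: at 220 trials/session this shifts the median SI up
  by about $+0.1$ at $\rho = 0$. Cohort medians additionally scatter by
  roughly $\pm 0.1$, so all statements about the curve are made on the
  median across three cohorts per $\rho$, and the endpoint anchors are
  asserted at $\pm 0.25$ — the accuracy the ratio statistic permits —
  while the quantitative band at the reference $\rho = 0.3$ is
  $[0.15, 0.45]$.

## Resolved design questions

- **SI pooling.** Session-level $d'$ is pooled over the five nonzero
  difficulty levels before the SI is formed (the per-difficulty SI table is
  also emitted). Pooling keeps the denominator away from zero for typical
  learners; subjects with $d'_{\text{last}} = d'_{\text{first}}$ are flagged
  undefined rather than imputed.
- **Boundary-to-choice coding.** Whether a fitted $z < 0.5$ means a
  clockwise or counterclockwise bias depends on an arbitrary coding choice;
  both codings are supported (`coding = "cw_upper"` default).
- **Effector-conditioned fits.** For the control group, the `ses` factor of
  the model space can be bound to the effector blocks instead of sessions
  (`condition = "effector"`), which is how the drift difference between
  effectors is estimated without inventing a session structure.
- **Hedges' g convention.** $g$ is computed from the difference-score SD
  with the small-sample correction $J = 1 - 3/(4\,df - 1)$. Printed effect
  sizes in the literature are not always reproducible from printed $t$ and
  $n$ under any single convention, so $g$ is reported but not used as a
  cross-check target.
- **Partial $\eta^2$.** The standard identity
  $\eta_p^2 = SS_e/(SS_e + SS_{err})$ (equivalently
  $F\,df_1/(F\,df_1+df_2)$) is implemented; each within-subject effect is
  tested against its own subject-interaction error term.

## Known limitations

- The likelihood ignores response-window truncation (above) — estimates
  from deadline tasks inherit that bias by design.
- The conditional DIC penalizes at the subject level; models differing only
  in group-level structure are compared through their subject-level
  shrinkage.
- The Euler sampler's remaining $O(dt)$ bias is negligible at the default
  `dt = 1e-4` but matters if `dt` is raised by two orders of magnitude.
- Between-group comparisons pair posterior draws across independent fits
  arbitrarily (after deterministic thinning to a common length); this is
  exact for the probability statement but does not model any shared
  uncertainty between groups.
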