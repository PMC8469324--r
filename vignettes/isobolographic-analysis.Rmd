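---
title: "Fixed-ratio isobolographic analysis of antinociceptive combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-ratio isobolographic analysis of antinociceptive combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobolab)
```

## The measurement model

The formalin test evokes a biphasic flinching response in the injected hind
paw: an immediate nociceptive phase (0–15 min) and, after a quiescent
interval, an inflammatory phase (15–60 min). The raw record for one animal
is the number of flinches counted in a 1-min window every 5 min for one
hour. `isobolab` treats the observation times as the start minutes of each
window and the counts as flinches/min rates, so the 13-point grid
0, 5, …, 60 defines a piecewise-linear intensity curve whose integral is
well defined over any sub-window.

Effect is quantified per animal by the area under that curve (trapezoidal
rule) and expressed relative to the vehicle arm:

$$\%\,\text{antinociception} \;=\;
  \frac{\mathrm{AUC}_{\text{vehicle}} - \mathrm{AUC}_{\text{treated}}}
       {\mathrm{AUC}_{\text{vehicle}}} \times 100 .$$

Three conventions matter and are fixed in the package:

* **Exact phase partition.** Phase AUCs integrate over [0, 15] and
  [15, 60]; the boundary observation contributes to both windows, so
  phase 1 + phase 2 equals the overall AUC exactly, not just approximately.
* **Phase-specific denominators.** Phase-1 percentages are taken relative
  to the vehicle *phase-1* mean AUC, phase-2 percentages to the phase-2
  mean. Phase shares of an overall denominator would force the phase
  percentages to sum to the overall one, which published formalin-test
  tables do not satisfy; phase-specific normalization is the standard
  reading.
* **Per-animal effects.** Each animal's AUC is converted to a percent
  effect against the vehicle mean, and the group value is the mean of
  those per-animal percentages with its SEM. This is what makes a
  "mean ± SE" per group well defined; the ratio-of-mean-AUCs alternative
  has no animal-level dispersion. Negative percentages (hyperalgesia) are
  retained, never truncated.

## Dose–response fits and effective doses

Over a log-spaced dose range the percent effect is modelled as linear in
$\log_{10}(\text{dose})$ and fitted by ordinary least squares — the
classical working model for effective-dose estimation in this assay; Hill
or probit models are deliberately out of scope. Two fitting modes share
one code path: group means (one row per dose, as printed in summary
tables) and per-animal effects (all animals, which implicitly weights
doses by their group sizes). Group-mean fits are unweighted, since
published tables rarely carry usable dispersion for every row.

The effective dose at level $L$ (ED30 by default) is the inverse
prediction $\widehat{\mathrm{ED}} = 10^{(L - b_0)/b_1}$. Uncertainty is
propagated by the delta method on the $\log_{10}$ scale — the gradient of
$(L - b_0)/b_1$ with respect to $(b_0, b_1)$ applied to the OLS
coefficient covariance — and the dose-scale SE adds the antilog Jacobian
$\widehat{\mathrm{ED}}\ln 10$. Confidence intervals are t-intervals on the
log scale, antilogged, hence asymmetric on the dose scale. An ED falling
outside the fitted dose range is returned with an explicit extrapolation
warning rather than an error: a combination arm whose lowest dose already
exceeds the target level makes mild extrapolation unavoidable, and hiding
it would be worse than flagging it.

A white-box check in the test suite verifies that the delta-method SE
agrees with the empirical SD of 2,000 parametric-bootstrap refits within
15% when the residual noise is small, isolating the linearization from
residual-variance sampling noise by using the generating model's exact
coefficient covariance.

## Fixed-ratio isobolographic analysis

With component effective doses $\mathrm{ED}_A$ and $\mathrm{ED}_B$ and a
fixed fraction $f$ (0.5 for the 1:1 design), Loewe additivity predicts a
total combination dose

$$Z_{\text{add}} = f\,\mathrm{ED}_A + (1-f)\,\mathrm{ED}_B,
\qquad
\mathrm{Var}(Z_{\text{add}}) = f^2 V_A + (1-f)^2 V_B .$$

The combination arm is laid out as a halving series: the top level
contains $f\,\mathrm{ED}_A$ of drug A and $(1-f)\,\mathrm{ED}_B$ of drug
B — so the top total *is* $Z_{\text{add}}$, simultaneously the additivity
line's midpoint and the theoretical ED — and each further level halves
both components. Totals are carried at full precision; two-decimal
rounding is display-only, which is why a printed 4.25 vs 4.27 discrepancy
between report tables is treated as a rounding artifact, not a data
conflict.

The experimental ED, $\mathrm{ED}_E$, comes from the combination arm's own
dose–response fit. Additivity is tested by Student's t:

$$t = \frac{Z_{\text{add}} - \mathrm{ED}_E}
           {\sqrt{SE_T^2 + SE_E^2}},$$

two-sided, with degrees of freedom summed over the two estimates (the
Tallarida convention; the underlying report names only "Student's
t-test"). The interaction index is $\gamma = \mathrm{ED}_E /
Z_{\text{add}}$ with first-order ratio-propagated SE. Classification is
deliberately conservative: *synergistic* requires both $\gamma < 1$ and a
significant t-test; *antagonistic* both $\gamma > 1$ and significance;
everything else is *additive*. The index alone never classifies, because a
$\gamma$ far from 1 with a non-significant test is indistinguishable from
estimation noise at these group sizes.

## The synthetic study generator

Raw animal records for studies of this kind are rarely deposited, so the
package ships a generator with known ground truth; every pipeline stage is
tested against it.

* **Vehicle intensity.** $\lambda(t) = a_1 e^{-t/\tau_1} +
  a_2 e^{-(t-\mu_2)^2/(2\sigma_2^2)}$ with defaults $a_1 = 6$ flinches/min,
  $\tau_1 = 4$ min, $a_2 = 4$ flinches/min, $\mu_2 = 35$ min,
  $\sigma_2 = 12$ min — an early spike decaying before the 15-min
  boundary, quiescence around 10–15 min, and a broad second phase. The
  shape and scale are order-of-magnitude choices for a rat formalin time
  course, not fitted values.
* **Suppression surface.** Each drug's true effect is linear in
  $\log_{10}$ dose on the percent scale, clamped to [0, 99]. The default
  lines (A: slope 22.791, intercept 9.698; B: slope 35.261, intercept
  −31.853) are the OLS refits of the shipped study tables, so default
  simulations live in the same dose decades as the real assay. A
  combination's effect solves the Loewe equation
  $d_A/D_A(E) + d_B/D_B(E) = \psi$ for $E$ (by root bracketing), where
  $D_X(E)$ inverts drug X's line. The single factor $\psi$ is the
  generator's only interaction knob: 1 is additivity, $\psi < 1$ synergy
  (the combination needs only $\psi$ times the additive dose), $\psi > 1$
  antagonism.
* **Noise.** Counts are Poisson with mean $\lambda(t)(1 - E)$,
  independent across animals and times — the simplest model consistent
  with count data; no overdispersion or between-animal random effects by
  default. Groups have $n = 6$ animals, the study-standard size.

**Design anchoring.** `default_dose_groups()` places the single-drug arms
at $\mathrm{ED}\times 10^{\{-0.4,\dots,1.6\}}$ and the combination halving
series so that the *true combination* ED sits at its geometric centre.
Anchoring the series at the additive top instead — the a-priori choice an
experimenter without ground truth must make — pushes its lowest levels
into the clamped zero-effect region of the surface whenever $\psi \ge 1$,
and the floor points bias the fitted line (about +26% on the ED under pure
additivity). Since the generator *knows* the truth, the default design
keeps every arm inside the informative range of the surface; this is a
property of the simulator's study layout, not of the analysis, which
accepts any design.

**What passing tests do and do not show.** The generator reproduces the
biphasic shape, the log-linear margins, fixed-ratio Loewe mixing and
Poisson counting noise. It does not emulate overdispersion, between-animal
heterogeneity, time-varying drug effect, pharmacokinetics, or departures
from log-linearity. Calibration and power results under the generator are
therefore statements about the pipeline's internal consistency at the
study's design sizes, not about any particular real dataset.

## Numerical choices and problem sizes

* Trapezoidal integration interpolates window endpoints linearly, so
  adjacent windows add exactly; agreement with a fine-grid Riemann oracle
  is required to 1e−9.
* The Loewe solve brackets the effect on (0, 0.99) with `uniroot` at
  tolerance 1e−12; unattainably small or large dose pairs return the
  clamp values 0 and 0.99 instead of failing.
* Bonferroni post-hoc comparisons use the pooled one-way ANOVA mean
  square with $t$ on the residual df and $p_{\text{adj}} = \min(1,
  m\,p_{\text{raw}})$, $m$ = number of versus-control comparisons.
* The test suite exercises calibration with 300 replicate studies at
  $\psi = 1$ and $n = 6$ (mean $\hat\gamma$ within [0.85, 1.15]; false
  synergy calls at most 7% plus two binomial Monte-Carlo standard
  errors), detection power with 60 replicates at $\psi = 0.1$ (at least
  80% synergy calls), and parameter recovery with 25 replicate studies at
  $n = 50$ per group (median EDs within 15% of truth). These replicate
  counts are chosen so Monte-Carlo error is small relative to the bands
  being checked while the whole suite stays quick to run.

## Known limitations

* Only two-drug, fixed-ratio combinations; no response-surface models
  (Bliss, ZIP, Chou–Talalay beyond $\gamma$), no nonlinear isoboles for
  drugs with variable potency ratio.
* The linear-in-log-dose model cannot represent effect ceilings; EDs near
  the clamp region of real data will extrapolate (and warn).
* The t-test on the dose scale with summed df is the field's convention,
  not an exact test; under the generator at $n = 6$ its empirical size is
  close to, but slightly above, nominal (about 6–8% at $\alpha = 0.05$),
  which the conservative classification rule absorbs.
* Group-level table inputs carry no animal-level dispersion, so
  table-mode SEs reflect residual scatter of the group means around the
  fitted line only.

## A worked run

```{r worked}
tabs <- popex_asa_tables()
res <- run_full_analysis(drug_a = tabs$drug_a, drug_b = tabs$drug_b,
                         combination = tabs$combination)
res
```

```{r sim}
p <- sim_params(psi = 0.1, seed = 11)
sim <- run_full_analysis(timecourses = simulate_study(p))
sim$result$classification
```
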