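---
title: "Simulating non-inferiority trials under treatment non-adherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating non-inferiority trials under treatment non-adherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niadhere)
```

## The problem

A non-inferiority (NI) trial asks whether an experimental treatment is no
worse than the standard of care by more than a pre-specified margin $M$ on
the failure-probability scale. Non-adherence — participants not receiving
the treatment they were randomized to — is particularly treacherous in
this design: whereas in a superiority trial dilution of the treatment
contrast is conservative, in an NI trial it pushes the intention-to-treat
(ITT) estimate toward zero difference and therefore *toward* the
non-inferiority conclusion, even when the experimental treatment is truly
inferior. `niadhere` provides a potential-outcomes simulator for this
situation, four risk-difference estimators, and Monte-Carlo machinery for
type-I error, power and sample size.

## Notation and data-generating mechanism

For participant $i$: $Z_i \in \{0,1\}$ is the randomized allocation
(1 = experimental arm), drawn iid Bernoulli(0.5); $C_i \in [0,1]^K$ are
prognostic covariates ("disease risk scores"), iid Beta$(a, b)$;
$A_i \in \{a_0, a_1, a_2\}$ is the treatment actually received (control,
experimental, or an alternative inferior to both); and
$Y_i^{a} \in \{0,1\}$ are counterfactual treatment-failure indicators,
with the observed outcome $Y_i = Y_i^{A_i}$ (consistency). Counterfactual
failure probabilities follow a clipped linear probability model,

$$ p_a(C) = \mathrm{clip}\Big\{\mu_a + \gamma \sum_k (C_k - E[C]),\ 0,\ 1\Big\}, $$

with $\mu_{a_0}$ the control failure probability (default 0.4),
$\mu_{a_1} = \mu_{a_0} + \theta$ where $\theta$ is the true average risk
difference, and $\mu_{a_2} = \max(\mu_{a_0}, \mu_{a_1}) + 0.1$, making
the alternative treatment inferior to *both* arms. Because the covariates
are centred, $E[p_1(C) - p_0(C)] = \theta$ whenever no individual
probability is clipped; at large $|\gamma|$ (the slope sweep uses 1, 5
and 9) clipping is heavy and the realized average effect is attenuated —
tests that assess estimator bias under heavy clipping therefore compare
against the population integral of $p_1(C) - p_0(C)$ computed from the
model itself, not against nominal $\theta$.

A note on one deliberate convention: the alternative treatment is 0.1
worse than the *worse* trial arm. Under $\theta = 0.1$ the three failure
probabilities are 0.4 / 0.5 / 0.6 (alternative 0.2 worse than control,
0.1 worse than experimental); under $\theta = 0$ they are 0.4 / 0.4 /
0.5. Descriptions of this configuration elsewhere are ambiguous about
which pairwise gap is 0.1 and which 0.2; the convention here is the one
that keeps "inferior to both arms" true in every configuration.

## The 18 non-adherence scenarios

Scenarios cross three factors: which arm(s) contain non-adherent
participants (experimental, control, both); what the non-adherers
receive (crossover to the opposite arm, or the alternative treatment
$a_2$); and whether non-adherence is driven by non-confounding factors
(independent of prognosis) or by the confounder. Confounded scenarios
additionally carry a direction: *concordant* when the confounder pushes
experimental-treatment uptake and failure risk the same way, *discordant*
when the signs oppose. That yields $3 \times 2 \times (1 + 2) = 18$
patterns:

```{r}
head(scenario_table(), 6)
```

The direction factor is modeled as a two-level label relative to the sign
of the outcome slope $\gamma$; the absolute sign of the confounder effect
on uptake can be overridden at simulation time (`uptake_sign`) without
changing scenario identity.

## Adherence mechanisms

The adherence proportion $\rho$ applies within each targeted arm. Two
modes are provided.

**Threshold (default).** Exactly $\lceil (1-\rho)\, n_{\text{arm}} \rceil$
participants are non-adherent. Non-confounded scenarios pick them
uniformly at random; confounded scenarios pick the participants whose
confounder score (the mean of the $K$ covariates, signed by direction)
makes them least likely to take their own arm's treatment — e.g. when
the confounder lowers experimental uptake, the highest-scoring
participants in the experimental arm and the lowest-scoring in the
control arm cross over. This mode realizes $\rho$ exactly and produces
the starkest selection, but note that adherence is then a *deterministic*
function of the confounder: the excluded stratum has adherence
probability zero, positivity fails, and no weighting analysis can recover
the effect — the adherence model separates perfectly and collapses to
weights of 1 (the estimate coincides with per-protocol). This is a
feature for studying per-protocol bias, not a defect.

**Stochastic.** Adherence is Bernoulli with propensity
$\text{logit}^{-1}(\lambda + \delta s)$, where $s$ is the signed centred
score and $\lambda$ is solved by monotone bisection so the arm-level mean
equals $\rho$. The logistic link keeps every propensity strictly inside
$(0,1)$ (positivity holds) and coincides with the logistic working model
of the inverse-probability-weighted analysis, which is the setting in
which weighting is advertised to remove confounding; with a clipped
linear propensity instead, the working model is misspecified near the
boundary and fully adjusted weighting retains a small systematic bias.
Properties of the weighting and instrumental-variable estimators are
therefore evaluated in stochastic mode, per-protocol selection properties
in threshold mode. The default slope $\delta = 3$ (log-odds scale) gives
moderate confounding: at $\rho = 0.8$ propensities span roughly 0.5–0.95.

## Estimators

All four estimators target a risk difference (experimental minus control
failure probability) with a two-sided Wald-type 95% interval
($z = 1.959964$).

* **ITT** — contrast of observed failure proportions by randomized arm;
  unpooled Wald standard error. Estimates the effect of *assignment*.
* **Per-protocol (PP)** — the same contrast restricted to adherent
  participants. Under confounded non-adherence this population is
  selected on prognosis and the estimate is biased; the direction
  follows the scenario direction (discordant: downward, inflating the NI
  rate; concordant: upward).
* **IPW** — a logistic model of adherence on chosen covariates is fitted
  separately within each arm; adherent participants are weighted by the
  reciprocal of their fitted adherence probability, and the weighted
  failure proportions are contrasted. The default interval uses a
  Horvitz–Thompson-style sandwich variance treating weights as known; a
  nonparametric bootstrap percentile interval is available as a check.
  Weighting removes confounding only for covariates actually adjusted;
  adjusting 1 of 4 active confounders removes only part of the bias.
* **IV** — randomization as a binary instrument: the ITT risk difference
  divided by the between-arm difference in experimental-treatment
  receipt (the linear structural-mean-model / Wald ratio estimator),
  with a delta-method standard error that includes the within-arm
  outcome–treatment covariance. It needs no confounder measurements but
  pays in variance: the ratio inflates the standard error by roughly the
  reciprocal of the compliance difference, so power degrades quickly as
  adherence falls. IV applies only to crossover scenarios (binary
  received treatment); alternative-destination trials are a usage error.

Degenerate situations (an empty per-protocol arm, a vanishing IV
denominator, a non-convergent adherence model) are returned as recorded
failure objects rather than errors; the experiment engine counts them in
a `failed` column and, by default, excludes them from the NI-rate
denominator (a conservative "failures count as not-NI" policy is
available).

## Decision rule, type-I error and power

Non-inferiority is concluded when the upper bound of the two-sided 95%
confidence interval is strictly below the margin (default $M = 0.1$).
With $\theta = 0.1$ — the experimental arm inferior by exactly the
margin — the proportion of iterations concluding non-inferiority is the
empirical type-I error; with $\theta = 0$ it is the power. At the
closed-form design size the full-adherence type-I error is the nominal
one-sided 0.025 and power is 0.90; at $\rho = 0.9$ with two-sided
crossover non-adherence the ITT type-I error roughly quadruples to about
0.1, which a normal-approximation calculation reproduces:
$\Phi\{(M - z\,\mathrm{SE} - \theta(2\rho - 1))/\mathrm{SE}\} \approx 0.094$
at the mixture failure probabilities 0.49/0.41.

## Design tools

`closed_form_n()` is the unpooled normal-approximation sample size
$n = \lceil (z_{1-\alpha} + z_{1-\beta})^2 \{p_c(1-p_c) + p_e(1-p_e)\} /
(M - (p_e - p_c))^2 \rceil$, which gives 505 per arm at the default
design (0.4/0.4, $M = 0.1$, $\alpha = 0.025$ one-sided, 90% power); this
convention (ceiling, one-sided $\alpha$ on a two-sided 95% interval) is
pinned by that anchor. `required_n()` searches a lattice of candidate
sizes (default step 5) by bisection on simulated power, reusing the same
master seed at every candidate (common random numbers) so the empirical
power curve is stable enough to bisect at moderate iteration counts.
`power_curve()` sweeps adherence at fixed $n$.

## Reproducibility and numerical choices

* Each (adherence level, iteration) cell gets a child seed drawn up
  front from the master seed, so results are bit-identical for a given
  master seed and independent of evaluation order, and all methods see
  the same trials.
* Allocation is Bernoulli(0.5) per participant, so arm sizes vary around
  $n/2$; `n_per_arm` is the expected arm size and the total is
  $2\,n_{\text{per arm}}$.
* The threshold non-adherent count uses
  $\lceil (1-\rho) n_{\text{arm}} - 10^{-12} \rceil$; the epsilon guards
  against floating-point noise in products like $0.1 \times 505$.
  Ties in the confounder score are broken randomly.
* The NI comparison is strict (`<`); equality with the margin is judged
  not non-inferior.
* Beta(2, 2) is the default confounder law: symmetric with mean 0.5 and
  no boundary pile-up, consistent with a disease-risk-score reading. The
  shapes are configurable.

## What the simulator does and does not emulate

The generator covers time-fixed binary treatment, binary adherence and a
binary endpoint, with non-adherence patterns treated as pure types (all
crossover, or all alternative-treatment). It does not emulate partial or
time-varying adherence, missing outcomes or censoring, measurement error
in the confounders, mixed destination types within one trial, or
informative cluster/site structure. Passing tests therefore demonstrate
the estimators' behaviour under the stated mechanism, not under every
real-world adherence process; in particular, real confounders are rarely
fully measured, which is exactly the gap between the weighting and
instrumental-variable results the experiments quantify.

Monte-Carlo summaries in the package's test suite use 200–1000
iterations per cell and 10,000 replicates for the attenuation check,
sizes chosen so that three Monte-Carlo standard errors resolve the
effects being asserted; the headline operating characteristics
(type-I error 0.025/0.1, power 0.90) use the full 1000-iteration,
505-per-arm design.
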