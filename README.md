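# niadhere

Simulation tools for studying how treatment non-adherence distorts the
conclusions of two-arm **non-inferiority trials** with binary endpoints,
and for planning such trials when non-adherence is anticipated.

Intended users are trial statisticians and methodologists who need to
quantify, for a concrete design, how much protection each analysis
population (intention-to-treat, per-protocol, inverse-probability
weighting, instrumental variable) actually offers against different
patterns of non-adherence.

## The model in brief

Each simulated participant carries a randomized allocation
$Z \sim \text{Bernoulli}(0.5)$, prognostic covariates
$C \sim \text{Beta}(a,b)^K$, a received treatment
$A \in \{a_0, a_1, a_2\}$ (control, experimental, or an alternative
inferior to both), and counterfactual failure indicators $Y^{a}$ drawn
from a clipped linear probability model

$$p_a(C) = \mathrm{clip}\{\mu_a + \gamma \textstyle\sum_k (C_k - E[C]),\, 0,\, 1\},$$

with $\mu_{a_1} - \mu_{a_0} = \theta$ the true risk difference. The
observed outcome is the counterfactual of the received treatment.
Non-adherence follows one of 18 scenario patterns (which arm is
non-adherent × crossover vs alternative destination × confounded vs
non-confounded mechanism × direction of confounding), and each trial is
analyzed as:

- **ITT**: failure proportions by randomized arm (Wald interval);
- **PP**: the same restricted to adherent participants;
- **IPW**: adherent participants weighted by inverse fitted adherence
  probabilities from per-arm logistic models;
- **IV**: the Wald-ratio / linear structural-mean-model estimator — ITT
  effect divided by the compliance difference — with a delta-method
  interval.

Non-inferiority is concluded when the upper 95% confidence bound of the
risk difference falls below the margin $M$ (default 0.1). Running 1000
such trials with $\theta = M$ gives the empirical type-I error; with
$\theta = 0$, the power.

## Worked example

How does the ITT analysis behave when adherence slips in a trial
designed for full adherence (40% failure in both arms, margin 10%,
one-sided α = 0.025, 90% power → 505 per arm), if non-adherers in both
arms simply cross over for reasons unrelated to prognosis?

```r
library(niadhere)

closed_form_n(0.4, 0.4, margin = 0.1, alpha_one_sided = 0.025, power = 0.9)
#> [1] 505

res <- run_experiment("both-cross-nonconf", methods = c("ITT", "PP", "IV"),
                      adherence_grid = c(0.8, 0.9, 1.0), n_per_arm = 505,
                      params = effect_params(true_effect = 0.1),
                      iterations = 1000, master_seed = 42)
summarize_experiment(res)
#>             scenario adherence method n_per_arm mean_estimate ni_rate   mc_se iterations failed
#> 1 both-cross-nonconf       0.8    ITT       505        0.0594   0.260 0.01387       1000      0
#> 2 both-cross-nonconf       0.8     IV       505        0.0993   0.023 0.00474       1000      0
#> 3 both-cross-nonconf       0.8     PP       505        0.0994   0.023 0.00474       1000      0
#> 4 both-cross-nonconf       0.9    ITT       505        0.0788   0.109 0.00985       1000      0
#> 5 both-cross-nonconf       0.9     IV       505        0.0987   0.021 0.00453       1000      0
#> 6 both-cross-nonconf       0.9     PP       505        0.0989   0.028 0.00522       1000      0
#> 7 both-cross-nonconf       1.0    ITT       505        0.0998   0.034 0.00573       1000      0
#> 8 both-cross-nonconf       1.0     IV       505        0.0998   0.034 0.00573       1000      0
#> 9 both-cross-nonconf       1.0     PP       505        0.0998   0.034 0.00573       1000      0
```

Here the experimental treatment is truly inferior by exactly the margin
(`true_effect = 0.1`), so `ni_rate` is the probability of *wrongly*
concluding non-inferiority. At full adherence all methods sit near the
nominal 0.025 (0.034 here, within Monte-Carlo error). With 10%
crossover in both arms the ITT estimate is diluted toward zero
(mean 0.079 instead of 0.10) and its false-conclusion rate quadruples to
0.109; at 20% crossover it reaches 0.260. Per-protocol and IV stay
unbiased in this *non-confounded* scenario — the confounded scenarios
(`*-conf-disc`, `*-conf-conc`) are where PP breaks down too.

A command-line interface wraps the same functions:

```sh
inst/cli/niadhere scenarios                  # list the 18 scenario labels
inst/cli/niadhere samplesize --p-control 0.4 --p-exp 0.4 --margin 0.1
inst/cli/niadhere experiment --scenario both-cross-nonconf --seed 1 --out results.csv
```

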