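---
title: "A biomarker-stratified Bayesian dose-schedule design: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biomarker-stratified Bayesian dose-schedule design: models, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosesched)
```

`dosesched` implements a phase I/II dose–schedule finding design for
immunotherapy trials with a binary predictive biomarker. This vignette is
the package's account of the science: the joint outcome model and its
assumptions, the prior construction, the utility and decision rules, what
the trial simulator does and does not emulate, and the numerical and design
choices made where the problem left them open.

## The joint outcome model

Each patient treated at dose $d_j$ ($j = 1, \dots, J$, grid rescaled so the
doses have population dispersion 0.5) under schedule $s_k$
($k = 1, \dots, K$) in biomarker subgroup $M \in \{0, 1\}$ contributes
three outcomes, modeled independently given the parameters:

**Immune response.** $Z$, the change in log immune activity from baseline,
follows $N(\mu_Z, \sigma_Z^2)$ with the plateau model
$\mu_Z((j,k),M) = \alpha_k e^{\delta M}\,(1 - e^{-\nu d_j})$.
The constraints $\alpha_k, \delta, \nu > 0$ encode that treatment
increases immune activity, that marker-positive patients reach a higher
plateau (by the factor $e^\delta$), and that the response rises and then
saturates with dose. $\mu_Z = 0$ at zero dose by construction.

**Toxicity.** Dose-limiting toxicity $X$ is Bernoulli with
$\operatorname{logit} p(j,k) = \beta_{0,k} + \beta_1 d_j$, shared across
subgroups. Leaving $\beta_1$ unconstrained in sign admits partial
orderings across schedules; within a schedule toxicity is monotone in dose
whenever $\beta_1 > 0$.

**Efficacy.** The ordinal response $Y \in \{0, 1, 2\}$ (PD, SD, CR/PR) is
parameterized through $\zeta_{(j,k),M} = \operatorname{logit} q_{2,(j,k),M}$
and the proportional-odds shift
$\operatorname{logit}(q_1 + q_2) = \lambda + \zeta$ with $\lambda > 0$,
which guarantees a valid simplex. Rather than a parametric dose–efficacy
curve, adjacent doses are tied by a dynamic model: for $j \ge 2$,
$$\zeta_{(j,k),0} \mid \zeta_{(j-1,k),0} \sim
N\!\left(\zeta_{(j-1,k),0} + \gamma\,
\frac{\mu_Z((j,k),0) - \mu_Z((j-1,k),0)}{M_\mu / 2},\; \sigma_{E,0}^2\right),$$
with $\zeta_{(1,k),0} \sim N(\zeta_{(0,k),0}, \tau^2)$ anchored at a
clinician's guess of the lowest-dose CR/PR rate. The increment is driven by
the modeled immune-response gain, reflecting the assumption that efficacy is
mediated by immune activation; when the immune response plateaus, so does
efficacy. The marker-positive logit borrows strength across subgroups
through a truncated link
$\zeta_{(j,k),1} \sim N(\zeta_{(j,k),0}, \sigma_{E,1}^2)\,
I(\zeta_{(j,k),1} > \zeta_{(j,k),0})$, so marker-positive efficacy
dominates cell-wise. We apply this link at every dose $j = 1, \dots, J$
(the joint posterior is coherent either way; restricting it to $j \ge 2$
would leave the lowest-dose marker-positive logit without a prior).

Three design variants alter the efficacy component: `dose_adjusted` adds a
direct dose increment $\gamma_2 (d_j - d_{j-1})$ for settings where
efficacy is not fully mediated by immune response; `alternative1` drops the
immune response entirely (dose increments in the dynamic mean, no $Z$
likelihood term) and serves as the "ignore the biomarker mechanism"
comparator; `alternative2` swaps the dynamic model for a parametric
proportional-odds regression on $\mu_Z$ and $\mu_Z^2$ with ordered
per-(schedule, subgroup) intercepts. With three response categories the
comparator needs two cut-points; we use $l \in \{0, 1\}$ sharing the
regression slopes, with the subgroup ordering imposed on the intercepts.

## Priors

Priors follow a "minimal prior knowledge" construction from three elicited
quantities: $\hat\alpha_k$ (expected maximum immune response,
marker-negative), $\hat r$ (expected subgroup ratio), and $M_\mu$ (largest
plausible mean immune response). Defaults (per `prior_spec()`):

| Parameter | Prior | Rationale |
|---|---|---|
| $\alpha_k$ | Gamma(1/9, 1/180) | mean $\hat\alpha_k = 20$, SD $3\times$ mean |
| $\delta$ | Gamma(1/9, shape/$\log \hat r$) | mean $\log 1.5$, SD $3\times$ mean |
| $\sigma_Z^2$ | Inv-Gamma(0.1, 0.1) | vague; conjugate Gibbs update |
| $\nu$ | $N(0, 2.3^2)\,I(\nu>0)$ | a 2-SD move of the scaled dose shifts $\nu d$ by $< 4.6$, the span from 1% to 99% saturation |
| $\beta_{0,k}$ | $N(-4, 1)$ | no-dose toxicity centered at 0.018, 97.5th percentile 0.12 |
| $\beta_1$ | Cauchy(0, 2.5) | heavy-tailed on the 0.5-SD dose scale |
| $\gamma$ | Cauchy(0, 2.5)$\,I(\gamma>0)$ | after dividing $\mu_Z$ by $M_\mu/2$ |
| $\lambda$ | Uniform(0, 8) | spans $\Pr(Y>0)$ up to 0.99 when $\Pr(Y=2) \ge 0.03$ |

The Gamma priors use the shape/rate convention; the derived pairs are
checked in the test suite (mean 20 / SD 60 for $\alpha_k$). The
$\delta$ rate is derived analytically as $\text{shape}/\log \hat r =
0.2740$, which matches the conventional rounded pair $(1/9,\, 5/18)$ to
well under its two-decimal precision. `sd_inflation = 5` together with the
other scale arguments reproduces a diffuse-prior sensitivity setting. One
dose scale is used everywhere: the standardized doses enter both the
priors and the likelihood, avoiding silent scale mismatches between the
two.

## Utility and decision rules

The desirability of a combination for subgroup $M$ is
$$U((j,k),M) = q_2 + w_1 q_1 - w_2\, p - w_3\, I(p > \phi_T),$$
with defaults $w_1 = 0.5$ (two SDs equal one CR/PR), $w_2 = 0.3$,
$w_3 = 1.2$, $\phi_T = 0.3$. The over-threshold penalty is a **fixed**
surcharge by default. A proportional form $w_3\, p\, I(p > \phi_T)$ is
available behind `utility_weights(penalty = "proportional")`, but the
built-in truth tables are algebraically consistent only with the fixed
form — back-solving their stored utilities under the proportional
convention produces CR/PR probabilities far outside $[0, \pi]$ — so the
fixed convention is the default and the proportional one is opt-in.

The true optimum per subgroup maximizes $U$ among combinations with
$p < \phi_T$ and $\pi = \Pr(Y > 0) > \phi_E$; during the trial the same
rules are applied to posterior quantities: admissibility requires
$\Pr(p < \phi_T \mid D) > C_T$ and $\Pr(\pi > \phi_E \mid D) > C_E$
(strict inequalities), and plug-in utilities use posterior means with the
penalty indicator evaluated at $\hat p$ (the literal form of the interim
utility). Ties resolve deterministically to the lowest dose, then lowest
schedule, for reproducibility.

**Two-stage algorithm.** Stage I explores each schedule independently:
one cohort at the lowest dose, then escalation one level per visit in
round-robin order, closing a schedule when its highest tried dose fails the
Beta-Binomial screen $\Pr(p < \phi_T) > C_I$ (pseudo-counts 0.1/0.2, so
the data dominate) or the top dose has been tried. Stage II refits the
joint posterior after every cohort and adaptively randomizes each enrolled
patient within their subgroup with probability proportional to the
posterior-mean utility over the admissible set. Design choices the problem
left open, and how we resolved them:

- *Utility floor in randomization.* Nonpositive utilities are floored at
  `rand_floor = 0.01` before normalizing, keeping $\psi$ a proper
  distribution while nearly excluding undesirable combinations.
- *Admissible set support.* Stage II may randomize to any admissible
  combination, including doses a schedule never reached in stage I: the
  admissibility rules are defined over the whole grid and the model shares
  strength across it.
- *Subgroup closure.* When a subgroup's admissible set empties at an
  interim, we conclude no dose is acceptable for that subgroup for the
  remainder of the trial; its later arrivals go off-protocol (not
  enrolled, not counted). The trial terminates early when both subgroups
  close. Admissibility is only evaluated in stage II, after the
  escalation phase has produced data.
- *Cohort formation.* Each arriving patient's subgroup is an independent
  Bernoulli(prevalence) draw; cohorts of size $c$ are formed by arrival
  order. This avoids indefinite waiting for a particular subgroup and
  matches the target prevalence on average.
- *Refit cadence.* Once per cohort, after its outcomes are observed;
  stage-I patients count toward $N$ and enter every stage-II fit.

## Posterior computation

The joint posterior is sampled by Metropolis-within-Gibbs: log-scale
random-walk proposals for the positive parameters
($\alpha_k, \delta, \nu, \gamma$), plain random walks for
$\beta_{0,k}, \beta_1, \lambda$, each $\zeta$ scalar (and the
`alternative2` intercepts), truncations enforced by rejection, and a
conjugate inverse-Gamma Gibbs draw for $\sigma_Z^2$. Heavy-tailed priors
and the truncated links preclude further conjugacy. The likelihood is
evaluated from per-cell sufficient statistics in compiled code, so a
sweep costs $O(JK)$ regardless of sample size. Step sizes adapt toward
30–40% acceptance during burn-in only and are frozen afterwards,
preserving detailed balance for the retained draws. Tail probabilities
are empirical draw fractions, not smoothed.

Initialization uses the elicited prior means for $\alpha_k$ and $\delta$
— their Gamma priors are so dispersed (shape $1/9$) that the prior
*median* is three orders of magnitude below the mean, a pathological
starting point — and prior medians or mid-supports elsewhere
($\nu$ at its half-normal median, $\lambda$ at 4, $\zeta$ at its anchor
with a $+0.1$ subgroup offset to satisfy the truncation).

Chain length is not dictated by the method; the package defaults to
1000 burn-in / 2000 kept sweeps, calibrated by our own diagnostics
(`mcmc_diagnostics()` reports effective sample sizes, split-chain
convergence statistics, and acceptance-rate warnings). The whole-trial
simulations in the test suite use 500/1000 per interim fit — at that
length the per-cell posterior means that drive decisions are stable to
well under the decision margins — and the desk-scale
operating-characteristics runs use 40–50 replicate trials. Full-fidelity
replication (about 1000 replicates) uses the same code and is a
multi-hour single-CPU job.

## The trial simulator

Truth scenarios fix, per cell, the mean immune response, toxicity
probability, and efficacy distribution. Eight built-in scenarios cover a
shared optimum across subgroups, subgroup-specific schedules,
subgroup-specific doses, and multiple optima; user scenarios load from CSV
for arbitrary $J \times K$ grids. Outcomes are generated as
$Z \sim N(\mu_Z^{\text{true}}, \sigma_Z^{\text{true}\,2})$ and $(X, Y)$
from the **exact** discrete cell probabilities induced by a Gumbel copula
($\theta = 1.5$) on the toxicity and efficacy margins — rectangle
inclusion–exclusion of the copula CDF rather than continuous-pair
transformation, which is equivalent in distribution and exactly testable
(margins reproduce to $10^{-12}$). We orient the copula so that the
non-toxic event occupies the lower $u$-tail and response categories
increase along $v$; positive dependence then associates toxicity with
better response, consistent with immune activation driving both. Replicate
seeds are pre-drawn from the master seed, so operating characteristics are
reproducible and independent of execution order.

Two numerical points about the built-in tables deserve notice. Their
utilities are stored to at most two decimals, and the CR/PR probability is
reconstructed by inverting the utility, so reconstruction inherits up to
$0.05/(1 - w_1) = 0.1$ of rounding error for one-decimal entries. The
loader therefore clips back-solved $q_2$ into $[0, \pi]$ when the
excursion is within that rounding bound (`round_tol = 0.06`; the largest
observed excursion is 0.058, in a severely penalized cell whose utility is
stored to one decimal), and `validate_scenario()` checks subgroup
dominance with tolerances tied to the stored precision (0.0101 for
$\pi$, 0.2 for reconstructed $q_2$). Similarly, `true_optimal()` accepts a
tie tolerance: one scenario stores two co-optimal combinations whose
utilities differ by 0.01, i.e. tie at the stored precision.

**What the generator emulates:** immediate, completely observed outcomes;
Bernoulli biomarker prevalence; a constant immune-response SD
($\sigma_Z^{\text{true}} = 2$ by default — the truth tables do not pin it
down; on their immune-response scale of roughly 1–27 this makes $Z$
informative but noisy, and it is configurable); positive
toxicity–efficacy dependence of fixed strength. **What it does not:**
delayed or missing outcomes (and hence accrual suspension), measurement
error or drift in the biomarker assay, non-stationary accrual,
within-patient dose changes, or unknown subgroup membership. Passing
operating-characteristic tests therefore demonstrates the design's
behaviour under the stated generative conditions, not robustness to these
real-data complications.

## Degenerate inputs and edge behaviour

Empty patient data are rejected unless the prior-only sampling hook is
requested; a non-finite starting log-posterior triggers bounded
re-initialization and then a hard error. An empty admissible set raises an
error in `randomization_probabilities()` (callers handle subgroup
closure) and yields "no acceptable dose" in `select_final()`. The copula
handles boundary margins ($u$ or $v$ in $\{0, 1\}$) through its closed
form; `theta < 1`, invalid simplexes, and non-monotone dose grids are
rejected with explicit errors.

## Known limitations

- The sampler is a single-chain random-walk scheme; very flat utility
  surfaces combined with short interim chains can let Monte-Carlo noise
  influence randomization between near-tied combinations (the floor and
  deterministic tie-breaks bound, but do not remove, this).
- The design assumes the biomarker is measured without error and before
  treatment assignment.
- Operating characteristics at desk scale (tens of replicates) carry
  binomial noise of several percentage points; conclusions about small
  selection-percentage differences need the full-fidelity run.
- The independence of the three outcome likelihood terms given parameters
  is a modeling choice (dependence enters only in the generator); it
  keeps estimation stable at early-phase sample sizes.
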