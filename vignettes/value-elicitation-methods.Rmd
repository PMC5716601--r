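---
title: "Estimating value functions from choice, rating and grip-force tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating value functions from choice, rating and grip-force tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valuelicit)
```

## The problem

Neuroeconomics routinely measures the subjective value of an outcome in
three quite different ways: by asking people to *choose* between two
options, to *rate* how much they would like an outcome on an analog scale,
or to *work* for it — here, squeezing a handgrip, with the probability of
winning the outcome set by the force produced. `valuelicit` implements a
complete modelling pipeline for comparing the value functions these three
paradigms elicit when outcomes are composite: a monetary gain $G$ for the
subject and a donation $D$ to a charity, both on a 0–100€ range.

The package covers five layers:

1. a twelve-member space of candidate value functions $V(G, D)$;
2. task-specific observation models linking $V$ to choices, ratings and
   forces;
3. MAP fitting with a Laplace approximation to the log model evidence;
4. group-level random-effects Bayesian model selection (RFX-BMS), including
   family-wise inference over the $12^3$ task-combination space and
   parameter-sharing comparisons;
5. A-optimal adaptive design of choice offers and a convergence analysis of
   estimation efficiency.

Because no trial-level human data are available for this design, the
package ships a synthetic-cohort generator (`simulate_cohort()`) that
emulates the experiment — 19 subjects, 121-offer rating and force tasks, a
200-trial adaptive binary choice task — and every statistical claim the
package makes is demonstrated closed-loop on that generator.

## The model space

The twelve candidate functions (`value_model_space()`) combine the two
dimensions in qualitatively different ways: single-dimension rules
(`mini` $= \min(\alpha G, \beta D)$, i.e. Leontief, and `maxi`), additive
and interactive forms with optional power transforms
($\alpha G^{\delta} + \beta D^{\varepsilon} (+ \gamma G^{\delta} D^{\varepsilon})$),
equity-sensitive forms (a linear model with an $|G - D|$ regressor, and
Fehr–Schmidt inequity aversion
$G - \alpha\max(D - G, 0) - \beta\max(G - D, 0)$), and two production
functions: Cobb–Douglas $G^{\delta} D^{1-\delta}$ and the constant
elasticity of substitution (CES) family

$$ V(G, D) = \left( \alpha G^{\delta} + (1 - \alpha) D^{\delta} \right)^{1/\delta}, $$

whose weight $\alpha \in [0, 1]$ is read as *selfishness* (how much the
subject's own gain counts relative to the donation) and whose exponent
$\delta > 0$ is the *concavity* of preferences. Linear ($\delta = 1$),
Cobb–Douglas ($\delta \to 0$) and Leontief ($\delta \to -\infty$) are
special or limit cases; the test suite verifies the first two numerically.

Parameter domains are enforced by transforms rather than constrained
optimization: positive parameters are log-transformed, unit-interval
parameters logit-transformed, unconstrained ones left alone. Design
choices worth recording:

* **Exponents are restricted to $(0, \infty)$.** The general CES family
  admits $\delta < 0$, but its Leontief limit is already model 1 and
  Cobb–Douglas is model 11, so the negative branch would duplicate members
  of the space while introducing $0^{\delta}$ singularities at the grid
  edges. Fitted concavities for this design sit around 1–2, comfortably
  inside the branch we keep.
* **Cobb–Douglas' exponent is restricted to $(0, 1)$** via the logit
  transform. With $\delta > 1$ the complementary exponent $1 - \delta$
  turns negative and the function diverges on the $D = 0$ edge of the
  grid; within $(0,1)$ both factors are well defined everywhere and the
  conventional interpretation (exponents summing to one) is preserved.
* **Fehr–Schmidt envy/guilt weights are unconstrained.** The conventional
  restriction $0 \le \beta < \alpha$ is an economic hypothesis, not a
  mathematical requirement, and is not imposed.
* $0^{\delta}$ evaluates to 0 for $\delta > 0$; CES is computed by
  factoring out $\max(G, D)$ so that $100^{\delta}$ never overflows even
  for the large exponents an unconstrained optimizer may visit.

## Observation models

Each task observes the same covert value through a different response
channel, and in each case a simple net-utility argument justifies a linear
(or logistic) link:

* **Choice**: the chosen option is won with probability 0.7, the unchosen
  one is foregone, so the net utility of a choice is
  $0.7\,(V_{\text{chosen}} - V_{\text{unchosen}})$ and choices follow a
  softmax on the value difference,
  $P(\text{left}) = 1 / (1 + e^{-(V_L - V_R)/\beta})$ with temperature
  $\beta$ (smaller $\beta$ = more deterministic). The 0.7 factor cancels
  against a rescaled temperature — the package tests this equivalence
  class explicitly.
* **Rating**: ratings have no consequence, so the only sensible objective
  is to minimize $(R - V)^2$; the optimal rating *is* the value, hence a
  linear scaling $R = aV + b$ on the 0–10 scale.
* **Force**: the force $F$ (as a fraction of the subject's maximum) sets
  the win probability, and effort carries a quadratic cost, so the net
  utility is $VF - \gamma F^2$, maximized at $F^* = V / 2\gamma$ — again
  linear in value. Forces are expressed in percent of maximal force
  (10–100, the task imposing a 10% floor).

For fitting, ratings and forces get a Gaussian likelihood around the
clipped linear prediction with a task-specific noise SD fitted as an extra
log-transformed parameter; censoring at the scale bounds is deliberately
ignored in the likelihood (clipping compresses the response distribution
slightly but does not bend the linear scaling in the interior, and a
proper censored likelihood would buy little at these noise levels). Choices
get the Bernoulli-softmax likelihood.

## Fitting and model evidence

`fit_value_model()` maximizes the log joint (log-likelihood plus a
Gaussian prior on the unconstrained parameters) by multistart BFGS — the
first start at the prior mean, the rest randomized, ties broken by the
higher log joint and then the smaller parameter norm. The prior is
$\mathcal{N}(0, 3)$ on every unconstrained coordinate: weakly informative,
spanning roughly $[0.05, 20]$ for log-transformed positive parameters. The
log model evidence is the Laplace free energy

$$ \log p(y) \approx \log p(y \mid \theta^*)\, p(\theta^*)
   + \tfrac{k}{2} \log 2\pi + \tfrac{1}{2} \log \det \Sigma, $$

with $\Sigma$ the inverse Hessian of the negative log joint at the mode
(symmetrized and jitter-repaired if a Cholesky factorization fails). A full
variational-Bayes iteration would target the same free energy; MAP plus
Laplace is simpler and is validated here against two independent oracles
rather than against any toolbox's internals: on linear-Gaussian problems
(the Fehr–Schmidt model with fixed scaling is linear in its parameters)
the Laplace evidence must equal the conjugate closed form to $10^{-6}$,
and on two-parameter CES fits it must agree with a $200 \times 200$ grid
quadrature of the joint within 0.5 nats. Both checks run in the test
suite.

Explained variance is $1 - SS_{\text{res}}/SS_{\text{tot}}$ on the
response scale; for choices the binary outcome is compared against the
predicted probability. This Bernoulli-residual definition is a choice —
reported $R^2$ values for choice tasks are not comparable across
definitions, and ours is documented precisely so they can be interpreted.

`fit_shared()` pools a subject's three tasks and ties one named parameter
(selfishness or concavity) across the equality classes of one of the five
set partitions of {force, rating, choice} (`sharing_partitions()`); all
other parameters stay task-specific. Joint fits are warm-started from
quick per-task fits.

## Group-level model selection

`rfx_bms()` implements the variational Dirichlet-multinomial scheme:
subject-wise posterior model attributions
$u_{nk} \propto \exp(\log E_{nk} + \psi(\alpha_k) - \psi(\Sigma\alpha))$
alternate with the Dirichlet update $\alpha = \alpha_0 + \sum_n u_n$ until
the change in $\alpha$ is below tolerance. Expected frequencies are
$\alpha / \Sigma\alpha$; exceedance probabilities (the posterior
probability of being the most frequent model) use the exact regularized
incomplete Beta form for two models and a seeded Monte-Carlo estimate
($10^6$ draws by default) otherwise.

Family-wise inference over the $12^3 = 1728$ task-combination space
(`build_combined_space()` + `family_inference()`) compares the 12
"same function in all three tasks" triples against the 1716 mixed
triples. Prior Dirichlet counts are rescaled so each *family* carries
equal prior mass (per-model count = family mass / family size); without
this, the larger family would win on prior volume alone.

Two behaviours of this standard scheme are worth knowing and are asserted
as such in the tests. First, a subject with completely flat evidences is
*not* attributed half-and-half: the digamma weighting credits them mostly
to the more frequent model, so expected frequencies do not shrink toward
uniform when such a subject is added (they stay essentially unchanged).
Second, for the same reason, equal family-level *prior mass* does not
guarantee equal family-level *posterior* frequencies under flat evidence
when family sizes differ. Both are properties of the fixed point, not
bugs, and neither affects regimes with informative evidence.

## Adaptive design and convergence

The choice task's offers are optimized online against an a-priori value
model $V = \beta_G G + \beta_D D + \beta_{GD} G D$ observed through a
fixed-temperature softmax. Candidate offer pairs are the *informative*
ones (`informative_pairs()`): the two offers differ on both dimensions and
neither dominates — on the 10€ grid, $\binom{11}{2}^2 = 3025$ of the
$121^2 = 14641$ ordered combinations. `select_next_pair()` evaluates, for
each candidate, the expected trace of the post-update posterior covariance
(the one-step Bayesian preposterior, averaging the two choice outcomes
under the current predictive probabilities — the standard A-optimal
criterion) and returns the minimizer; mirroring the task, the search is
restricted to pairs differing from the previous trial along a single
dimension, alternating gain and donation, with seeded uniform
tie-breaking. The posterior refresh (`update_design_posterior()`) appends
the new trial to the accumulated logistic likelihood and relocates the
Laplace posterior by damped Newton steps warm-started at the previous
mode, so the sequential posterior agrees with a batch refit up to Newton
convergence (the suite checks 10% on the trace; agreement is in practice
much tighter). The trace of the covariance can tick up transiently while
the mode is still moving — curvature is re-evaluated at each new mode —
which is expected of a Laplace approximation and dissipates as trials
accumulate.

Estimation efficiency is summarized by the per-trial precision gain
$\gamma_t = (\sigma_{t-1} - \sigma_t) / \sigma_{t-1}$, where $\sigma_t$ is
the mean posterior variance over the fitted parameters after refitting on
trials $1..t$ (`convergence_analysis()`, warm-started incremental
refits). The convergence threshold is 5%: the threshold trial is the
*last* trial whose gain exceeds it. The analysis runs on the native trial
order or on an "optimized" order (`optimized_order()`): the first eleven
trials are a seeded random draw from offers with both amounts in
{0, 30, 50, 70, 100}€ (the range-coverage rule; the coverage set has 25
offers, so an eleven-trial draw cannot be unique and a seeded subset is
the only reproducible reading), and the remainder are appended greedily by
minimum trace of the local Laplace posterior, accumulating squared
prediction Jacobians at the full-data MAP — the standard local
A-optimality criterion.

## The synthetic cohort

`cohort_config()` fixes the study conditions: 19 subjects; 121-offer
rating and force designs, each offer once, randomized into sessions of
40/41/40; 200 informative choice pairs on the 1€ grid (random by default —
decoupling cohort generation from the adaptive-design engine keeps tests
fast; `run_adaptive_session()` provides the online variant). Generative
parameters are population draws:

* selfishness $\alpha$: logistic-normal centred at 0.58 (logit-scale SD
  0.5), one draw per subject shared by all three tasks — selfishness
  behaves as a stable trait;
* concavity $\delta$: log-normal draws *independent across tasks*, centred
  at task-specific values $1.5 \times (1.32, 1.07, 0.73)$ for force,
  rating and choice (≈ 1.98, 1.60, 1.10) with log-scale SD 0.5. Both the
  centres and the dispersion are taken from the group statistics reported
  for this design, and the independence mirrors the observed absence of
  cross-task correlation in concavity;
* softmax temperature: log-normal centred at 8 utility units, calibrated
  once so that simulated choices are predictable from the true values at a
  balanced accuracy near 0.8, matching the accuracy regime reported for
  the design;
* rating scale: slope ≈ 0.1 scale units per utility unit, intercept ≈ 0,
  Gaussian noise SD 1.0 scale units; force scale: slope ≈ 1, intercept ≈
  20, noise SD 8 percentage points — the force defaults put the average
  simulated force near 70% of maximum, the level grip studies with this
  incentive range report. Force feedback is Bernoulli(force/100); rating
  and choice feedback Bernoulli(0.7).

No fatigue process is simulated (the model-free stage checks that trial
and session effects on residuals are null, as they were in the original
data), and no reaction times or inter-session structure.

What passing closed-loop tests do and do not show: they demonstrate that
the pipeline is *consistent* — when data truly come from a shared CES
value function with these noise levels, the pipeline recovers the
function, the sharing pattern and the parameters. They cannot show that
human data satisfy those assumptions; real response distributions are
censored and heteroskedastic in ways the Gaussian likelihood only
approximates, and real concavity differences could partly reflect
non-quadratic effort costs rather than value curvature.

## Numerical choices and problem sizes

Optimizer: BFGS, relative tolerance $10^{-10}$, up to 500 iterations, 8
restarts by default (2–4 in the batched pipeline stages, which is
sufficient at these data sizes — the joint is smooth and the warm starts
good). Hessians by finite differences (`stats::optimHess`), symmetrized,
with escalating diagonal jitter if not positive definite. RFX-BMS
tolerance $10^{-6}$ on $\max|\Delta\alpha|$, 500 iterations maximum.
Exceedance probabilities: $10^6$ Monte-Carlo draws (blocked to bound
memory), exact Beta form whenever only two models or families compete.

The shipped tests and the acceptance script run the cohort analyses at
the study's own scale (19 subjects) but with restart counts reduced as
above, convergence analyses on a subset of subjects with a stride of 2
trials, and Monte-Carlo sizes of $2\times10^5$–$10^6$; these sizes were
chosen so the full closed loop demonstrates every claim while remaining
comfortably runnable on a laptop core.

## Known limitations

* The evidence is a Laplace approximation; strongly multimodal or
  heavy-tailed posteriors (e.g. near-deterministic choosers, where the
  temperature is weakly identified) are summarized only locally. The
  multistart and the grid-quadrature oracle bound the damage at this
  problem scale.
* The choice-task $R^2$ definition is package-specific (see above).
* The family-prior convention (equal mass per family) is one of several
  in use; results with informative evidence are insensitive to it, but
  degenerate flat-evidence cases are not (see the group-level section).
* The adaptive-design engine optimizes greedily one trial ahead; no
  multi-step or mutual-information criterion is provided.
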