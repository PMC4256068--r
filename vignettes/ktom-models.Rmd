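---
title: "Models and methods: recursive theory-of-mind learning in repeated games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: recursive theory-of-mind learning in repeated games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktom)
```

## The problem

In a repeated competitive 2x2 game such as hide-and-seek (matching pennies),
each player's payoff depends on the simultaneous choice of the other. A
player who treats the opponent as a stationary random process can track
choice frequencies; a player who *mentalizes* instead attributes beliefs to
the opponent — "she thinks that I think..." — and exploits the structure of
the opponent's own learning. This package implements a family of learners
that formalizes that distinction, a seeded arena for dyadic play, and the
statistical machinery needed to ask, from choice sequences alone, which
learner a subject most plausibly is.

## The k-ToM learner family

**0-ToM.** The non-mentalizing baseline of the family assumes the opponent
picks option 1 with probability $s(x_t)$, where $s$ is the logistic sigmoid
and the log-odds $x_t$ drifts across trials as a Gaussian random walk with
volatility $\lambda$. The agent carries a Gaussian posterior
$N(\mu_t, \sigma_t)$ over $x_t$ and updates it with a one-step variational
(Laplace) scheme:

$$\sigma_{t+1} = \Big(\frac{1}{\sigma_t + \lambda} + s(\mu_t)\big(1 - s(\mu_t)\big)\Big)^{-1},
\qquad
\mu_{t+1} = \mu_t + \sigma_{t+1}\,\big(o_t - s(\mu_t)\big),$$

a prediction-error rule whose effective learning rate is the updated
variance: it grows with the assumed volatility and with current
uncertainty. As $\lambda \to 0$ the predicted probability converges to the
opponent's empirical choice frequency, i.e. fictitious play. The predictive
probability integrates out the posterior uncertainty,
$\int s(x)\,N(x;\mu,\sigma)\,dx$, which shrinks predictions toward 0.5 when
the agent is unsure.

**k-ToM (k >= 1).** A k-ToM agent assumes its opponent is a k'-ToM agent
with $k' < k$ and maintains, per candidate level $k'$:

* a posterior probability that the opponent has sophistication $k'$ (the
  *level posterior*), and
* Gaussian beliefs over that scenario's hidden states: the opponent's
  current prediction of the agent's own next move, on the log-odds scale
  (a second-order belief $q$), and the opponent's log-volatility and
  log-temperature.

The observation map pushes a scenario's hidden states through the
opponent's own decision rule: the opponent predicts the agent's move from
$q$, values its two options under the game's payoffs, and softmaxes at its
inferred temperature. On every trial the level posterior is re-weighted by
each scenario's likelihood of the opponent's observed action, and each
scenario's hidden-state beliefs receive a gradient-weighted variational
update scaled by the scenario's posterior weight — an implausible scenario
is left (smoothly) unchanged. Finally the second-order belief is advanced
by simulating the modelled opponent's own learning step on the agent's
revealed action: analytically for a level-0 opponent, and through a
recursively instantiated k'-ToM simulator (run at the current
parameter-belief means) for deeper scenarios. Recursion depth is capped at
k = 3.

All members of the family have three free parameters: prior volatility
$\lambda > 0$, behavioural temperature $\beta > 0$, and a session-specific
bias. Actions are valued by expected payoff and chosen through the shared
softmax policy $P(a = 1) = s(\Delta V / \beta + b)$; the bias enters the
log-odds additively rather than being rescaled by the temperature, because
it represents a session-level preference for one option, not decision
noise.

### Design choices inside the recursion

* **Predictive integral.** The sigmoid-Gaussian integral is evaluated by
  fixed 21-node Gauss-Hermite quadrature. A closed-form probit-style moment
  match ($s(\mu/\sqrt{1 + c\sigma})$) was considered but errs by up to
  ~1.3e-2 in probability at moderate uncertainty, while the quadrature is
  exact to < 1e-6 at negligible cost and retains the two properties that
  matter: monotone in $\mu$, shrinking to 0.5 as $\sigma$ grows.
* **Gradients.** The observation map has a simple closed form, so its
  gradient in the hidden states is computed analytically (the map does not
  depend on the opponent's log-volatility, which instead drives the
  second-order belief dynamics).
* **What diffuses.** The agent's volatility parameter diffuses only the
  dynamic second-order belief $q$; the opponent's parameters are static
  unknowns whose uncertainty can only shrink. Diffusing the parameter
  beliefs as well makes every mentalizing agent degenerate within a few
  dozen trials — each prediction error inflates the inferred opponent
  temperature until the agent concludes its opponent is pure noise and
  plays randomly — which contradicts the characteristic imitation and
  alternation signatures this family is known for (see below).
* **"Like-me" initialization.** Parameter beliefs start centred on the
  agent's *own* log-volatility and log-temperature (variance 1), and the
  recursive simulators inherit the same parameters, so the prior assumption
  is "my opponent is like me". Centring them instead at 0 (opponent
  temperature 1) makes every scenario's predicted choice probabilities
  cluster so tightly around 0.5 that scenarios become indistinguishable.
  The second-order belief starts at 0 (variance 1): no initial information
  about what the opponent expects.
* **Tie-breaking.** At choice probability exactly 0.5 the action is decided
  by the seeded uniform draw itself, never by a fixed rule, avoiding
  degenerate deterministic cycles between symmetric agents.

## The comparison set

The package implements the full comparison set used with this task family,
factorized by *Bayesian?* (B+/B-) and *mentalizing?* (T+/T-):

| model | B | T | free parameters |
|---|---|---|---|
| k-ToM (k = 1..3) | + | + | $\lambda$, $\beta$, bias (3) |
| 0-ToM | + | - | $\lambda$, $\beta$, bias (3) |
| hBL (alias HGF) | + | - | $\kappa$, $\omega$, $\theta$, $\beta$, bias (5) |
| n-BSL (n = 1..3) | + | - | $\lambda$, $\beta$, bias (3) |
| 1-Inf | - | + | $\eta_1$, $\eta_2$, bias (3) |
| 2-Inf | - | + | $\eta_1$, $\eta_2$, $\eta_3$, bias (4) |
| RL | - | - | $\alpha$, $\beta$, bias (3) |
| WSLS | - | - | $\beta$, bias (2) |
| Nash | - | - | bias (1) |

* **hBL** is a hierarchical (volatility-tracking) extension of 0-ToM: the
  tendency's drift variance is $\exp(\kappa \mu_3 + \omega)$ where the
  log-volatility state $\mu_3$ is itself tracked by a Gaussian belief with
  drift $\theta$ (the standard three-level binary hierarchical Gaussian
  filter). $\kappa$ and $\omega$ are the two parameters it adds over a
  fixed-volatility tracker; $\theta$ replaces the fixed $\lambda$.
* **n-BSL** duplicates the 0-ToM tracker across the $2^n$ contexts defined
  by the last $n$ opponent actions and updates only the active context;
  during the first $n$ trials the prediction is 0.5.
* **k-Inf** are heuristic mentalizers: the tracked opponent tendency moves
  by $\eta_1$ times the prediction error plus an influence correction
  ($\eta_2$) proportional to the opponent's own prediction error about the
  agent, signed by the opponent's best-response direction; 2-Inf applies
  the same logic ($\eta_3$) to its estimate of the opponent's prediction.
  The published parameter counts (3 and 4) are only consistent with these
  models not carrying a separate temperature, so their policy uses a unit
  softmax slope: the $\eta$ weights set the scale of the tracked
  probability, making a temperature redundant. Probabilities are clipped to
  $(10^{-6}, 1 - 10^{-6})$ because the additive update can exit $(0,1)$.
* **WSLS** repeats a rewarded choice and switches otherwise, through the
  shared softmax (its two parameters). **Nash** plays a constant
  (possibly biased) mixture — in hide-and-seek the equilibrium is the fair
  coin, so Nash doubles as the chance model. **RB**, the biased random
  opponent used in the synthetic design, is a fixed 65/35 coin and is not a
  fitted model.

## The simulation arena and the synthetic cohort

`play_dyad()` runs simultaneous-move, seeded games: both agents act on
trial $t$ from beliefs formed strictly before $t$, and each agent draws
from its own uniform stream derived from the master seed by a fixed counter
scheme, so a session is bit-reproducible and independent of roster changes.
`simulate_cohort()` mirrors the reference experimental design: by default
26 subjects each play 60-trial sessions against four opponents — RB (65%
bias, counterbalanced), 0-ToM, 1-ToM and 2-ToM — in randomized order.

**Default simulation parameters.** The published account of this task
family reports the behaviour of its simulated agents (kernel shapes, fit
accuracies) but not the underlying volatility and temperature constants.
The package therefore fixes its standard regime once: $\lambda = e^{-1}
\approx 0.37$ (appreciable drift on the 60-trial scale) and $\beta = 0.15$
(mostly exploitative play; choice probabilities near saturation when the
value difference approaches its +/-1 bound). This operating point
reproduces the published endpoint regularities — linear decodability of
around 86% for 0-ToM falling to the low 70s for 3-ToM, imitation kernels
for 0-ToM, alternation kernels for 1-ToM, and a positive earnings gradient
in sophistication — and is frozen across all studies in the package. The
session bias defaults to 0. For cohort and recovery studies,
`cohort_param_sampler()` adds mild between-subject heterogeneity
(log-normal jitter, sd 0.5, on positive parameters; additive sd 0.5 on
biases and influence weights), a dispersion wide enough to make recovery
non-trivial but narrow enough that every subject remains in a sensible
operating range.

**What the generator does and does not emulate.** Simulated cohorts
reproduce the design's structure (roster, trial counts, counterbalancing,
seeding) and the agents' learning dynamics. They contain no framing
manipulation — framing changes which model a human brings to the task, not
the generative loop — no response deadlines or missed trials (the
missed-trial scoring rule, a point to the other player, is honoured by the
data reader for observed data), and no within-session non-stationarity of
the subject's strategy. Passing recovery tests on such cohorts shows the
pipeline is consistent and identifiable under the model family's own
assumptions; it cannot certify that human data satisfy those assumptions.

## Volterra decomposition

`fit_volterra()` regresses each binary choice on both players' previous
$L$ actions (default $L = 5$; the kernels of interest are short-memory)
with a logistic link. Regressors are coded +/-1 so that a positive weight
on an opponent lag literally reads "copies the opponent" and a negative
weight on an own lag "alternates own choices". A ridge penalty of $10^{-3}$
on the lag weights (not the intercept) keeps estimates bounded when
near-deterministic agents produce separable designs; warm-up trials
$t \le L$ are excluded. Fit accuracy is the in-sample fraction of trials
where the more probable predicted choice matches the actual one.
`chance_band()` gives the null reference (per-lag extremum weights over
i.i.d. coin-flip sequences, the conventional definition — note that
extrema of many null fits are intrinsically seed-sensitive, so the package's
stability test tracks a 95% quantile band instead), and
`ktom_reference_kernels()` produces the mean kernels of simulated k-ToM
agents, whose level-(k+1) member serves as the "best response" reference
when scoring a subject's kernel against opponent level k
(`best_response_similarity()`, a Pearson correlation over the concatenated
lag weights).

## Model evidence and group-level selection

`sequence_loglik()` replays a model deterministically along a recorded
history and accumulates the log-probability of each observed choice.
`log_evidence()` approximates the marginal likelihood by a Laplace
expansion around the posterior mode on an unconstrained scale (log for
positive parameters, log-odds for learning rates, identity for biases and
influence weights), with independent $N(0, 3)$ priors — weakly informative
over the dynamic range within which the sigmoid nonlinearity
discriminates behaviour. The penalized objective is optimized by BFGS from
the prior mean plus random prior draws (default 4 starts; the large
recovery studies use 2, which left attribution decisions unchanged in
calibration runs while halving cost). The forward pass for every learner
is implemented twice: as the R agent objects (the reference) and as a
compiled single-pass engine used inside the optimizer; an equivalence test
keeps the two within 1e-10 of each other. The Volterra decomposition
enters model comparisons as a logistic likelihood with its $2L + 1$
weights as parameters under the same prior scheme. The session bias is
fitted per session and never shared across sessions.

`rfx_bms()` performs random-effects group selection: model identity is a
random effect across subjects with Dirichlet-multinomial structure, fitted
by the standard variational fixed point from a uniform Dirichlet prior
($\alpha_0 = 1$). Exceedance probabilities use $10^5$ seeded Dirichlet
draws (reproducible to about +/-0.01). Family-level inference
(`family_bms()`) marginalizes within-family model identity by log-sum-exp
with equal within-family priors — marginalization, not maximum, is what
"family" means — and `restricted_bms()` re-runs selection inside a winning
family. `between_condition_test()` scores, per subject, a "same family in
both conditions" hypothesis against an "independent families" hypothesis
and submits the two-column evidence to the same machinery; the
construction is symmetric in the condition labels.

## Numerical and scale choices

* Likelihood probabilities are clipped at $10^{-12}$; level-posterior
  likelihood weights at $10^{-12}$; the hBL volatility exponent at +/-30;
  the top-level hBL precision at $10^{-6}$.
* A non-positive-definite Hessian at the optimum (rare, typically at a
  prior-dominated flat optimum) falls back to the prior curvature and
  flags the fit as non-converged.
* The package's standard study sizes — 400 Monte-Carlo games per
  sophistication level for reference kernels, 500 games per pairing for
  tournament contrasts, 100 records per generator for recovery, 64
  subjects for planted-mixture recovery — were chosen so that Monte-Carlo
  error is small against the effect sizes being checked while keeping each
  study in the minutes range on one core.

## Known limitations

* The k-ToM update is a variational approximation evaluated at belief
  means; no claim is made that it matches any particular reference
  implementation trial-by-trial, only that it satisfies the family's
  defining contracts (level-posterior reweighting, posterior-scaled
  hidden-state updates, recursive opponent simulation).
* The opponent's log-volatility is weakly identified by design: it shapes
  predictions only through the second-order belief dynamics.
* Model evidence uses a single-mode Laplace approximation; multimodality
  is handled by restarts, not mixture corrections.
* Group-level tools implement plain exceedance probabilities, not the
  protected variant.
* In synthetic recovery studies, win-stay/lose-switch and the deeper
  sequence learners remain distinguishable at 60 trials — their evidences
  can come within a fraction of a nat on 2-BSL data, but the true model's
  likelihood advantage almost always survives the complexity penalty. The
  often-noted practical confusability of these models concerns empirical
  data, for which no model in the set is the true generator; recovery on
  model-generated data cannot exhibit it.
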