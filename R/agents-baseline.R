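#' @title Baseline (non-mentalizing and non-Bayesian) learners
#'
#' @description
#' The comparison set against which the k-ToM family is evaluated: a biased
#' random policy (RB), the static Nash/chance policy, win-stay/lose-switch
#' (WSLS), Rescorla-Wagner reinforcement learning (RL), Bayesian sequence
#' learners conditioning on the last n opponent actions (n-BSL), a
#' hierarchical Bayesian learner that also tracks the volatility of the
#' opponent's tendency (hBL, alias HGF), and the heuristic influence models
#' (1-Inf, 2-Inf) that correct their tracking for the effect of their own
#' actions on the opponent. All share the learner interface of
#' [make_agent()].
#'
#' @name baseline_agents
NULL

INF_EPS <- 1e-6  # probability clipping bound for the influence models

# ---- biased random opponent --------------------------------------------

new_rb <- function(params, role, payoff) {
  structure(list(state = list()), class = c("rb_agent", "ktom_agentobj"))
}

#' @export
choice_prob.rb_agent <- function(agent) {
  if (agent$params$preferred == 1) agent$params$p else 1 - agent$params$p
}

#' @export
agent_update.rb_agent <- function(agent, own, opp) agent

# ---- Nash / chance -----------------------------------------------------

new_nash <- function(params, role, payoff) {
  structure(list(state = list()), class = c("nash_agent", "ktom_agentobj"))
}

#' @export
choice_prob.nash_agent <- function(agent) sigmoid(agent$params$bias)

#' @export
agent_update.nash_agent <- function(agent, own, opp) agent

#' Static Nash (chance) policy
#'
#' In hide-and-seek the mixed-strategy Nash equilibrium plays both options
#' with probability 1/2, which makes the policy a constant-probability chance
#' model, possibly biased toward one option.
#'
#' @param bias log-odds preference for option 1.
#' @return Constant per-trial probability of option 1.
#' @export
nash_policy <- function(bias = 0) sigmoid(bias)

#' Biased random policy
#'
#' The control opponent used in the synthetic cohorts: an i.i.d. random
#' sequence with a 65% bias for one (configurable) option, independent of the
#' other player's actions.
#'
#' @param p bias of the preferred option.
#' @param preferred which option (0/1) carries the bias.
#' @return Per-trial probability of option 1.
#' @export
rb_policy <- function(p = 0.65, preferred = 1) if (preferred == 1) p else 1 - p

# ---- win-stay / lose-switch --------------------------------------------

new_wsls <- function(params, role, payoff) {
  structure(list(state = list(last_choice = NA_integer_,
                              last_outcome = NA_integer_)),
            class = c("wsls_agent", "ktom_agentobj"))
}

#' Win-stay/lose-switch target preference
#'
#' Returns the signed preference (+1: option 1, -1: option 0, 0: no
#' information) of the deterministic stay/switch rule: repeat the last choice
#' after a success, switch after a failure. The preference is passed through
#' the shared softmax, so WSLS keeps two free parameters (temperature, bias).
#'
#' @param last_choice previous action (0/1) or `NA` on the first trial.
#' @param last_outcome previous outcome (1 = correct) or `NA`.
#' @return Signed preference in \{-1, 0, +1\}.
#' @export
wsls_policy <- function(last_choice, last_outcome) {
  if (is.na(last_choice) || is.na(last_outcome)) return(0)
  target <- if (last_outcome == 1) last_choice else 1 - last_choice
  if (target == 1) 1 else -1
}

#' @export
choice_prob.wsls_agent <- function(agent) {
  dv <- wsls_policy(agent$state$last_choice, agent$state$last_outcome)
  softmax_prob(dv, agent$params$temperature, agent$params$bias)
}

#' @export
agent_update.wsls_agent <- function(agent, own, opp) {
  r <- match(agent$role, agent$payoff$roles)
  agent$state$last_choice <- own
  agent$state$last_outcome <- as.integer(agent$payoff$u[r, own + 1, opp + 1] ==
                                           max(agent$payoff$u[r, , ]))
  agent
}

# ---- reinforcement learning --------------------------------------------

new_rl <- function(params, role, payoff) {
  structure(list(state = list(values = c(0.5, 0.5))),  # indifferent start
            class = c("rl_agent", "ktom_agentobj"))
}

#' Rescorla-Wagner value update
#'
#' Moves the chosen option's value toward the received reward in proportion
#' to the reward prediction error; the unchosen option is untouched.
#'
#' @param values numeric length-2 vector of option values (option 0, 1).
#' @param chosen chosen option (0/1).
#' @param reward received reward.
#' @param alpha learning rate in (0, 1].
#' @return Updated value vector.
#' @export
rl_update <- function(values, chosen, reward, alpha) {
  stopifnot(alpha > 0, alpha <= 1, chosen %in% c(0, 1))
  values[chosen + 1] <- values[chosen + 1] + alpha * (reward - values[chosen + 1])
  values
}

#' @export
choice_prob.rl_agent <- function(agent) {
  v <- agent$state$values
  softmax_prob(v[2] - v[1], agent$params$temperature, agent$params$bias)
}

#' @export
agent_update.rl_agent <- function(agent, own, opp) {
  reward <- payoff(agent$payoff, agent$role, own, opp)
  agent$state$values <- rl_update(agent$state$values, own, reward,
                                  agent$params$alpha)
  agent
}

# ---- Bayesian sequence learners ----------------------------------------

new_bsl <- function(n) function(params, role, payoff) {
  structure(list(n = n,
                 state = list(mu = rep(0, 2^n), sigma = rep(1, 2^n),
                              hist = rep(NA_integer_, n))),
            class = c("bsl_agent", "ktom_agentobj"))
}

# 1-based cell index of an opponent-action context (most recent action last)
bsl_context_index <- function(hist) sum(hist * 2^(seq_along(hist) - 1)) + 1L

#' @export
agent_predict.bsl_agent <- function(agent) {
  h <- agent$state$hist
  if (anyNA(h)) return(0.5)  # warm-up: context undefined
  i <- bsl_context_index(h)
  sigmoid_gauss(agent$state$mu[i], agent$state$sigma[i])
}

#' @export
agent_update.bsl_agent <- function(agent, own, opp) {
  st <- agent$state
  if (!anyNA(st$hist)) {
    i <- bsl_context_index(st$hist)
    stp <- .tom0_step(st$mu[i], st$sigma[i], opp, agent$params$volatility)
    st$mu[i] <- stp[1]
    st$sigma[i] <- stp[2]
  }
  st$hist <- c(st$hist[-1], opp)
  agent$state <- st
  agent
}

#' Sequence-learner belief-bank update
#'
#' Functional form of the n-BSL update: one frequency-tracking Gaussian
#' belief per length-n opponent-action context (2^n cells); only the cell
#' indexed by the current context is updated, with the same rule as
#' [tom0_update()]. During the first n trials the context is undefined and
#' nothing is updated.
#'
#' @param bank list with elements `mu`, `sigma` (length 2^n) and `hist`
#'   (last n opponent actions, oldest first, `NA` while warming up).
#' @param opp_action observed opponent action (0/1).
#' @param volatility diffusion variance per trial.
#' @return The updated bank.
#' @export
bsl_update <- function(bank, opp_action, volatility) {
  ag <- structure(list(state = bank, params = list(volatility = volatility)),
                  class = c("bsl_agent", "ktom_agentobj"))
  agent_update(ag, own = NA, opp = opp_action)$state
}

# ---- hierarchical Bayesian learner (3-level binary HGF) ----------------

new_hbl <- function(params, role, payoff) {
  structure(list(state = list(mu2 = 0, sigma2 = 1, mu3 = 0, sigma3 = 1)),
            class = c("hbl_agent", "ktom_agentobj"))
}

#' @export
agent_predict.hbl_agent <- function(agent) {
  st <- agent$state
  v2 <- exp(agent$params$kappa * st$mu3 + agent$params$omega)
  sigmoid_gauss(st$mu2, st$sigma2 + v2)
}

#' @export
agent_update.hbl_agent <- function(agent, own, opp) {
  agent$state <- hbl_update(agent$state, opp, agent$params$kappa,
                            agent$params$omega, agent$params$theta)
  agent
}

#' Hierarchical Gaussian filter update for binary observations
#'
#' One trial of the two-level volatility-tracking filter: the opponent's
#' choice tendency (log-odds, level 2) diffuses with a variance
#' `exp(kappa * mu3 + omega)` controlled by a higher log-volatility state
#' (level 3) that is itself tracked by a Gaussian belief with drift variance
#' `theta`. The coupling parameters `kappa` and `omega` are the two
#' parameters this learner adds over a fixed-volatility tracker.
#'
#' @param state list with `mu2`, `sigma2`, `mu3`, `sigma3`.
#' @param obs binary observation (opponent action).
#' @param kappa,omega coupling of the volatility state to the tendency drift.
#' @param theta drift variance of the volatility state.
#' @return Updated state list.
#' @export
hbl_update <- function(state, obs, kappa, omega, theta) {
  mu2 <- state$mu2; sigma2 <- state$sigma2
  mu3 <- state$mu3; sigma3 <- state$sigma3

  # level 2: tendency update at the volatility implied by level 3; the
  # exponent is clamped so extreme parameter draws stay finite
  v2 <- exp(pmin(pmax(kappa * mu3 + omega, -30), 30))
  muhat1 <- sigmoid(mu2)
  pihat2 <- 1 / (sigma2 + v2)
  pi2 <- pihat2 + muhat1 * (1 - muhat1)
  mu2_new <- mu2 + (obs - muhat1) / pi2
  sigma2_new <- 1 / pi2

  # level 3: volatility update driven by the level-2 prediction error
  pihat3 <- 1 / (sigma3 + theta)
  w2 <- v2 * pihat2
  r2 <- (v2 - sigma2) * pihat2
  delta2 <- (sigma2_new + (mu2_new - mu2)^2) * pihat2 - 1
  pi3 <- pihat3 + (kappa^2 / 2) * w2 * (w2 + r2 * delta2)
  pi3 <- max(pi3, 1e-6)  # keep the volatility belief proper
  mu3_new <- mu3 + (kappa / 2) * (w2 / pi3) * delta2

  list(mu2 = mu2_new, sigma2 = sigma2_new, mu3 = mu3_new, sigma3 = 1 / pi3)
}

# ---- influence models --------------------------------------------------

new_inf <- function(order) function(params, role, payoff) {
  structure(list(order = order,
                 state = list(p = 0.5, q = 0.5)),
            class = c("inf_agent", "ktom_agentobj"))
}

#' @export
agent_predict.inf_agent <- function(agent) agent$state$p

#' @export
choice_prob.inf_agent <- function(agent) {
  # unit softmax slope: the eta weights already set the scale of p
  sigmoid(expected_value_diff(agent$payoff, agent$role, agent$state$p) +
            agent$params$bias)
}

# sign of d(value difference)/d(predicted probability) for a role: +1 when a
# player wants to match the other's choice, -1 when she wants to mismatch
.br_slope_sign <- function(payoff, role) {
  sign(expected_value_diff(payoff, role, 1) - expected_value_diff(payoff, role, 0))
}

#' @export
agent_update.inf_agent <- function(agent, own, opp) {
  agent$state <- inf_update(agent$state, own, opp, order = agent$order,
                            eta1 = agent$params$eta1,
                            eta2 = agent$params$eta2,
                            eta3 = if (agent$order == 2) agent$params$eta3 else 0,
                            sgn_opp = .br_slope_sign(agent$payoff, other_role(agent)),
                            sgn_self = .br_slope_sign(agent$payoff, agent$role))
  agent
}

#' Influence-model tracking update
#'
#' Heuristic (non-Bayesian) mentalizing update. The tracked opponent tendency
#' `p` moves by `eta1` times the prediction error plus an influence
#' correction proportional (weight `eta2`) to the opponent's own prediction
#' error about the agent, signed by the direction in which the opponent
#' best-responds to that error. A second-order model (`order = 2`) applies
#' the same influence logic to its estimate `q` of the opponent's prediction
#' of itself (weight `eta3`), incorporating that the opponent is itself an
#' influence learner. Probabilities are clipped to `(1e-6, 1 - 1e-6)`.
#'
#' @param state list with `p` (tracked opponent tendency) and `q` (estimate
#'   of the opponent's prediction of the agent).
#' @param own,opp revealed actions (0/1).
#' @param order 1 or 2.
#' @param eta1,eta2,eta3 tracking, influence, and second-order weights.
#' @param sgn_opp,sgn_self best-response direction of the opponent / agent
#'   (+1 matcher, -1 mismatcher); derived from the payoff table.
#' @return Updated state list.
#' @export
inf_update <- function(state, own, opp, order = 1, eta1, eta2, eta3 = 0,
                       sgn_opp = -1, sgn_self = 1) {
  clip <- function(p) pmin(pmax(p, INF_EPS), 1 - INF_EPS)
  p <- state$p; q <- state$q
  # opponent's prediction error about the agent, before q is refreshed
  opp_pe <- own - q
  p_new <- clip(p + eta1 * (opp - p) + eta2 * sgn_opp * opp_pe)
  q_new <- q + eta1 * opp_pe
  if (order == 2)
    q_new <- q_new + eta3 * sgn_self * (opp - p)
  list(p = p_new, q = clip(q_new))
}
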