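#' @title Recursive theory-of-mind (k-ToM) learners
#'
#' @description
#' A 0-ToM agent does not mentalize: it tracks the opponent's choice tendency
#' as a Gaussian belief over a drifting log-odds (see [tom0_update()]) and
#' best-responds through the softmax policy. A k-ToM agent (k >= 1) instead
#' assumes its opponent is a k'-ToM agent with k' < k, and jointly infers
#' (i) the opponent's sophistication level k' (a posterior over levels) and
#' (ii) for each candidate level, the opponent's hidden states: the
#' opponent's current prediction of the agent's own next move (a second-order
#' belief, on the log-odds scale) and the opponent's log-volatility and
#' log-temperature. Each hidden state carries an independent Gaussian belief.
#'
#' On every trial, each level scenario assigns a likelihood to the opponent's
#' observed action (obtained by pushing the hidden-state belief through the
#' opponent's own softmax policy); the level posterior is re-weighted by
#' these likelihoods, and each scenario's hidden-state beliefs receive a
#' prediction-error-driven, gradient-weighted variational update whose
#' magnitude scales with the scenario's posterior weight — a scenario with
#' zero posterior weight is left untouched. Finally, the second-order belief
#' is advanced by simulating the modelled opponent's own learning step on
#' the agent's revealed action: for level 0 the analytic frequency-tracking
#' filter, for levels >= 1 a recursively instantiated k'-ToM simulator run
#' at the current parameter-belief means.
#'
#' Recursion depth is capped at k = 3. All agents of the family have the
#' same three free parameters: prior volatility, behavioural temperature,
#' and a session-specific bias.
#'
#' @name ktom_agents
NULL

new_tom0 <- function(params, role, payoff) {
  structure(list(state = list(belief = gaussian_belief(0, 1))),
            class = c("tom0_agent", "ktom_agentobj"))
}

new_ktom <- function(k) function(params, role, payoff) {
  opp_role <- payoff$roles[3 - match(role, payoff$roles)]
  # linear value-difference coefficients of the modelled opponent:
  # dv_opp(p_me) = d0 + (d1 - d0) * p_me
  d0 <- expected_value_diff(payoff, opp_role, 0)
  d1 <- expected_value_diff(payoff, opp_role, 1)
  lev <- lapply(0:(k - 1), function(j) {
    list(j = j,
         # "like-me" prior: the opponent's parameters are a priori believed
         # to equal one's own (belief means at the agent's log-parameters)
         mu = c(q = 0, llam = log(params$volatility),
                lbeta = log(params$temperature)),
         sig = c(q = 1, llam = 1, lbeta = 1),
         vq = 1,                    # modelled opponent's own uncertainty (j = 0)
         # the recursive simulator inherits the agent's own parameters
         # (the like-me prior propagates down the recursion); its working
         # parameters are overwritten each trial by the belief means
         sim = if (j >= 1)
           make_agent(paste0(j, "-ToM"), role = opp_role,
                      params = list(volatility = params$volatility,
                                    temperature = params$temperature,
                                    bias = 0),
                      payoff = payoff))
  })
  structure(list(k = k, opp_d0 = d0, opp_d1 = d1,
                 state = list(lp = rep(1 / k, k), lev = lev,
                              last_own = NA_integer_, p_opp = 0.5)),
            class = c("ktom_agent", "ktom_agentobj"))
}

#' @export
agent_predict.tom0_agent <- function(agent) tom0_predict(agent$state$belief)

#' @export
agent_update.tom0_agent <- function(agent, own, opp) {
  agent$state$belief <- tom0_update(agent$state$belief, opp,
                                    agent$params$volatility)
  agent
}

# scalar sigmoid-Gaussian integral and its derivative in mu, one GH pass
.sg_both <- function(mu, v) {
  if (v <= 0) {
    s <- sigmoid(mu)
    return(c(s, s * (1 - s)))
  }
  s <- sigmoid(mu + sqrt(2 * v) * .gh$nodes)
  w <- .gh$wnorm
  c(sum(w * s), sum(w * s * (1 - s)))
}

# Per-level predicted probability that the opponent plays option 1, with the
# log-odds map and its analytic gradient in the hidden states (q, llam,
# lbeta). The map is f(x) = dv_opp(sigmoid-Gaussian(q; vq)) / exp(lbeta);
# llam enters the hidden-state dynamics, not the instantaneous map.
.ktom_level_pred <- function(lv, d0, d1) {
  pm <- .sg_both(lv$mu[[1]], lv$vq)
  eb <- exp(lv$mu[[3]])
  f <- (d0 + (d1 - d0) * pm[1]) / eb
  g <- c((d1 - d0) * pm[2] / eb, 0, -f)
  var_f <- g[1]^2 * lv$sig[[1]] + f^2 * lv$sig[[3]]
  sg <- .sg_both(f, var_f)
  list(p1 = sg[1], f = f, g = g)
}

#' @export
agent_predict.ktom_agent <- function(agent) {
  st <- agent$state
  p <- vapply(st$lev, function(lv)
    .ktom_level_pred(lv, agent$opp_d0, agent$opp_d1)$p1, numeric(1))
  sum(st$lp * p)
}

#' @export
agent_update.ktom_agent <- function(agent, own, opp) {
  st <- agent$state
  vol <- agent$params$volatility
  k <- agent$k

  preds <- lapply(st$lev, .ktom_level_pred, d0 = agent$opp_d0,
                  d1 = agent$opp_d1)

  # (i) re-weight the level posterior by each scenario's likelihood
  lik <- vapply(preds, function(pr) if (opp == 1) pr$p1 else 1 - pr$p1,
                numeric(1))
  lp <- st$lp * pmax(lik, 1e-12)
  st$lp <- lp / sum(lp)

  for (j in seq_len(k)) {
    w <- st$lp[j]
    if (w <= 0) next
    lv <- st$lev[[j]]
    pr <- preds[[j]]
    s <- sigmoid(pr$f)

    # (ii) gradient-weighted variational update of the hidden-state beliefs;
    # both the diffusion and the precision gain scale with the scenario's
    # posterior weight, so unlikely scenarios are (smoothly) left unchanged.
    # Only the dynamic second-order belief q diffuses: the opponent's
    # parameters are static unknowns, so their uncertainty only shrinks.
    sig_pred <- lv$sig + w * vol * c(1, 0, 0)
    sig_new <- 1 / (1 / sig_pred + w * pr$g^2 * s * (1 - s))
    lv$mu <- lv$mu + w * sig_new * pr$g * (opp - s)
    lv$sig <- sig_new

    # (iii) advance the modelled opponent's own learning on the agent's
    # revealed action (the second-order belief update)
    if (lv$j == 0) {
      stp <- .tom0_step(lv$mu[[1]], lv$vq, own, exp(lv$mu[[2]]))
      lv$mu[[1]] <- stp[1]
      lv$vq <- stp[2]
    } else {
      sim <- lv$sim
      sim$params$volatility <- exp(lv$mu[[2]])
      sim$params$temperature <- exp(lv$mu[[3]])
      q_old <- logit(agent_predict(sim))
      sim <- agent_update(sim, own = opp, opp = own)
      lv$mu[[1]] <- lv$mu[[1]] + (logit(agent_predict(sim)) - q_old)
      lv$sim <- sim
    }
    st$lev[[j]] <- lv
  }

  st$last_own <- own
  st$p_opp <- sum(st$lp * vapply(st$lev, function(lv)
    .ktom_level_pred(lv, agent$opp_d0, agent$opp_d1)$p1, numeric(1)))
  agent$state <- st
  agent
}

#' k-ToM convenience wrappers
#'
#' Thin functional wrappers over the shared learner interface for k-ToM
#' agents: `ktom_predict()` returns the level-posterior-weighted probability
#' that the opponent plays option 1, `ktom_update()` performs the joint
#' update of the level posterior and hidden-state beliefs, and `ktom_act()`
#' draws an action through the softmax policy from a seeded uniform variate.
#'
#' @param agent a k-ToM agent from [make_agent()].
#' @param own,opp revealed actions (0/1).
#' @param seed integer seed for the action draw.
#' @return `ktom_predict()`: probability; `ktom_update()`: updated agent;
#'   `ktom_act()`: binary action.
#' @export
ktom_predict <- function(agent) agent_predict(agent)

#' @rdname ktom_predict
#' @export
ktom_update <- function(agent, own, opp) agent_update(agent, own, opp)

#' @rdname ktom_predict
#' @export
ktom_act <- function(agent, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  agent_act(agent, stats::runif(1))
}

#' Level posterior of a k-ToM agent
#'
#' @param agent a k-ToM agent (k >= 1).
#' @return Named numeric vector: posterior probability that the opponent is
#'   a 0-ToM, 1-ToM, ... agent.
#' @export
level_posterior <- function(agent) {
  stopifnot(inherits(agent, "ktom_agent"))
  stats::setNames(agent$state$lp, paste0(seq_along(agent$state$lp) - 1, "-ToM"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
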