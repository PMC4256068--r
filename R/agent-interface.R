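#' Construct a learning agent by model name
#'
#' All agents in the package — recursive theory-of-mind learners and the
#' baseline comparison set — share one learner interface: construct with
#' `make_agent()`, then alternate [choice_prob()] / [agent_act()] (decide) and
#' [agent_update()] (learn from the revealed pair of actions). This keeps the
#' game arena and the model-inversion machinery model-agnostic.
#'
#' Registered models: `"RB"` (biased random), `"Nash"`, `"WSLS"`, `"RL"`,
#' `"1-BSL"`, `"2-BSL"`, `"3-BSL"`, `"hBL"` (alias `"HGF"`), `"1-Inf"`,
#' `"2-Inf"`, `"0-ToM"`, `"1-ToM"`, `"2-ToM"`, `"3-ToM"`.
#'
#' @param model model name (see above).
#' @param role `"seeker"` or `"hider"`; decides how predicted opponent
#'   behaviour maps to option values.
#' @param params named list of model parameters; unspecified entries fall
#'   back to [default_params()].
#' @param payoff a [payoff_table()].
#' @return An agent object (classed list) implementing the learner interface.
#' @examples
#' ag <- make_agent("0-ToM", role = "seeker")
#' choice_prob(ag)          # 0.5 before any observation
#' ag <- agent_update(ag, own = 1, opp = 1)
#' @export
make_agent <- function(model, role = "seeker", params = list(),
                       payoff = hide_and_seek()) {
  model <- resolve_model_name(model)
  p <- utils::modifyList(default_params(model), params)
  ctor <- .agent_registry[[model]]
  ag <- ctor(p, role, payoff)
  ag$model <- model
  ag$role <- role
  ag$params <- p
  ag$payoff <- payoff
  ag
}

#' Registered model names
#'
#' @param aliases logical; include accepted aliases (`"HGF"` for `"hBL"`).
#' @return Character vector of model names accepted by [make_agent()].
#' @export
agent_models <- function(aliases = FALSE) {
  nm <- names(.agent_registry)
  if (aliases) nm <- c(nm, names(.model_aliases))
  nm
}

.model_aliases <- c("HGF" = "hBL")

resolve_model_name <- function(model) {
  if (model %in% names(.model_aliases)) model <- .model_aliases[[model]]
  if (!model %in% names(.agent_registry))
    stop("unknown model '", model, "'; see agent_models()")
  model
}

#' Default agent parameters
#'
#' One place defining the parameters used for simulated agents throughout the
#' package (tournaments, reference kernels, synthetic cohorts). Every
#' simulation record logs the parameters actually used. See the methods
#' vignette for the rationale behind each value.
#'
#' @param model model name.
#' @return Named list of parameters.
#' @export
default_params <- function(model) {
  model <- if (model %in% names(.model_aliases)) .model_aliases[[model]] else model
  base <- list(volatility = exp(-1), temperature = 0.15, bias = 0)
  switch(model,
    "RB"    = list(p = 0.65, preferred = 1),
    "Nash"  = list(bias = 0),
    "WSLS"  = list(temperature = base$temperature, bias = 0),
    "RL"    = list(alpha = 0.7, temperature = base$temperature, bias = 0),
    "1-BSL" = base, "2-BSL" = base, "3-BSL" = base,
    "hBL"   = list(kappa = 1, omega = -2, theta = 0.5,
                   temperature = base$temperature, bias = 0),
    "1-Inf" = list(eta1 = 0.4, eta2 = 0.3, bias = 0),
    "2-Inf" = list(eta1 = 0.4, eta2 = 0.3, eta3 = 0.2, bias = 0),
    "0-ToM" = base, "1-ToM" = base, "2-ToM" = base, "3-ToM" = base,
    stop("unknown model '", model, "'"))
}

#' Probability that the agent picks option 1 on the next trial
#'
#' @param agent an agent from [make_agent()].
#' @return Probability in (0, 1).
#' @export
choice_prob <- function(agent) UseMethod("choice_prob")

#' @export
choice_prob.default <- function(agent) {
  p_opp <- agent_predict(agent)
  softmax_prob(expected_value_diff(agent$payoff, agent$role, p_opp),
               agent$params$temperature, agent$params$bias)
}

#' Predicted probability that the opponent picks option 1
#'
#' Only meaningful for models that track the opponent (k-ToM, sequence and
#' hierarchical learners, influence models); value-based models (RL, WSLS,
#' Nash, RB) do not form such a prediction.
#'
#' @param agent an agent from [make_agent()].
#' @return Probability in (0, 1).
#' @export
agent_predict <- function(agent) UseMethod("agent_predict")

#' Learn from one revealed trial
#'
#' Called once per trial after both simultaneous actions are revealed;
#' beliefs used to act on trial `t` only ever depend on trials before `t`.
#'
#' @param agent an agent from [make_agent()].
#' @param own the agent's own action (0/1).
#' @param opp the opponent's action (0/1).
#' @return The updated agent.
#' @export
agent_update <- function(agent, own, opp) UseMethod("agent_update")

#' Draw an action from the agent's policy
#'
#' The draw is made from a uniform variate supplied by the caller so that the
#' game arena controls all randomness (one stream per agent per session).
#' Ties at probability exactly 0.5 are resolved by the draw itself.
#'
#' @param agent an agent from [make_agent()].
#' @param u uniform(0,1) variate.
#' @return Binary action (integer 0/1).
#' @export
agent_act <- function(agent, u) as.integer(u < choice_prob(agent))

#' @export
print.ktom_agentobj <- function(x, ...) {
  cat(x$model, "agent (", x$role, ")\n")
  cat("params:", paste(names(x$params),
                       signif(unlist(x$params), 3), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# role index of the other player
other_role <- function(agent) {
  r <- match(agent$role, agent$payoff$roles)
  agent$payoff$roles[3 - r]
}
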