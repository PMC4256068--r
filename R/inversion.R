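#' Fitted-parameter specification of a model
#'
#' Every model is fitted on an unconstrained (transformed) scale with
#' independent Gaussian priors: positive parameters (volatility, temperature,
#' HGF coupling/drift) on a log scale, learning rates on a log-odds scale,
#' biases and influence weights on the identity scale. The special model
#' `"Volterra"` denotes the lagged logistic decomposition of
#' [fit_volterra()] treated as a likelihood with `2L + 1` weight parameters.
#'
#' @param model model name (see [agent_models()]) or `"Volterra"`.
#' @param L maximum lag (Volterra only).
#' @return Data frame with columns `name` and `transform`
#'   (`"log"`, `"logit"`, `"identity"`).
#' @export
param_spec <- function(model, L = 5) {
  if (model == "Volterra") {
    return(data.frame(
      name = c("bias", paste0("self", seq_len(L)), paste0("opp", seq_len(L))),
      transform = "identity"))
  }
  model <- resolve_model_name(model)
  sp <- switch(model,
    "RB"    = stop("RB is an opponent policy, not a fitted model"),
    "Nash"  = list(bias = "identity"),
    "WSLS"  = list(temperature = "log", bias = "identity"),
    "RL"    = list(alpha = "logit", temperature = "log", bias = "identity"),
    "1-BSL" = , "2-BSL" = , "3-BSL" = ,
    "0-ToM" = , "1-ToM" = , "2-ToM" = , "3-ToM" =
      list(volatility = "log", temperature = "log", bias = "identity"),
    "hBL"   = list(kappa = "log", omega = "identity", theta = "log",
                   temperature = "log", bias = "identity"),
    "1-Inf" = list(eta1 = "identity", eta2 = "identity", bias = "identity"),
    "2-Inf" = list(eta1 = "identity", eta2 = "identity", eta3 = "identity",
                   bias = "identity"))
  data.frame(name = names(sp), transform = unlist(sp), row.names = NULL)
}

# transformed -> native parameter list
.to_native <- function(theta, spec) {
  val <- ifelse(spec$transform == "log", exp(theta),
         ifelse(spec$transform == "logit", sigmoid(theta), theta))
  stats::setNames(as.list(val), spec$name)
}

#' Log-likelihood of a recorded choice sequence under a model
#'
#' Runs the model's learner forward deterministically on the recorded
#' history and accumulates the log-probability of each of the focal player's
#' choices, `sum_t log P(a_self[t] | history < t, params)`.
#'
#' @param model model name, or `"Volterra"` (see [param_spec()]).
#' @param params named list of native-scale parameters; for `"Volterra"` a
#'   numeric vector `(bias, self lags, opp lags)`.
#' @param record a [choice_record()].
#' @param payoff a [payoff_table()].
#' @param role role of the recorded (focal) player.
#' @param L maximum lag (Volterra only).
#' @param engine `"cpp"` (compiled forward pass, the default) or `"r"` (the
#'   R agent objects); both produce the same probabilities and the test
#'   suite holds them together.
#' @return The log-likelihood (a negative real).
#' @export
sequence_loglik <- function(model, params, record, payoff = hide_and_seek(),
                            role = "seeker", L = 5, engine = "cpp") {
  p <- .choice_prob_path(model, params, record, payoff, role, L, engine)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(ifelse(record$a_self == 1, log(p), log1p(-p)))
}

# per-trial probability of option 1 under the model, run forward on history
.choice_prob_path <- function(model, params, record, payoff, role,
                              L = 5, engine = "cpp") {
  T <- record$trials
  if (engine == "cpp" && model != "Volterra") {
    model <- resolve_model_name(model)
    params <- utils::modifyList(default_params(model), params)
    return(.cpp_choice_path(model, params,
                            as.integer(record$a_self),
                            as.integer(record$a_opp),
                            as.numeric(payoff$u),
                            match(role, payoff$roles) - 1L))
  }
  if (model == "Volterra") {
    theta <- unlist(params, use.names = FALSE)
    p <- rep(0.5, T)  # warm-up trials: undefined lags
    if (T > L) {
      idx <- (L + 1):T
      X <- matrix(0, length(idx), 2 * L)
      for (l in seq_len(L)) {
        X[, l] <- 2 * record$a_self[idx - l] - 1
        X[, L + l] <- 2 * record$a_opp[idx - l] - 1
      }
      p[idx] <- sigmoid(theta[1] + drop(X %*% theta[-1]))
    }
    return(p)
  }
  ag <- make_agent(model, role = role, params = params, payoff = payoff)
  p <- numeric(T)
  for (t in seq_len(T)) {
    p[t] <- choice_prob(ag)
    ag <- agent_update(ag, own = record$a_self[t], opp = record$a_opp[t])
  }
  p
}

#' Laplace approximation to the log model evidence of one session
#'
#' Approximates the marginal likelihood of a recorded choice sequence under
#' a model by a Gaussian (Laplace) expansion around the posterior mode on
#' the transformed parameter scale. The prior is independent Gaussian
#' (default mean 0, variance 3) on every transformed parameter, so the
#' evidence is complexity-penalized by construction. The penalized
#' log-likelihood is optimized by quasi-Newton from multiple restarts drawn
#' from the prior (recursive models have multimodal likelihoods); the
#' Hessian at the best mode gives the Gaussian correction.
#'
#' @param model model name or `"Volterra"`.
#' @param record a [choice_record()].
#' @param prior_mean,prior_var Gaussian prior moments on the transformed
#'   scale (scalar or per-parameter vector).
#' @param n_restarts number of optimizer starts: the prior mean plus
#'   `n_restarts - 1` random draws from the prior.
#' @param seed seed for the restart draws.
#' @param payoff,role,L as in [sequence_loglik()].
#' @return An object of class `evidence_result`: `log_evidence`, posterior
#'   `mode` (transformed) and `params` (native), posterior covariance `cov`,
#'   `accuracy` and `balanced_accuracy` of the fitted model's one-step-ahead
#'   choice predictions, and a `converged` flag.
#' @export
log_evidence <- function(model, record, prior_mean = 0, prior_var = 3,
                         n_restarts = 4, seed = 1,
                         payoff = hide_and_seek(), role = "seeker", L = 5) {
  spec <- param_spec(model, L = L)
  d <- nrow(spec)
  pm <- rep_len(prior_mean, d); pv <- rep_len(prior_var, d)

  negobj <- function(theta) {
    ll <- tryCatch(
      sequence_loglik(model, .to_native(theta, spec), record,
                      payoff = payoff, role = role, L = L),
      error = function(e) -Inf)
    val <- -(ll + sum(stats::dnorm(theta, pm, sqrt(pv), log = TRUE)))
    if (!is.finite(val)) 1e10 else val
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  starts <- rbind(pm,
                  matrix(stats::rnorm((n_restarts - 1) * d, pm, sqrt(pv)),
                         ncol = d, byrow = TRUE))
  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], negobj, method = "BFGS",
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("all optimizer restarts failed for model ", model)

  H <- tryCatch(stats::optimHess(best$par, negobj), error = function(e) NULL)
  ld <- NULL
  if (!is.null(H)) {
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) ch <- tryCatch(chol(H + diag(1e-6, d)),
                                    error = function(e) NULL)
    if (!is.null(ch)) ld <- 2 * sum(log(diag(ch)))
  }
  if (is.null(ld)) {  # fall back to the prior curvature
    H <- diag(1 / pv, d)
    ld <- sum(log(1 / pv))
    converged <- FALSE
  }

  le <- -best$value + d / 2 * log(2 * pi) - ld / 2
  pars <- .to_native(best$par, spec)
  p <- .choice_prob_path(model, pars, record, payoff, role, L)
  pred <- as.integer(p > 0.5)
  acc <- mean(pred == record$a_self)
  bacc <- mean(vapply(unique(record$a_self), function(a)
    mean(pred[record$a_self == a] == a), numeric(1)))

  structure(list(model = model, log_evidence = le,
                 mode = stats::setNames(best$par, spec$name),
                 params = pars,
                 cov = tryCatch(solve(H), error = function(e) NULL),
                 accuracy = acc, balanced_accuracy = bacc,
                 converged = converged),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf("%s: log evidence %.2f (accuracy %.1f%%)\n",
              x$model, x$log_evidence, 100 * x$accuracy))
  cat("posterior mode:", paste(names(x$mode), signif(unname(x$mode), 3),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Log-evidence matrix of a model set over a list of sessions
#'
#' @param records list of [choice_record()]s.
#' @param models character vector of model names.
#' @param ... passed to [log_evidence()].
#' @return A `length(models) x length(records)` matrix of log evidences with
#'   model names as row names.
#' @export
evidence_matrix <- function(records, models, ...) {
  E <- matrix(NA_real_, length(models), length(records),
              dimnames = list(models, NULL))
  for (m in seq_along(models))
    for (r in seq_along(records))
      E[m, r] <- log_evidence(models[m], records[[r]], ...)$log_evidence
  E
}

#' Model-recovery confusion matrix
#'
#' For a cohort of simulated sessions with known generating models, fits
#' every candidate model to every record, attributes each record to the
#' model with the highest evidence, and tabulates attribution proportions by
#' generating model. Rows (generators) sum to 1.
#'
#' @param records list of simulated [choice_record()]s whose
#'   `meta$model_self` names the generator.
#' @param models candidate model names (defaults to the generators present).
#' @param E optional precomputed [evidence_matrix()] for `records`.
#' @param ... passed to [evidence_matrix()].
#' @return A `generators x models` matrix of attribution proportions,
#'   with attribute `"counts"` carrying the raw counts.
#' @export
recover_models <- function(records, models = NULL, E = NULL, ...) {
  gen <- vapply(records, function(r) r$meta$model_self, character(1))
  if (is.null(models)) models <- unique(gen)
  if (is.null(E)) E <- evidence_matrix(records, models, ...)
  attributed <- models[apply(E, 2, which.max)]
  gens <- unique(gen)
  counts <- matrix(0L, length(gens), length(models),
                   dimnames = list(generator = gens, attributed = models))
  for (i in seq_along(records))
    counts[gen[i], attributed[i]] <- counts[gen[i], attributed[i]] + 1L
  prop <- counts / rowSums(counts)
  attr(prop, "counts") <- counts
  prop
}
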