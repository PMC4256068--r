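# shared fixtures: all built in code at test time

# a short deterministic record from a seeded dyad
quick_record <- function(model_a = "0-ToM", model_b = "RB", T = 60, seed = 1,
                         params_a = list(), params_b = list(p = 0.5)) {
  play_dyad(make_agent(model_a, params = params_a),
            make_agent(model_b, role = "hider", params = params_b),
            T = T, seed = seed)
}

# exact Bayesian filter for the 0-ToM state-space model on a dense grid:
# x_t = x_{t-1} + N(0, vol), obs ~ Bernoulli(sigmoid(x_t))
grid_filter_predict <- function(obs, vol, ngrid = 2001, lim = 8) {
  x <- seq(-lim, lim, length.out = ngrid)
  dx <- x[2] - x[1]
  post <- dnorm(x, 0, 1)
  K <- outer(x, x, function(a, b) dnorm(a, b, sqrt(vol)))
  for (o in obs) {
    post <- drop(K %*% post) * dx
    lik <- if (o == 1) plogis(x) else 1 - plogis(x)
    post <- post * lik
    post <- post / (sum(post) * dx)
  }
  sum(plogis(x) * post) * dx
}

# simulated records from a generator playing the standard opponent roster,
# with mild between-subject parameter dispersion
generator_records <- function(gen, n, seed0,
                              opponents = c("RB", "0-ToM", "1-ToM", "2-ToM"),
                              T = 60, sd = 0.5) {
  samp <- cohort_param_sampler(sd)
  lapply(seq_len(n), function(i) {
    set.seed(seed0 + i)
    pars <- samp(gen, i)
    opp <- opponents[(i - 1) %% length(opponents) + 1]
    op_par <- if (opp == "RB") list(p = 0.65, preferred = i %% 2) else list()
    play_dyad(make_agent(gen, params = pars),
              make_agent(opp, role = "hider", params = op_par),
              T = T, seed = seed0 + i, meta = list(opponent = opp))
  })
}

# the paper's model comparison set (13 agent models) and family partitions
models13 <- c("1-ToM", "2-ToM", "3-ToM", "1-Inf", "2-Inf", "0-ToM", "hBL",
              "1-BSL", "2-BSL", "3-BSL", "RL", "WSLS", "Nash")
family_tom <- list(
  "T+" = c("1-ToM", "2-ToM", "3-ToM", "1-Inf", "2-Inf"),
  "T-" = c("0-ToM", "hBL", "1-BSL", "2-BSL", "3-BSL", "RL", "WSLS", "Nash"))

# sum per-subject log evidences over sessions (fixed effect over opponents)
sum_by_subject <- function(E, records) {
  subj <- vapply(records, function(r) r$meta$subject, numeric(1))
  ids <- sort(unique(subj))
  out <- sapply(ids, function(s) rowSums(E[, subj == s, drop = FALSE]))
  colnames(out) <- ids
  out
}
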