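#' Volterra decomposition of a binary choice sequence
#'
#' Fits a lagged logistic regression of the focal player's choices on both
#' players' past actions: the choice at trial t is modelled as a logistic
#' function of an intercept plus the last `L` own actions and the last `L`
#' opponent actions, each coded +/-1. The fitted lag weights are first-order
#' Volterra kernels: a positive weight on an opponent lag reads as a tendency
#' to copy the opponent's action at that lag, a negative weight on an own lag
#' as a tendency to alternate one's own choices. A small ridge penalty keeps
#' the weights bounded when a (near-)deterministic sequence makes the design
#' separable. Warm-up trials `t <= L` are excluded from the fit.
#'
#' @param record a [choice_record()] (or a list with `a_self`, `a_opp`).
#' @param L maximum lag; the fit needs `T > 2L + 5` trials.
#' @param ridge ridge penalty on the lag weights (the intercept is not
#'   penalized).
#' @return An object of class `volterra_kernel`: list with `self_weights`,
#'   `opp_weights` (length `L`), `intercept`, `L`, `fit_accuracy` (in-sample
#'   fraction of correctly predicted choices, predicting the more probable
#'   option), and `n_fit` (number of fitted trials).
#' @export
fit_volterra <- function(record, L = 5, ridge = 1e-3) {
  a <- record$a_self; b <- record$a_opp
  T <- length(a)
  if (T <= 2 * L + 5)
    stop("sequence too short for L = ", L, " (need T > 2L + 5)")
  idx <- (L + 1):T
  y <- a[idx]
  X <- matrix(0, length(idx), 2 * L)
  for (l in seq_len(L)) {
    X[, l] <- 2 * a[idx - l] - 1      # own action, lag l, coded +/-1
    X[, L + l] <- 2 * b[idx - l] - 1  # opponent action, lag l
  }
  fit <- .ridge_logistic(X, y, ridge)
  eta <- fit$intercept + drop(X %*% fit$w)
  acc <- mean((eta > 0) == (y == 1))
  structure(list(self_weights = fit$w[seq_len(L)],
                 opp_weights = fit$w[L + seq_len(L)],
                 intercept = fit$intercept, L = L,
                 fit_accuracy = acc, n_fit = length(y)),
            class = "volterra_kernel")
}

# Newton/IRLS for ridge-penalized logistic regression; the penalty applies
# to the lag weights only. Deterministic, no stochastic elements.
.ridge_logistic <- function(X, y, ridge, max_iter = 100, tol = 1e-8) {
  Z <- cbind(1, X)
  d <- ncol(Z)
  pen <- c(0, rep(ridge, d - 1))
  beta <- numeric(d)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    p <- sigmoid(eta)
    g <- drop(crossprod(Z, y - p)) - pen * beta
    W <- p * (1 - p)
    H <- crossprod(Z * W, Z) + diag(pen, d)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(intercept = beta[1], w = beta[-1])
}

#' @export
print.volterra_kernel <- function(x, ...) {
  cat("Volterra kernel, L =", x$L,
      sprintf("(fit accuracy %.1f%% over %d trials)\n",
              100 * x$fit_accuracy, x$n_fit))
  print(round(rbind(self = x$self_weights, opponent = x$opp_weights), 3))
  invisible(x)
}

#' Chance band for Volterra weights
#'
#' The null reference for interpreting fitted kernels: Volterra weights
#' estimated from i.i.d. fair-coin choice sequences (both players random).
#' The band at each lag is the extremum (min/max) weight observed across
#' `n_mc` Monte-Carlo fits; weights inside the band are indistinguishable
#' from chance.
#'
#' @param T sequence length.
#' @param L maximum lag.
#' @param n_mc number of Monte-Carlo null sequences (`>= 100`).
#' @param seed RNG seed.
#' @param ridge passed to [fit_volterra()].
#' @return List with `self` and `opp`, each a `2 x L` matrix (rows `lo`,
#'   `hi`) of per-lag extremum weights.
#' @export
chance_band <- function(T = 60, L = 5, n_mc = 1000, seed = 1, ridge = 1e-3) {
  stopifnot(n_mc >= 100)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ws <- matrix(0, n_mc, 2 * L)
  for (i in seq_len(n_mc)) {
    rec <- list(a_self = stats::rbinom(T, 1, 0.5),
                a_opp = stats::rbinom(T, 1, 0.5))
    k <- fit_volterra(rec, L = L, ridge = ridge)
    ws[i, ] <- c(k$self_weights, k$opp_weights)
  }
  band <- function(cols) rbind(lo = apply(cols, 2, min),
                               hi = apply(cols, 2, max))
  list(self = band(ws[, seq_len(L), drop = FALSE]),
       opp = band(ws[, L + seq_len(L), drop = FALSE]))
}

#' Reference kernels of simulated k-ToM agents
#'
#' Simulates k-ToM agents playing hide-and-seek against an unbiased i.i.d.
#' random opponent and averages the fitted Volterra kernels and fit
#' accuracies across Monte-Carlo games. These mean kernels characterise each
#' sophistication level's behavioural signature (0-ToM copies its opponent;
#' 1-ToM alternates its own choices) and serve as "best k-ToM response"
#' references: the best response to a level-k opponent is the level-(k+1)
#' kernel.
#'
#' @param levels integer vector of sophistication levels to simulate.
#' @param n_mc Monte-Carlo games per level.
#' @param T trials per game.
#' @param seed master seed.
#' @param L maximum lag.
#' @param params parameters of the simulated agents (defaults:
#'   [default_params()]).
#' @param payoff a [payoff_table()].
#' @return A list of class `ktom_reference`, one element per level, each with
#'   the mean `self_weights`, `opp_weights`, `intercept`, mean
#'   `fit_accuracy`, `level`, and `n_mc`.
#' @export
ktom_reference_kernels <- function(levels = 0:3, n_mc = 1000, T = 60,
                                   seed = 1, L = 5, params = list(),
                                   payoff = hide_and_seek()) {
  out <- lapply(levels, function(k) {
    model <- paste0(k, "-ToM")
    sw <- matrix(0, n_mc, L); ow <- matrix(0, n_mc, L)
    ic <- numeric(n_mc); acc <- numeric(n_mc)
    for (i in seq_len(n_mc)) {
      ag <- make_agent(model, role = "seeker", params = params,
                       payoff = payoff)
      rb <- make_agent("RB", role = "hider", params = list(p = 0.5),
                       payoff = payoff)
      rec <- play_dyad(ag, rb, payoff = payoff, T = T,
                       seed = .stream_seed(seed, k * 100000L + i))
      kern <- fit_volterra(rec, L = L)
      sw[i, ] <- kern$self_weights; ow[i, ] <- kern$opp_weights
      ic[i] <- kern$intercept; acc[i] <- kern$fit_accuracy
    }
    structure(list(self_weights = colMeans(sw), opp_weights = colMeans(ow),
                   intercept = mean(ic), L = L,
                   fit_accuracy = mean(acc), n_fit = NA_integer_,
                   level = k, n_mc = n_mc),
              class = "volterra_kernel")
  })
  names(out) <- paste0(levels, "-ToM")
  structure(out, class = "ktom_reference", levels = levels)
}

#' Similarity of a kernel to the best k-ToM response
#'
#' The best response to a level-k opponent is the kernel of a level-(k+1)
#' agent (one sophistication level above). Similarity is the Pearson
#' correlation between the concatenated (self, opponent) lag-weight vectors
#' of the subject kernel and the reference kernel; it is a proxy for the
#' optimality of the learning rule behind the subject's choices, and can be
#' Fisher-transformed for group statistics.
#'
#' @param kernel a `volterra_kernel` (e.g. from [fit_volterra()]).
#' @param opponent_level sophistication level of the opponent faced.
#' @param refs a [ktom_reference_kernels()] object containing level
#'   `opponent_level + 1`.
#' @return Correlation in `[-1, 1]`, or `NA` if either kernel has zero
#'   variance.
#' @export
best_response_similarity <- function(kernel, opponent_level, refs) {
  stopifnot(inherits(refs, "ktom_reference"))
  ref_name <- paste0(opponent_level + 1, "-ToM")
  if (!ref_name %in% names(refs))
    stop("reference kernels do not include level ", opponent_level + 1)
  ref <- refs[[ref_name]]
  if (ref$L != kernel$L) stop("kernel and reference use different max lags")
  v1 <- c(kernel$self_weights, kernel$opp_weights)
  v2 <- c(ref$self_weights, ref$opp_weights)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}
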