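#' Logistic sigmoid and logit
#'
#' @param x real number (vectorised).
#' @param p probability (vectorised); clipped away from 0 and 1.
#' @return `sigmoid()` maps reals to (0,1); `logit()` is its inverse.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname sigmoid
#' @export
logit <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

# Gauss-Hermite nodes/weights by Golub-Welsch (symmetric tridiagonal Jacobi
# matrix); computed once at load time. 21 nodes put the sigmoid-Gaussian
# integral error below 1e-6 over the belief ranges arising here.
.gh_rule <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2 * sqrt(pi))
}
.gh <- .gh_rule(21)
.gh$wnorm <- .gh$weights / sqrt(pi)

#' Posterior-predictive probability under a Gaussian log-odds belief
#'
#' Evaluates the sigmoid-Gaussian integral
#' \eqn{\int s(x)\,N(x;\mu,\sigma)\,dx} by fixed-node Gauss-Hermite
#' quadrature. This is the probability that a Bernoulli event whose log-odds
#' is believed to be Gaussian with mean `mu` and variance `sigma` occurs;
#' uncertainty shrinks the prediction toward 0.5.
#'
#' @param mu posterior mean of the log-odds (vectorised).
#' @param sigma posterior variance, `>= 0` (vectorised or scalar).
#' @return Probability in (0, 1).
#' @export
sigmoid_gauss <- function(mu, sigma = 0) {
  if (all(sigma == 0)) return(sigmoid(mu))
  sd2 <- sqrt(2 * pmax(sigma, 0))
  # outer over quadrature nodes; weights sum to sqrt(pi)
  z <- outer(mu, .gh$nodes, function(m, x) m) +
    outer(sd2, .gh$nodes, function(s, x) s * x)
  drop(sigmoid(z) %*% .gh$weights) / sqrt(pi)
}

#' Gaussian belief over a log-odds hidden state
#'
#' A minimal mean/variance summary of a posterior over a log-odds state.
#'
#' @param mu posterior mean.
#' @param sigma posterior variance, `>= 0`.
#' @return An object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mu = 0, sigma = 1) {
  stopifnot(sigma >= 0)
  structure(list(mu = mu, sigma = sigma), class = "gaussian_belief")
}

#' One-step update of a frequency-tracking Gaussian log-odds belief
#'
#' Variational (Laplace) update of a Gaussian posterior over a hidden
#' log-odds that is assumed to diffuse with variance `volatility` per trial
#' and to emit binary observations through a sigmoid. The mean moves in the
#' direction of the prediction error `obs - sigmoid(mu)` with an effective
#' learning rate equal to the updated variance, which grows with both the
#' volatility and the current uncertainty. As `volatility -> 0` the predicted
#' probability converges to the empirical observation frequency
#' (fictitious-play tracking).
#'
#' @param belief a [gaussian_belief()].
#' @param obs binary observation (0/1).
#' @param volatility assumed diffusion variance per trial, `> 0`.
#' @return The updated [gaussian_belief()].
#' @export
tom0_update <- function(belief, obs, volatility) {
  stopifnot(inherits(belief, "gaussian_belief"), volatility > 0,
            obs %in% c(0, 1))
  st <- .tom0_step(belief$mu, belief$sigma, obs, volatility)
  gaussian_belief(st[1], st[2])
}

# bare numeric kernel shared by every frequency-tracking filter in the
# package (0-ToM, sequence learners, the second-order belief of k-ToM)
.tom0_step <- function(mu, sigma, obs, volatility) {
  sp <- sigma + volatility
  s <- sigmoid(mu)
  sigma_new <- 1 / (1 / sp + s * (1 - s))
  c(mu + sigma_new * (obs - s), sigma_new)
}

#' Predictive probability of a frequency-tracking belief
#'
#' @param belief a [gaussian_belief()].
#' @return Probability that the tracked agent plays option 1, integrating
#'   over the posterior uncertainty (see [sigmoid_gauss()]).
#' @export
tom0_predict <- function(belief) {
  stopifnot(inherits(belief, "gaussian_belief"))
  sigmoid_gauss(belief$mu, belief$sigma)
}

#' Softmax (logistic) decision policy
#'
#' Probability of choosing option 1 given the expected-value difference
#' between the options. The temperature scales decision noise: as it goes to
#' zero the policy becomes greedy, as it grows the policy becomes random. The
#' session-specific bias enters the log-odds additively and is not rescaled
#' by the temperature.
#'
#' @param value_diff expected payoff of option 1 minus option 0.
#' @param temperature behavioural temperature, `> 0`.
#' @param bias additive preference for option 1 on the log-odds scale.
#' @return Probability of option 1.
#' @export
softmax_prob <- function(value_diff, temperature, bias = 0) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("'temperature' must be strictly positive")
  sigmoid(value_diff / temperature + bias)
}

# numerically safe log-sum-exp
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
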