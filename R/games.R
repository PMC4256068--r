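#' Payoff table for a 2x2 simultaneous game
#'
#' A payoff table is a 2x2x2 numeric array `u[role, a, b]` giving the payoff
#' of a player in a given role when she plays action `a` and the other player
#' plays action `b`. Actions are coded 0/1 throughout the package; option 1 is
#' the reference option for every bias and log-odds convention.
#'
#' @param u numeric array of dimension `c(2, 2, 2)`; first margin is the role
#'   (seeker, hider), second the player's own action (0, 1), third the other
#'   player's action (0, 1).
#' @param roles character vector of length 2 naming the roles.
#' @return An object of class `payoff_table`.
#' @export
payoff_table <- function(u, roles = c("seeker", "hider")) {
  u <- as.array(u)
  if (!identical(dim(u), c(2L, 2L, 2L)))
    stop("'u' must be a 2x2x2 array (role x own action x other action)")
  dimnames(u) <- list(roles, c("0", "1"), c("0", "1"))
  structure(list(u = u, roles = roles), class = "payoff_table")
}

#' Hide-and-seek (matching pennies) payoffs
#'
#' The seeker earns 1 when both players pick the same option, the hider earns
#' 1 when they differ; in every cell the two payoffs sum to one, so the
#' winner's gain is balanced by the loser's loss.
#'
#' @return A [payoff_table()] with roles `"seeker"` and `"hider"`.
#' @examples
#' pt <- hide_and_seek()
#' payoff(pt, "seeker", a = 0, b = 0)  # 1: seeker matched the hider
#' payoff(pt, "hider",  a = 0, b = 0)  # 0
#' @export
hide_and_seek <- function() {
  u <- array(0, c(2, 2, 2))
  for (a in 0:1) for (b in 0:1) {
    u[1, a + 1, b + 1] <- as.numeric(a == b)   # seeker
    u[2, a + 1, b + 1] <- as.numeric(a != b)   # hider
  }
  payoff_table(u)
}

#' Look up a single payoff
#'
#' @param pt a [payoff_table()].
#' @param role role name or index.
#' @param a,b own and other player's binary actions (0 or 1).
#' @return The payoff, a scalar.
#' @export
payoff <- function(pt, role, a, b) {
  stopifnot(inherits(pt, "payoff_table"))
  if (is.character(role)) role <- match(role, pt$roles)
  pt$u[role, a + 1, b + 1]
}

#' Expected-value difference between the two options
#'
#' Computes `E[U(a = 1, b)] - E[U(a = 0, b)]` for a player in `role`, where
#' the other player's action `b` is Bernoulli with success probability
#' `p_other`. This is the decision variable entering the softmax policy.
#'
#' @param pt a [payoff_table()].
#' @param role role name or index of the deciding player.
#' @param p_other probability that the other player picks option 1.
#' @return Numeric scalar (vectorised over `p_other`).
#' @export
expected_value_diff <- function(pt, role, p_other) {
  stopifnot(inherits(pt, "payoff_table"))
  if (is.character(role)) role <- match(role, pt$roles)
  u <- pt$u
  d1 <- u[role, 2, 2] - u[role, 1, 2]  # advantage of option 1 when b = 1
  d0 <- u[role, 2, 1] - u[role, 1, 1]  # advantage of option 1 when b = 0
  p_other * d1 + (1 - p_other) * d0
}

#' Trial outcome implied by a pair of actions
#'
#' The outcome is the seeker-role payoff: 1 when the focal (seeker) player was
#' correct, 0 otherwise. Under hide-and-seek exactly one option is correct on
#' every trial, so the counterfactual outcome is known.
#'
#' @param pt a [payoff_table()].
#' @param a_self focal (seeker) action, 0/1; vectorised.
#' @param a_opp opponent action, 0/1; vectorised.
#' @return Integer vector of outcomes.
#' @export
trial_outcome <- function(pt, a_self, a_opp) {
  stopifnot(inherits(pt, "payoff_table"))
  as.integer(pt$u[cbind(1, a_self + 1, a_opp + 1)])
}

#' Net earnings of a sequence of outcomes
#'
#' Earnings are the number of correct minus the number of incorrect trials,
#' the behavioural performance summary used for all cumulative-earnings
#' statistics. An empty sequence earns 0.
#'
#' @param outcomes binary vector (1 = correct).
#' @return Integer in `[-T, T]` for `T` trials.
#' @export
earnings <- function(outcomes) {
  if (length(outcomes) == 0) return(0L)
  stopifnot(all(outcomes %in% c(0, 1)))
  as.integer(sum(outcomes == 1) - sum(outcomes == 0))
}

#' Serialize / deserialize payoff tables
#'
#' @param pt a [payoff_table()].
#' @param path file path; for [payoff_from_json()] a path or JSON string.
#' @return `payoff_to_json()` writes `path` (invisibly returns it);
#'   `payoff_from_json()` returns a [payoff_table()].
#' @export
payoff_to_json <- function(pt, path) {
  stopifnot(inherits(pt, "payoff_table"))
  # flat column-major vector avoids any row/column ambiguity in JSON
  obj <- list(roles = pt$roles, u = as.numeric(pt$u))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname payoff_to_json
#' @export
payoff_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  payoff_table(array(as.numeric(obj$u), c(2, 2, 2)), roles = obj$roles)
}

#' @export
print.payoff_table <- function(x, ...) {
  cat("2x2 payoff table; roles:", paste(x$roles, collapse = ", "), "\n")
  for (r in seq_along(x$roles)) {
    cat("  ", x$roles[r], ":\n", sep = "")
    print(x$u[r, , ])
  }
  invisible(x)
}
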