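#' One trial record container
#'
#' A `choice_record` holds one session of a repeated 2x2 game from the focal
#' (seeker) player's perspective: aligned binary action sequences of both
#' players, the per-trial outcome, and metadata (subject/condition labels,
#' generating models and parameters when simulated, seeds).
#'
#' @param a_self,a_opp binary action vectors of equal length.
#' @param outcome binary outcome vector (1 = focal player correct); if `NULL`
#'   it is recomputed from the actions under `payoff`.
#' @param meta named list of metadata.
#' @param payoff a [payoff_table()] used to validate/recompute outcomes.
#' @return An object of class `choice_record`.
#' @export
choice_record <- function(a_self, a_opp, outcome = NULL, meta = list(),
                          payoff = hide_and_seek()) {
  a_self <- as.integer(a_self); a_opp <- as.integer(a_opp)
  stopifnot(length(a_self) == length(a_opp),
            all(a_self %in% 0:1), all(a_opp %in% 0:1))
  implied <- trial_outcome(payoff, a_self, a_opp)
  if (is.null(outcome)) outcome <- implied
  else if (!identical(as.integer(outcome), implied))
    stop("outcome is inconsistent with the actions under the game's payoffs")
  structure(list(trials = length(a_self), a_self = a_self, a_opp = a_opp,
                 outcome = as.integer(outcome), meta = meta),
            class = "choice_record")
}

#' @export
print.choice_record <- function(x, ...) {
  cat("choice_record:", x$trials, "trials, earnings", earnings(x$outcome), "\n")
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), unlist(lapply(x$meta, function(m)
      paste(format(unlist(m)), collapse = "/"))), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# derived per-agent stream seeds; documented counter scheme so a session's
# stream does not depend on the rest of the roster
.stream_seed <- function(seed, index)
  as.integer((as.numeric(seed) + as.numeric(index) * 1000003) %% 2147483647)

#' Play a seeded dyadic game
#'
#' Runs `T` trials of simultaneous play between two agents. Both agents act
#' on trial t from beliefs formed on trials < t; updates happen only after
#' both actions are revealed. Each agent draws from its own uniform random
#' stream derived from the master seed by a fixed counter scheme, so records
#' are fully reproducible.
#'
#' @param agent_a the focal agent (seeker-role by convention).
#' @param agent_b the opponent agent.
#' @param payoff a [payoff_table()].
#' @param T number of trials, `> 0`.
#' @param seed master seed for the session.
#' @param meta extra metadata merged into the record.
#' @return A [choice_record()] from `agent_a`'s perspective; `meta` includes
#'   both model names, their parameters and the seed.
#' @export
play_dyad <- function(agent_a, agent_b, payoff = hide_and_seek(), T = 60,
                      seed = 1, meta = list()) {
  if (T <= 0) stop("'T' must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.stream_seed(seed, 1L)); u_a <- stats::runif(T)
  set.seed(.stream_seed(seed, 2L)); u_b <- stats::runif(T)

  a <- integer(T); b <- integer(T)
  for (t in seq_len(T)) {
    a[t] <- agent_act(agent_a, u_a[t])
    b[t] <- agent_act(agent_b, u_b[t])
    agent_a <- agent_update(agent_a, own = a[t], opp = b[t])
    agent_b <- agent_update(agent_b, own = b[t], opp = a[t])
  }
  meta <- utils::modifyList(
    list(model_self = agent_a$model, model_opp = agent_b$model,
         params_self = agent_a$params, params_opp = agent_b$params,
         seed = seed), meta)
  choice_record(a, b, meta = meta, payoff = payoff)
}

#' Design of a synthetic cohort
#'
#' Mirrors the experimental layout the package emulates by default: every
#' subject plays 60-trial sessions against four opponents (a biased-random
#' sequence and 0-, 1- and 2-ToM agents), with the opponent order randomized
#' per subject.
#'
#' @param n_subjects number of subjects.
#' @param opponents character vector of opponent model names.
#' @param trials trials per session.
#' @param seed master seed.
#' @param randomize_order randomize opponent order per subject.
#' @param rb_preferred preferred option of the RB opponent (counterbalanced
#'   across subjects when `NA`, the default).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 26,
                          opponents = c("RB", "0-ToM", "1-ToM", "2-ToM"),
                          trials = 60, seed = 1, randomize_order = TRUE,
                          rb_preferred = NA) {
  structure(list(n_subjects = n_subjects, opponents = opponents,
                 trials = trials, seed = seed,
                 randomize_order = randomize_order,
                 rb_preferred = rb_preferred),
            class = "cohort_design")
}

#' Simulate a synthetic cohort
#'
#' Generates one [choice_record()] per subject x opponent. Each subject is
#' assigned a generating model (and optionally subject-specific parameters),
#' plays every opponent in the design, and all seeds/parameters are logged in
#' the record metadata.
#'
#' @param design a [cohort_design()].
#' @param subject_models character vector (length 1 or `n_subjects`) naming
#'   the generating model of each subject.
#' @param subject_params either `NULL` (model defaults), a list of per-subject
#'   parameter lists, or a `function(model, subject)` returning a parameter
#'   list (called with the session RNG active, so parameter draws are seeded).
#' @param payoff a [payoff_table()].
#' @return List of [choice_record()]s, one per subject x opponent.
#' @export
simulate_cohort <- function(design, subject_models,
                            subject_params = NULL,
                            payoff = hide_and_seek()) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_subjects
  models <- rep_len(subject_models, n)
  for (m in models) resolve_model_name(m)  # fail early on unknown names

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  records <- list()
  for (s in seq_len(n)) {
    subj_seed <- .stream_seed(design$seed, 10000L + s)
    set.seed(subj_seed)
    opps <- design$opponents
    if (design$randomize_order) opps <- sample(opps)
    pars <- if (is.null(subject_params)) default_params(models[s])
            else if (is.function(subject_params)) subject_params(models[s], s)
            else utils::modifyList(default_params(models[s]), subject_params[[s]])
    rb_pref <- if (is.na(design$rb_preferred)) (s - 1L) %% 2L
               else design$rb_preferred

    for (o in seq_along(opps)) {
      opp_pars <- if (opps[o] == "RB") list(preferred = rb_pref) else list()
      ag_subj <- make_agent(models[s], role = "seeker", params = pars,
                            payoff = payoff)
      ag_opp <- make_agent(opps[o], role = "hider", params = opp_pars,
                           payoff = payoff)
      sess_seed <- .stream_seed(subj_seed, o)
      rec <- play_dyad(ag_subj, ag_opp, payoff = payoff, T = design$trials,
                       seed = sess_seed,
                       meta = list(subject = s, opponent = opps[o],
                                   opponent_order = o))
      records[[length(records) + 1]] <- rec
    }
  }
  records
}

#' Null threshold for mean cumulative earnings
#'
#' Under the null hypothesis every trial is as likely correct as incorrect,
#' so each session's cumulative earnings is a +/-1 random walk and the mean
#' cumulative earnings over `n_subjects * n_opponents` independent sessions
#' has an exact (shifted, scaled) binomial distribution at every trial index.
#' The threshold at trial t is the smallest mean earnings value whose null
#' exceedance probability is at most `alpha`.
#'
#' @param n_subjects,n_opponents cohort dimensions.
#' @param T number of trials.
#' @param alpha one-sided false-positive rate.
#' @return Numeric vector of length `T`: the critical mean cumulative
#'   earnings at each trial index (grows like `sqrt(t)`).
#' @export
chance_threshold <- function(n_subjects, n_opponents, T, alpha = 0.05) {
  stopifnot(n_subjects > 0, n_opponents > 0, T > 0, alpha > 0, alpha < 1)
  N <- n_subjects * n_opponents
  vapply(seq_len(T), function(t) {
    m <- N * t  # total coin flips pooled at trial t
    # smallest k with P(Binom(m, 1/2) >= k) <= alpha
    k <- stats::qbinom(1 - alpha, m, 0.5) + 1
    (2 * k - m) / N  # back to mean-earnings units
  }, numeric(1))
}
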