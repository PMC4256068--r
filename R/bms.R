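#' Random-effects Bayesian model selection (RFX-BMS)
#'
#' Treats model identity as a random effect across subjects: the population
#' is described by unknown model frequencies with a Dirichlet prior
#' (uniform, `alpha0 = 1` per model), and each subject's log evidences enter
#' through a multinomial assignment. The variational posterior over
#' frequencies is a Dirichlet whose concentrations are estimated by the
#' standard fixed-point iteration; exceedance probabilities (the posterior
#' probability that each model is the most frequent in the population) are
#' computed by seeded Monte-Carlo draws from that Dirichlet.
#'
#' @param E log-evidence matrix, `models x subjects`, with model row names.
#' @param alpha0 Dirichlet prior concentration per model.
#' @param n_samples Dirichlet draws used for the exceedance probabilities.
#' @param seed seed for those draws.
#' @param max_iter,tol fixed-point iteration controls.
#' @return An object of class `bms_result`: posterior concentrations
#'   `alpha`, expected frequencies `freq` (simplex), exceedance
#'   probabilities `ep` (sums to 1), per-subject posterior model assignments
#'   `assignment` (`models x subjects`), and the inputs' dimensions.
#' @export
rfx_bms <- function(E, alpha0 = 1, n_samples = 1e5, seed = 1,
                    max_iter = 500, tol = 1e-8) {
  E <- as.matrix(E)
  K <- nrow(E); n <- ncol(E)
  if (is.null(rownames(E))) rownames(E) <- paste0("m", seq_len(K))
  if (any(!is.finite(E))) stop("log-evidence matrix has non-finite entries")
  if (K < 1) stop("need at least one model")

  if (K == 1) {
    return(structure(list(alpha = stats::setNames(alpha0 + n, rownames(E)),
                          freq = stats::setNames(1, rownames(E)),
                          ep = stats::setNames(1, rownames(E)),
                          assignment = matrix(1, 1, n,
                                              dimnames = list(rownames(E), NULL)),
                          n_subjects = n, models = rownames(E)),
                     class = "bms_result"))
  }

  alpha <- rep(alpha0, K)
  u <- matrix(0, K, n)
  for (it in seq_len(max_iter)) {
    lw <- E + digamma(alpha) - digamma(sum(alpha))
    u <- apply(lw, 2, function(x) exp(x - logsumexp(x)))
    alpha_new <- alpha0 + rowSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }

  ep <- .dirichlet_exceedance(alpha, n_samples, seed)
  dimnames(u) <- list(rownames(E), colnames(E))
  structure(list(alpha = stats::setNames(alpha, rownames(E)),
                 freq = stats::setNames(alpha / sum(alpha), rownames(E)),
                 ep = stats::setNames(ep, rownames(E)),
                 assignment = u, n_subjects = n, models = rownames(E)),
            class = "bms_result")
}

# P(component k is the largest) under Dirichlet(alpha), by seeded sampling
.dirichlet_exceedance <- function(alpha, n_samples, seed) {
  K <- length(alpha)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- integer(K)
  block <- 1e5
  done <- 0
  while (done < n_samples) {
    nb <- min(block, n_samples - done)
    g <- matrix(stats::rgamma(nb * K, shape = rep(alpha, each = nb)), nb, K)
    mx <- max.col(g, ties.method = "random")
    counts <- counts + tabulate(mx, K)
    done <- done + nb
  }
  counts / n_samples
}

#' @export
print.bms_result <- function(x, ...) {
  cat("RFX-BMS over", length(x$models), "models,", x$n_subjects, "subjects\n")
  print(round(rbind(frequency = x$freq, exceedance = x$ep), 3))
  invisible(x)
}

# per-subject family log evidence: log-sum-exp over member models with equal
# within-family priors (marginalization, not max)
.family_evidence <- function(E, partition) {
  fams <- names(partition)
  all_members <- unlist(partition)
  if (anyDuplicated(all_members)) stop("family partition has overlapping models")
  if (!setequal(all_members, rownames(E)))
    stop("family partition must cover exactly the models in E")
  Ef <- matrix(NA_real_, length(fams), ncol(E),
               dimnames = list(fams, colnames(E)))
  for (f in fams) {
    rows <- E[partition[[f]], , drop = FALSE]
    Ef[f, ] <- apply(rows, 2, logsumexp) - log(nrow(rows))
  }
  Ef
}

#' Family-level RFX-BMS
#'
#' Marginalizes within-family model identity (log-sum-exp of member
#' evidences under equal within-family priors) and runs [rfx_bms()] on the
#' resulting family evidence matrix, e.g. to compare mentalizing (T+) vs
#' non-mentalizing (T-) or Bayesian (B+) vs non-Bayesian (B-) model
#' families.
#'
#' @param E log-evidence matrix, `models x subjects`.
#' @param partition named list mapping family names to disjoint sets of
#'   model (row) names covering all of `E`.
#' @param ... passed to [rfx_bms()].
#' @return A `bms_result` over families.
#' @export
family_bms <- function(E, partition, ...) {
  rfx_bms(.family_evidence(as.matrix(E), partition), ...)
}

#' RFX-BMS restricted to a winning family
#'
#' Re-runs model selection among the members of one family only, e.g. to
#' estimate the distribution of ToM sophistication levels after the
#' mentalizing family has won the family comparison.
#'
#' @param E log-evidence matrix, `models x subjects`.
#' @param winning_family character vector of model (row) names.
#' @param ... passed to [rfx_bms()].
#' @return A `bms_result` over the family members.
#' @export
restricted_bms <- function(E, winning_family, ...) {
  if (length(winning_family) == 0) stop("winning family is empty")
  missing <- setdiff(winning_family, rownames(E))
  if (length(missing)) stop("models not in E: ", paste(missing, collapse = ", "))
  rfx_bms(as.matrix(E)[winning_family, , drop = FALSE], ...)
}

#' Between-condition model-identity test
#'
#' Asks whether the model family generating a subject's behaviour is the
#' same in two conditions. For each subject, the "same" hypothesis scores
#' the conditions with one shared family (log-sum-exp over families of the
#' summed family evidences), while the "different" hypothesis lets each
#' condition pick its family independently; both use equal family priors.
#' The two per-subject scores are then compared by a two-model [rfx_bms()],
#' and the exceedance probability of "same" is returned. The construction is
#' symmetric under swapping the condition labels.
#'
#' @param E_cond1,E_cond2 log-evidence matrices (`models x subjects`) for
#'   the same subjects in two conditions.
#' @param partition family partition as in [family_bms()].
#' @param ... passed to [rfx_bms()].
#' @return List with `ep_same` (exceedance probability that families are
#'   the same across conditions) and the underlying `bms` result.
#' @export
between_condition_test <- function(E_cond1, E_cond2, partition, ...) {
  E1 <- as.matrix(E_cond1); E2 <- as.matrix(E_cond2)
  if (!identical(dim(E1), dim(E2)) || !identical(rownames(E1), rownames(E2)))
    stop("condition evidence matrices must match in models and subjects")
  F1 <- .family_evidence(E1, partition)
  F2 <- .family_evidence(E2, partition)
  nf <- nrow(F1)
  ev_same <- apply(F1 + F2, 2, logsumexp) - log(nf)
  ev_diff <- (apply(F1, 2, logsumexp) - log(nf)) +
             (apply(F2, 2, logsumexp) - log(nf))
  Eh <- rbind(same = ev_same, different = ev_diff)
  bms <- rfx_bms(Eh, ...)
  list(ep_same = unname(bms$ep["same"]), bms = bms)
}
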