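test_that("fitted-parameter counts match the model comparison table", {
  counts <- c("Nash" = 1, "WSLS" = 2, "RL" = 3, "1-BSL" = 3, "2-BSL" = 3,
              "3-BSL" = 3, "hBL" = 5, "1-Inf" = 3, "2-Inf" = 4,
              "0-ToM" = 3, "1-ToM" = 3, "2-ToM" = 3, "3-ToM" = 3)
  for (m in names(counts)) expect_equal(nrow(param_spec(m)), unname(counts[m]))
  expect_equal(nrow(param_spec("Volterra", L = 8)), 17)  # 2L + 1
})

test_that("unbiased Nash log-likelihood is exactly T log(1/2)", {
  rec <- quick_record("Nash", "RB", T = 60, seed = 2)
  expect_equal(sequence_loglik("Nash", list(bias = 0), rec), 60 * log(0.5))
})

test_that("a near-deterministic WSLS fits its own sequence almost perfectly", {
  rec <- quick_record("WSLS", "RB", T = 60, seed = 3,
                      params_a = list(temperature = 1e-3))
  ll <- sequence_loglik("WSLS", list(temperature = 1e-3, bias = 0), rec)
  # only the uninformative first trial costs anything (log 1/2)
  expect_gt(ll, log(0.5) - 0.01)
  expect_lte(ll, 0)
})

test_that("true generating parameters beat strongly perturbed ones on average", {
  set.seed(31)
  diffs <- vapply(1:40, function(i) {
    pars <- list(alpha = 0.7, temperature = 0.15, bias = 0)
    rec <- quick_record("RL", "RB", T = 60, seed = 600 + i, params_a = pars)
    bad <- list(alpha = 0.05, temperature = 3, bias = 1.5)
    sequence_loglik("RL", pars, rec) - sequence_loglik("RL", bad, rec)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("evidence is invariant to a consistent 0/1 relabelling", {
  rec <- quick_record("RL", "0-ToM", T = 60, seed = 8, params_b = list())
  flipped <- choice_record(1 - rec$a_self, 1 - rec$a_opp)
  for (m in c("Nash", "RL", "WSLS", "0-ToM")) {
    p1 <- sequence_loglik(m, list(bias = 0.4), rec)
    p2 <- sequence_loglik(m, list(bias = -0.4), flipped)
    expect_equal(p1, p2, tolerance = 1e-9)
    e1 <- log_evidence(m, rec, seed = 5)$log_evidence
    e2 <- log_evidence(m, flipped, seed = 5)$log_evidence
    expect_equal(e1, e2, tolerance = 0.05)
  }
})

test_that("Laplace evidence agrees with 1-D quadrature for the chance model", {
  for (i in 1:5) {
    set.seed(i)
    rec <- quick_record("Nash", "RB", T = 60, seed = 40 + i,
                        params_a = list(bias = rnorm(1, 0, 0.8)))
    le <- log_evidence("Nash", rec, seed = i)
    f <- function(b) vapply(b, function(bi)
      exp(sequence_loglik("Nash", list(bias = bi), rec) +
            dnorm(bi, 0, sqrt(3), log = TRUE)), numeric(1))
    oracle <- log(integrate(f, -10, 10, rel.tol = 1e-10)$value)
    expect_lt(abs(le$log_evidence - oracle), 0.5)
    expect_lte(le$log_evidence, 0)
    expect_true(le$converged)
  }
})

test_that("the Occam penalty favours the simpler true model", {
  # data simulated from Nash: the 3-parameter recursive model fits no
  # better and pays a complexity price
  d <- vapply(1:10, function(i) {
    rec <- quick_record("Nash", "RB", T = 60, seed = 70 + i)
    log_evidence("Nash", rec, seed = i)$log_evidence -
      log_evidence("2-ToM", rec, seed = i)$log_evidence
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("evidence results carry usable diagnostics", {
  rec <- quick_record("RL", "RB", T = 60, seed = 91)
  e <- log_evidence("RL", rec, seed = 2)
  expect_true(is.finite(e$log_evidence))
  expect_true(e$accuracy >= 0 && e$accuracy <= 1)
  expect_true(e$balanced_accuracy >= 0 && e$balanced_accuracy <= 1)
  expect_equal(names(e$mode), c("alpha", "temperature", "bias"))
  expect_equal(dim(e$cov), c(3, 3))
})

test_that("the Volterra likelihood model matches a direct lagged logistic fit", {
  rec <- quick_record("1-ToM", "RB", T = 60, seed = 17)
  kern <- fit_volterra(rec, L = 5)
  theta <- c(kern$intercept, kern$self_weights, kern$opp_weights)
  ll <- sequence_loglik("Volterra", as.list(theta), rec, L = 5)
  # warm-up trials contribute log(1/2) each; the rest should beat chance
  expect_gt(ll, 60 * log(0.5))
  e <- log_evidence("Volterra", rec, seed = 3, L = 5)
  expect_true(is.finite(e$log_evidence))
  expect_equal(unname(nrow(e$cov)), 11)
})

test_that("small recovery study attributes cheap generators to themselves", {
  gens <- c("Nash", "RL", "WSLS")
  recs <- unlist(lapply(seq_along(gens), function(g)
    generator_records(gens[g], 8, 5000 * g)), recursive = FALSE)
  cm <- recover_models(recs, c(gens, "1-BSL"), n_restarts = 2, seed = 12)
  expect_equal(unname(rowSums(cm)), rep(1, 3))
  for (g in gens) expect_gt(cm[g, g], 0.5)
})
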