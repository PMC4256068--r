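test_that("flat evidence gives uniform frequencies and 1/K exceedance", {
  E <- matrix(0, 4, 12, dimnames = list(paste0("m", 1:4), NULL))
  b <- rfx_bms(E, seed = 1)
  expect_equal(unname(b$freq), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(unname(b$ep), rep(0.25, 4), tolerance = 0.02)
  # posterior concentration = prior + subjects shared uniformly
  expect_equal(unname(b$alpha), rep(1 + 12 / 4, 4), tolerance = 1e-6)
})

test_that("a dominant model saturates the exceedance probability", {
  E <- matrix(0, 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  E["b", ] <- 10  # 10-nat lead for every subject
  b <- rfx_bms(E, seed = 2)
  expect_gt(b$ep["b"], 0.99)
  expect_gt(b$freq["b"], 0.8)
  expect_equal(sum(b$freq), 1)
  expect_equal(sum(b$ep), 1, tolerance = 1e-9)
})

test_that("exceedance probabilities match independent Dirichlet sampling", {
  set.seed(3)
  E <- matrix(rnorm(3 * 20, sd = 2), 3, 20,
              dimnames = list(c("a", "b", "c"), NULL))
  b <- rfx_bms(E, n_samples = 1e5, seed = 4)
  # independent oracle: draw from the fitted Dirichlet with plain rgamma
  set.seed(99)
  g <- matrix(rgamma(3 * 1e5, shape = rep(b$alpha, each = 1e5)), 1e5, 3)
  ep_mc <- tabulate(max.col(g), 3) / 1e5
  expect_lt(max(abs(b$ep - ep_mc)), 0.02)
})

test_that("degenerate and malformed inputs are handled", {
  E1 <- matrix(-5, 1, 8, dimnames = list("only", NULL))
  b <- rfx_bms(E1)
  expect_equal(unname(b$ep), 1)
  expect_error(rfx_bms(matrix(c(0, NA), 2, 1)), "finite")
})

test_that("family inference marginalizes members and reduces to model inference", {
  set.seed(5)
  E <- matrix(rnorm(4 * 15), 4, 15,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  # singleton families reproduce the 2-model answer on the same evidence
  fb <- family_bms(E[1:2, ], list(fa = "a", fb = "b"), seed = 6)
  direct <- rfx_bms(E[1:2, ], seed = 6)
  expect_equal(unname(fb$freq), unname(direct$freq), tolerance = 1e-9)
  expect_equal(unname(fb$ep), unname(direct$ep), tolerance = 0.01)
  fb2 <- family_bms(E, list(f1 = c("a", "b"), f2 = c("c", "d")), seed = 6)
  expect_equal(sum(fb2$freq), 1)
  expect_error(family_bms(E, list(f1 = c("a", "b"), f2 = c("b", "c", "d"))),
               "overlap")
  expect_error(family_bms(E, list(f1 = "a", f2 = c("c", "d"))), "cover")
})

test_that("restricted selection recovers planted within-family frequencies", {
  # 64 subjects, 2/3 planted on model B and 1/3 on model A, 10-nat gaps
  set.seed(7)
  n <- 64
  truth <- c(rep("B", 43), rep("A", 21))
  E <- matrix(0, 3, n, dimnames = list(c("A", "B", "C"), NULL))
  for (i in seq_len(n)) E[truth[i], i] <- 10
  b <- restricted_bms(E, c("A", "B", "C"), seed = 8)
  expect_lt(abs(b$freq["B"] - 43 / 64), 0.1)
  expect_lt(abs(b$freq["A"] - 21 / 64), 0.1)
  expect_lt(b$freq["C"], 0.1)
  # roughly the planted 2:1 ratio
  expect_gt(b$freq["B"] / b$freq["A"], 1.5)
  expect_error(restricted_bms(E, character(0)), "empty")
  expect_error(restricted_bms(E, "nope"), "not in E")
  b1 <- restricted_bms(E, "B", seed = 8)
  expect_equal(unname(b1$freq), 1)
})

test_that("model selection only depends on within-subject evidence differences", {
  set.seed(9)
  E <- matrix(rnorm(3 * 12), 3, 12, dimnames = list(c("a", "b", "c"), NULL))
  shift <- E + matrix(rnorm(12, sd = 30), 3, 12, byrow = TRUE)
  b1 <- rfx_bms(E, seed = 10)
  b2 <- rfx_bms(shift, seed = 10)
  expect_equal(b1$freq, b2$freq, tolerance = 1e-6)
})

test_that("between-condition test detects shared and distinct family structure", {
  part <- list(f1 = c("a", "b"), f2 = c("c", "d"))
  set.seed(11)
  E1 <- matrix(rnorm(4 * 20), 4, 20,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  # identical conditions: evidence favours "same"
  same <- between_condition_test(E1, E1, part, seed = 12)
  expect_gt(same$ep_same, 0.5)
  # conditions planted on different families: evidence favours "different"
  E_f1 <- E1; E_f1[c("a", "b"), ] <- E_f1[c("a", "b"), ] + 8
  E_f2 <- E1; E_f2[c("c", "d"), ] <- E_f2[c("c", "d"), ] + 8
  diff <- between_condition_test(E_f1, E_f2, part, seed = 12)
  expect_lt(diff$ep_same, 0.1)
  # symmetric under swapping the condition labels
  swapped <- between_condition_test(E_f2, E_f1, part, seed = 12)
  expect_equal(diff$ep_same, swapped$ep_same, tolerance = 0.02)
  expect_error(between_condition_test(E1, E1[, 1:5], part), "match")
})
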