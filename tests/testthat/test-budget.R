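test_that("transition matrices are row-normalised counts", {
  cnt <- matrix(c(9, 1, 5, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("Resting", "Traveling"),
                                c("Resting", "Traveling")))
  tm <- estimate_matrix(cnt)
  expect_equal(unname(tm$probs),
               matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE))
  expect_equal(tm$n_transitions, 20L)

  # permuting the state order permutes probabilities consistently
  perm <- c(2, 1)
  tm2 <- estimate_matrix(cnt[perm, perm])
  expect_equal(tm2$probs, tm$probs[perm, perm])

  zero <- cnt
  zero[2, ] <- 0
  tmz <- estimate_matrix(zero)
  expect_equal(tmz$zero_rows, "Traveling")
  expect_true(all(is.na(tmz$probs[2, ])))
  expect_error(estimate_matrix(matrix(0, 2, 2)), "all-zero")
  expect_error(estimate_matrix(matrix(1, 2, 3)), "square")

  # explicit Jeffreys-style regularisation revives zero rows
  tmj <- estimate_matrix(zero, pseudo_count = 0.5)
  expect_equal(length(tmj$zero_rows), 0)
  expect_equal(unname(tmj$probs[2, ]), c(0.5, 0.5))
  expect_equal(unname(tmj$probs[1, ]), c(9.5, 1.5) / 11)
})

test_that("stationary distribution solves pi P = pi", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(c("R", "T"), c("R", "T")))
  pi_hat <- stationary_distribution(P)
  expect_equal(unname(pi_hat), c(5 / 6, 1 / 6), tolerance = 1e-10)
  expect_equal(sum(pi_hat), 1)
  expect_lt(max(abs(pi_hat %*% P - pi_hat)), 1e-10)

  # doubly stochastic -> uniform
  D <- matrix(c(0.2, 0.3, 0.5, 0.5, 0.2, 0.3, 0.3, 0.5, 0.2), 3, 3,
              byrow = TRUE, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(stationary_distribution(D)), rep(1 / 3, 3))

  # near-absorbing state dominates; power iteration agrees
  A <- matrix(c(0.999, 0.001, 0.05, 0.95), 2, 2, byrow = TRUE,
              dimnames = list(c("stay", "go"), c("stay", "go")))
  pa <- stationary_distribution(A)
  expect_gt(pa[["stay"]], 0.95)
  expect_equal(pa, stationary_power_iteration(A), tolerance = 1e-8)

  # reducible chains are refused with their communicating classes
  B <- diag(2)
  dimnames(B) <- list(c("R", "T"), c("R", "T"))
  expect_error(stationary_distribution(B), "reducible")
  # period-2 chain: dominant eigenvalue not unique in modulus
  C <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("R", "T"), c("R", "T")))
  expect_error(stationary_distribution(C), "unique|periodic")
})

test_that("eigenvector and power-iteration budgets agree on random chains", {
  set.seed(41)
  for (i in 1:50) {
    P <- random_stochastic_matrix(4)
    expect_equal(stationary_distribution(P), stationary_power_iteration(P),
                 tolerance = 1e-6)
  }
})

test_that("the pooled two-proportion Z test matches its formula and prop.test", {
  same <- z_test_proportions(0.4, 50, 0.4, 80)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  zt <- z_test_proportions(0.6, 100, 0.5, 100)
  expect_equal(zt$z, 0.1 / sqrt(0.55 * 0.45 * 0.02), tolerance = 1e-10)
  expect_equal(zt$z, 1.4213, tolerance = 1e-4)

  # antisymmetry
  sw <- z_test_proportions(0.5, 100, 0.6, 100)
  expect_equal(sw$z, -zt$z)
  expect_equal(sw$p_value, zt$p_value)

  expect_error(z_test_proportions(0, 10, 0, 10), "0 or 1")

  # reference: chi-square of prop.test without continuity correction
  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    z <- z_test_proportions(x1 / n1, n1, x2 / n2, n2)
    pt <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
    expect_equal(z$z^2, unname(pt$statistic), tolerance = 1e-10)
    expect_equal(z$p_value, pt$p.value, tolerance = 1e-10)
  }
})

test_that("budget confidence intervals behave per method", {
  ci <- budget_ci(c(R = 0.5, T = 0.5), n = 100)
  expect_equal(ci$ci_low[1], 0.5 - qnorm(0.975) * 0.05, tolerance = 1e-10)
  expect_equal(round(ci$ci_low[1], 3), 0.402)
  expect_equal(round(ci$ci_high[1], 3), 0.598)

  degen <- budget_ci(c(R = 0, T = 1), n = 50)
  expect_equal(degen$ci_low, c(0, 1))
  expect_equal(degen$ci_high, c(0, 1))
  expect_equal(degen$degenerate, c(TRUE, TRUE))

  expect_error(budget_ci(c(R = 0.5, T = 0.5), 100, method = "bootstrap"),
               "transition-level")

  # bootstrap over a single follow always resamples the same data
  set.seed(6)
  seqs <- simulate_markov_sequence(
    matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2, byrow = TRUE,
           dimnames = list(c("R", "T"), c("R", "T"))), 200)
  tr <- data.frame(follow_id = "F1", preceding = head(seqs, -1),
                   succeeding = tail(seqs, -1))
  cnt <- sequence_to_counts(seqs, c("R", "T"))
  pi_hat <- stationary_distribution(estimate_matrix(cnt))
  bs <- budget_ci(pi_hat, sum(cnt), method = "bootstrap",
                  transitions = tr, B = 5)
  expect_equal(bs$ci_low, bs$ci_high, tolerance = 1e-12)
  expect_equal(bs$ci_low, unname(pi_hat), tolerance = 1e-12)
})

test_that("budget comparison flags a planted drop in resting", {
  set.seed(51)
  states <- analysis_states()
  P_control <- matrix(0.05, 4, 4, dimnames = list(states, states))
  diag(P_control) <- 0.85
  P_treat <- shift_rows(P_control, "Resting", "Milling", 0.12)

  n <- 5000
  s_c <- simulate_markov_sequence(P_control, n)
  s_t <- simulate_markov_sequence(P_treat, n)
  bud_c <- behavioural_budget(sequence_to_counts(s_c, states),
                              stratum = "pooled", condition = "Control")
  bud_t <- behavioural_budget(sequence_to_counts(s_t, states),
                              stratum = "pooled", condition = "Treatment")
  cmp <- compare_budgets(bud_c, bud_t)
  rest <- cmp[cmp$state == "Resting", ]
  expect_true(rest$significant)
  expect_equal(rest$direction, "decrease")

  # identical budgets -> z = 0 everywhere, nothing flagged
  cmp0 <- compare_budgets(bud_c, bud_c)
  expect_true(all(cmp0$z == 0))
  expect_false(any(cmp0$significant))

  # mismatched state sets are refused
  bud_small <- behavioural_budget(
    sequence_to_counts(simulate_markov_sequence(
      matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2,
             dimnames = list(c("R", "T"), c("R", "T")), byrow = TRUE), 500),
      c("R", "T")), stratum = "pooled", condition = "Treatment")
  expect_error(compare_budgets(bud_c, bud_small), "state sets")

  # Holm adjustment never decreases a p-value
  cmp_h <- compare_budgets(bud_c, bud_t, adjust = "holm")
  expect_true(all(cmp_h$p_value >= cmp$p_value - 1e-15))
})

test_that("wald budget intervals cover the estimate", {
  set.seed(61)
  P <- random_stochastic_matrix(4)
  s <- simulate_markov_sequence(P, 2000)
  bud <- behavioural_budget(sequence_to_counts(s, rownames(P)),
                            stratum = "x", condition = "Control")
  expect_equal(sum(bud$proportions), 1, tolerance = 1e-10)
  expect_true(all(bud$ci$ci_low <= bud$ci$proportion + 1e-12))
  expect_true(all(bud$ci$ci_high >= bud$ci$proportion - 1e-12))
  expect_equal(bud$n, 2000L)
})
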