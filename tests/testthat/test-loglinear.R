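two_by_two <- function() {
  array(c(20, 10, 10, 20), dim = c(2, 2),
        dimnames = list(preceding = c("a", "b"), succeeding = c("x", "y")))
}

test_that("the saturated model reproduces the observed table exactly", {
  tab <- two_by_two()
  fit <- fit_ipf(tab, list(c("preceding", "succeeding")))
  expect_equal(unname(fit$expected), unname(unclass(tab)) * 1.0)
  expect_equal(fit$g2, 0)
  expect_equal(fit$df, 0L)
  expect_equal(aic_loglinear(fit), 0)
  expect_equal(fit$iterations, 1L)
})

test_that("independence on a 2x2 table matches the closed form", {
  tab <- two_by_two()
  fit <- fit_ipf(tab, list("preceding", "succeeding"))
  expect_true(fit$converged)
  expect_equal(unname(fit$expected), matrix(15, 2, 2), tolerance = 1e-10)
  # G2 = 2 * (40 ln(4/3) + 20 ln(2/3)), frozen from direct evaluation
  expect_equal(fit$g2, 6.795964, tolerance = 1e-6)
  expect_equal(fit$df, 1L)
  expect_equal(aic_loglinear(fit), fit$g2 - 2)
})

test_that("G-squared follows the 2*sum(O log(O/E)) convention", {
  o <- c(20, 10, 10, 20)
  expect_equal(g_squared(o, o), 0)
  expect_equal(g_squared(o, rep(15, 4)), 2 * sum(o * log(o / 15)))
  # zero observed cells contribute nothing
  expect_equal(g_squared(c(0, 10), c(5, 10)), 0)
  expect_error(g_squared(c(1, 0), c(0, 1)), "zero")
  expect_error(g_squared(c(1, 2, 3), c(1, 2)), "congruent")
})

test_that("model df matches brute-force parameter counting", {
  # independence on I x J: (I-1)(J-1)
  expect_equal(model_df(list("preceding", "succeeding"),
                        c(preceding = 4, succeeding = 4)), 9L)
  expect_equal(model_df(list(c("preceding", "succeeding")),
                        c(preceding = 4, succeeding = 4)), 0L)

  # oracle: df = cells - rank of the model matrix of the matching glm
  brute_df <- function(formula, dims) {
    grid <- do.call(expand.grid, lapply(dims, function(k) factor(seq_len(k))))
    names(grid) <- names(dims)
    mm <- model.matrix(formula, grid)
    nrow(grid) - qr(mm)$rank
  }
  dims <- c(preceding = 4, succeeding = 4, condition = 2)
  expect_equal(
    model_df(list(c("preceding", "succeeding"), "condition"), dims),
    brute_df(~ preceding * succeeding + condition, dims))
  expect_equal(
    model_df(list(c("preceding", "succeeding"),
                  c("succeeding", "condition")), dims),
    brute_df(~ preceding * succeeding + succeeding * condition, dims))
  dims5 <- c(preceding = 4, succeeding = 4, season = 4, time_block = 3,
             condition = 2)
  expect_equal(
    model_df(list(c("preceding", "succeeding"),
                  c("season", "time_block", "condition")), dims5),
    brute_df(~ preceding * succeeding + season * time_block * condition,
             dims5))

  # free parameters + df partition the cell dimension
  dims3 <- c(preceding = 3, succeeding = 3, condition = 2)
  for (gens in list(list("preceding"),
                    list(c("preceding", "succeeding")),
                    list(c("preceding", "condition"),
                         c("succeeding", "condition")))) {
    df <- model_df(gens, dims3)
    expect_gte(df, 0)
    expect_lte(df, prod(dims3) - 1)
  }
})

test_that("IPF agrees with independently fitted poisson models", {
  set.seed(11)
  tab <- array(rpois(8, 30) + 1, dim = c(2, 2, 2),
               dimnames = list(A = c("a1", "a2"), B = c("b1", "b2"),
                               C = c("c1", "c2")))
  fit <- fit_ipf(tab, list(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_true(fit$converged)
  expect_lt(fit$margin_error, 1e-9)

  # oracle 1: poisson glm via IRLS, a different maximiser of the likelihood
  df <- as.data.frame.table(tab, responseName = "count")
  gfit <- glm(count ~ (A + B + C)^2, family = poisson, data = df)
  expect_equal(as.numeric(fit$expected), as.numeric(fitted(gfit)),
               tolerance = 1e-6)
  expect_equal(fit$g2, gfit$deviance, tolerance = 1e-6)
  expect_equal(fit$df, gfit$df.residual)

  # oracle 2: stats::loglin on the same margins
  lfit <- suppressWarnings(
    stats::loglin(tab, list(c(1, 2), c(1, 3), c(2, 3)),
                  fit = TRUE, print = FALSE, eps = 1e-10, iter = 50))
  expect_equal(as.numeric(fit$expected), as.numeric(lfit$fit),
               tolerance = 1e-6)
})

test_that("IPF reproduces every generator margin on random tables", {
  set.seed(21)
  dims <- c(preceding = 4, succeeding = 4, condition = 2)
  for (rep in 1:10) {
    tab <- array(rpois(prod(dims), 8), dim = dims,
                 dimnames = list(preceding = 1:4, succeeding = 1:4,
                                 condition = 1:2))
    names(dimnames(tab)) <- names(dims)
    gens <- list(c("preceding", "succeeding"),
                 c("preceding", "condition"),
                 c("succeeding", "condition"))
    fit <- fit_ipf(tab, gens)
    expect_true(fit$converged)
    expect_lt(fit$margin_error, 1e-10 * max(1, sum(tab)))
    expect_equal(sum(fit$expected), sum(tab), tolerance = 1e-8)
    expect_gte(fit$g2, -1e-10)
  }
})

test_that("nested model comparison gives the chi-square tail of delta G2", {
  tab <- two_by_two()
  ind <- fit_ipf(tab, list("preceding", "succeeding"))
  sat <- fit_ipf(tab, list(c("preceding", "succeeding")))
  same <- compare_nested(ind, ind)
  expect_equal(same$delta_g2, 0)
  expect_equal(same$delta_df, 0L)
  expect_equal(same$p_value, 1)

  cmp <- compare_nested(ind, sat)
  expect_equal(cmp$delta_g2, ind$g2)
  expect_equal(cmp$delta_df, 1L)
  expect_equal(cmp$p_value, pchisq(ind$g2, 1, lower.tail = FALSE))

  # frozen numeric example: delta G2 = 6 on 2 df
  red <- structure(list(generators = list("preceding"), g2 = 10, df = 5L),
                   class = "loglinear_fit")
  full <- structure(list(generators = list(c("preceding", "succeeding")),
                         g2 = 4, df = 3L), class = "loglinear_fit")
  cmp2 <- compare_nested(red, full)
  expect_equal(cmp2$delta_g2, 6)
  expect_equal(cmp2$delta_df, 2L)
  expect_equal(cmp2$p_value, exp(-3), tolerance = 1e-10)

  non_nested <- structure(list(generators = list(c("preceding", "condition")),
                               g2 = 3, df = 2L), class = "loglinear_fit")
  expect_error(compare_nested(non_nested, full), "not nested")
})

test_that("the lattice enumerates all effect combinations and is monotone", {
  set.seed(31)
  cfg <- simulation_config(vessel_shift = 0.12, feeding_entry = 0, seed = 31)
  study <- simulate_study(cfg, force_vessels = "split")
  an_tab <- tabulate_transitions(
    subset(assign_condition(extract_transitions(study$records),
                            study$records), condition != "Excluded"),
    states = analysis_states())
  lat <- run_lattice(an_tab)
  # 2^3 single-factor combinations plus 2 with the time x season interaction
  expect_equal(nrow(lat$table), 10)
  expect_setequal(lat$table$label[1:2],
                  lat$table$label[order(lat$table$aic)][1:2])
  # G2 never increases along an edge from reduced to fuller
  for (i in seq_len(nrow(lat$edges))) {
    g_from <- lat$fits[[lat$edges$from[i]]]$g2
    g_to <- lat$fits[[lat$edges$to[i]]]$g2
    expect_gte(g_from - g_to, -1e-8)
  }
  # the planted vessel effect is picked up
  expect_match(lat$best, "condition")
  expect_true(all(lat$edges$delta_df > 0))
})
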