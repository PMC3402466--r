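#' Estimate a transition probability matrix from counts
#'
#' Row-normalises a square matrix of transition counts (preceding state in
#' rows, succeeding state in columns).  Rows with no observed transitions
#' have undefined probabilities (NA) and are flagged.
#'
#' @param counts square non-negative integer matrix with matching row and
#'   column names.
#' @param pseudo_count Jeffreys-style regularisation added to every cell
#'   before normalising (e.g. 0.5).  Off by default: sparse or reducible
#'   chains are surfaced as errors downstream, never smoothed silently.
#' @return Object of class `transition_matrix`: list with `probs`
#'   (row-stochastic matrix), `counts`, `n_transitions` and `zero_rows`.
#' @export
estimate_matrix <- function(counts, pseudo_count = 0) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("counts must be square", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  stopifnot(pseudo_count >= 0)
  total <- sum(counts)
  if (total == 0) stop("all-zero count matrix", call. = FALSE)
  work <- counts + pseudo_count
  rs <- rowSums(work)
  probs <- work / ifelse(rs == 0, NA_real_, rs)
  zero_rows <- rownames(counts)[rowSums(counts) == 0 & pseudo_count == 0]
  if (is.null(zero_rows)) zero_rows <- which(rs == 0)
  structure(list(probs = probs, counts = counts,
                 n_transitions = as.integer(total), zero_rows = zero_rows),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition matrix on", nrow(x$probs), "states,",
      x$n_transitions, "transitions\n")
  print(round(x$probs, 3))
  if (length(x$zero_rows) > 0) {
    cat("Rows with no observed transitions:",
        paste(x$zero_rows, collapse = ", "), "\n")
  }
  invisible(x)
}

as_prob_matrix <- function(x) {
  if (inherits(x, "transition_matrix")) x$probs else as.matrix(x)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' The long-run behavioural budget of a first-order chain: the left
#' eigenvector of the dominant eigenvalue of the transition matrix,
#' normalised to sum to 1.  The chain must be irreducible (its positive
#' entries must form a strongly connected digraph); reducible chains raise
#' an error listing the communicating classes.  If a second eigenvalue ties
#' with the dominant one in modulus (as in a periodic chain) the stationary
#' distribution is not the unique long-run budget, and the function refuses.
#'
#' @param P a `transition_matrix` or row-stochastic numeric matrix.
#' @param tol tolerance on row sums and on the dominant eigenvalue's
#'   distance from 1.
#' @return Named numeric vector pi with `pi %*% P = pi` and `sum(pi) = 1`.
#' @export
stationary_distribution <- function(P, tol = 1e-8) {
  M <- as_prob_matrix(P)
  n <- nrow(M)
  if (any(!is.finite(M))) {
    stop("transition matrix has undefined rows (no observed transitions); ",
         "cannot compute a stationary distribution", call. = FALSE)
  }
  if (any(M < 0) || max(abs(rowSums(M) - 1)) > 1e-6) {
    stop("matrix is not row-stochastic", call. = FALSE)
  }
  classes <- communicating_classes(M)
  if (length(classes) > 1) {
    stop("chain is reducible; communicating classes: ",
         paste(vapply(classes, function(cl) paste(cl, collapse = ","), ""),
               collapse = " | "), call. = FALSE)
  }
  e <- eigen(t(M))
  mods <- Mod(e$values)
  dom <- which.max(mods)
  if (abs(mods[dom] - 1) > tol) {
    stop("dominant eigenvalue is not 1 within tolerance", call. = FALSE)
  }
  others <- mods[-dom]
  if (length(others) > 0 && max(others) > mods[dom] - 1e-6) {
    stop("dominant eigenvalue is not unique (modulus gap < 1e-6); the chain ",
         "may be periodic", call. = FALSE)
  }
  v <- Re(e$vectors[, dom])
  v <- v / sum(v)
  v[abs(v) < 1e-14] <- 0
  if (any(v < 0)) {
    stop("dominant eigenvector is not non-negative", call. = FALSE)
  }
  if (max(abs(v %*% M - v)) > tol) {
    stop("stationarity check pi P = pi failed", call. = FALSE)
  }
  stats::setNames(as.numeric(v), rownames(M))
}

communicating_classes <- function(M) {
  n <- nrow(M)
  A <- (M > 0) | diag(n) > 0
  R <- A
  for (k in seq_len(ceiling(log2(max(n, 2))))) {
    R <- (R %*% R) > 0
  }
  comm <- R & t(R)
  labels <- rownames(M)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  seen <- rep(FALSE, n)
  classes <- list()
  for (i in seq_len(n)) {
    if (!seen[i]) {
      members <- which(comm[i, ])
      seen[members] <- TRUE
      classes <- c(classes, list(labels[members]))
    }
  }
  classes
}

#' Stationary distribution by power iteration
#'
#' Independent route to the long-run budget: repeated left-multiplication of
#' a probability vector by the transition matrix until the change falls
#' below `tol`.  Used to cross-check the eigenvector method.
#'
#' @param P a `transition_matrix` or row-stochastic matrix.
#' @param tol convergence tolerance on the max absolute change.
#' @param max_iter iteration cap.
#' @return Named stationary probability vector.
#' @export
stationary_power_iteration <- function(P, tol = 1e-12, max_iter = 100000) {
  M <- as_prob_matrix(P)
  v <- rep(1 / nrow(M), nrow(M))
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(v %*% M)
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < tol) {
      return(stats::setNames(v_new, rownames(M)))
    }
    v <- v_new
  }
  stop("power iteration did not converge in ", max_iter, " iterations",
       call. = FALSE)
}

#' Two-proportion Z test with pooled variance
#'
#' Tests the difference between two independent proportions using the pooled
#' estimate \eqn{\bar p = (p_1 n_1 + p_2 n_2)/(n_1 + n_2)} and
#' \eqn{z = (p_1 - p_2)/\sqrt{\bar p (1-\bar p)(1/n_1 + 1/n_2)}}, with a
#' two-sided p-value from the standard normal.
#'
#' @param p1,p2 proportions in \[0, 1\].
#' @param n1,n2 sample sizes (>= 1).
#' @return Object of class `prop_ztest`: list with `z`, `p_value`, `p1`,
#'   `p2`, `n1`, `n2`.
#' @export
z_test_proportions <- function(p1, n1, p2, n2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 1, n2 >= 1)
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) {
    stop("pooled proportion is 0 or 1: no variance to test against",
         call. = FALSE)
  }
  z <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(z = z, p_value = p, p1 = p1, p2 = p2, n1 = n1, n2 = n2),
            class = "prop_ztest")
}

#' Confidence intervals for behavioural-budget proportions
#'
#' Wald intervals \eqn{\pi \pm z_{\alpha/2}\sqrt{\pi(1-\pi)/n}} (clamped to
#' \[0, 1\]) with `n` the number of observed transitions; or a percentile
#' bootstrap that resamples whole follows, the natural exchangeable unit
#' when transitions within a follow are autocorrelated.
#'
#' @param proportions stationary proportions (summing to 1).
#' @param n effective number of transitions behind the estimate.
#' @param alpha two-sided error rate (0.05 for 95 % intervals).
#' @param method `"wald"` or `"bootstrap"`.
#' @param transitions for the bootstrap: transition-level data frame with
#'   columns `follow_id`, `preceding`, `succeeding` for this stratum and
#'   condition.
#' @param B number of bootstrap resamples.
#' @return Data frame with columns `state`, `proportion`, `ci_low`,
#'   `ci_high`, `degenerate` (TRUE where the proportion is exactly 0 or 1).
#' @export
budget_ci <- function(proportions, n, alpha = 0.05,
                      method = c("wald", "bootstrap"),
                      transitions = NULL, B = 1000) {
  method <- match.arg(method)
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  states <- names(proportions)
  if (method == "wald") {
    zcrit <- stats::qnorm(1 - alpha / 2)
    half <- zcrit * sqrt(proportions * (1 - proportions) / n)
    lo <- pmax(proportions - half, 0)
    hi <- pmin(proportions + half, 1)
  } else {
    if (is.null(transitions)) {
      stop("bootstrap CIs need transition-level data (follow_id, preceding, ",
           "succeeding)", call. = FALSE)
    }
    follows <- unique(transitions$follow_id)
    boot <- matrix(NA_real_, nrow = B, ncol = length(states),
                   dimnames = list(NULL, states))
    for (b in seq_len(B)) {
      pick <- sample(follows, length(follows), replace = TRUE)
      rows <- unlist(lapply(pick, function(f) {
        which(transitions$follow_id == f)
      }))
      cnt <- table(factor(transitions$preceding[rows], levels = states),
                   factor(transitions$succeeding[rows], levels = states))
      pi_b <- tryCatch(stationary_distribution(estimate_matrix(cnt)),
                       error = function(e) NULL)
      if (!is.null(pi_b)) boot[b, ] <- pi_b
    }
    boot <- boot[stats::complete.cases(boot), , drop = FALSE]
    if (nrow(boot) == 0) {
      stop("no bootstrap resample produced an irreducible chain",
           call. = FALSE)
    }
    lo <- apply(boot, 2, stats::quantile, probs = alpha / 2)
    hi <- apply(boot, 2, stats::quantile, probs = 1 - alpha / 2)
  }
  data.frame(state = states, proportion = as.numeric(proportions),
             ci_low = as.numeric(lo), ci_high = as.numeric(hi),
             degenerate = proportions %in% c(0, 1),
             stringsAsFactors = FALSE)
}

#' Behavioural budget of a stratum
#'
#' Estimates the transition matrix from a count matrix, takes its stationary
#' distribution as the behavioural budget, and attaches confidence
#' intervals.  The effective n is the number of observed transitions, the
#' sampling unit of the Markov analysis.
#'
#' @param counts square transition count matrix for one stratum and
#'   condition.
#' @param stratum label of the stratum (e.g. a season or a time block).
#' @param condition `"Control"` or `"Treatment"`.
#' @param alpha two-sided error rate for the intervals.
#' @param ci_method `"wald"` or `"bootstrap"` (see [budget_ci()]).
#' @param transitions transition-level data for the bootstrap.
#' @param B bootstrap resamples.
#' @return Object of class `behavioural_budget`: list with `proportions`,
#'   `ci` (data frame), `n`, `stratum`, `condition`, `states`.
#' @export
behavioural_budget <- function(counts, stratum = NA_character_,
                               condition = NA_character_, alpha = 0.05,
                               ci_method = "wald", transitions = NULL,
                               B = 1000) {
  tm <- estimate_matrix(counts)
  pi_hat <- stationary_distribution(tm)
  ci <- budget_ci(pi_hat, tm$n_transitions, alpha = alpha,
                  method = ci_method, transitions = transitions, B = B)
  structure(list(proportions = pi_hat, ci = ci, n = tm$n_transitions,
                 stratum = stratum, condition = condition,
                 states = names(pi_hat)),
            class = "behavioural_budget")
}

#' @export
print.behavioural_budget <- function(x, ...) {
  cat(sprintf("Behavioural budget [%s, %s], n = %d transitions\n",
              x$stratum, x$condition, x$n))
  print(transform(x$ci, proportion = round(proportion, 4),
                  ci_low = round(ci_low, 4), ci_high = round(ci_high, 4)))
  invisible(x)
}

#' Compare Control and Treatment behavioural budgets
#'
#' One pooled two-proportion Z test per behavioural state, with the
#' direction of change under Treatment and a significance flag at `alpha`.
#' P-values are reported unadjusted by default; `adjust = "holm"` applies a
#' Holm correction across the states.
#'
#' @param control,treatment `behavioural_budget` objects over the same state
#'   set.
#' @param alpha significance level.
#' @param adjust `"none"` or `"holm"`.
#' @return Data frame with one row per state: proportions under each
#'   condition, `z`, `p_value`, `direction` (change under Treatment) and
#'   `significant`.
#' @export
compare_budgets <- function(control, treatment, alpha = 0.05,
                            adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(control, "behavioural_budget"),
            inherits(treatment, "behavioural_budget"))
  if (!identical(control$states, treatment$states)) {
    stop("budgets are defined over different state sets", call. = FALSE)
  }
  tests <- lapply(control$states, function(s) {
    z_test_proportions(control$proportions[[s]], control$n,
                       treatment$proportions[[s]], treatment$n)
  })
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  if (adjust == "holm") p <- stats::p.adjust(p, method = "holm")
  delta <- vapply(control$states, function(s) {
    treatment$proportions[[s]] - control$proportions[[s]]
  }, numeric(1))
  data.frame(
    state = control$states,
    control = as.numeric(control$proportions),
    treatment = as.numeric(treatment$proportions),
    n_control = control$n, n_treatment = treatment$n,
    z = vapply(tests, `[[`, numeric(1), "z"),
    p_value = p,
    direction = ifelse(delta > 0, "increase",
                       ifelse(delta < 0, "decrease", "none")),
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
}
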