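#' Fit a hierarchical log-linear model by iterative proportional fitting
#'
#' Given a multi-way contingency table of observed counts and a model stated
#' as its generating class (the maximal marginal interaction terms), IPF
#' rescales an initially flat table so that every generator margin of the
#' fitted expected counts matches the observed margin.  The fixed point is
#' the maximum-likelihood expected table under the hierarchical model.
#' Sampling zeros are retained as zeros — no continuity constant is added.
#'
#' @param observed non-negative count array with named dimnames (e.g. a
#'   [tabulate_transitions()] table).
#' @param generators list of character vectors, each naming a subset of the
#'   table's dimensions; lower-order terms are implied (hierarchical
#'   closure).  Generators that are subsets of another are dropped.
#' @param label human-readable model name.
#' @param tol convergence tolerance: maximum absolute change in any expected
#'   count between successive sweeps.
#' @param max_iter maximum number of IPF sweeps.
#' @return An object of class `loglinear_fit`: list with `observed`,
#'   `expected`, `generators`, `label`, `g2`, `df`, `aic`, `converged`,
#'   `iterations`, and `margin_error` (largest absolute discrepancy between
#'   fitted and observed generator margins).
#' @export
fit_ipf <- function(observed, generators, label = NULL,
                    tol = 1e-10, max_iter = 1000) {
  if (any(observed < 0)) stop("observed counts must be non-negative",
                              call. = FALSE)
  dn <- names(dimnames(observed))
  if (is.null(dn) || any(dn == "")) {
    stop("observed table must have named dimensions", call. = FALSE)
  }
  generators <- normalise_generators(generators, dn)
  if (is.null(label)) {
    label <- paste(vapply(generators, paste, "", collapse = ":"),
                   collapse = " + ")
  }

  obs <- unclass(observed)
  storage.mode(obs) <- "double"
  margins <- lapply(generators, function(g) apply(obs, match(g, dn), sum))

  # saturated model: the full table is its own generator margin
  if (length(generators) == 1 && setequal(generators[[1]], dn)) {
    fit <- structure(
      list(observed = obs, expected = obs, generators = generators,
           label = label, converged = TRUE, iterations = 1L,
           margin_error = 0),
      class = "loglinear_fit")
    return(finish_fit(fit))
  }

  m <- array(1, dim = dim(obs), dimnames = dimnames(obs))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    m_old <- m
    for (k in seq_along(generators)) {
      idx <- match(generators[[k]], dn)
      fit_margin <- apply(m, idx, sum)
      ratio <- margins[[k]] / fit_margin
      zero <- fit_margin == 0
      if (any(zero & margins[[k]] > 0)) {
        stop("IPF stalled: fitted margin vanished where observed margin is ",
             "positive", call. = FALSE)
      }
      ratio[zero] <- 0
      m <- sweep(m, idx, ratio, "*", check.margin = FALSE)
    }
    if (max(abs(m - m_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  margin_error <- max(vapply(seq_along(generators), function(k) {
    max(abs(apply(m, match(generators[[k]], dn), sum) - margins[[k]]))
  }, numeric(1)))
  fit <- structure(
    list(observed = obs, expected = m, generators = generators,
         label = label, converged = converged, iterations = iter,
         margin_error = margin_error),
    class = "loglinear_fit")
  finish_fit(fit)
}

finish_fit <- function(fit) {
  fit$g2 <- g_squared(fit$observed, fit$expected)
  fit$df <- model_df(fit$generators, dim(fit$observed),
                     names(dimnames(fit$observed)))
  fit$aic <- if (fit$converged) fit$g2 - 2 * fit$df else NA_real_
  fit
}

normalise_generators <- function(generators, dims) {
  if (is.character(generators)) generators <- list(generators)
  generators <- lapply(generators, function(g) {
    g <- unique(as.character(g))
    bad <- setdiff(g, dims)
    if (length(bad) > 0) {
      stop("unknown dimension(s) in generator: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    g[order(match(g, dims))]
  })
  # drop generators implied by a larger one (hierarchical closure)
  maximal <- vapply(seq_along(generators), function(i) {
    !any(vapply(seq_along(generators), function(j) {
      i != j && all(generators[[i]] %in% generators[[j]]) &&
        length(generators[[j]]) > length(generators[[i]])
    }, logical(1)))
  }, logical(1))
  unique(generators[maximal])
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat("Log-linear fit:", x$label, "\n")
  cat(sprintf("  G2 = %.4f on %d df, AIC = %.4f (%s, %d iterations)\n",
              x$g2, x$df, x$aic,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Likelihood-ratio goodness-of-fit statistic G-squared
#'
#' \eqn{G^2 = 2 \sum O \ln(O/E)} over all cells, with the convention that
#' cells with zero observed count contribute nothing.
#'
#' @param observed,expected congruent non-negative arrays; `expected` must be
#'   positive wherever `observed` is positive.
#' @return The G-squared statistic (non-negative up to round-off).
#' @export
g_squared <- function(observed, expected) {
  if (length(observed) != length(expected) ||
      !identical(dim(observed), dim(expected))) {
    stop("observed and expected are not congruent", call. = FALSE)
  }
  o <- as.numeric(observed)
  e <- as.numeric(expected)
  if (any(e < 0)) stop("expected counts must be non-negative", call. = FALSE)
  pos <- o > 0
  if (any(pos & e == 0)) {
    stop("expected count is zero where observed count is positive",
         call. = FALSE)
  }
  2 * sum(o[pos] * log(o[pos] / e[pos]))
}

#' Residual degrees of freedom of a hierarchical log-linear model
#'
#' df = (number of cells - 1) minus the number of free parameters implied by
#' the generating class.  Each distinct non-empty subset of a generator
#' contributes \eqn{\prod (d_i - 1)} free parameters (the standard corner
#' parameterisation); the count is over the union of the generators'
#' downward closures, so shared lower-order terms are counted once.
#'
#' @param generators list of character vectors naming marginal terms.
#' @param dims integer vector of axis sizes.
#' @param dim_names names of the axes, in the order of `dims`.
#' @return Integer residual df (0 for the saturated model).
#' @export
model_df <- function(generators, dims, dim_names = names(dims)) {
  if (is.null(dim_names)) stop("dims must be named", call. = FALSE)
  names(dims) <- dim_names
  generators <- normalise_generators(generators, dim_names)
  closure <- unique(unlist(lapply(generators, function(g) {
    subs <- unlist(lapply(seq_along(g), function(k) {
      utils::combn(g, k, simplify = FALSE)
    }), recursive = FALSE)
    vapply(subs, function(s) paste(sort(s), collapse = "\r"), "")
  })))
  n_params <- sum(vapply(closure, function(key) {
    s <- strsplit(key, "\r", fixed = TRUE)[[1]]
    prod(dims[s] - 1)
  }, numeric(1)))
  as.integer(prod(dims) - 1 - n_params)
}

#' AIC of a log-linear fit
#'
#' Uses the deviance form \eqn{AIC = G^2 - 2\,df}, which ranks hierarchical
#' models of the same table identically to \eqn{-2\ell + 2k}.
#'
#' @param fit a converged `loglinear_fit`.
#' @return The AIC value.
#' @export
aic_loglinear <- function(fit) {
  stopifnot(inherits(fit, "loglinear_fit"))
  if (!fit$converged) {
    stop("fit did not converge (", fit$iterations, " iterations, margin ",
         "error ", format(fit$margin_error), "); AIC is not defined",
         call. = FALSE)
  }
  fit$g2 - 2 * fit$df
}

#' Compare two nested log-linear models
#'
#' The change in G-squared between a reduced model and a fuller model nested
#' above it is asymptotically chi-squared on the difference in df; its upper
#' tail probability tests the significance of the added terms.
#'
#' @param reduced,fuller `loglinear_fit` objects on the same table; every
#'   generator of `reduced` must be contained in a generator of `fuller`.
#' @return List of class `model_comparison`: `delta_g2`, `delta_df`,
#'   `p_value`.
#' @export
compare_nested <- function(reduced, fuller) {
  stopifnot(inherits(reduced, "loglinear_fit"),
            inherits(fuller, "loglinear_fit"))
  nested <- all(vapply(reduced$generators, function(g) {
    any(vapply(fuller$generators, function(h) all(g %in% h), logical(1)))
  }, logical(1)))
  if (!nested) stop("models are not nested", call. = FALSE)
  delta_g2 <- reduced$g2 - fuller$g2
  if (delta_g2 < -1e-8) {
    stop("nested G2 difference is negative beyond numerical tolerance",
         call. = FALSE)
  }
  delta_g2 <- max(delta_g2, 0)
  delta_df <- reduced$df - fuller$df
  p <- if (delta_df == 0) 1 else
    stats::pchisq(delta_g2, df = delta_df, lower.tail = FALSE)
  structure(list(delta_g2 = delta_g2, delta_df = delta_df, p_value = p),
            class = "model_comparison")
}

#' Enumerate and fit the lattice of factor-effect models
#'
#' Every model keeps the Markov association between preceding and succeeding
#' state (generator preceding:succeeding) and the fixed design margin
#' (condition:time_block:season, set by the sampling scheme).  Candidate
#' effects modify the transition structure: each single factor f adds the
#' generator preceding:succeeding:f, and the time-of-day-by-season
#' interaction adds preceding:succeeding:time_block:season.  The lattice
#' runs from the null model (no factor effects) through every hierarchical
#' combination of the candidate effects; models are ranked by AIC and each
#' single-term addition edge is tested by its change in G-squared.
#'
#' @param observed a `transition_table` (or any count array with dimensions
#'   preceding, succeeding, season, time_block, condition).
#' @param effects candidate single factors acting on the transition
#'   structure.
#' @param interactions list of factor pairs whose interaction with the
#'   transition structure is also a candidate (only included in models that
#'   already contain both factors).
#' @param alpha significance level for flagging lattice edges.
#' @param ... further arguments passed to [fit_ipf()].
#' @return Object of class `loglinear_lattice`: list with `fits` (named list
#'   of `loglinear_fit`), `saturated` fit, `table` (one row per model:
#'   label, generators, g2, df, aic, delta_g2 and p vs the saturated model,
#'   AIC rank), `edges` (single-term additions with delta G2, delta df, p,
#'   significance flag), and `best` (label of the AIC-best model).
#' @export
run_lattice <- function(observed,
                        effects = c("condition", "time_block", "season"),
                        interactions = list(c("time_block", "season")),
                        alpha = 0.05, ...) {
  dn <- names(dimnames(observed))
  base_assoc <- c("preceding", "succeeding")
  design <- setdiff(dn, base_assoc)
  stopifnot(all(effects %in% design))

  term_sets <- list(character(0))
  for (f in effects) {
    term_sets <- c(term_sets, lapply(term_sets, function(s) c(s, f)))
  }
  for (ia in interactions) {
    ia_label <- paste(ia, collapse = "x")
    with_both <- Filter(function(s) all(ia %in% s), term_sets)
    term_sets <- c(term_sets,
                   lapply(with_both, function(s) c(s, ia_label)))
  }

  model_label <- function(terms) {
    if (length(terms) == 0) "null" else paste(terms, collapse = "+")
  }
  build_generators <- function(terms) {
    gens <- list(base_assoc, design)
    for (tm in terms) {
      fs <- strsplit(tm, "x", fixed = TRUE)[[1]]
      gens <- c(gens, list(c(base_assoc, fs)))
    }
    gens
  }

  fits <- list()
  for (terms in term_sets) {
    lab <- model_label(terms)
    fits[[lab]] <- fit_ipf(observed, build_generators(terms), label = lab, ...)
  }
  saturated <- fit_ipf(observed, list(dn), label = "saturated", ...)

  tab <- do.call(rbind, lapply(names(fits), function(lab) {
    f <- fits[[lab]]
    cmp <- compare_nested(f, saturated)
    data.frame(label = lab,
               generators = paste(vapply(f$generators, paste, "",
                                         collapse = ":"), collapse = " + "),
               g2 = f$g2, df = f$df, aic = f$aic,
               delta_g2_vs_saturated = cmp$delta_g2,
               p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  }))
  tab$rank <- rank(tab$aic, ties.method = "min")
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL

  terms_of <- function(lab) if (lab == "null") character(0) else
    strsplit(lab, "+", fixed = TRUE)[[1]]
  edges <- NULL
  for (to in names(fits)) {
    to_terms <- terms_of(to)
    for (from in names(fits)) {
      from_terms <- terms_of(from)
      if (length(to_terms) == length(from_terms) + 1 &&
          all(from_terms %in% to_terms)) {
        cmp <- compare_nested(fits[[from]], fits[[to]])
        edges <- rbind(edges, data.frame(
          from = from, to = to,
          added = setdiff(to_terms, from_terms),
          delta_g2 = cmp$delta_g2, delta_df = cmp$delta_df,
          p_value = cmp$p_value,
          significant = cmp$p_value < alpha,
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(fits = fits, saturated = saturated, table = tab,
                 edges = edges, best = tab$label[1], alpha = alpha),
            class = "loglinear_lattice")
}

#' @export
print.loglinear_lattice <- function(x, ...) {
  cat("Log-linear model lattice (", nrow(x$table), " models)\n", sep = "")
  print(x$table[, c("label", "g2", "df", "aic", "p_value", "rank")],
        digits = 5)
  cat("AIC-best model:", x$best, "\n")
  invisible(x)
}

#' Write a lattice report and its edge list
#'
#' `write_lattice_report()` writes the per-model CSV (label, generators, G2,
#' df, AIC, delta G2 and p versus the saturated model, AIC rank).
#' `write_lattice_dot()` writes a Graphviz digraph of the lattice with
#' dashed edges marking significant single-term additions.
#'
#' @param lattice a `loglinear_lattice`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lattice_report <- function(lattice, path) {
  utils::write.csv(lattice$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lattice_report
#' @export
write_lattice_dot <- function(lattice, path) {
  lines <- c("digraph lattice {", "  rankdir=TB;")
  for (i in seq_len(nrow(lattice$table))) {
    row <- lattice$table[i, ]
    shape <- if (row$label == lattice$best) "box, peripheries=2" else "box"
    lines <- c(lines, sprintf(
      '  "%s" [shape=%s, label="%s\\nG2=%.1f df=%d AIC=%.1f"];',
      row$label, shape, row$label, row$g2, row$df, row$aic))
  }
  for (i in seq_len(NROW(lattice$edges))) {
    e <- lattice$edges[i, ]
    style <- if (e$significant) "dashed" else "solid"
    lines <- c(lines, sprintf('  "%s" -> "%s" [style=%s, label="+%s"];',
                              e$from, e$to, style, e$added))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
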