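# Marginality-respecting backward elimination of fixed effects, and AIC
# arbitration between alternative predictor sets. No selection is applied to
# the random part.

removable_terms <- function(graph) {
  cand <- setdiff(graph$label, "(Intercept)")
  keep <- purrr::map_lgl(cand, function(tm) {
    length(intersect(containers_of(graph, tm), graph$label)) == 0L
  })
  cand[keep]
}

#' Backward elimination of fixed-effect terms
#'
#' Iteratively removes the least significant *removable* term. A term is
#' removable only when no term still in the model contains it (the principle
#' of marginality: lower-order relatives of retained interactions stay
#' regardless of their own significance; the intercept is never removable).
#' At each step every removable term is tested by a type-II F-test; if the
#' largest p-value exceeds `alpha` that term is dropped and the model is
#' refitted. Ties at identical p-values are broken deterministically: the
#' highest-order term first, then reverse-alphabetical label order. The
#' procedure stops when no removable term is nonsignificant.
#'
#' @param obj A converged `te_lmm` on the full term graph.
#' @param alpha Retention threshold. Default 0.05.
#' @param method Degrees-of-freedom method override.
#' @param config A [run_config()] used for refits.
#' @param verbose Print each elimination step.
#' @return A list of class `te_selection`: `fit` (final `te_lmm`), `trace`
#'   (tibble: step, term_dropped, p_at_drop, model_aic), `graph` (final term
#'   graph), `alpha`.
#' @export
backward_select <- function(obj, alpha = 0.05, method = NULL,
                            config = run_config(), verbose = FALSE) {
  if (!obj$converged) abort("full fit did not converge; aborting selection")
  graph <- obj$graph
  fit <- obj
  trace <- tibble::tibble(step = integer(), term_dropped = character(),
                          p_at_drop = numeric(), model_aic = numeric())
  step <- 0L
  repeat {
    cand <- removable_terms(graph)
    if (!length(cand)) break
    p <- purrr::map_dbl(cand, function(tm) {
      f_test(fit, type2_contrast(fit, tm), method = method)$p_value
    })
    if (max(p) <= alpha) break
    worst <- cand[p == max(p)]
    if (length(worst) > 1L) {
      ord <- order(-graph$order[match(worst, graph$label)], worst,
                   method = "radix")
      worst <- worst[ord]
    }
    drop_term <- worst[1L]
    step <- step + 1L
    graph <- graph_drop_term(graph, drop_term)
    fit <- fit_lmm(obj$data, graph, config = config, reml = obj$reml)
    if (!fit$converged) {
      abort(paste0("refit failed to converge after dropping ", drop_term,
                   " at step ", step))
    }
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, term_dropped = drop_term, p_at_drop = max(p),
      model_aic = information_criterion(fit)
    ))
    if (verbose) {
      message("step ", step, ": dropped ", drop_term,
              " (p = ", signif(max(p), 3), ")")
    }
  }
  structure(
    list(fit = fit, trace = trace, graph = graph, alpha = alpha),
    class = "te_selection"
  )
}

#' Replay a selection trace
#'
#' Re-applies the recorded drops in order, refitting after each, and returns
#' the resulting fit; used to re-validate that a trace reproduces its final
#' model.
#'
#' @param obj The full-model `te_lmm` the selection started from.
#' @param trace A selection trace tibble.
#' @param config A [run_config()].
#' @return A `te_lmm`.
#' @export
replay_selection <- function(obj, trace, config = run_config()) {
  graph <- obj$graph
  for (tm in trace$term_dropped) graph <- graph_drop_term(graph, tm)
  fit_lmm(obj$data, graph, config = config, reml = obj$reml)
}

#' @export
print.te_selection <- function(x, ...) {
  cat("<te_selection> ", nrow(x$trace), " term(s) eliminated at alpha = ",
      x$alpha, "\n", sep = "")
  if (nrow(x$trace)) print(as.data.frame(x$trace), row.names = FALSE)
  cat("final terms:", paste(setdiff(x$graph$label, "(Intercept)"),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.te_selection <- function(x, ...) x$trace

#' Choose among alternative final models by AIC
#'
#' Arbitrates between final models fitted from alternative predictor sets
#' (e.g. the soil-N versus soil-C branch created by collinearity screening):
#' the fit with the smallest AIC wins; exact ties go to the first candidate
#' in input order and are reported.
#'
#' @param fits A list of `te_lmm` or `te_selection` objects on the same
#'   response and rows.
#' @param likelihood AIC likelihood override (`"reml"` or `"ml"`).
#' @return List of class `te_comparison`: `chosen` (the winning object),
#'   `table` (tibble: candidate, aic, chosen), `tie` (logical).
#' @export
compare_alternatives <- function(fits, likelihood = NULL) {
  stopifnot(length(fits) >= 1L)
  get_fit <- function(x) if (inherits(x, "te_selection")) x$fit else x
  objs <- purrr::map(fits, get_fit)
  resp <- purrr::map_chr(objs, function(o) attr(o$graph, "spec")$response)
  ns <- purrr::map_int(objs, function(o) o$n)
  if (length(unique(resp)) > 1L) abort("candidates model different responses")
  if (length(unique(ns)) > 1L) abort("candidates use differing row sets")
  if (length(objs) > 1L) {
    y1 <- stats::model.frame(objs[[1]]$fit)[[1L]]
    for (o in objs[-1L]) {
      if (!isTRUE(all.equal(y1, stats::model.frame(o$fit)[[1L]]))) {
        abort("candidates use differing row sets")
      }
    }
  }
  aic <- purrr::map_dbl(objs, information_criterion, likelihood = likelihood)
  best <- which.min(aic)
  tie <- sum(aic == aic[best]) > 1L
  if (tie) warn("AIC tie; first candidate in input order chosen")
  nms <- names(fits) %||% paste0("candidate_", seq_along(fits))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    nms <- paste0("candidate_", seq_along(fits))
  }
  structure(
    list(
      chosen = fits[[best]],
      table = tibble::tibble(candidate = nms, aic = aic,
                             chosen = seq_along(aic) == best),
      tie = tie
    ),
    class = "te_comparison"
  )
}

#' @export
print.te_comparison <- function(x, ...) {
  cat("<te_comparison>\n")
  print(as.data.frame(x$table), row.names = FALSE)
  if (x$tie) cat("  (tie broken by input order)\n")
  invisible(x)
}
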