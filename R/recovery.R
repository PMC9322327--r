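# Simulation harness: parameter recovery (bias, RMSE, CI coverage, variance
# component bias) and selection behaviour (retention rates of true and null
# terms) under the generator's study conditions.

analysis_graph_for <- function(truth) {
  spec <- attr(truth$graph, "spec")
  spec$response <- paste0(truth$response, "_t")
  build_term_graph(spec, n_varieties = max(attr(truth$graph, "n_varieties"), 0L))
}

#' Parameter-recovery and selection experiment
#'
#' Repeatedly generates a trial, preprocesses it (by default standardizing
#' with the generator's population constants, isolating estimator behaviour
#' from sampling noise in the standardization itself), fits the generative
#' term graph by REML, and aggregates per-coefficient bias, RMSE and 95%
#' Wald confidence-interval coverage (adjusted covariance, per-contrast
#' denominator df) plus variance-component relative bias. Optionally runs
#' backward elimination per replicate and reports per-term retention rates.
#'
#' @param config A [generator_config()]; each replicate uses seed
#'   `config$seed + i`.
#' @param n_reps Number of replicates.
#' @param run_cfg A [run_config()] for preprocessing / fitting.
#' @param do_selection Also run [backward_select()] per replicate.
#' @param use_truth_standardization Standardize with the generator's
#'   population constants (default) instead of per-sample estimates.
#' @param progress Print a dot every 25 replicates.
#' @return List of class `te_recovery`:
#' \describe{
#'   \item{coefficients}{tibble: coefficient, true, mean_est, bias, rmse,
#'     coverage.}
#'   \item{variance}{tibble: component, true, mean_est, rel_bias (residual
#'     included).}
#'   \item{retention}{tibble (term, rate) over replicates, or `NULL`.}
#'   \item{overall_coverage}{coverage pooled over coefficients and reps.}
#' }
#' @export
recovery_experiment <- function(config = generator_config(), n_reps = 100L,
                                run_cfg = run_config(),
                                do_selection = FALSE,
                                use_truth_standardization = TRUE,
                                progress = FALSE) {
  stopifnot(n_reps >= 1L)
  est <- vector("list", n_reps)
  thetas <- vector("list", n_reps)
  retained <- vector("list", n_reps)
  truth0 <- NULL

  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + i
    sim <- simulate_trial(cfg)
    if (is.null(truth0)) truth0 <- sim$truth
    prm <- if (use_truth_standardization) sim$truth$standardization else NULL
    prep <- preprocess_observations(sim$observations, run_cfg,
                                    standardization_params = prm)
    graph <- analysis_graph_for(sim$truth)
    fit <- fit_lmm(prep$data, graph, config = run_cfg)
    td <- tidy(fit)
    td$rep <- i
    est[[i]] <- td
    thetas[[i]] <- c(fit$theta, residual = fit$sigma2)
    if (do_selection) {
      sel <- backward_select(fit, alpha = run_cfg$alpha, config = run_cfg)
      retained[[i]] <- setdiff(sel$graph$label, "(Intercept)")
    }
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")

  truth_beta <- tibble::tibble(term = names(truth0$beta),
                               true = unname(truth0$beta))
  ests <- dplyr::bind_rows(est)
  ests <- dplyr::left_join(ests, truth_beta, by = "term")
  ests$covered <- abs(ests$estimate - ests$true) <=
    qt(0.975, ests$df) * ests$std_error
  coefs <- dplyr::summarise(
    dplyr::group_by(ests, coefficient = .data$term),
    true = .data$true[1],
    mean_est = mean(.data$estimate),
    bias = mean(.data$estimate - .data$true),
    rmse = sqrt(mean((.data$estimate - .data$true)^2)),
    coverage = mean(.data$covered),
    .groups = "drop"
  )

  th <- do.call(rbind, thetas)
  truth_th <- c(truth0$theta, residual = truth0$sigma2)
  variance <- tibble::tibble(
    component = colnames(th),
    true = unname(truth_th[colnames(th)]),
    mean_est = colMeans(th)
  )
  variance$rel_bias <- (variance$mean_est - variance$true) / variance$true

  retention <- NULL
  if (do_selection) {
    all_terms <- setdiff(analysis_graph_for(truth0)$label, "(Intercept)")
    retention <- tibble::tibble(
      term = all_terms,
      rate = purrr::map_dbl(all_terms, function(tm) {
        mean(purrr::map_lgl(retained, function(r) tm %in% r))
      })
    )
  }

  structure(
    list(
      coefficients = coefs,
      variance = variance,
      retention = retention,
      overall_coverage = mean(ests$covered),
      n_reps = n_reps
    ),
    class = "te_recovery"
  )
}

#' @export
print.te_recovery <- function(x, ...) {
  cat("<te_recovery> ", x$n_reps, " replicates; overall 95% CI coverage ",
      round(x$overall_coverage, 3), "\n", sep = "")
  cat("variance components:\n")
  print(as.data.frame(x$variance), row.names = FALSE)
  if (!is.null(x$retention)) {
    cat("retention rates:\n")
    print(as.data.frame(x$retention), row.names = FALSE)
  }
  invisible(x)
}
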