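# End-to-end orchestration: preprocess -> alternative full models (one per
# collinearity-driven environmental predictor set) -> backward selection ->
# AIC choice -> type-II ANOVA -> slopes, surfaces, R2, diagnostics.

#' Run the full trait-environment-performance pipeline
#'
#' For each response (sqrt light-saturated photosynthesis, log water-use
#' efficiency): fits one full polynomial-interaction model per alternative
#' environmental predictor set (the sets come from collinearity screening,
#' e.g. soil N versus soil C), backward-eliminates each under marginality,
#' chooses the final model by AIC, and extracts the type-II ANOVA table,
#' the trait-environment slope table, per-variety slope contrasts for
#' retained interactions, response surfaces for retained trait-environment
#' pairs, the R-squared decomposition, and residual diagnostics.
#'
#' @param observations An observation tibble ([read_observations()] /
#'   [simulate_trial()]).
#' @param config A [run_config()].
#' @param responses Responses to analyse (natural-scale names).
#' @param traits Trait predictors.
#' @param covariates Farm-level covariates.
#' @param outdir Optional output directory; tables are written as
#'   tab-separated text and the manifest + results as JSON.
#' @param verbose Log stage progress.
#' @return List of class `te_pipeline`: `prep`, per-response result bundles
#'   (`full_fits`, `selections`, `comparison`, `final`, `anova`, `slopes`,
#'   `surfaces`, `r2`, `diagnostics`), and `manifest`.
#' @export
run_pipeline <- function(observations, config = run_config(),
                         responses = c("Asat", "WUE"),
                         traits = c("LA", "LMA", "PD", "TTD"),
                         covariates = c("temp", "precip"),
                         outdir = NULL, verbose = FALSE) {
  t_start <- Sys.time()
  if (!is.null(config$seed)) set.seed(config$seed)
  say <- function(...) if (verbose) message(...)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  say("preprocessing")
  prep <- stage("preprocess", preprocess_observations(observations, config))
  env_sets <- prep$screen$alternative_sets
  g <- nlevels(factor(prep$data$variety_id))

  results <- list()
  for (resp in responses) {
    resp_t <- paste0(resp, "_t")
    say("response ", resp, ": fitting ", length(env_sets), " full model(s)")
    sels <- list()
    fulls <- list()
    for (es in env_sets) {
      nm <- paste(es, collapse = "+")
      sp <- model_spec(resp_t, traits = traits, environments = es,
                       variety = if (g >= 2) "variety_id" else NULL,
                       covariates = covariates)
      graph <- build_term_graph(sp, n_varieties = g)
      full <- stage(paste0(resp, "_full_", nm),
                    fit_lmm(prep$data, graph, config = config))
      fulls[[nm]] <- full
      sels[[nm]] <- stage(paste0(resp, "_select_", nm),
                          backward_select(full, alpha = config$alpha,
                                          config = config))
    }
    comparison <- compare_alternatives(sels,
                                       likelihood = config$aic_likelihood)
    final <- comparison$chosen$fit
    anova_tab <- stage(paste0(resp, "_anova"),
                       type2_anova(final, alpha = config$alpha))
    slopes <- stage(paste0(resp, "_slopes"), slope_table(final))
    fgraph <- final$graph
    retained_pairs <- dplyr::distinct(
      dplyr::filter(slopes, .data$retained), .data$trait, .data$env
    )
    surfaces <- purrr::pmap(retained_pairs, function(trait, env) {
      response_surface(final, trait, env,
                       params = prep$report$standardization_params,
                       transform_map = config$transform_map)
    })
    names(surfaces) <- paste0(retained_pairs$trait, ":", retained_pairs$env)
    contrasts <- purrr::pmap(retained_pairs, function(trait, env) {
      variety_slope_contrasts(final, trait, env)
    })
    names(contrasts) <- names(surfaces)
    results[[resp]] <- list(
      full_fits = fulls,
      selections = sels,
      comparison = comparison,
      final = final,
      anova = anova_tab,
      slopes = slopes,
      surfaces = surfaces,
      contrasts = contrasts,
      r2 = r2_nakagawa(final),
      diagnostics = diagnostics(final)
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("traitenv")),
    config_hash = rlang::hash(config),
    input_hash = rlang::hash(observations),
    seed = config$seed,
    n_input = prep$report$n_input,
    n_final = prep$report$n_final,
    responses = responses,
    env_sets = purrr::map_chr(env_sets, paste, collapse = "+"),
    timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  out <- structure(list(prep = prep, results = results, manifest = manifest),
                   class = "te_pipeline")
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

#' Write pipeline outputs
#'
#' Emits, per response: ANOVA table, slope table and selection trace as
#' tab-separated text; plus a machine-readable JSON summary (every number in
#' the tables also appears there) and the run manifest.
#'
#' @param x A `te_pipeline`.
#' @param outdir Output directory (created if needed).
#' @return `x`, invisibly.
#' @export
write_pipeline <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # manifest (with timings) kept apart so results.json is byte-identical
  # across reruns with the same input, config and seed
  writeLines(
    jsonlite::toJSON(x$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(outdir, "manifest.json")
  )
  summary_payload <- list(
    seed = x$manifest$seed,
    config_hash = x$manifest$config_hash,
    input_hash = x$manifest$input_hash
  )
  for (resp in names(x$results)) {
    rr <- x$results[[resp]]
    write_table(rr$anova, file.path(outdir, paste0(resp, "_anova.tsv")))
    write_table(rr$slopes, file.path(outdir, paste0(resp, "_slopes.tsv")))
    for (nm in names(rr$selections)) {
      tr <- rr$selections[[nm]]$trace
      write_table(tr, file.path(outdir,
                                paste0(resp, "_trace_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv")))
    }
    summary_payload[[resp]] <- list(
      anova = rr$anova,
      slopes = rr$slopes,
      aic_comparison = rr$comparison$table,
      r2 = rr$r2,
      final_terms = setdiff(rr$final$graph$label, "(Intercept)"),
      variance_components = c(as.list(rr$final$theta),
                              residual = rr$final$sigma2),
      shapiro_p = rr$diagnostics$shapiro_p
    )
  }
  writeLines(
    jsonlite::toJSON(summary_payload, auto_unbox = TRUE, digits = NA,
                     pretty = TRUE, dataframe = "rows"),
    file.path(outdir, "results.json")
  )
  invisible(x)
}

#' @export
print.te_pipeline <- function(x, ...) {
  cat("<te_pipeline> n =", x$manifest$n_final, "of", x$manifest$n_input,
      "plants;", length(x$results), "response(s)\n")
  for (resp in names(x$results)) {
    rr <- x$results[[resp]]
    cat("  ", resp, ": final terms ",
        paste(setdiff(rr$final$graph$label, "(Intercept)"), collapse = ", "),
        "\n    R2m = ", round(rr$r2$r2_marginal, 3),
        ", R2c = ", round(rr$r2$r2_conditional, 3), "\n", sep = "")
  }
  invisible(x)
}
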