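#' Analysis run configuration
#'
#' Bundles the tunable choices of the pipeline: variable transformations, the
#' collinearity screening threshold, the outlier cutoff, the selection /
#' testing level, the denominator-degrees-of-freedom method, which likelihood
#' feeds the AIC, and the reference variety for treatment coding.
#'
#' Default transformations follow the analysis conventions of the framework:
#' log for taproot tissue density (TTD), leaf mass per area (LMA), soil P, N
#' and C, and the water-use-efficiency response; square root for leaf area
#' (LA), petiole diameter (PD) and the light-saturated photosynthesis
#' response; identity for the farm-level climate covariates. Predictors are
#' standardized to zero mean and unit variance after transformation;
#' responses are transformed but not standardized.
#'
#' @param transform_map Named character vector mapping variable names to one
#'   of `"log"`, `"sqrt"`, `"identity"`. Entries here override the defaults.
#' @param collinearity_threshold Pairwise absolute Pearson correlation above
#'   which (strictly) a predictor pair is flagged. Default 0.6.
#' @param outlier_z_threshold Absolute standardized score beyond which a
#'   plant is removed as an outlier on the screened variable. Default 4.
#' @param alpha Significance level used by backward elimination and for
#'   significance flags. Default 0.05.
#' @param df_method Denominator degrees-of-freedom method for F- and t-tests:
#'   `"kenward_roger"` (default) or `"satterthwaite"`.
#' @param aic_likelihood Likelihood used for AIC: `"reml"` (default) or
#'   `"ml"`. Comparing REML-based AIC across different fixed-effect sets is
#'   heterodox but mirrors common mixed-model practice; set `"ml"` for an
#'   orthodox comparison.
#' @param reference_variety Variety label used as the treatment-coding
#'   reference; per-variety slope contrasts are reported against it.
#'   Default `"H1"`.
#' @param use_radius If `TRUE`, halve the recorded taproot diameter before
#'   evaluating the truncated-cone volume (treat RD as a diameter, as a cone
#'   formula in radii expects). Default `FALSE`: the volume formula is
#'   evaluated verbatim with RD as printed.
#' @param taproot_shape `"truncated_cone"` (default) or `"cylinder"` for
#'   sensitivity runs.
#' @param outlier_variable Variable screened for outliers (on its
#'   transformed, standardized scale). Default `"LA"`.
#' @param seed Optional integer seed recorded in the configuration.
#'
#' @return A list of class `te_config`.
#' @examples
#' cfg <- run_config(alpha = 0.05)
#' cfg$transform_map[["TTD"]]
#' @export
run_config <- function(transform_map = character(),
                       collinearity_threshold = 0.6,
                       outlier_z_threshold = 4,
                       alpha = 0.05,
                       df_method = c("kenward_roger", "satterthwaite"),
                       aic_likelihood = c("reml", "ml"),
                       reference_variety = "H1",
                       use_radius = FALSE,
                       taproot_shape = c("truncated_cone", "cylinder"),
                       outlier_variable = "LA",
                       seed = NULL) {
  stopifnot(
    collinearity_threshold > 0, collinearity_threshold < 1,
    alpha > 0, alpha < 1,
    outlier_z_threshold > 0
  )
  df_method <- match.arg(df_method)
  aic_likelihood <- match.arg(aic_likelihood)
  taproot_shape <- match.arg(taproot_shape)

  tm <- c(
    TTD = "log", LMA = "log", SP = "log", SN = "log", SC = "log",
    WUE = "log", LA = "sqrt", PD = "sqrt", Asat = "sqrt",
    temp = "identity", precip = "identity"
  )
  if (length(transform_map)) {
    bad <- setdiff(unname(transform_map), c("log", "sqrt", "identity"))
    if (length(bad)) {
      abort(paste0("unknown transform(s): ", paste(bad, collapse = ", ")))
    }
    tm[names(transform_map)] <- transform_map
  }

  structure(
    list(
      transform_map = tm,
      collinearity_threshold = collinearity_threshold,
      outlier_z_threshold = outlier_z_threshold,
      alpha = alpha,
      df_method = df_method,
      aic_likelihood = aic_likelihood,
      reference_variety = reference_variety,
      use_radius = use_radius,
      taproot_shape = taproot_shape,
      outlier_variable = outlier_variable,
      seed = seed
    ),
    class = "te_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `transform_map` is a mapping
#' of variable name to transform name. Unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `te_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$transform_map)) {
    raw$transform_map <- unlist(raw$transform_map)
  }
  do.call(run_config, raw)
}

#' @export
print.te_config <- function(x, ...) {
  cat("<te_config>\n")
  cat("  collinearity threshold:", x$collinearity_threshold,
      " outlier |z| >", x$outlier_z_threshold, "\n")
  cat("  alpha:", x$alpha, " df method:", x$df_method,
      " AIC likelihood:", x$aic_likelihood, "\n")
  cat("  reference variety:", x$reference_variety, "\n")
  tm <- paste0(names(x$transform_map), "=", x$transform_map)
  cat("  transforms:", paste(tm, collapse = ", "), "\n")
  invisible(x)
}
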