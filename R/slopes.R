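# Environment-dependent trait-performance slopes: for trait T, environment E
# and variety v, the line phi(E) = (beta_T + beta_{T:v}) + (beta_{TE} +
# beta_{TE:v}) * E, assembled from the treatment-coded coefficients; absent
# interaction coefficients contribute zero.

label_for <- function(graph, vars) {
  vars <- sort(vars)
  hit <- purrr::map_lgl(graph$vars, function(v) identical(sort(v), vars))
  if (!any(hit)) return(NA_character_)
  graph$label[which(hit)[1L]]
}

coef_index <- function(obj, term_label, level = NULL) {
  cm <- obj$column_map
  rows <- cm[cm$term == term_label, , drop = FALSE]
  if (!is.null(level)) rows <- rows[!is.na(rows$variety_level) &
                                      rows$variety_level == level, , drop = FALSE]
  rows$index
}

variety_column <- function(obj) attr(obj$graph, "spec")$variety

reference_level <- function(obj) {
  v <- variety_column(obj)
  if (is.null(v)) return(NULL)
  levels(factor(obj$data[[v]]))[1L]
}

variety_levels <- function(obj) {
  v <- variety_column(obj)
  if (is.null(v)) return(NA_character_)
  levels(factor(obj$data[[v]]))
}

# contrast vectors for the phi intercept and slope of (trait, env, variety)
phi_contrasts <- function(obj, trait, env, variety = NULL) {
  graph <- obj$graph
  k <- obj$k_fixed
  v <- variety_column(obj)
  ref <- reference_level(obj)
  lab_t <- label_for(graph, trait)
  if (is.na(lab_t)) abort(paste0("trait not in model: ", trait))
  c_int <- numeric(k)
  c_int[coef_index(obj, lab_t)] <- 1
  c_slope <- numeric(k)
  lab_te <- label_for(graph, c(trait, env))
  retained <- !is.na(lab_te)
  if (retained) c_slope[coef_index(obj, lab_te)] <- 1
  if (!is.null(v) && !is.null(variety) && variety != ref) {
    lab_tv <- label_for(graph, c(trait, v))
    if (!is.na(lab_tv)) c_int[coef_index(obj, lab_tv, variety)] <- 1
    lab_tev <- label_for(graph, c(trait, env, v))
    if (!is.na(lab_tev)) {
      c_slope[coef_index(obj, lab_tev, variety)] <- 1
      retained <- TRUE
    }
  }
  list(intercept = c_int, slope = c_slope, retained = retained)
}

#' Environment-dependent trait-performance slope for one variety
#'
#' Assembles the trait-environment relationship phi(E) = intercept +
#' slope * E for a (trait, environment, variety) triple from the fitted
#' coefficients: the intercept is the trait's main effect (plus its variety
#' offset), the slope the trait-by-environment interaction (plus its variety
#' offset). Standard errors are linear-combination variances under the
#' Kenward-Roger adjusted covariance; 95% confidence limits use t quantiles
#' at the per-contrast denominator df.
#'
#' @param obj A `te_lmm` containing the trait's main effect.
#' @param trait,env Predictor names (standardized scale).
#' @param variety Variety level; `NULL` for a no-variety model.
#' @return One-row tibble of class `te_phi`: trait, env, variety, intercept,
#'   slope, se_intercept, se_slope, conf_low/conf_high (slope), df_slope,
#'   p_slope, retained.
#' @seealso [phi_at()], [slope_table()]
#' @export
phi_slope <- function(obj, trait, env, variety = NULL) {
  cs <- phi_contrasts(obj, trait, env, variety)
  ti <- contrast_test(obj, cs$intercept)
  if (any(cs$slope != 0)) {
    ts <- contrast_test(obj, cs$slope)
  } else {
    ts <- tibble::tibble(estimate = 0, std_error = 0, df = NA_real_,
                         statistic = NA_real_, p_value = 1)
  }
  tcrit <- if (is.finite(ts$df %||% NA)) qt(0.975, ts$df) else NA_real_
  out <- tibble::tibble(
    trait = trait, env = env,
    variety = variety %||% NA_character_,
    intercept = ti$estimate, se_intercept = ti$std_error,
    slope = ts$estimate, se_slope = ts$std_error,
    conf_low = ts$estimate - tcrit * ts$std_error,
    conf_high = ts$estimate + tcrit * ts$std_error,
    df_slope = ts$df, p_slope = ts$p_value,
    retained = cs$retained
  )
  class(out) <- c("te_phi", class(out))
  out
}

#' Evaluate a trait-environment relationship at environment values
#'
#' @param phi A one-row tibble from [phi_slope()] (or any row of a
#'   [slope_table()]).
#' @param E Environment values (standardized scale).
#' @return `phi$intercept + phi$slope * E`.
#' @export
phi_at <- function(phi, E) {
  stopifnot(nrow(phi) == 1L)
  phi$intercept + phi$slope * E
}

#' All trait-environment slopes of a fitted model
#'
#' Enumerates phi lines for every trait x environment pair and every variety.
#' Pairs whose interaction was eliminated during selection report slope 0
#' with `retained = FALSE`.
#'
#' @param obj A `te_lmm`.
#' @param traits,envs Defaults: the spec's environments, and those of the
#'   spec's traits whose main effect is still in the fitted graph. Pass
#'   explicitly to restrict or extend the enumeration.
#' @return A tibble of class `te_slope_table`, one row per (trait, env,
#'   variety).
#' @export
slope_table <- function(obj, traits = NULL, envs = NULL) {
  spec <- attr(obj$graph, "spec")
  traits <- traits %||% intersect(spec$traits, obj$graph$label)
  envs <- envs %||% spec$environments
  vars <- variety_levels(obj)
  grid <- tidyr::expand_grid(trait = traits, env = envs, variety = vars)
  out <- purrr::pmap(grid, function(trait, env, variety) {
    phi_slope(obj, trait, env,
              variety = if (is.na(variety)) NULL else variety)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("te_slope_table", "te_phi", class(tibble::tibble()))
  attr(out, "response") <- spec$response
  out
}

#' Per-variety slope contrasts against the reference variety
#'
#' For the trait-environment slope (or, with `trait = NULL`, the
#' environment-performance slope), reports each variety's slope offset
#' relative to the reference variety with its Wald test under the adjusted
#' covariance. Under treatment coding the offset is the three-way (or
#' environment-by-variety) interaction coefficient; the reference's contrast
#' is identically zero (p = 1), as are all contrasts when the model has no
#' variety interaction for the pair.
#'
#' @param obj A `te_lmm` with a variety factor.
#' @param trait Trait name, or `NULL` for environment-performance slopes.
#' @param env Environment name.
#' @param reference Reference variety; must be the treatment-coding
#'   reference of the fit.
#' @return Tibble: variety, delta_slope, std_error, df, statistic, p_value.
#' @export
variety_slope_contrasts <- function(obj, trait, env, reference = NULL) {
  v <- variety_column(obj)
  if (is.null(v)) abort("model has no variety factor")
  ref <- reference_level(obj)
  if (!is.null(reference) && reference != ref) {
    abort(paste0("reference must equal the fit's coding reference (", ref, ")"))
  }
  graph <- obj$graph
  if (is.null(trait)) {
    if (is.na(label_for(graph, env))) {
      abort(paste0("environment not in model: ", env))
    }
    lab_int <- label_for(graph, c(env, v))
  } else {
    if (is.na(label_for(graph, trait))) {
      abort(paste0("trait not in model: ", trait))
    }
    lab_int <- label_for(graph, c(trait, env, v))
  }
  lev <- variety_levels(obj)
  rows <- purrr::map(lev, function(vl) {
    if (vl == ref || is.na(lab_int)) {
      return(tibble::tibble(variety = vl, delta_slope = 0, std_error = 0,
                            df = NA_real_, statistic = NA_real_, p_value = 1))
    }
    cvec <- numeric(obj$k_fixed)
    cvec[coef_index(obj, lab_int, vl)] <- 1
    ct <- contrast_test(obj, cvec)
    tibble::tibble(variety = vl, delta_slope = ct$estimate,
                   std_error = ct$std_error, df = ct$df,
                   statistic = ct$statistic, p_value = ct$p_value)
  })
  dplyr::bind_rows(rows)
}

#' Variety differences in the traits themselves
#'
#' Fits, per trait, the nested mixed model `trait ~ variety + (1|farm) +
#' (1|plot) + (1|subplot)` and reports the variety F-test. Used to judge
#' whether variety effects on performance reflect trait differences.
#'
#' @param data Analysis-ready tibble with standardized traits.
#' @param traits Trait columns to model.
#' @param config A [run_config()].
#' @return Tibble: trait, statistic, ndf, ddf, p_value.
#' @export
trait_by_variety_models <- function(data, traits, config = run_config()) {
  g <- nlevels(factor(data$variety_id))
  if (g < 2L) abort("need at least two varieties", class = "te_spec_error")
  rows <- purrr::map(traits, function(tr) {
    sp <- model_spec(tr, variety = "variety_id",
                     include_quadratics = FALSE, include_three_way = FALSE)
    fit <- fit_lmm(data, build_term_graph(sp, n_varieties = g), config = config)
    at <- type2_anova(fit, alpha = config$alpha)
    tibble::tibble(trait = tr, statistic = at$statistic, ndf = at$ndf,
                   ddf = at$ddf, p_value = at$p_value)
  })
  dplyr::bind_rows(rows)
}
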