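# Quadratic response surfaces over (trait, environment), stationary-point
# classification, and the variance-explained decomposition.

#' Predicted response surface over a trait-environment plane
#'
#' Evaluates the fitted fixed-effect surface on a grid of the focal trait
#' and environment (standardized scale), holding every other predictor at 0
#' (the standardized mean) and covariates at their mean. One layer per
#' variety. When standardization parameters are supplied, original-unit axis
#' values are attached, and the observed range of the environment is
#' recorded for annotation.
#'
#' @param obj A `te_lmm`.
#' @param trait,env Focal predictors.
#' @param variety Varieties to evaluate; default all levels.
#' @param grid_n Grid points per axis. Default 41.
#' @param sd_range Half-width of the grid in standardized units. Default 2.5.
#' @param params Optional standardization-parameter tibble (columns
#'   `variable`, `mean`, `sd`) from preprocessing, with the transform map as
#'   attribute-free context: original-unit values are reconstructed by
#'   inverting the configured transform.
#' @param transform_map Named transforms used with `params` (e.g. from
#'   `run_config()$transform_map`).
#' @return Object of class `te_surface`: `grid` (tibble: trait_z, env_z,
#'   variety, predicted, and original units when reconstructable),
#'   `stationary` (per-variety stationary point and class), `trait`, `env`,
#'   `response`, `env_range` (observed standardized range of `env`).
#' @export
response_surface <- function(obj, trait, env, variety = NULL, grid_n = 41L,
                             sd_range = 2.5, params = NULL,
                             transform_map = NULL) {
  spec <- attr(obj$graph, "spec")
  vcol <- variety_column(obj)
  lev <- if (is.null(vcol)) NA_character_ else (variety %||% variety_levels(obj))
  tz <- seq(-sd_range, sd_range, length.out = grid_n)
  ez <- seq(-sd_range, sd_range, length.out = grid_n)
  grid <- tidyr::expand_grid(variety = lev, trait_z = tz, env_z = ez)

  newdata <- grid
  names(newdata)[names(newdata) == "trait_z"] <- trait
  names(newdata)[names(newdata) == "env_z"] <- env
  others <- setdiff(unique(unlist(obj$graph$vars)), c(trait, env, vcol))
  for (v in others) newdata[[v]] <- 0
  if (!is.null(vcol)) {
    newdata[[vcol]] <- factor(newdata$variety, levels = variety_levels(obj))
  }
  for (gcol in spec$random_nesting) {
    newdata[[gcol]] <- factor(obj$data[[gcol]][1L],
                              levels = levels(factor(obj$data[[gcol]])))
  }
  grid$predicted <- if (is_mixed(obj)) {
    as.numeric(predict(obj$fit, newdata = newdata, re.form = NA))
  } else {
    as.numeric(predict(obj$fit, newdata = newdata))
  }

  if (!is.null(params) && all(c(trait, env) %in% params$variable)) {
    inv <- function(var, z) {
      mu <- params$mean[params$variable == var]
      s <- params$sd[params$variable == var]
      x <- z * s + mu
      tr <- (transform_map %||% character())[var]
      switch(tr %||% "identity",
             log = exp(x), sqrt = x^2, identity = x, x)
    }
    grid$trait_orig <- inv(trait, grid$trait_z)
    grid$env_orig <- inv(env, grid$env_z)
  }

  stat <- purrr::map(lev, function(vl) {
    q <- beta_quintet(obj, trait, env, if (is.na(vl)) NULL else vl)
    sp <- stationary_point(q)
    dplyr::bind_cols(tibble::tibble(variety = vl), sp)
  })
  env_obs <- obj$data[[env]]
  out <- list(
    grid = grid,
    stationary = dplyr::bind_rows(stat),
    trait = trait, env = env, response = spec$response,
    env_range = range(env_obs, na.rm = TRUE)
  )
  class(out) <- "te_surface"
  out
}

# (beta1..beta5) for a (trait, env, variety): linear trait, quadratic trait,
# linear env, quadratic env, interaction; variety offsets folded in
beta_quintet <- function(obj, trait, env, variety = NULL) {
  graph <- obj$graph
  b <- obj$beta
  pick <- function(vars, level = NULL) {
    lab <- label_for(graph, vars)
    if (is.na(lab)) return(0)
    idx <- coef_index(obj, lab, level)
    if (!length(idx)) return(0)
    sum(b[idx])
  }
  v <- variety_column(obj)
  ref <- reference_level(obj)
  off <- !is.null(v) && !is.null(variety) && variety != ref
  c(
    beta1 = pick(trait) + if (off) pick(c(trait, v), variety) else 0,
    beta2 = pick(c(trait, trait)),
    beta3 = pick(env) + if (off) pick(c(env, v), variety) else 0,
    beta4 = pick(c(env, env)),
    beta5 = pick(c(trait, env)) +
      if (off) pick(c(trait, env, v), variety) else 0
  )
}

#' Stationary point of the quadratic trait-environment surface
#'
#' For the surface `y = b0 + b1 T + b2 T^2 + b3 E + b4 E^2 + b5 T E`, solves
#' the gradient system `(b1 + 2 b2 T + b5 E, b3 + 2 b4 E + b5 T) = 0` and
#' classifies the point by the eigenvalue signs of the Hessian
#' `H = [[2 b2, b5], [b5, 2 b4]]`: maximum (both negative), minimum (both
#' positive), saddle (mixed), or degenerate (singular Hessian, in which case
#' the flat axis direction is returned instead of a point).
#'
#' @param beta Numeric vector `(b1, b2, b3, b4, b5)`.
#' @return One-row tibble: `T_star`, `E_star`, `class`, `flat_direction`
#'   (list column; `NULL` unless degenerate).
#' @examples
#' stationary_point(c(1, -1, 1, -1, 1)) # maximum at (1, 1)
#' @export
stationary_point <- function(beta) {
  stopifnot(length(beta) == 5L)
  b <- unname(as.numeric(beta))
  H <- matrix(c(2 * b[2], b[5], b[5], 2 * b[4]), 2L, 2L)
  ev <- eigen(H, symmetric = TRUE)
  tol <- 1e-10 * max(abs(ev$values), 1e-300)
  if (any(abs(ev$values) <= tol)) {
    flat <- ev$vectors[, which.min(abs(ev$values))]
    return(tibble::tibble(T_star = NA_real_, E_star = NA_real_,
                          class = "degenerate", flat_direction = list(flat)))
  }
  sol <- solve(H, -c(b[1], b[3]))
  cls <- if (all(ev$values < 0)) "maximum"
  else if (all(ev$values > 0)) "minimum"
  else "saddle"
  tibble::tibble(T_star = sol[1], E_star = sol[2], class = cls,
                 flat_direction = list(NULL))
}

#' Marginal and conditional R-squared
#'
#' Variance-explained decomposition for the Gaussian identity-link mixed
#' model: with `s2_f` the variance of the fixed-effect predictor `X beta`
#' over the data, `R2_marginal = s2_f / (s2_f + sum(theta) + s2_e)` and
#' `R2_conditional = (s2_f + sum(theta)) / (s2_f + sum(theta) + s2_e)` — the
#' proportions of total variance attributable to fixed effects alone and to
#' fixed plus random effects. (For Gaussian identity-link models the
#' delta-method variant collapses to this standard variance ratio.)
#'
#' @param obj A `te_lmm`.
#' @return One-row tibble: `r2_marginal`, `r2_conditional`.
#' @export
r2_nakagawa <- function(obj) {
  fixed_fit <- as.numeric(obj$X %*% obj$beta)
  s2f <- var(fixed_fit)
  tot <- s2f + sum(obj$theta) + obj$sigma2
  tibble::tibble(
    r2_marginal = s2f / tot,
    r2_conditional = (s2f + sum(obj$theta)) / tot
  )
}

#' Residual diagnostics of a fitted model
#'
#' Conditional residuals against fitted values and normal-quantile pairs,
#' with a Shapiro-Wilk summary (on a subsample above 4000 observations).
#'
#' @param obj A `te_lmm`.
#' @return Object of class `te_diagnostics`: `data` (tibble: fitted,
#'   residual, theoretical_quantile), `shapiro_p`, `shapiro_w`.
#' @export
diagnostics <- function(obj) {
  r <- resid(obj$fit)
  f <- stats::fitted(obj$fit)
  ord <- order(r)
  tq <- numeric(length(r))
  tq[ord] <- qnorm(ppoints(length(r))) * sd(r)
  sw_sample <- if (length(r) > 4000) sample(r, 4000) else r
  sw <- if (length(r) >= 3) shapiro.test(sw_sample) else NULL
  out <- list(
    data = tibble::tibble(fitted = f, residual = r, theoretical_quantile = tq),
    shapiro_p = if (is.null(sw)) NA_real_ else unname(sw$p.value),
    shapiro_w = if (is.null(sw)) NA_real_ else unname(sw$statistic)
  )
  class(out) <- "te_diagnostics"
  out
}

#' @export
print.te_diagnostics <- function(x, ...) {
  cat("<te_diagnostics> n =", nrow(x$data),
      " Shapiro-Wilk W =", signif(x$shapiro_w, 4),
      " p =", signif(x$shapiro_p, 4), "\n")
  invisible(x)
}
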