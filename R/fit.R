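# REML fitting of the nested mixed model. Estimation is delegated to
# lme4::lmer (REML; the nested random intercepts are (1|farm) + (1|plot) +
# (1|subplot)); the fitted object is wrapped together with the term graph,
# the column map, and a lazily computed Kenward-Roger core.

#' Fit the nested linear mixed model for a term graph
#'
#' Fits `response ~ fixed terms + (1|farm) + (1|plot) + (1|subplot)` by
#' restricted maximum likelihood. With an empty `random_nesting` in the
#' model spec the fit collapses to ordinary least squares, whose REML
#' solution it is.
#'
#' @param data Analysis-ready tibble (from [preprocess_observations()] or
#'   [simulate_trial()] + preprocessing).
#' @param graph A `te_term_graph` from [build_term_graph()].
#' @param config A [run_config()]; sets the degrees-of-freedom method and
#'   AIC likelihood recorded in the fit.
#' @param reml Fit by REML (default) or ML.
#' @return An object of class `te_lmm` with elements `fit` (the underlying
#'   `lmerMod` or `lm`), `graph`, `column_map`, `beta`, `theta` (named
#'   variance components), `sigma2`, `n`, `k_fixed`, `converged`.
#' @examples
#' sim <- simulate_trial(generator_config(seed = 1))
#' prep <- preprocess_observations(sim$observations)
#' sp <- model_spec("Asat_t", traits = "TTD", environments = "SP",
#'                  variety = "variety_id")
#' fit <- fit_lmm(prep$data, build_term_graph(sp, n_varieties = 5))
#' glance(fit)
#' @export
fit_lmm <- function(data, graph, config = run_config(), reml = TRUE) {
  spec <- attr(graph, "spec")
  nesting <- spec$random_nesting
  vars_needed <- unique(unlist(graph$vars))
  absent <- setdiff(c(spec$response, vars_needed, nesting), names(data))
  if (length(absent)) {
    abort(paste0("data lacks column(s): ", paste(absent, collapse = ", ")))
  }
  des <- expand_design(data, graph)

  if (is.null(nesting) || length(nesting) == 0L) {
    f <- graph_fixed_formula(graph, response = spec$response)
    fit <- lm(f, data = data)
    beta <- coef(fit)
    names(beta) <- colnames(des$X)
    obj <- structure(list(
      fit = fit, graph = graph, data = data, column_map = des$column_map,
      beta = beta, theta = numeric(0), sigma2 = sigma(fit)^2,
      n = nrow(data), k_fixed = length(coef(fit)),
      df_method = config$df_method, aic_likelihood = config$aic_likelihood,
      reml = reml, converged = TRUE, X = des$X, Zlist = list(),
      cache = new.env(parent = emptyenv())
    ), class = "te_lmm")
    return(obj)
  }

  f <- graph_formula(graph, random_nesting = nesting)
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    calc.derivs = FALSE
  )
  fit <- lme4::lmer(f, data = data, REML = reml, control = ctrl)

  X <- des$X # canonical column names; values identical to the fitter's
  if (!isTRUE(all.equal(unname(as.matrix(lme4::getME(fit, "X"))), unname(X),
                        check.attributes = FALSE))) {
    abort("internal error: design columns disagree with the fitter's")
  }
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(X)
  vc <- lme4::VarCorr(fit)
  theta <- purrr::map_dbl(nesting, function(g) as.numeric(vc[[g]][1, 1]))
  names(theta) <- nesting
  ztl <- lme4::getME(fit, "Ztlist")
  names(ztl) <- sub("\\.\\(Intercept\\)$", "", names(ztl))
  Zlist <- purrr::map(nesting, function(g) Matrix::t(ztl[[g]]))
  names(Zlist) <- nesting

  conv <- is.null(fit@optinfo$conv$lme4$code) ||
    fit@optinfo$conv$lme4$code >= 0
  structure(list(
    fit = fit, graph = graph, data = data, column_map = des$column_map,
    beta = beta, theta = theta, sigma2 = sigma(fit)^2,
    n = nrow(data), k_fixed = ncol(X),
    df_method = config$df_method, aic_likelihood = config$aic_likelihood,
    reml = reml, converged = conv, X = X, Zlist = Zlist,
    cache = new.env(parent = emptyenv())
  ), class = "te_lmm")
}

is_mixed <- function(obj) length(obj$Zlist) > 0L

# lazily computed Kenward-Roger core shared by all tests on one fit
kr_core_of <- function(obj) {
  if (!is.null(obj$cache$kr)) return(obj$cache$kr)
  core <- kr_core(obj$X, obj$Zlist, obj$theta, obj$sigma2)
  assign("kr", core, envir = obj$cache)
  core
}

#' Model-based and small-sample-adjusted coefficient covariance
#'
#' `vcov_beta()` returns the model-based GLS covariance of the fixed
#' coefficients; `vcov_beta_adj()` the Kenward-Roger adjusted covariance
#' (identical to the model-based one for a fixed-effects-only model).
#'
#' @param obj A `te_lmm`.
#' @return A symmetric covariance matrix.
#' @export
vcov_beta <- function(obj) {
  if (!is_mixed(obj)) return(unname_matrix(vcov(obj$fit), obj))
  kr_core_of(obj)$Phi
}

#' @rdname vcov_beta
#' @export
vcov_beta_adj <- function(obj) {
  if (!is_mixed(obj)) return(unname_matrix(vcov(obj$fit), obj))
  kr_core_of(obj)$Phi_adj
}

unname_matrix <- function(V, obj) {
  V <- as.matrix(V)
  dimnames(V) <- list(names(obj$beta), names(obj$beta))
  V
}

#' Information criterion of a fitted model
#'
#' `AIC = -2 * loglik + 2 * k` with `k = k_fixed + k_random + 1` (the
#' residual variance), computed under the configured likelihood. The REML
#' variant mirrors common mixed-model reporting; comparing REML-based AIC
#' across different fixed-effect sets is heterodox, and `likelihood = "ml"`
#' refits under maximum likelihood for an orthodox comparison.
#'
#' @param obj A `te_lmm`.
#' @param likelihood `"reml"` or `"ml"`; defaults to the fit's configured
#'   choice.
#' @return A single AIC value.
#' @export
information_criterion <- function(obj, likelihood = NULL) {
  likelihood <- likelihood %||% obj$aic_likelihood
  if (!is_mixed(obj)) {
    return(as.numeric(AIC(obj$fit)))
  }
  fit <- obj$fit
  if (likelihood == "ml" && lme4::isREML(fit)) {
    fit <- lme4::refitML(fit)
  } else if (likelihood == "reml" && !lme4::isREML(fit)) {
    fit <- stats::update(fit, REML = TRUE)
  }
  as.numeric(AIC(fit))
}

#' F-test of a linear hypothesis on the fixed effects
#'
#' Tests `L beta = 0` with `F = (L b)' (L V_adj L')^{-1} (L b) / rank(L)`,
#' using the Kenward-Roger adjusted covariance and denominator degrees of
#' freedom (default), the Satterthwaite approximation, or residual df.
#'
#' @param obj A `te_lmm`.
#' @param L Contrast matrix (rows are contrasts) or a single numeric
#'   contrast vector.
#' @param method `"kenward_roger"`, `"satterthwaite"`, or `"residual"`;
#'   defaults to the fit's configured method.
#' @return A one-row tibble: `statistic`, `ndf`, `ddf`, `p_value`, `method`.
#' @export
f_test <- function(obj, L, method = NULL) {
  method <- method %||% obj$df_method
  if (is.vector(L)) L <- matrix(L, nrow = 1L)
  if (ncol(L) != obj$k_fixed) abort("contrast has wrong length")
  if (qr(L)$rank < nrow(L)) abort("contrast matrix is rank deficient")

  if (!is_mixed(obj)) {
    V <- unname_matrix(vcov(obj$fit), obj)
    b <- obj$beta
    lvl <- L %*% V %*% t(L)
    if (rcond_safe(lvl) < 1e-12) abort("singular contrast covariance")
    Fstat <- drop(crossprod(L %*% b, solve(lvl, L %*% b))) / nrow(L)
    ddf <- obj$n - obj$k_fixed
    return(tibble::tibble(
      statistic = Fstat, ndf = nrow(L), ddf = ddf,
      p_value = pf(Fstat, nrow(L), ddf, lower.tail = FALSE),
      method = "residual"
    ))
  }

  core <- kr_core_of(obj)
  if (method == "kenward_roger") {
    kr_f_test(core, L, obj$beta)
  } else if (method == "satterthwaite") {
    if (nrow(L) == 1L) {
      sat_f_test(core, drop(L), obj$beta)
    } else {
      # multi-df Satterthwaite per contrast row is not defined here; use KR
      kr_f_test(core, L, obj$beta)
    }
  } else {
    b <- obj$beta
    lvl <- L %*% core$Phi %*% t(L)
    Fstat <- drop(crossprod(L %*% b, solve(lvl, L %*% b))) / nrow(L)
    ddf <- obj$n - obj$k_fixed
    tibble::tibble(
      statistic = Fstat, ndf = nrow(L), ddf = ddf,
      p_value = pf(Fstat, nrow(L), ddf, lower.tail = FALSE),
      method = "residual"
    )
  }
}

rcond_safe <- function(M) {
  tryCatch(rcond(as.matrix(M)), error = function(e) 0)
}

# single linear combination: estimate, adjusted SE, df, t, p
contrast_test <- function(obj, cvec, method = NULL) {
  method <- method %||% obj$df_method
  est <- drop(crossprod(cvec, obj$beta))
  if (!is_mixed(obj)) {
    V <- unname_matrix(vcov(obj$fit), obj)
    se <- sqrt(drop(crossprod(cvec, V %*% cvec)))
    df <- obj$n - obj$k_fixed
  } else {
    core <- kr_core_of(obj)
    se <- sqrt(drop(crossprod(cvec, core$Phi_adj %*% cvec)))
    df <- if (method == "satterthwaite") {
      sat_df(core, cvec)
    } else {
      kr_contrast_df(core, cvec)
    }
  }
  tstat <- est / se
  tibble::tibble(
    estimate = est, std_error = se, df = df, statistic = tstat,
    p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE)
  )
}

#' @export
print.te_lmm <- function(x, ...) {
  cat("<te_lmm> ", attr(x$graph, "spec")$response, " ~ ",
      nrow(x$graph) - 1L, " terms (", x$k_fixed, " fixed effects), n = ",
      x$n, "\n", sep = "")
  if (is_mixed(x)) {
    cat("  variance components:",
        paste0(names(x$theta), "=", signif(x$theta, 4), collapse = ", "),
        " residual=", signif(x$sigma2, 4), "\n")
  } else {
    cat("  fixed-effects-only fit; residual variance",
        signif(x$sigma2, 4), "\n")
  }
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' Tidy the fixed effects of a fitted nested mixed model
#'
#' @param x A `te_lmm`.
#' @param ... Unused.
#' @return Tibble: term (coefficient), estimate, adjusted std_error, df,
#'   statistic, p_value.
#' @export
tidy.te_lmm <- function(x, ...) {
  k <- x$k_fixed
  rows <- purrr::map(seq_len(k), function(j) {
    cvec <- numeric(k)
    cvec[j] <- 1
    contrast_test(x, cvec)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(tibble::tibble(term = names(x$beta)), out)
}

#' One-row model summary
#'
#' @param x A `te_lmm`.
#' @param ... Unused.
#' @return Tibble with dimensions, variance components, log-likelihood, AIC
#'   and the marginal / conditional R-squared decomposition.
#' @export
glance.te_lmm <- function(x, ...) {
  r2 <- r2_nakagawa(x)
  tibble::tibble(
    nobs = x$n,
    k_fixed = x$k_fixed,
    k_random = length(x$theta),
    sigma2_farm = if (length(x$theta) >= 1) x$theta[[1]] else NA_real_,
    sigma2_plot = if (length(x$theta) >= 2) x$theta[[2]] else NA_real_,
    sigma2_subplot = if (length(x$theta) >= 3) x$theta[[3]] else NA_real_,
    sigma2_residual = x$sigma2,
    logLik = as.numeric(logLik(x$fit)),
    AIC = information_criterion(x),
    r2_marginal = r2$r2_marginal,
    r2_conditional = r2$r2_conditional,
    converged = x$converged
  )
}

#' Export a fit summary as JSON
#'
#' Coefficients with adjusted standard errors, variance components,
#' log-likelihood, AIC and R-squared, mirroring a supplementary fit table.
#'
#' @param obj A `te_lmm`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written).
#' @export
fit_summary_json <- function(obj, path = NULL) {
  payload <- list(
    coefficients = tidy(obj),
    variance_components = c(as.list(obj$theta), residual = obj$sigma2),
    glance = glance(obj)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
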