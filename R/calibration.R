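# Monte-Carlo calibration of the small-sample F-test: repeated null
# simulations on the fixed nested design, testing a subplot-level
# coefficient at its nominal level.

#' Type-I error calibration of the adjusted F-test
#'
#' Simulates the nested design (farms / plots / subplots / plants) under the
#' null for a subplot-level continuous predictor: the response is pure
#' random-intercept noise plus residual, the predictor coefficient is zero.
#' Each replicate refits the mixed model and tests the coefficient with the
#' configured denominator-df method; the rejection rate at `alpha` estimates
#' the test's size. The design matrix is drawn once (size is assessed
#' conditional on the design, as in a real trial).
#'
#' @param n_sims Number of null replicates.
#' @param alpha Nominal level. Default 0.05.
#' @param n_farms,n_varieties,n_subplots,n_plants Design counts (defaults:
#'   the 9 x 5 x 3 x 3 study design).
#' @param theta True variance components (farm, plot, subplot).
#' @param sigma2 True residual variance.
#' @param method `"kenward_roger"` (default) or `"satterthwaite"`.
#' @param seed Integer seed.
#' @return List of class `te_calibration`: `rejection_rate`, `p_values`,
#'   `n_sims`, `alpha`, `method`, and the binomial `mc_se` of the rate.
#' @export
f_test_calibration <- function(n_sims = 1000L, alpha = 0.05,
                               n_farms = 9L, n_varieties = 5L,
                               n_subplots = 3L, n_plants = 3L,
                               theta = c(farm = 0.16, plot = 0.06,
                                         subplot = 0.025),
                               sigma2 = 0.09,
                               method = c("kenward_roger", "satterthwaite"),
                               seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  d <- tidyr::expand_grid(
    farm_id = factor(paste0("F", seq_len(n_farms))),
    variety_id = factor(variety_labels(n_varieties)),
    subplot_id = factor(paste0("S", seq_len(n_subplots))),
    plant_id = factor(paste0("P", seq_len(n_plants)))
  )
  d$plot_uid <- factor(paste(d$farm_id, d$variety_id, sep = ":"))
  d$subplot_uid <- factor(paste(d$plot_uid, d$subplot_id, sep = ":"))
  n <- nrow(d)
  # subplot-level predictor, drawn once
  xs <- rnorm(nlevels(d$subplot_uid))
  d$x <- xs[as.integer(d$subplot_uid)]

  nf <- nlevels(d$farm_id)
  np <- nlevels(d$plot_uid)
  ns <- nlevels(d$subplot_uid)
  draw_y <- function() {
    rnorm(nf, 0, sqrt(theta[[1]]))[as.integer(d$farm_id)] +
      rnorm(np, 0, sqrt(theta[[2]]))[as.integer(d$plot_uid)] +
      rnorm(ns, 0, sqrt(theta[[3]]))[as.integer(d$subplot_uid)] +
      rnorm(n, 0, sqrt(sigma2))
  }

  d$y <- draw_y()
  sp <- model_spec("y", covariates = "x")
  obj <- fit_lmm(d, build_term_graph(sp, n_varieties = 0))
  jx <- match("x", names(obj$beta))
  nesting <- attr(obj$graph, "spec")$random_nesting

  p <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    fit_i <- suppressMessages(lme4::refit(obj$fit, draw_y()))
    vc <- lme4::VarCorr(fit_i)
    th <- purrr::map_dbl(nesting, function(g) as.numeric(vc[[g]][1, 1]))
    core <- kr_core(obj$X, obj$Zlist, th, sigma(fit_i)^2)
    beta_i <- lme4::fixef(fit_i)
    L <- matrix(0, 1L, length(beta_i))
    L[1, jx] <- 1
    p[i] <- if (method == "kenward_roger") {
      kr_f_test(core, L, beta_i)$p_value
    } else {
      sat_f_test(core, drop(L), beta_i)$p_value
    }
  }
  rate <- mean(p < alpha)
  structure(
    list(
      rejection_rate = rate,
      mc_se = sqrt(alpha * (1 - alpha) / n_sims),
      p_values = p, n_sims = n_sims, alpha = alpha, method = method
    ),
    class = "te_calibration"
  )
}

#' @export
print.te_calibration <- function(x, ...) {
  cat("<te_calibration> ", x$method, ": rejection rate ",
      round(x$rejection_rate, 4), " at alpha = ", x$alpha,
      " (", x$n_sims, " sims, MC se ", round(x$mc_se, 4), ")\n", sep = "")
  invisible(x)
}
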