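# Independent oracles and shared fixtures.

# Closed-form restricted log-likelihood for y = X b + sum_r Z_r u_r + e,
# evaluated by dense linear algebra; independent of the fitting path.
reml_loglik <- function(y, X, Zlist, theta, sigma2) {
  n <- length(y)
  k <- ncol(X)
  V <- diag(sigma2, n)
  for (r in seq_along(Zlist)) {
    Z <- as.matrix(Zlist[[r]])
    V <- V + theta[r] * tcrossprod(Z)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(
    -0.5 * ((n - k) * log(2 * pi) +
              determinant(V, logarithm = TRUE)$modulus +
              determinant(XtViX, logarithm = TRUE)$modulus +
              t(r) %*% Vi %*% r)
  )
}

# Method-of-moments (expected-mean-square) variance-component estimators for
# the balanced 4-level nested design: a farms, b plots per farm, c subplots
# per plot, m plants per subplot.
nested_mom <- function(y, farm, plot, subplot) {
  dat <- data.frame(y = y, farm = farm, plot = plot, subplot = subplot)
  a <- length(unique(farm))
  b <- length(unique(plot)) / a
  cc <- length(unique(subplot)) / (a * b)
  m <- length(y) / (a * b * cc)
  gm <- mean(y)
  fm <- tapply(dat$y, dat$farm, mean)
  pm <- tapply(dat$y, dat$plot, mean)
  sm <- tapply(dat$y, dat$subplot, mean)
  ms_farm <- b * cc * m * sum((fm - gm)^2) / (a - 1)
  farm_of_plot <- tapply(as.character(dat$farm), dat$plot, `[`, 1L)
  ms_plot <- cc * m * sum((pm - fm[farm_of_plot])^2) / (a * (b - 1))
  plot_of_sub <- tapply(as.character(dat$plot), dat$subplot, `[`, 1L)
  ms_sub <- m * sum((sm - pm[plot_of_sub])^2) / (a * b * (cc - 1))
  sub_of_row <- as.character(dat$subplot)
  ms_plant <- sum((dat$y - sm[sub_of_row])^2) / (a * b * cc * (m - 1))
  c(
    farm = (ms_farm - ms_plot) / (b * cc * m),
    plot = (ms_plot - ms_sub) / (cc * m),
    subplot = (ms_sub - ms_plant) / m,
    residual = ms_plant
  )
}

# one-way balanced ANOVA estimators (a groups, m per group)
oneway_anova_vc <- function(y, grp) {
  a <- length(unique(grp))
  m <- length(y) / a
  gm <- tapply(y, grp, mean)
  msb <- m * sum((gm - mean(y))^2) / (a - 1)
  msw <- sum((y - gm[as.character(grp)])^2) / (a * (m - 1))
  c(between = max(0, (msb - msw) / m), within = msw)
}

# shared fixtures (built once per test run)
te_cfg_small <- generator_config(seed = 101, traits = "TTD",
                                 environments = "SP",
                                 covariates = character(0))
te_sim_small <- simulate_trial(te_cfg_small)
te_prep_small <- preprocess_observations(te_sim_small$observations)
te_graph_small <- build_term_graph(
  model_spec("Asat_t", traits = "TTD", environments = "SP",
             variety = "variety_id"),
  n_varieties = 5
)
te_fit_small <- fit_lmm(te_prep_small$data, te_graph_small)

te_sim_default <- simulate_trial(generator_config(seed = 202))
te_prep_default <- preprocess_observations(te_sim_default$observations)

# balanced one-way toy
te_oneway <- local({
  set.seed(11)
  d <- data.frame(grp = factor(rep(paste0("g", 1:6), each = 4)))
  d$y <- rnorm(6, 0, 1.2)[as.integer(d$grp)] + rnorm(24, 0, 0.8)
  d
})
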