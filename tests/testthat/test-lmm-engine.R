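test_that("without random effects the REML fit is ordinary least squares", {
  set.seed(3)
  d <- tibble::tibble(x = rnorm(20))
  d$y <- 1 + 0.5 * d$x + rnorm(20)
  sp <- model_spec("y", traits = "x", include_quadratics = FALSE,
                   random_nesting = NULL)
  fit <- fit_lmm(d, build_term_graph(sp, n_varieties = 0))
  ref <- lm(y ~ x, data = d)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-12)
  expect_equal(fit$sigma2, sum(resid(ref)^2) / (20 - 2), tolerance = 1e-12)
  ft <- f_test(fit, c(0, 1))
  expect_equal(ft$ddf, 18)
  expect_equal(ft$statistic, unname(summary(ref)$coefficients["x", "t value"]^2),
               tolerance = 1e-10)
})

test_that("balanced one-way REML equals the ANOVA estimators", {
  sp <- model_spec("y", random_nesting = "grp")
  fit <- fit_lmm(te_oneway, build_term_graph(sp, n_varieties = 0))
  vc <- oneway_anova_vc(te_oneway$y, te_oneway$grp)
  expect_equal(unname(fit$theta), unname(vc["between"]), tolerance = 1e-6)
  expect_equal(fit$sigma2, unname(vc["within"]), tolerance = 1e-6)
})

test_that("the optimum beats a brute-force grid of the REML criterion", {
  set.seed(9)
  d <- tibble::tibble(
    grp = factor(rep(paste0("g", 1:4), each = 3)),
    x = rnorm(12)
  )
  d$y <- 0.3 * d$x + rnorm(4, 0, 1)[as.integer(d$grp)] + rnorm(12, 0, 0.7)
  sp <- model_spec("y", covariates = "x", random_nesting = "grp")
  fit <- fit_lmm(d, build_term_graph(sp, n_varieties = 0))
  X <- fit$X
  Z <- fit$Zlist
  ll_hat <- reml_loglik(d$y, X, Z, fit$theta, fit$sigma2)
  grid_theta <- seq(0.001, 4, length.out = 50)
  grid_sigma <- seq(0.05, 4, length.out = 50)
  ll_grid <- outer(grid_theta, grid_sigma, Vectorize(function(th, s2) {
    reml_loglik(d$y, X, Z, th, s2)
  }))
  expect_gte(ll_hat, max(ll_grid) - 1e-6)
})

test_that("duplicating every row changes components as the ANOVA oracle predicts", {
  dup <- te_oneway[rep(seq_len(nrow(te_oneway)), 2), ]
  sp <- model_spec("y", random_nesting = "grp")
  fit <- fit_lmm(dup, build_term_graph(sp, n_varieties = 0))
  vc <- oneway_anova_vc(dup$y, dup$grp)
  expect_equal(unname(fit$theta), unname(vc["between"]), tolerance = 1e-6)
  expect_equal(fit$sigma2, unname(vc["within"]), tolerance = 1e-6)
})

test_that("AIC matches a hand-computed Gaussian information criterion", {
  d <- tibble::tibble(x = c(-2, -1, 0, 1, 2), y = c(0.5, 0.9, 1.7, 2.4, 3.4))
  sp <- model_spec("y", traits = "x", include_quadratics = FALSE,
                   random_nesting = NULL)
  fit <- fit_lmm(d, build_term_graph(sp, n_varieties = 0))
  r <- resid(lm(y ~ x, data = d))
  n <- 5
  ll <- -n / 2 * (log(2 * pi) + log(sum(r^2) / n) + 1)
  expect_equal(information_criterion(fit), -2 * ll + 2 * 3, tolerance = 1e-10)
  expect_equal(information_criterion(fit), information_criterion(fit))
})

test_that("REML and ML information criteria differ as configured", {
  aic_reml <- information_criterion(te_fit_small, likelihood = "reml")
  aic_ml <- information_criterion(te_fit_small, likelihood = "ml")
  expect_false(isTRUE(all.equal(aic_reml, aic_ml)))
  # k = k_fixed + k_random + 1 enters both
  ll <- as.numeric(logLik(te_fit_small$fit))
  expect_equal(aic_reml, -2 * ll + 2 * (te_fit_small$k_fixed + 3 + 1))
})

test_that("farm-level coefficients get the classical between-cluster df", {
  set.seed(5)
  d <- tidyr::expand_grid(farm_id = factor(paste0("F", 1:9)),
                          plot_uid = factor(paste0("p", 1:5)),
                          rep = 1:3)
  d$plot_uid <- factor(paste(d$farm_id, d$plot_uid))
  xf <- rnorm(9)
  d$x <- xf[as.integer(d$farm_id)]
  d$y <- rnorm(9, 0, 1)[as.integer(d$farm_id)] +
    rnorm(45, 0, 0.5)[as.integer(d$plot_uid)] + rnorm(nrow(d))
  sp <- model_spec("y", covariates = "x",
                   random_nesting = c("farm_id", "plot_uid"))
  fit <- fit_lmm(d, build_term_graph(sp, n_varieties = 0))
  ft <- f_test(fit, c(0, 1), method = "kenward_roger")
  expect_equal(ft$ddf, 7, tolerance = 1e-2) # 9 clusters - intercept - slope
  st <- f_test(fit, c(0, 1), method = "satterthwaite")
  expect_lt(abs(st$ddf - ft$ddf), 0.1)
})

test_that("the adjustment agrees with an independent implementation", {
  skip_if_not_installed("pbkrtest")
  # unbalanced: drop rows so no closed form applies
  d <- te_prep_small$data[-c(1, 5, 9, 100, 200, 301), ]
  fit <- fit_lmm(d, te_graph_small)
  Vp <- as.matrix(pbkrtest::vcovAdj(fit$fit))
  expect_lt(max(abs(vcov_beta_adj(fit) - Vp)) / max(abs(Vp)), 1e-8)
  k <- fit$k_fixed
  L <- matrix(0, 4, k)
  L[cbind(1:4, 2:5)] <- 1 # the variety dummies
  mine <- f_test(fit, L, method = "kenward_roger")
  ref <- pbkrtest::KRmodcomp(fit$fit, L)
  expect_equal(mine$statistic, ref$stats$Fstat, tolerance = 1e-6)
  expect_equal(mine$ddf, ref$stats$ddf, tolerance = 1e-6)
  expect_equal(mine$p_value, ref$stats$p.value, tolerance = 1e-6)
})

test_that("Satterthwaite df agree with an independent implementation", {
  skip_if_not_installed("lmerTest")
  d <- te_prep_small$data[-c(2, 33, 150), ]
  fit <- fit_lmm(d, te_graph_small)
  fl <- lmerTest::lmer(formula(fit$fit), data = d)
  j <- match("TTD", names(fit$beta))
  cvec <- as.numeric(seq_along(fit$beta) == j)
  mine <- f_test(fit, cvec, method = "satterthwaite")
  ref <- lmerTest::contest1D(fl, cvec, ddf = "Satterthwaite")
  expect_equal(mine$ddf, ref$df, tolerance = 0.02)
})

test_that("a one-coefficient F-test is the squared adjusted t", {
  td <- tidy(te_fit_small)
  j <- match("SP:TTD", td$term)
  cvec <- as.numeric(seq_len(te_fit_small$k_fixed) == j)
  ft <- f_test(te_fit_small, cvec)
  expect_equal(ft$statistic, td$statistic[j]^2, tolerance = 1e-10)
  expect_equal(ft$ddf, td$df[j], tolerance = 1e-8)
})

test_that("the global OLS regression F matches the textbook statistic", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6),
                      y = c(1.1, 2.3, 2.8, 4.5, 4.9, 6.2))
  sp <- model_spec("y", traits = "x", include_quadratics = FALSE,
                   random_nesting = NULL)
  fit <- fit_lmm(d, build_term_graph(sp, n_varieties = 0))
  ft <- f_test(fit, c(0, 1))
  ref <- summary(lm(y ~ x, data = d))$fstatistic
  expect_equal(ft$statistic, unname(ref["value"]), tolerance = 1e-10)
  expect_equal(ft$ddf, unname(ref["dendf"]))
})

test_that("the likelihood is invariant to row order and farm relabeling", {
  d <- te_prep_small$data
  perm <- withr::with_seed(8, sample(nrow(d)))
  fit1 <- te_fit_small
  fit2 <- fit_lmm(d[perm, ], te_graph_small)
  expect_equal(as.numeric(logLik(fit2$fit)), as.numeric(logLik(fit1$fit)),
               tolerance = 1e-6)
  expect_equal(fit2$theta, fit1$theta, tolerance = 1e-4)

  relab <- d
  relab$farm_id <- factor(paste0("farm_", relab$farm_id))
  relab$plot_uid <- factor(paste(relab$farm_id, relab$variety_id))
  relab$subplot_uid <- factor(paste(relab$plot_uid, relab$subplot_id))
  fit3 <- fit_lmm(relab, te_graph_small)
  expect_equal(as.numeric(logLik(fit3$fit)), as.numeric(logLik(fit1$fit)),
               tolerance = 1e-6)
})

test_that("rank-deficient contrasts and singular designs are rejected", {
  L <- rbind(c(0, 1, rep(0, te_fit_small$k_fixed - 2)),
             c(0, 1, rep(0, te_fit_small$k_fixed - 2)))
  expect_error(f_test(te_fit_small, L), "rank deficient")
  expect_error(f_test(te_fit_small, c(0, 1)), "wrong length")
})
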