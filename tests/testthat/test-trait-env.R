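test_that("phi lines evaluate as intercept plus slope times environment", {
  flat <- tibble::tibble(intercept = 2, slope = 0)
  expect_equal(phi_at(flat, c(-3, 0, 3)), c(2, 2, 2))
  tilted <- tibble::tibble(intercept = -1, slope = 0.5)
  expect_equal(phi_at(tilted, 2), 0)
})

test_that("phi slopes assemble reference and offset coefficients", {
  fit <- te_fit_small
  td <- tidy(fit)
  ref <- phi_slope(fit, "TTD", "SP", "H1")
  expect_equal(ref$intercept, td$estimate[match("TTD", td$term)])
  expect_equal(ref$slope, td$estimate[match("SP:TTD", td$term)])
  off <- phi_slope(fit, "TTD", "SP", "OP3")
  expect_equal(off$intercept,
               td$estimate[match("TTD", td$term)] +
                 td$estimate[match("TTD:variety_idOP3", td$term)])
  expect_equal(off$slope,
               td$estimate[match("SP:TTD", td$term)] +
                 td$estimate[match("SP:TTD:variety_idOP3", td$term)])
  expect_error(phi_slope(fit, "LMA", "SP"), "not in model")
})

test_that("phi equals the numerical trait-derivative of the surface", {
  fit <- te_fit_small
  h <- 1e-5
  for (v in c("H1", "OP2")) {
    ph <- phi_slope(fit, "TTD", "SP", v)
    for (E in c(-1.3, 0, 0.7)) {
      nd <- tibble::tibble(
        TTD = c(h, -h), SP = E,
        variety_id = factor(v, levels = levels(fit$data$variety_id)),
        farm_id = fit$data$farm_id[1], plot_uid = fit$data$plot_uid[1],
        subplot_uid = fit$data$subplot_uid[1]
      )
      pr <- predict(fit$fit, newdata = nd, re.form = NA)
      deriv <- (pr[1] - pr[2]) / (2 * h)
      expect_lt(abs(unname(deriv) - phi_at(ph, E)), 1e-8)
    }
  }
})

test_that("the slope table enumerates all trait-environment pairs", {
  sim <- te_sim_default
  prep <- te_prep_default
  sp <- model_spec("Asat_t", traits = c("LA", "LMA", "PD", "TTD"),
                   environments = c("SP", "SN", "SC"),
                   variety = "variety_id")
  fit <- fit_lmm(prep$data, build_term_graph(sp, n_varieties = 5))
  st <- slope_table(fit)
  expect_equal(nrow(st), 4 * 3 * 5) # 12 pairs x 5 varieties
  expect_equal(nrow(dplyr::distinct(st, trait, env)), 12)
  expect_true(all(st$retained))
})

test_that("eliminated interactions report zero slopes, not retained", {
  sp <- model_spec("Asat_t", traits = "TTD", environments = "SP",
                   variety = "variety_id", include_quadratics = FALSE,
                   include_three_way = FALSE)
  g <- build_term_graph(sp, n_varieties = 5)
  g <- traitenv:::graph_drop_term(g, "SP:TTD")
  fit <- fit_lmm(te_prep_small$data, g)
  st <- slope_table(fit, traits = "TTD", envs = "SP")
  expect_true(all(!st$retained))
  expect_true(all(st$slope == 0))
  expect_true(all(st$p_slope == 1))
})

test_that("without variety interactions all varieties share one slope", {
  sp <- model_spec("Asat_t", traits = "TTD", environments = "SP",
                   variety = "variety_id", include_three_way = FALSE)
  g <- build_term_graph(sp, n_varieties = 5)
  g <- traitenv:::graph_drop_term(g, "TTD:variety_id")
  g <- traitenv:::graph_drop_term(g, "SP:variety_id")
  fit <- fit_lmm(te_prep_small$data, g)
  st <- slope_table(fit, traits = "TTD", envs = "SP")
  expect_equal(length(unique(st$slope)), 1)
  expect_equal(length(unique(st$intercept)), 1)
})

test_that("stationary points solve the gradient system and classify", {
  expect_equal(stationary_point(c(0, -1, 0, -1, 0))$class, "maximum")
  expect_equal(stationary_point(c(0, -1, 0, 1, 0))$class, "saddle")
  st <- stationary_point(c(1, -1, 1, -1, 1))
  expect_equal(c(st$T_star, st$E_star), c(1, 1))
  expect_equal(st$class, "maximum")
  # eigenvalues of [[-2, 1], [1, -2]] are -1 and -3
  expect_equal(sort(eigen(matrix(c(-2, 1, 1, -2), 2))$values), c(-3, -1))
  deg <- stationary_point(c(1, 0, 1, 0, 0))
  expect_equal(deg$class, "degenerate")
  expect_false(is.null(deg$flat_direction[[1]]))
})

test_that("surfaces equal direct polynomial evaluation", {
  fit <- te_fit_small
  surf <- response_surface(fit, "TTD", "SP", variety = "OP1", grid_n = 7,
                           sd_range = 2)
  b <- fit$beta
  q <- traitenv:::beta_quintet(fit, "TTD", "SP", "OP1")
  b0 <- b[["(Intercept)"]] + b[["variety_idOP1"]]
  withr::with_seed(3, idx <- sample(nrow(surf$grid), 5))
  for (i in idx) {
    T <- surf$grid$trait_z[i]
    E <- surf$grid$env_z[i]
    manual <- b0 + q[["beta1"]] * T + q[["beta2"]] * T^2 +
      q[["beta3"]] * E + q[["beta4"]] * E^2 + q[["beta5"]] * T * E
    expect_equal(surf$grid$predicted[i], unname(manual), tolerance = 1e-10)
  }
})

test_that("an intercept-only surface is flat", {
  sp <- model_spec("Asat_t", traits = "TTD", environments = "SP",
                   variety = "variety_id", include_quadratics = FALSE,
                   include_three_way = FALSE)
  g <- build_term_graph(sp, n_varieties = 5)
  for (tm in c("SP:TTD", "TTD:variety_id", "SP:variety_id", "TTD", "SP",
               "variety_id")) {
    g <- traitenv:::graph_drop_term(g, tm)
  }
  fit <- fit_lmm(te_prep_small$data, g)
  surf <- response_surface(fit, "TTD", "SP", grid_n = 5)
  expect_equal(diff(range(surf$grid$predicted)), 0, tolerance = 1e-10)
})

test_that("a negative interaction without curvature gives a ruled saddle", {
  # quadratics zero, interaction negative: highest response in the
  # low-trait / high-environment corner
  sp <- model_spec("Asat_t", traits = "TTD", environments = "SP",
                   include_quadratics = FALSE)
  sim <- simulate_trial(generator_config(
    seed = 404, traits = "TTD", environments = "SP",
    covariates = character(0), n_varieties = 1,
    include_quadratics = FALSE, include_three_way = FALSE,
    beta = c("(Intercept)" = sqrt(12), "SP:TTD" = -0.4)
  ))
  prep <- preprocess_observations(sim$observations)
  fit <- fit_lmm(prep$data, build_term_graph(sp, n_varieties = 0))
  surf <- response_surface(fit, "TTD", "SP", grid_n = 11)
  g <- surf$grid
  corner <- function(tt, ee) {
    g$predicted[which.min(abs(g$trait_z - tt) + abs(g$env_z - ee))]
  }
  expect_gt(corner(-2.5, 2.5), corner(2.5, 2.5))
  expect_gt(corner(2.5, -2.5), corner(-2.5, -2.5))
})

test_that("R-squared decomposition obeys its closed-form identities", {
  r2 <- r2_nakagawa(te_fit_small)
  expect_gte(r2$r2_conditional, r2$r2_marginal)
  expect_lte(r2$r2_conditional, 1)

  # theta = 0 (no random part): marginal equals conditional
  d <- tibble::tibble(x = rnorm(30), y = rnorm(30))
  sp <- model_spec("y", traits = "x", include_quadratics = FALSE,
                   random_nesting = NULL)
  ols <- fit_lmm(d, build_term_graph(sp, n_varieties = 0))
  r2o <- r2_nakagawa(ols)
  expect_equal(r2o$r2_marginal, r2o$r2_conditional)

  # intercept-only fixed part: marginal R2 is zero
  spi <- model_spec("y", random_nesting = "grp")
  fiti <- fit_lmm(te_oneway, build_term_graph(spi, n_varieties = 0))
  expect_equal(r2_nakagawa(fiti)$r2_marginal, 0)
})

test_that("R-squared is invariant to row permutation", {
  d <- te_prep_small$data
  perm <- withr::with_seed(10, sample(nrow(d)))
  fit2 <- fit_lmm(d[perm, ], te_graph_small)
  expect_equal(r2_nakagawa(fit2)$r2_marginal,
               r2_nakagawa(te_fit_small)$r2_marginal, tolerance = 1e-5)
})

test_that("autoplot methods return ggplot objects", {
  surf <- response_surface(te_fit_small, "TTD", "SP", grid_n = 5)
  expect_s3_class(autoplot(surf), "ggplot")
  st <- slope_table(te_fit_small)
  expect_s3_class(autoplot(st), "ggplot")
  expect_s3_class(autoplot(diagnostics(te_fit_small)), "ggplot")
})
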