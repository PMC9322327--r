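test_that("type-II equals sequential sums of squares on orthogonal designs", {
  d <- tidyr::expand_grid(T1 = c(-1, 1), E1 = c(-1, 1), rep = 1:5)
  withr::with_seed(2, {
    d$y <- 0.4 * d$T1 - 0.2 * d$E1 + 0.3 * d$T1 * d$E1 + rnorm(20)
  })
  sp <- model_spec("y", traits = "T1", environments = "E1",
                   include_quadratics = FALSE, random_nesting = NULL)
  fit <- fit_lmm(d, build_term_graph(sp, n_varieties = 0))
  mine <- type2_anova(fit)
  ref <- stats::anova(lm(y ~ T1 + E1 + T1:E1, data = d))
  for (tm in c("T1", "E1")) {
    expect_equal(mine$sum_sq[mine$term == tm], ref[tm, "Sum Sq"],
                 tolerance = 1e-8)
  }
  expect_equal(mine$sum_sq[mine$term == "E1:T1"], ref["T1:E1", "Sum Sq"],
               tolerance = 1e-8)
})

test_that("type-II matches an independent implementation off balance", {
  skip_if_not_installed("car")
  withr::with_seed(13, {
    n <- 80
    d <- tibble::tibble(
      V = factor(sample(c("a", "b", "c"), n, TRUE, prob = c(0.5, 0.3, 0.2))),
      T1 = rnorm(n), E1 = rnorm(n)
    )
    d$y <- rnorm(n) + d$T1 + (as.integer(d$V) - 2) * d$T1
  })
  sp <- model_spec("y", traits = "T1", environments = "E1", variety = "V",
                   include_quadratics = FALSE, random_nesting = NULL)
  fit <- fit_lmm(d, build_term_graph(sp, n_varieties = 3))
  mine <- type2_anova(fit)
  ref <- car::Anova(lm(y ~ V + T1 + E1 + T1:E1 + T1:V + E1:V + T1:E1:V,
                       data = d), type = 2)
  canon <- function(x) {
    vapply(strsplit(x, ":", fixed = TRUE),
           function(p) paste(sort(p), collapse = ":"), "")
  }
  ref_key <- canon(rownames(ref))
  for (tm in setdiff(mine$term, character(0))) {
    i <- match(canon(tm), ref_key)
    expect_false(is.na(i), label = paste("term found:", tm))
    expect_equal(mine$statistic[mine$term == tm], ref[i, "F value"],
                 tolerance = 1e-8, info = tm)
  }
})

test_that("a single-predictor table reduces to the overall regression F", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6),
                      y = c(2.1, 2.9, 4.2, 4.4, 6.1, 6.8))
  sp <- model_spec("y", traits = "x", include_quadratics = FALSE,
                   random_nesting = NULL)
  fit <- fit_lmm(d, build_term_graph(sp, n_varieties = 0))
  tab <- type2_anova(fit)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$statistic, unname(summary(lm(y ~ x, d))$fstatistic["value"]),
               tolerance = 1e-10)
})

test_that("the published photosynthesis term set produces its table layout", {
  fit <- fit_lmm(te_prep_default$data, published_term_graph("Asat"))
  tab <- type2_anova(fit)
  expect_setequal(tab$term, c("TTD", "SP", "variety_id", "SP:TTD",
                              "SP:variety_id"))
  expect_equal(tab$ndf[tab$term == "variety_id"], 4)
  expect_equal(tab$ndf[tab$term == "SP:TTD"], 1)
  expect_equal(tab$mean_sq, tab$sum_sq / tab$ndf)
})

test_that("a pure-noise fixed effect inflates the ML criterion on average", {
  diffs <- withr::with_seed(42, replicate(60, {
    d <- tibble::tibble(x = rnorm(40), noise = rnorm(40))
    d$y <- 0.8 * d$x + rnorm(40)
    sp1 <- model_spec("y", traits = "x", include_quadratics = FALSE,
                      random_nesting = NULL)
    sp2 <- model_spec("y", traits = c("x", "noise"),
                      include_quadratics = FALSE, random_nesting = NULL)
    f1 <- fit_lmm(d, build_term_graph(sp1, n_varieties = 0))
    f2 <- fit_lmm(d, build_term_graph(sp2, n_varieties = 0))
    information_criterion(f2, "ml") - information_criterion(f1, "ml")
  }))
  expect_gt(mean(diffs), 0) # E[delta AIC] = 2 - E[chi-square_1] = +1
})

test_that("marginality protects contained terms from removal", {
  g <- te_fit_small$graph
  rem <- traitenv:::removable_terms(g)
  expect_false("variety_id" %in% rem) # protected by x variety interactions
  expect_false("TTD" %in% rem) # protected by quadratic and interactions
  expect_true("SP:TTD:variety_id" %in% rem)
  expect_true("I(TTD^2)" %in% rem)
})

test_that("backward selection stops immediately when everything is significant", {
  sim <- simulate_trial(generator_config(
    seed = 77, traits = "TTD", environments = "SP",
    covariates = character(0),
    include_quadratics = FALSE, include_three_way = FALSE,
    n_varieties = 2,
    beta = c("(Intercept)" = sqrt(12), "TTD" = -0.5, "SP" = 0.5,
             "SP:TTD" = -0.5, "variety_idH2" = 0.8,
             "TTD:variety_idH2" = 0.6, "SP:variety_idH2" = 0.6)
  ))
  prep <- preprocess_observations(sim$observations)
  sp <- model_spec("Asat_t", traits = "TTD", environments = "SP",
                   variety = "variety_id", include_quadratics = FALSE,
                   include_three_way = FALSE)
  fit <- fit_lmm(prep$data, build_term_graph(sp, n_varieties = 2))
  sel <- backward_select(fit)
  expect_equal(nrow(sel$trace), 0)
  expect_identical(sel$graph$label, fit$graph$label)
})

test_that("a selection trace replays to the identical final model", {
  sel <- backward_select(te_fit_small)
  expect_gt(nrow(sel$trace), 0)
  replayed <- replay_selection(te_fit_small, sel$trace)
  expect_identical(replayed$graph$label, sel$fit$graph$label)
  expect_equal(replayed$beta, sel$fit$beta, tolerance = 1e-12)
  # in the final model every removable term is significant
  final_rem <- traitenv:::removable_terms(sel$graph)
  for (tm in final_rem) {
    p <- f_test(sel$fit, traitenv:::type2_contrast(sel$fit, tm))$p_value
    expect_lte(p, sel$alpha)
  }
  # no dropped term was contained in a term retained at its step
  graph <- te_fit_small$graph
  for (tm in sel$trace$term_dropped) {
    expect_true(tm %in% traitenv:::removable_terms(graph))
    graph <- traitenv:::graph_drop_term(graph, tm)
  }
})

test_that("AIC arbitration picks the smallest and reports ties", {
  prep <- te_prep_small
  spN <- model_spec("Asat_t", traits = "TTD", environments = "SP",
                    variety = "variety_id")
  spC <- model_spec("Asat_t", traits = "TTD", environments = "SC",
                    variety = "variety_id")
  fitN <- fit_lmm(prep$data, build_term_graph(spN, n_varieties = 5))
  fitC <- fit_lmm(prep$data, build_term_graph(spC, n_varieties = 5))
  cmp <- compare_alternatives(list(N = fitN, C = fitC))
  expect_equal(cmp$table$candidate[cmp$table$chosen],
               cmp$table$candidate[which.min(cmp$table$aic)])
  expect_false(cmp$tie)

  expect_warning(tie <- compare_alternatives(list(fitN, fitN)), "tie")
  expect_true(tie$tie)
  expect_true(tie$table$chosen[1])

  single <- compare_alternatives(list(only = fitN))
  expect_identical(single$chosen, fitN)

  sub <- fit_lmm(prep$data[-1, ], build_term_graph(spN, n_varieties = 5))
  expect_error(compare_alternatives(list(fitN, sub)), "row sets")
})

test_that("variety slope contrasts are offsets against the reference", {
  vc <- variety_slope_contrasts(te_fit_small, "TTD", "SP")
  ref <- vc[vc$variety == "H1", ]
  expect_equal(ref$delta_slope, 0)
  expect_equal(ref$p_value, 1)
  # under treatment coding the offset is the three-way coefficient
  td <- tidy(te_fit_small)
  j <- match("SP:TTD:variety_idOP2", td$term)
  expect_equal(vc$delta_slope[vc$variety == "OP2"], td$estimate[j])
  expect_equal(vc$p_value[vc$variety == "OP2"], td$p_value[j])
  expect_error(variety_slope_contrasts(te_fit_small, "LMA", "SP"),
               "not in model")
})

test_that("without a three-way term all slope contrasts vanish", {
  sp <- model_spec("Asat_t", traits = "TTD", environments = "SP",
                   variety = "variety_id", include_three_way = FALSE)
  fit <- fit_lmm(te_prep_small$data, build_term_graph(sp, n_varieties = 5))
  vc <- variety_slope_contrasts(fit, "TTD", "SP")
  expect_true(all(vc$delta_slope == 0))
  expect_true(all(vc$p_value == 1))
})

test_that("environment-performance slope offsets recover the truth", {
  # the generator's default soil P x variety offsets: 0.15 -0.12 0.10 -0.15
  vc <- variety_slope_contrasts(te_fit_small, trait = NULL, env = "SP")
  true_off <- c(H1 = 0, H2 = 0.15, OP1 = -0.12, OP2 = 0.10, OP3 = -0.15)
  est <- setNames(vc$delta_slope, vc$variety)
  se <- setNames(vc$std_error, vc$variety)
  for (v in c("H2", "OP1", "OP2", "OP3")) {
    expect_lt(abs(est[[v]] - true_off[[v]]), 3 * se[[v]])
  }
})

test_that("trait-by-variety models flag shifted varieties and need >= 2", {
  sim <- simulate_trial(generator_config(
    seed = 55, trait_shifts = list(TTD = c(2, 0, 0, 0, 0))
  ))
  prep <- preprocess_observations(sim$observations)
  tv <- trait_by_variety_models(prep$data, c("TTD", "LA"))
  expect_lt(tv$p_value[tv$trait == "TTD"], 0.001)
  expect_gt(tv$p_value[tv$trait == "LA"], 0.05) # no shift injected

  one <- dplyr::filter(prep$data, .data$variety_id == "H1")
  expect_error(trait_by_variety_models(one, "TTD"), class = "te_spec_error")
})
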