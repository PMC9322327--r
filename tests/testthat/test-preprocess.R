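test_that("gas-exchange triplicates average to the per-plant mean", {
  expect_equal(average_gas_triplicates(rbind(c(10, 12, 14))), 12)
  expect_equal(average_gas_triplicates(rbind(c(5, 5, 5))), 5)
  expect_warning(
    out <- average_gas_triplicates(rbind(c(8, 10, NA))),
    "fewer than 3"
  )
  expect_equal(out, 9)
  expect_true(is.na(average_gas_triplicates(rbind(c(NA, NA, NA)))))
})

test_that("water-use efficiency is the A_sat / TR ratio", {
  expect_equal(compute_wue(10, 5), 2)
  expect_equal(compute_wue(0, 3), 0)
  expect_equal(compute_wue(7.2, 2.4), 3)
  expect_true(is.na(compute_wue(5, 0)))
})

test_that("taproot volume follows the truncated-cone formula", {
  expect_equal(taproot_volume(10, 1), (1 / 3) * pi * 10 * (1 + 0.05^2 + 0.05))
  # continuity: at r = RD the truncated cone equals the cylinder
  expect_equal(taproot_volume(8, 2, r = 2), pi * 8 * 2^2)
  expect_equal(taproot_volume(8, 2, shape = "cylinder"), pi * 8 * 4)
  # use_radius halves the recorded diameter first
  expect_equal(taproot_volume(10, 2, use_radius = TRUE), taproot_volume(10, 1))
  expect_error(taproot_volume(10, 0.01), class = "te_geometry_error")
  expect_error(taproot_volume(0, 1), class = "te_geometry_error")
})

test_that("taproot volume is monotone in length and diameter", {
  rl <- seq(5, 30, length.out = 11)
  expect_true(all(diff(taproot_volume(rl, 2)) > 0))
  rd <- seq(0.5, 5, length.out = 11)
  expect_true(all(diff(taproot_volume(10, rd)) > 0))
})

test_that("tissue density is mass over volume", {
  expect_equal(compute_ttd(1.5, 10), 0.15)
  expect_equal(compute_ttd(0, 10), 0)
  expect_equal(compute_ttd(2.2, taproot_volume(10, 1)),
               2.2 / ((1 / 3) * pi * 10 * (1 + 0.0025 + 0.05)))
  expect_true(is.na(compute_ttd(2, 0)))
})

test_that("transform + standardize yields zero-mean unit-variance columns", {
  out <- transform_standardize(
    tibble::tibble(x = c(1, exp(1), exp(2))),
    transform_map = c(x = "log"), standardize = "x"
  )
  expect_equal(out$data$x, c(-1, 0, 1)) # z-scores of (0, 1, 2), sd = 1
  expect_equal(out$params$mean, 1)
  expect_equal(out$params$sd, 1)

  expect_error(
    transform_standardize(tibble::tibble(x = rep(2, 5)),
                          transform_map = c(x = "identity"),
                          standardize = "x"),
    "zero-variance"
  )
  expect_error(
    transform_standardize(tibble::tibble(x = c(1, -2, 3)),
                          transform_map = c(x = "log"), standardize = "x"),
    "non-positive"
  )
})

test_that("standardization is idempotent and params are reusable", {
  set.seed(1)
  x <- rnorm(50, 3, 2)
  once <- transform_standardize(tibble::tibble(x = x),
                                transform_map = c(x = "identity"),
                                standardize = "x")
  twice <- transform_standardize(once$data,
                                 transform_map = c(x = "identity"),
                                 standardize = "x")
  expect_equal(twice$data$x, once$data$x, tolerance = 1e-12)

  reused <- transform_standardize(tibble::tibble(x = x + 1),
                                  transform_map = c(x = "identity"),
                                  standardize = "x", params = once$params)
  expect_equal(reused$data$x, once$data$x + 1 / once$params$sd)
})

test_that("collinearity screening flags pairs strictly above the threshold", {
  set.seed(4)
  n <- 200
  z <- rnorm(n)
  d <- tibble::tibble(
    SN = 0.9 * z + sqrt(1 - 0.81) * rnorm(n),
    SC = 0.9 * z - sqrt(1 - 0.81) * rnorm(n),
    SP = rnorm(n)
  )
  # force a high empirical correlation
  d$SC <- 0.8 * d$SN + sqrt(1 - 0.64) * rnorm(n)
  sc <- screen_collinearity(d, c("SN", "SC", "SP"), threshold = 0.6)
  flagged <- sc$pairs[sc$pairs$flagged, ]
  expect_true(any(flagged$var1 == "SN" & flagged$var2 == "SC"))
  expect_equal(length(sc$alternative_sets), 2L)
  expect_setequal(sc$alternative_sets[[1]], c("SN", "SP"))
  expect_setequal(sc$alternative_sets[[2]], c("SC", "SP"))
})

test_that("orthogonal predictors are not flagged and r == threshold is kept", {
  x <- rep(c(1, 1, -1, -1), 10)
  w <- rep(c(1, -1, 1, -1), 10)
  d <- tibble::tibble(a = x, b = w, e = 0.6 * x + 0.8 * w)
  sc0 <- screen_collinearity(d, c("a", "b"), threshold = 0.6)
  expect_false(any(sc0$pairs$flagged))
  # cor(a, e) is exactly 0.6: strictly-above rule keeps it
  expect_equal(cor(d$a, d$e), 0.6)
  sc1 <- screen_collinearity(d, c("a", "e"), threshold = 0.6)
  expect_false(any(sc1$pairs$flagged))
  sc2 <- screen_collinearity(d, c("a", "e"), threshold = 0.59)
  expect_true(any(sc2$pairs$flagged))
})

test_that("outlier removal drops |z| above the cutoff and reports counts", {
  d <- tibble::tibble(LA = c(rnorm(50), 6.5, -7))
  out <- remove_outliers(d, "LA", 4)
  expect_equal(out$n_removed, 2)
  expect_equal(nrow(out$data), 50)
  keep <- remove_outliers(d, "LA", Inf)
  expect_equal(keep$n_removed, 0)
  expect_identical(keep$data, d)
})

test_that("the preprocessing chain reconciles 405 -> 398 and its counts", {
  rep <- te_prep_default$report
  expect_equal(rep$n_input, 405)
  expect_equal(rep$n_dropped_missing_phys, 5)
  expect_equal(rep$n_dropped_outliers, 2)
  expect_equal(rep$n_final, 398)
  expect_equal(rep$n_final,
               rep$n_input - rep$n_dropped_missing_phys - rep$n_dropped_outliers)
  # predictors standardized, responses transformed but not standardized
  d <- te_prep_default$data
  for (v in c("LA", "LMA", "PD", "TTD", "SP", "SN", "SC")) {
    expect_lt(abs(mean(d[[v]])), 0.35)
  }
  expect_gt(mean(d$Asat_t), 2) # sqrt scale, not centered
  expect_equal(d$Asat_t^2, d$Asat)
  expect_equal(exp(d$WUE_t), d$WUE)
})

test_that("pipeline counts reconcile across generator seeds", {
  for (s in c(7, 21)) {
    sim <- simulate_trial(generator_config(seed = s, n_missing_phys = 3,
                                           n_la_outliers = 1))
    rep <- preprocess_observations(sim$observations)$report
    expect_equal(rep$n_final,
                 rep$n_input - rep$n_dropped_missing_phys - rep$n_dropped_outliers)
    expect_equal(rep$n_dropped_missing_phys, 3)
    expect_equal(rep$n_dropped_outliers, 1)
  }
})
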