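# Synthetic nested field trials: 9 farms x 5 varieties (one plot each) x 3
# subplots x 3 plants, with farm-level climate, correlated subplot-level
# soils, mildly correlated plant-level traits, and performance generated
# from the polynomial-interaction fixed-effect model plus nested random
# intercepts. Soils are log-normal and traits are drawn on their transformed
# scales and inverted to natural units, so the preprocessing path (log/sqrt
# then z-score) is exercised end to end.

variety_labels <- function(g) {
  base <- c("H1", "H2", "OP1", "OP2", "OP3")
  if (g <= 5L) base[seq_len(g)] else c(base, paste0("V", 6:g))
}

# transformed-scale population location/scale of each generated variable
gen_scale_params <- function(config) {
  tibble::tribble(
    ~variable, ~mean, ~sd,
    "LA", 10, 1.5, # sqrt(cm^2)
    "LMA", -5.1, 0.25, # log(g cm^-2)
    "PD", 3, 0.35, # sqrt(mm)
    "TTD", -1.75, 0.3, # log(g cm^-3)
    "SP", log(30), sqrt(0.45^2 + 0.3^2), # log(mg kg^-1)
    "SN", log(2.5), sqrt(0.3^2 + 0.2^2), # log(mg g^-1)
    "SC", log(30), sqrt(0.3^2 + 0.2^2), # log(mg g^-1)
    "temp", mean(config$temp_range), diff(config$temp_range) / sqrt(12),
    "precip", mean(config$precip_range), diff(config$precip_range) / sqrt(12)
  )
}

#' Configuration of the synthetic trial generator
#'
#' Defaults reproduce the study design the analysis assumes: 9 farms, 5
#' varieties (one plot per variety per farm), 3 subplots per plot, 3 plants
#' per subplot (405 plants); variance components ordered farm > plot >
#' subplot; soil N and C correlated at 0.8; pairwise trait correlations
#' mild (0.3, below the 0.6 screening threshold); farm temperature and
#' precipitation uniform over the study's observed ranges; 5
#' missing-physiology plants and 2 extreme leaf-area plants injected so the
#' 405 -> 398 attrition path is exercised.
#'
#' @param n_farms,n_varieties,n_subplots,n_plants Design counts.
#' @param theta True variance components `(farm, plot, subplot)` on the
#'   response's transformed scale.
#' @param sigma2 True residual variance.
#' @param beta Named numeric vector of true fixed-effect coefficients on the
#'   design columns of the generative term graph (standardized predictors;
#'   treatment-coded variety). When supplied it is a complete specification
#'   (unnamed coefficients are zero); the default (`NULL`) is a sparse
#'   trait-by-soil interaction structure with a nonzero trait x soil
#'   interaction and soil x variety offsets.
#' @param response Which performance variable the fixed-effect model drives:
#'   `"Asat"` (response scale sqrt) or `"WUE"` (log).
#' @param traits,environments,covariates Predictors entering the generative
#'   fixed-effect model.
#' @param include_quadratics,include_three_way Generative structure switches.
#' @param soil_nc_correlation Correlation of log soil N and log soil C at
#'   both the farm and subplot levels.
#' @param trait_correlation Common pairwise correlation of the transformed
#'   traits.
#' @param trait_shifts Optional named list `trait -> numeric(g)` of
#'   per-variety mean shifts (standardized units) for trait-difference
#'   studies.
#' @param temp_range,precip_range Farm-level climate ranges (degrees C, mm).
#' @param n_missing_phys,n_la_outliers Injected attrition counts.
#' @param rep_noise Multiplicative noise sd of individual gas-exchange
#'   readings around the plant value.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `te_generator_config`.
#' @export
generator_config <- function(n_farms = 9L, n_varieties = 5L, n_subplots = 3L,
                             n_plants = 3L,
                             theta = c(farm = 0.16, plot = 0.06, subplot = 0.025),
                             sigma2 = 0.09,
                             beta = NULL,
                             response = c("Asat", "WUE"),
                             traits = c("LA", "LMA", "PD", "TTD"),
                             environments = c("SP", "SN"),
                             covariates = c("temp", "precip"),
                             include_quadratics = TRUE,
                             include_three_way = TRUE,
                             soil_nc_correlation = 0.8,
                             trait_correlation = 0.3,
                             trait_shifts = NULL,
                             temp_range = c(16.6, 20.5),
                             precip_range = c(97.2, 237.9),
                             n_missing_phys = 5L, n_la_outliers = 2L,
                             rep_noise = 0.02,
                             seed = 1L) {
  stopifnot(
    n_farms >= 1, n_varieties >= 1, n_subplots >= 1, n_plants >= 1,
    length(theta) == 3L, all(theta >= 0), sigma2 > 0,
    abs(soil_nc_correlation) < 1, abs(trait_correlation) < 1
  )
  structure(
    list(
      n_farms = as.integer(n_farms), n_varieties = as.integer(n_varieties),
      n_subplots = as.integer(n_subplots), n_plants = as.integer(n_plants),
      theta = theta, sigma2 = sigma2, beta = beta,
      response = match.arg(response),
      traits = traits, environments = environments, covariates = covariates,
      include_quadratics = include_quadratics,
      include_three_way = include_three_way,
      soil_nc_correlation = soil_nc_correlation,
      trait_correlation = trait_correlation,
      trait_shifts = trait_shifts,
      temp_range = temp_range, precip_range = precip_range,
      n_missing_phys = as.integer(n_missing_phys),
      n_la_outliers = as.integer(n_la_outliers),
      rep_noise = rep_noise, seed = as.integer(seed)
    ),
    class = "te_generator_config"
  )
}

# generative term graph (variety omitted below 2 levels)
generator_graph <- function(config) {
  v <- if (config$n_varieties >= 2L) "variety_id" else NULL
  sp <- model_spec(
    response = "y_t",
    traits = config$traits, environments = config$environments,
    variety = v, covariates = config$covariates,
    include_quadratics = config$include_quadratics,
    include_three_way = config$include_three_way
  )
  build_term_graph(sp, n_varieties = config$n_varieties)
}

default_true_beta <- function(config, design_cols) {
  beta <- setNames(numeric(length(design_cols)), design_cols)
  b0 <- if (config$response == "Asat") sqrt(12) else log(3)
  defaults <- c(
    "(Intercept)" = b0,
    "TTD" = -0.06, "SP" = 0.03,
    "SP:TTD" = -0.105,
    "variety_idH2" = 0.05, "variety_idOP1" = -0.05,
    "variety_idOP2" = 0.08, "variety_idOP3" = -0.08,
    "SP:variety_idH2" = 0.15, "SP:variety_idOP1" = -0.12,
    "SP:variety_idOP2" = 0.10, "SP:variety_idOP3" = -0.15
  )
  hit <- intersect(names(defaults), design_cols)
  beta[hit] <- defaults[hit]
  beta
}

rmvnorm_chol <- function(n, sigma) {
  p <- ncol(sigma)
  matrix(rnorm(n * p), n, p) %*% chol(sigma)
}

#' Generate a synthetic nested observation table
#'
#' Draws a full trial under the configuration: farm-level climate, subplot
#' soils (log-normal; N and C correlated), plant-level traits (transformed
#' scale, exchangeable correlation), then the performance response from
#' `X beta + u_farm + u_plot + u_subplot + e` on the transformed scale,
#' inverted to natural units. Raw morphology is back-constructed so the
#' preprocessing chain (triplicate averaging, volume, tissue density, LMA,
#' transforms) recovers the generative quantities. Optional
#' missing-physiology and extreme leaf-area plants are injected last.
#'
#' @param config A [generator_config()].
#' @return List of class `te_sim`: `observations` (a validated observation
#'   tibble) and `truth` (true `beta`, `theta`, `sigma2`, the generative
#'   term graph, and the population standardization parameters on the
#'   transformed scale).
#' @examples
#' sim <- simulate_trial(generator_config(seed = 42))
#' nrow(sim$observations) # 405
#' @export
simulate_trial <- function(config = generator_config()) {
  set.seed(config$seed)
  g <- config$n_varieties
  vlab <- variety_labels(g)
  ids <- tidyr::expand_grid(
    farm_id = paste0("F", seq_len(config$n_farms)),
    variety_id = vlab,
    subplot_id = paste0("S", seq_len(config$n_subplots)),
    plant_id = paste0("P", seq_len(config$n_plants))
  )
  n <- nrow(ids)
  scl <- gen_scale_params(config)
  pget <- function(v, what) scl[[what]][scl$variable == v]

  # farm-level climate
  farms <- tibble::tibble(
    farm_id = paste0("F", seq_len(config$n_farms)),
    temp = runif(config$n_farms, config$temp_range[1], config$temp_range[2]),
    precip = runif(config$n_farms, config$precip_range[1], config$precip_range[2])
  )

  # subplot-level soils on the log scale: farm mean + subplot deviation,
  # with the N-C correlation present at both levels
  rho <- config$soil_nc_correlation
  nc_cor <- matrix(c(1, rho, rho, 1), 2L)
  farm_nc <- rmvnorm_chol(config$n_farms, 0.3^2 * nc_cor)
  subplots <- dplyr::distinct(ids, .data$farm_id, .data$variety_id,
                              .data$subplot_id)
  ns <- nrow(subplots)
  sub_nc <- rmvnorm_chol(ns, 0.2^2 * nc_cor)
  fidx <- match(subplots$farm_id, farms$farm_id)
  subplots$SN <- exp(pget("SN", "mean") + farm_nc[fidx, 1] + sub_nc[, 1])
  subplots$SC <- exp(pget("SC", "mean") + farm_nc[fidx, 2] + sub_nc[, 2])
  farm_p <- rnorm(config$n_farms, 0, 0.45)
  subplots$SP <- exp(pget("SP", "mean") + farm_p[fidx] + rnorm(ns, 0, 0.3))

  data <- dplyr::left_join(ids, farms, by = "farm_id")
  data <- dplyr::left_join(
    data, subplots, by = c("farm_id", "variety_id", "subplot_id")
  )

  # plant-level traits, transformed scale, exchangeable correlation
  p <- 4L
  tc <- matrix(config$trait_correlation, p, p)
  diag(tc) <- 1
  tz <- rmvnorm_chol(n, tc)
  colnames(tz) <- c("LA", "LMA", "PD", "TTD")
  if (!is.null(config$trait_shifts)) {
    vi <- match(data$variety_id, vlab)
    for (tr in names(config$trait_shifts)) {
      tz[, tr] <- tz[, tr] + config$trait_shifts[[tr]][vi]
    }
  }

  # standardized predictors for the generative fixed-effect model
  zfun <- function(v, x) (x - pget(v, "mean")) / pget(v, "sd")
  zdat <- tibble::tibble(
    LA = tz[, "LA"], LMA = tz[, "LMA"], PD = tz[, "PD"], TTD = tz[, "TTD"],
    SP = zfun("SP", log(data$SP)),
    SN = zfun("SN", log(data$SN)),
    SC = zfun("SC", log(data$SC)),
    temp = zfun("temp", data$temp),
    precip = zfun("precip", data$precip)
  )
  if (g >= 2L) {
    zdat$variety_id <- factor(data$variety_id, levels = vlab)
  }

  graph <- generator_graph(config)
  # no rank requirement here: the truth design only multiplies beta
  X <- expand_design(zdat, graph, check_rank = FALSE)$X
  if (is.null(config$beta)) {
    beta <- default_true_beta(config, colnames(X))
  } else {
    # an explicit beta is a complete specification: unnamed coefficients are 0
    unknown <- setdiff(names(config$beta), colnames(X))
    if (length(unknown)) {
      abort(paste0("beta name(s) not in design: ",
                   paste(unknown, collapse = ", ")))
    }
    beta <- setNames(numeric(ncol(X)), colnames(X))
    beta[names(config$beta)] <- config$beta
  }

  plot_key <- paste(data$farm_id, data$variety_id)
  sub_key <- paste(plot_key, data$subplot_id)
  u_farm <- rnorm(config$n_farms, 0, sqrt(config$theta[[1]]))
  u_plot <- rnorm(length(unique(plot_key)), 0, sqrt(config$theta[[2]]))
  u_sub <- rnorm(length(unique(sub_key)), 0, sqrt(config$theta[[3]]))
  y_t <- as.numeric(X %*% beta) +
    u_farm[match(data$farm_id, farms$farm_id)] +
    u_plot[match(plot_key, unique(plot_key))] +
    u_sub[match(sub_key, unique(sub_key))] +
    rnorm(n, 0, sqrt(config$sigma2))

  # natural-scale performance + gas exchange
  if (config$response == "Asat") {
    if (any(y_t <= 0.05)) {
      abort("generated sqrt-scale response not positive; lower the noise")
    }
    Asat <- y_t^2
    TR <- exp(rnorm(n, log(2.8), 0.25))
  } else {
    WUE <- exp(y_t)
    Asat <- exp(rnorm(n, log(12), 0.2))
    TR <- Asat / WUE
  }
  gs <- exp(rnorm(n, log(150), 0.3)) * (TR / mean(TR))
  reps <- function(x) x * exp(rnorm(n, 0, config$rep_noise))
  for (j in 1:3) data[[paste0("Asat_r", j)]] <- reps(Asat)
  for (j in 1:3) data[[paste0("gs_r", j)]] <- reps(gs)
  for (j in 1:3) data[[paste0("TR_r", j)]] <- reps(TR)

  # raw morphology back-constructed from transformed traits
  LA_s <- pget("LA", "mean") + pget("LA", "sd") * tz[, "LA"]
  PD_s <- pget("PD", "mean") + pget("PD", "sd") * tz[, "PD"]
  LMA_s <- pget("LMA", "mean") + pget("LMA", "sd") * tz[, "LMA"]
  TTD_s <- pget("TTD", "mean") + pget("TTD", "sd") * tz[, "TTD"]
  data$LA <- pmax(LA_s, 1)^2
  data$PD <- pmax(PD_s, 0.5)^2
  data$leaf_dry_mass <- exp(LMA_s) * data$LA
  data$RL <- pmax(rnorm(n, 16, 2.5), 5)
  RD_cm <- pmax(rnorm(n, 2.8, 0.35), 0.5)
  data$RD <- RD_cm * 10 # stored in mm
  vol <- taproot_volume(data$RL, RD_cm)
  data$taproot_dry_mass <- exp(TTD_s) * vol

  # injected attrition
  if (config$n_missing_phys > 0L) {
    miss <- sample.int(n, config$n_missing_phys)
    for (cn in rep_cols) data[[cn]][miss] <- NA_real_
  } else {
    miss <- integer(0)
  }
  if (config$n_la_outliers > 0L) {
    pool <- setdiff(seq_len(n), miss)
    out <- sample(pool, config$n_la_outliers)
    data$LA[out] <- (pget("LA", "mean") + 6.5 * pget("LA", "sd"))^2
    data$leaf_dry_mass[out] <- exp(LMA_s[out]) * data$LA[out]
  }

  data$farm_id <- factor(data$farm_id, levels = farms$farm_id)
  data$variety_id <- factor(data$variety_id, levels = vlab)
  data$subplot_id <- factor(data$subplot_id)
  data$plant_id <- factor(data$plant_id)
  data <- data[c(id_cols, measure_cols)]
  data$flag_missing_phys <- flag_missing_phys(data)
  validate_observations(data)

  truth <- list(
    beta = beta,
    theta = setNames(as.numeric(config$theta),
                     c("farm_id", "plot_uid", "subplot_uid")),
    sigma2 = config$sigma2,
    graph = graph,
    response = config$response,
    standardization = scl,
    config = config
  )
  structure(list(observations = data, truth = truth), class = "te_sim")
}

#' @export
print.te_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat("<te_sim> ", nrow(x$observations), " plants (",
      cfg$n_farms, " farms x ", cfg$n_varieties, " varieties x ",
      cfg$n_subplots, " subplots x ", cfg$n_plants, " plants), response ",
      cfg$response, "\n", sep = "")
  invisible(x)
}

#' Write a simulated trial to disk
#'
#' Writes the observation table as tab-separated text plus a JSON truth
#' record (true coefficients and variance components).
#'
#' @param sim A `te_sim`.
#' @param obs_path,truth_path Output paths.
#' @return `sim`, invisibly.
#' @export
write_trial <- function(sim, obs_path, truth_path) {
  write_table(sim$observations, obs_path)
  payload <- list(
    beta = as.list(sim$truth$beta),
    theta = as.list(sim$truth$theta),
    sigma2 = sim$truth$sigma2,
    response = sim$truth$response,
    seed = sim$truth$config$seed
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), truth_path)
  invisible(sim)
}
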