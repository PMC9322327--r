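# Trait derivation, transformation, standardization, screening.

#' Average gas-exchange triplicates
#'
#' Each plant carries up to three instantaneous readings per gas-exchange
#' variable; the per-plant value is the arithmetic mean of the available
#' readings. A warning is raised for plants with fewer than three readings;
#' plants with none return `NA` (flagged missing-physiology downstream).
#'
#' @param reps Numeric matrix or data frame, one row per plant, up to three
#'   readings per row.
#' @return Numeric vector of per-plant means.
#' @examples
#' average_gas_triplicates(rbind(c(10, 12, 14), c(8, 10, NA)))
#' @export
average_gas_triplicates <- function(reps) {
  m <- as.matrix(reps)
  n_ok <- rowSums(is.finite(m))
  if (any(n_ok > 0 & n_ok < ncol(m))) {
    warn(paste0(sum(n_ok > 0 & n_ok < ncol(m)),
                " plant(s) with fewer than ", ncol(m), " gas-exchange readings;",
                " mean of available readings used"))
  }
  out <- rowMeans(m, na.rm = TRUE)
  out[n_ok == 0L] <- NA_real_
  out
}

#' Instantaneous photosynthetic water-use efficiency
#'
#' WUE = A_sat / TR, in micromol CO2 per mmol H2O. Non-positive transpiration
#' yields `NA` (plant flagged rather than an infinite ratio).
#'
#' @param Asat Light-saturated photosynthesis, micromol CO2 m^-2 s^-1.
#' @param TR Transpiration rate, mmol m^-2 s^-1.
#' @return Numeric vector.
#' @examples
#' compute_wue(7.2, 2.4)
#' @export
compute_wue <- function(Asat, TR) {
  out <- Asat / TR
  out[!is.na(TR) & TR <= 0] <- NA_real_
  out
}

#' Taproot volume from length and diameter
#'
#' Truncated-cone approximation `V = 1/3 * pi * RL * (RD^2 + r^2 + RD * r)`
#' where `r = 0.05` cm is the threshold radius at which taproot length is
#' measured. The formula is evaluated verbatim with `RD` as recorded
#' (converted to cm); set `use_radius = TRUE` to halve `RD` first, as a cone
#' formula expressed in radii would expect. A cylinder alternative
#' (`shape = "cylinder"`, `V = pi * RL * RD^2`) supports sensitivity runs.
#'
#' @param RL Taproot length, cm.
#' @param RD Taproot diameter at the widest point, **cm** (convert from mm
#'   before calling).
#' @param r Threshold radius, cm. Default 0.05.
#' @param shape `"truncated_cone"` (default) or `"cylinder"`.
#' @param use_radius Halve `RD` before evaluation. Default `FALSE`.
#' @return Volume in cm^3. Errors if any `RD <= r` (degenerate geometry).
#' @examples
#' taproot_volume(RL = 10, RD = 1) # ~11.02 cm^3
#' @export
taproot_volume <- function(RL, RD, r = 0.05,
                           shape = c("truncated_cone", "cylinder"),
                           use_radius = FALSE) {
  shape <- match.arg(shape)
  if (use_radius) RD <- RD / 2
  ok <- !is.na(RD) & !is.na(RL)
  if (any(ok & RD < r) && shape == "truncated_cone") {
    abort("taproot diameter must not fall below the tip radius r",
          class = "te_geometry_error")
  }
  if (any(ok & RL <= 0)) {
    abort("taproot length must be positive", class = "te_geometry_error")
  }
  switch(shape,
    truncated_cone = (1 / 3) * pi * RL * (RD^2 + r^2 + RD * r),
    cylinder = pi * RL * RD^2
  )
}

#' Taproot tissue density
#'
#' TTD = taproot dry mass / volume, g cm^-3. Non-positive volume yields `NA`.
#'
#' @param dry_mass Taproot dry mass, g.
#' @param volume Taproot volume, cm^3.
#' @return Numeric vector.
#' @export
compute_ttd <- function(dry_mass, volume) {
  out <- dry_mass / volume
  out[!is.na(volume) & volume <= 0] <- NA_real_
  out
}

apply_transform <- function(x, transform, name = "variable") {
  switch(transform,
    log = {
      if (any(x <= 0, na.rm = TRUE)) {
        bad <- which(x <= 0)
        abort(paste0("non-positive value under log transform of ", name,
                     " at row(s) ", paste(head(bad, 5L), collapse = ", ")))
      }
      log(x)
    },
    sqrt = {
      if (any(x < 0, na.rm = TRUE)) {
        abort(paste0("negative value under sqrt transform of ", name))
      }
      sqrt(x)
    },
    identity = x,
    abort(paste0("unknown transform for ", name))
  )
}

#' Transform and standardize analysis variables
#'
#' Applies the configured transformation (log / sqrt / identity) to each
#' variable, then standardizes the variables listed in `standardize` to zero
#' mean and unit variance. Responses are transformed but *not* standardized,
#' so model coefficients are standardized slopes on the response's
#' transformed scale. The per-variable `(mean, sd)` used for standardization
#' is returned for back-transformation of surfaces to original units; pass a
#' previous `params` to reuse fixed centers and scales.
#'
#' @param data A data frame.
#' @param transform_map Named character vector, variable -> transform.
#'   Variables absent from the map are left untouched.
#' @param standardize Character vector of variables to z-score after
#'   transformation (the model's predictors).
#' @param params Optional tibble from a previous call (columns `variable`,
#'   `mean`, `sd`) fixing the standardization constants.
#' @return A list with `data` (transformed tibble) and `params`.
#' @examples
#' out <- transform_standardize(
#'   tibble::tibble(x = c(1, exp(1), exp(2))),
#'   transform_map = c(x = "log"), standardize = "x"
#' )
#' out$data$x
#' @export
transform_standardize <- function(data, transform_map, standardize = character(),
                                  params = NULL) {
  data <- tibble::as_tibble(data)
  for (v in intersect(names(transform_map), names(data))) {
    data[[v]] <- apply_transform(data[[v]], transform_map[[v]], v)
  }
  prm <- tibble::tibble(variable = character(), mean = numeric(), sd = numeric())
  for (v in standardize) {
    if (!v %in% names(data)) next
    if (!is.null(params) && v %in% params$variable) {
      mu <- params$mean[params$variable == v]
      s <- params$sd[params$variable == v]
    } else {
      mu <- mean(data[[v]], na.rm = TRUE)
      s <- sd(data[[v]], na.rm = TRUE)
    }
    if (!is.finite(s) || s <= 0) {
      abort(paste0("zero-variance column: ", v))
    }
    data[[v]] <- (data[[v]] - mu) / s
    prm <- dplyr::bind_rows(prm, tibble::tibble(variable = v, mean = mu, sd = s))
  }
  list(data = data, params = prm)
}

#' Screen predictor pairs for collinearity
#'
#' Pearson correlations among (transformed, standardized) predictors; pairs
#' with `|r|` strictly above the threshold are flagged. Flagged pairs among
#' the environmental predictors spawn one alternative predictor set per
#' member, so downstream model comparison can arbitrate by AIC (the soil-N
#' versus soil-C branch of the analysis).
#'
#' @param data A data frame of predictors.
#' @param variables Variables to screen.
#' @param threshold Flagging threshold on `|r|` (strict). Default 0.6.
#' @param env_variables Subset of `variables` treated as environmental
#'   predictors when building alternative sets. Default: all.
#' @return A list with `pairs` (tibble: var1, var2, r, flagged) and
#'   `alternative_sets` (list of environmental-variable character vectors;
#'   length 1 when nothing is flagged).
#' @export
screen_collinearity <- function(data, variables, threshold = 0.6,
                                env_variables = variables) {
  cc <- stats::complete.cases(data[variables])
  if (sum(cc) < 3L) abort("need at least 3 complete rows to screen collinearity")
  cm <- cor(data[cc, variables, drop = FALSE])
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- tibble::tibble(
    var1 = variables[idx[, 1L]],
    var2 = variables[idx[, 2L]],
    r = cm[idx],
    flagged = abs(cm[idx]) > threshold
  )
  flagged_env <- dplyr::filter(pairs, .data$flagged,
                               .data$var1 %in% env_variables,
                               .data$var2 %in% env_variables)
  if (nrow(flagged_env) == 0L) {
    alt <- list(env_variables)
  } else {
    # one alternative per member of each flagged pair, holding the rest fixed
    alt <- purrr::map2(
      rep(seq_len(nrow(flagged_env)), each = 2L),
      rep(1:2, nrow(flagged_env)),
      function(i, j) {
        drop_var <- c(flagged_env$var2[i], flagged_env$var1[i])[j]
        setdiff(env_variables, drop_var)
      }
    )
    alt <- unique(alt)
  }
  list(pairs = pairs, alternative_sets = alt)
}

#' Remove outliers on a standardized variable
#'
#' Drops rows whose absolute standardized score on `variable` exceeds
#' `z_threshold`. Intended for the post-standardization screen that removes
#' extreme leaf-area plants.
#'
#' @param data A data frame with `variable` already transformed and
#'   standardized.
#' @param variable Column to screen.
#' @param z_threshold Cutoff on `|z|`. Default 4.
#' @return List with `data` (filtered), `n_removed`, and `removed` (the
#'   dropped rows).
#' @export
remove_outliers <- function(data, variable, z_threshold = 4) {
  z <- data[[variable]]
  drop <- !is.na(z) & abs(z) > z_threshold
  list(
    data = data[!drop, , drop = FALSE],
    n_removed = sum(drop),
    removed = data[drop, , drop = FALSE]
  )
}

#' Preprocess an observation table into an analysis-ready table
#'
#' Runs the full derivation chain: triplicate averaging, WUE, taproot volume
#' and tissue density, leaf mass per area; removal of flagged
#' missing-physiology plants; transformation and standardization of
#' predictors (responses transformed only); collinearity screening; and
#' outlier removal on the configured variable. Counts always reconcile:
#' `n_final = n_input - n_dropped_missing_phys - n_dropped_outliers`.
#'
#' @param data An observation tibble from [read_observations()] or
#'   [simulate_trial()].
#' @param config A [run_config()].
#' @param standardization_params Optional tibble (`variable`, `mean`, `sd`)
#'   fixing the standardization constants (e.g. known population values in
#'   simulation studies) instead of estimating them from the sample.
#' @return A list of class `te_preprocess` with:
#' \describe{
#'   \item{data}{analysis-ready tibble: ids (+ `plot_uid`, `subplot_uid`
#'     nesting factors), standardized predictors `LA, LMA, PD, TTD, SP, SN,
#'     SC, temp, precip`, transformed responses `Asat_t`, `WUE_t`.}
#'   \item{report}{`PreprocessReport`: counts, flagged collinear pairs,
#'     transforms applied, standardization parameters.}
#'   \item{screen}{full [screen_collinearity()] output (alternative
#'     environmental predictor sets).}
#' }
#' @export
preprocess_observations <- function(data, config = run_config(),
                                    standardization_params = NULL) {
  n_input <- nrow(data)
  data <- tibble::as_tibble(data)

  data$Asat <- average_gas_triplicates(data[paste0("Asat_r", 1:3)])
  data$gs <- average_gas_triplicates(data[paste0("gs_r", 1:3)])
  data$TR <- average_gas_triplicates(data[paste0("TR_r", 1:3)])
  data$WUE <- compute_wue(data$Asat, data$TR)
  data$LMA <- data$leaf_dry_mass / data$LA
  vol <- taproot_volume(data$RL, data$RD / 10, shape = config$taproot_shape,
                        use_radius = config$use_radius)
  data$TTD <- compute_ttd(data$taproot_dry_mass, vol)

  miss <- is.na(data$Asat) | is.na(data$WUE)
  n_missing <- sum(miss)
  data <- data[!miss, , drop = FALSE]

  predictors <- c("LA", "LMA", "PD", "TTD", "SP", "SN", "SC", "temp", "precip")
  responses <- c("Asat", "WUE")
  ts <- transform_standardize(
    data,
    transform_map = config$transform_map[predictors],
    standardize = predictors,
    params = standardization_params
  )
  data <- ts$data
  # responses are transformed into new columns but kept on their natural
  # scale too; they are never standardized
  data$Asat_t <- apply_transform(data$Asat, config$transform_map[["Asat"]],
                                 "Asat")
  data$WUE_t <- apply_transform(data$WUE, config$transform_map[["WUE"]],
                                "WUE")

  screen <- screen_collinearity(
    data, variables = c("LA", "LMA", "PD", "TTD", "SP", "SN", "SC"),
    threshold = config$collinearity_threshold,
    env_variables = c("SP", "SN", "SC")
  )

  out <- remove_outliers(data, config$outlier_variable,
                         config$outlier_z_threshold)
  data <- out$data

  data$plot_uid <- factor(paste(data$farm_id, data$variety_id, sep = ":"))
  data$subplot_uid <- factor(paste(data$farm_id, data$variety_id,
                                   data$subplot_id, sep = ":"))

  report <- list(
    n_input = n_input,
    n_dropped_missing_phys = n_missing,
    n_dropped_outliers = out$n_removed,
    n_final = nrow(data),
    flagged_pairs = dplyr::filter(screen$pairs, .data$flagged),
    transforms_applied = config$transform_map[c(predictors, responses)],
    standardization_params = ts$params
  )
  stopifnot(report$n_final ==
              report$n_input - report$n_dropped_missing_phys - report$n_dropped_outliers)

  structure(list(data = data, report = report, screen = screen),
            class = "te_preprocess")
}

#' @export
print.te_preprocess <- function(x, ...) {
  r <- x$report
  cat("<te_preprocess> ", r$n_input, " plants -> ", r$n_final,
      " analysed (", r$n_dropped_missing_phys, " missing physiology, ",
      r$n_dropped_outliers, " outliers)\n", sep = "")
  if (nrow(r$flagged_pairs)) {
    cat("  collinear pairs (|r| > threshold):",
        paste0(r$flagged_pairs$var1, "~", r$flagged_pairs$var2,
               " (r=", round(r$flagged_pairs$r, 2), ")", collapse = ", "), "\n")
  }
  invisible(x)
}
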