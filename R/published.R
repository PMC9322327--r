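# The final published model structures for the two performance currencies,
# used for bookkeeping checks and for refitting on the deposited field data
# when it is available locally.

#' Term graph of a published final model
#'
#' Returns the final fixed-effect term set of the reported best model for
#' each response, as a term graph under treatment coding:
#' \describe{
#'   \item{Asat}{TTD, soil P, variety, TTD x soil P, soil P x variety —
#'     12 fixed-effect parameters with 5 varieties.}
#'   \item{WUE}{LA, PD, soil P, soil N, variety, soil P^2, soil N^2,
#'     LA x soil P, PD x soil P, PD x soil N, LA x variety, PD x variety,
#'     soil P x variety, soil N x variety, LA x soil P x variety,
#'     PD x soil P x variety, PD x soil N x variety — 42 fixed-effect
#'     parameters with 5 varieties.}
#' }
#'
#' @param response `"Asat"` or `"WUE"`.
#' @param n_varieties Number of variety levels. Default 5.
#' @return A `te_term_graph`.
#' @examples
#' count_fixed_effects(published_term_graph("Asat")) # 12
#' count_fixed_effects(published_term_graph("WUE")) # 42
#' @export
published_term_graph <- function(response = c("Asat", "WUE"),
                                 n_varieties = 5L) {
  response <- match.arg(response)
  v <- "variety_id"
  if (response == "Asat") {
    terms <- list(
      "TTD", "SP", v,
      c("TTD", "SP"), c("SP", v)
    )
    sp <- model_spec("Asat_t", traits = "TTD", environments = "SP",
                     variety = v)
  } else {
    terms <- list(
      "LA", "PD", "SP", "SN", v,
      c("SP", "SP"), c("SN", "SN"),
      c("LA", "SP"), c("PD", "SP"), c("PD", "SN"),
      c("LA", v), c("PD", v), c("SP", v), c("SN", v),
      c("LA", "SP", v), c("PD", "SP", v), c("PD", "SN", v)
    )
    sp <- model_spec("WUE_t", traits = c("LA", "PD"),
                     environments = c("SP", "SN"), variety = v)
  }
  graph_from_terms(terms, sp, n_varieties)
}

#' Refit the published final models on a deposited observation table
#'
#' Preprocesses a plant-level observation table and refits the printed final
#' term sets for both responses (conditional on those term sets; the
#' backward-selection path itself is not replayed). Returns the fits plus
#' the headline quantities: marginal/conditional R-squared per response, the
#' TTD x soil P standardized slope in the photosynthesis model, and the
#' per-variety petiole-diameter-by-soil-N slopes in the water-use-efficiency
#' model.
#'
#' @param observations An observation tibble (e.g. from
#'   [read_observations()] on the deposited data reshaped to the canonical
#'   columns).
#' @param config A [run_config()].
#' @return List: `asat_fit`, `wue_fit`, `summary` (one-row tibble),
#'   `pd_sn_slopes` (per-variety tibble).
#' @export
refit_published_models <- function(observations, config = run_config()) {
  prep <- preprocess_observations(observations, config)
  g <- nlevels(factor(prep$data$variety_id))
  asat <- fit_lmm(prep$data, published_term_graph("Asat", g), config = config)
  wue <- fit_lmm(prep$data, published_term_graph("WUE", g), config = config)
  r2a <- r2_nakagawa(asat)
  r2w <- r2_nakagawa(wue)
  ttd_sp <- phi_slope(asat, "TTD", "SP",
                      variety = reference_level(asat))$slope
  pd_sn <- slope_table(wue, traits = "PD", envs = "SN")
  list(
    asat_fit = asat,
    wue_fit = wue,
    summary = tibble::tibble(
      asat_r2_marginal = r2a$r2_marginal,
      asat_r2_conditional = r2a$r2_conditional,
      wue_r2_marginal = r2w$r2_marginal,
      wue_r2_conditional = r2w$r2_conditional,
      ttd_sp_slope = ttd_sp
    ),
    pd_sn_slopes = pd_sn
  )
}
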