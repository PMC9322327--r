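# Fixed-effect term graph of the polynomial-interaction model and its
# marginality (containment) partial order.
#
# A term is a factor multiset: {T}, {T,T} (quadratic), {T,E}, {T,E,V}. The
# containment rule is multiset inclusion, so T < T^2, T < TxE < TxExV, while
# a quadratic is never contained in interactions of its linear term.

#' Declare the model family
#'
#' Describes the response, the trait and environmental predictors (all on
#' their transformed, standardized scale), the variety factor, farm-level
#' covariates, and the random nesting. The implied fixed-effect structure is
#' the polynomial-interaction family: intercept + variety + trait and
#' environment linears and quadratics + covariates + trait x environment +
#' trait x variety + environment x variety + trait x environment x variety.
#' Quadratics do not interact with variety, and environment quadratics do not
#' interact with traits.
#'
#' @param response Response column name (transformed scale), e.g. `"Asat_t"`.
#' @param traits Character vector of trait columns.
#' @param environments Character vector of environmental columns.
#' @param variety Variety factor column, or `NULL` for a no-variety model.
#' @param covariates Farm-level covariate columns entering linearly.
#' @param random_nesting Ordered grouping factors, outermost first.
#' @param include_quadratics,include_three_way Structure switches.
#' @return A list of class `te_model_spec`.
#' @examples
#' sp <- model_spec("Asat_t", traits = c("LA", "LMA", "PD", "TTD"),
#'                  environments = c("SP", "SN"), variety = "variety_id",
#'                  covariates = c("temp", "precip"))
#' @export
model_spec <- function(response,
                       traits = character(),
                       environments = character(),
                       variety = NULL,
                       covariates = character(),
                       random_nesting = c("farm_id", "plot_uid", "subplot_uid"),
                       include_quadratics = TRUE,
                       include_three_way = TRUE) {
  if (!is.null(variety) && variety %in% covariates) {
    abort("the variety factor cannot also be a covariate")
  }
  structure(
    list(
      response = response, traits = traits, environments = environments,
      variety = variety, covariates = covariates,
      random_nesting = random_nesting,
      include_quadratics = include_quadratics,
      include_three_way = include_three_way
    ),
    class = "te_model_spec"
  )
}

new_term <- function(vars, variety = NULL) {
  vars <- sort(vars)
  has_v <- !is.null(variety) && variety %in% vars
  tab <- table(vars)
  label_parts <- character()
  for (v in names(tab)) {
    label_parts <- c(label_parts,
                     if (tab[[v]] == 2L) paste0("I(", v, "^2)") else v)
  }
  # canonical label order: continuous factors first, variety last
  if (has_v) label_parts <- c(setdiff(label_parts, variety), variety)
  tibble::tibble(
    label = if (length(vars)) paste(label_parts, collapse = ":") else "(Intercept)",
    vars = list(vars),
    order = length(unique(vars)),
    has_variety = has_v
  )
}

#' Build the fixed-effect term graph
#'
#' Enumerates the model family's terms for a [model_spec()] and records, per
#' term, its factor multiset, interaction order, whether it involves variety,
#' and its design-matrix column count under treatment coding (`g - 1` dummy
#' columns for each variety-containing term).
#'
#' @param spec A [model_spec()].
#' @param n_varieties Number of variety levels `g` (ignored when the spec has
#'   no variety factor). Must be at least 2 when variety terms are requested.
#' @return A tibble of class `te_term_graph` with attributes `spec` and
#'   `n_varieties`.
#' @examples
#' sp <- model_spec("y", traits = "TTD", environments = "SP")
#' build_term_graph(sp, n_varieties = 0) # the 6-coefficient quintet family
#' @export
build_term_graph <- function(spec, n_varieties = 5L) {
  v <- spec$variety
  if (!is.null(v) && n_varieties < 2L) {
    abort("variety terms requested with fewer than 2 variety levels")
  }
  g <- if (is.null(v)) 0L else as.integer(n_varieties)

  terms <- list(new_term(character()))
  if (!is.null(v)) terms <- c(terms, list(new_term(v, v)))
  for (t in spec$traits) {
    terms <- c(terms, list(new_term(t)))
    if (spec$include_quadratics) terms <- c(terms, list(new_term(c(t, t))))
  }
  for (e in spec$environments) {
    terms <- c(terms, list(new_term(e)))
    if (spec$include_quadratics) terms <- c(terms, list(new_term(c(e, e))))
  }
  for (cv in spec$covariates) terms <- c(terms, list(new_term(cv)))
  for (t in spec$traits) for (e in spec$environments) {
    terms <- c(terms, list(new_term(c(t, e))))
  }
  if (!is.null(v)) {
    for (t in spec$traits) terms <- c(terms, list(new_term(c(t, v), v)))
    for (e in spec$environments) terms <- c(terms, list(new_term(c(e, v), v)))
    if (spec$include_three_way) {
      for (t in spec$traits) for (e in spec$environments) {
        terms <- c(terms, list(new_term(c(t, e, v), v)))
      }
    }
  }
  graph <- dplyr::bind_rows(terms)
  graph$ncols <- ifelse(graph$has_variety, max(g - 1L, 1L), 1L)
  graph$ncols[graph$label == "(Intercept)"] <- 1L
  structure(graph, class = c("te_term_graph", class(tibble::tibble()))) |>
    (\(x) { attr(x, "spec") <- spec; attr(x, "n_varieties") <- g; x })()
}

#' Marginality containment between terms
#'
#' `term_contains(graph, a, b)` is `TRUE` when term `a`'s factor multiset is
#' contained in term `b`'s — i.e. `a` is a lower-order relative of `b` that
#' the principle of marginality protects while `b` is in the model. Under the
#' multiset rule `T` is contained in `T^2`, `TxE` and `TxExV`, but `T^2` is
#' not contained in `TxE`.
#'
#' @param graph A `te_term_graph`.
#' @param a,b Term labels present in the graph.
#' @return Logical scalar.
#' @export
term_contains <- function(graph, a, b) {
  va <- graph$vars[[match_term(graph, a)]]
  vb <- graph$vars[[match_term(graph, b)]]
  multiset_contained(va, vb)
}

multiset_contained <- function(va, vb) {
  if (length(va) > length(vb)) return(FALSE)
  ta <- table(va)
  tb <- table(vb)
  all(names(ta) %in% names(tb)) &&
    all(as.integer(ta) <= as.integer(tb[names(ta)]))
}

match_term <- function(graph, label) {
  i <- match(label, graph$label)
  if (is.na(i)) abort(paste0("term not in graph: ", label))
  i
}

# strict containers of each term; i contains j means vars[[i]] superset
containers_of <- function(graph, label) {
  i <- match_term(graph, label)
  hits <- purrr::map_lgl(seq_len(nrow(graph)), function(j) {
    j != i && multiset_contained(graph$vars[[i]], graph$vars[[j]])
  })
  graph$label[hits]
}

#' Total fixed-effect column count of a term graph
#'
#' @param graph A `te_term_graph`.
#' @return Integer: the number of fixed-effect design columns under treatment
#'   coding (83 for the full 4-trait, 2-environment, 5-variety, 2-covariate
#'   model).
#' @export
count_fixed_effects <- function(graph) {
  sum(graph$ncols)
}

# model formula (fixed + random) for lme4
graph_formula <- function(graph, response = NULL,
                          random_nesting = c("farm_id", "plot_uid", "subplot_uid")) {
  spec <- attr(graph, "spec")
  response <- response %||% spec$response
  fixed <- setdiff(graph$label, "(Intercept)")
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  re <- paste(paste0("(1 | ", random_nesting, ")"), collapse = " + ")
  as.formula(paste(response, "~", rhs, "+", re), env = globalenv())
}

# one-sided when response is NULL (design expansion without the response)
graph_fixed_formula <- function(graph, response = NULL) {
  fixed <- setdiff(graph$label, "(Intercept)")
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  as.formula(paste(response %||% "", "~", rhs), env = globalenv())
}

# canonical key for matching R's term.labels (which sorts interactions by
# degree and preserves within-degree order) back to graph labels
canonical_key <- function(label) {
  purrr::map_chr(strsplit(label, ":", fixed = TRUE),
                 function(p) paste(sort(p), collapse = ":"))
}

# drop a term from the graph, preserving attributes
graph_drop_term <- function(graph, label) {
  i <- match_term(graph, label)
  out <- graph[-i, , drop = FALSE]
  attr(out, "spec") <- attr(graph, "spec")
  attr(out, "n_varieties") <- attr(graph, "n_varieties")
  class(out) <- class(graph)
  out
}

# build a graph from an explicit list of terms (character vectors of factor
# names, possibly with repeats for quadratics); used for published term sets
graph_from_terms <- function(term_list, spec, n_varieties) {
  v <- spec$variety
  terms <- c(list(new_term(character())),
             purrr::map(term_list, function(tv) new_term(tv, v)))
  graph <- dplyr::bind_rows(terms)
  g <- if (is.null(v)) 0L else as.integer(n_varieties)
  graph$ncols <- ifelse(graph$has_variety, max(g - 1L, 1L), 1L)
  graph$ncols[graph$label == "(Intercept)"] <- 1L
  structure(graph, class = c("te_term_graph", class(tibble::tibble()))) |>
    (\(x) { attr(x, "spec") <- spec; attr(x, "n_varieties") <- g; x })()
}

#' Serialize a term graph to JSON
#'
#' @param graph A `te_term_graph`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
term_graph_json <- function(graph, path = NULL) {
  payload <- list(
    terms = purrr::pmap(
      list(graph$label, graph$vars, graph$order, graph$ncols),
      function(l, v, o, k) list(label = l, factors = v, order = o, columns = k)
    ),
    n_varieties = attr(graph, "n_varieties"),
    total_columns = count_fixed_effects(graph)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
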