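# Design matrices: fixed-effect expansion of a term graph and random-effect
# indicator matrices for the nested grouping factors.

#' Expand the fixed-effect design matrix
#'
#' Builds the treatment-coded design matrix for a term graph and a column map
#' linking each column back to its term and (for variety-containing terms)
#' the variety level, which slope extraction uses.
#'
#' @param data Analysis-ready tibble (predictors standardized).
#' @param graph A `te_term_graph`.
#' @return List with `X` (matrix) and `column_map` (tibble: column, term,
#'   variety_level). Errors on rank deficiency, naming the aliased columns.
#' @export
expand_design <- function(data, graph, check_rank = TRUE) {
  f <- graph_fixed_formula(graph, response = NULL)
  tt <- terms(f, keep.order = FALSE)
  X <- model.matrix(tt, data = data)
  if (check_rank) {
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
      abort(paste0("rank-deficient design; aliased column(s): ",
                   paste(aliased, collapse = ", ")))
    }
  }
  column_map <- design_column_map(X, tt, graph)
  cn <- canonical_colnames(column_map, graph)
  colnames(X) <- cn
  column_map$column <- cn
  list(X = X, column_map = column_map)
}

design_column_map <- function(X, tt, graph) {
  assign <- attr(X, "assign")
  labels <- attr(tt, "term.labels")
  key <- canonical_key(graph$label)
  spec <- attr(graph, "spec")
  v <- spec$variety
  term_of_col <- character(ncol(X))
  level_of_col <- rep(NA_character_, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (assign[j] == 0L) {
      term_of_col[j] <- "(Intercept)"
      next
    }
    lab <- labels[assign[j]]
    i <- match(canonical_key(lab), key)
    if (is.na(i)) abort(paste0("design column term not in graph: ", lab))
    term_of_col[j] <- graph$label[i]
    if (!is.null(v) && graph$has_variety[i]) {
      cn <- strsplit(colnames(X)[j], ":", fixed = TRUE)[[1]]
      vpart <- cn[startsWith(cn, v)]
      if (length(vpart)) level_of_col[j] <- sub(paste0("^", v), "", vpart[1L])
    }
  }
  tibble::tibble(
    column = colnames(X),
    index = seq_len(ncol(X)),
    term = term_of_col,
    variety_level = level_of_col
  )
}

# stable coefficient names in graph-label order: the variety factor name is
# suffixed with its level (R's own interaction column names reorder variables
# by first appearance in the formula, which is fragile to match against)
canonical_colnames <- function(column_map, graph) {
  v <- attr(graph, "spec")$variety
  purrr::pmap_chr(column_map, function(column, index, term, variety_level) {
    if (term == "(Intercept)") return("(Intercept)")
    if (is.na(variety_level) || is.null(v)) return(term)
    sub(v, paste0(v, variety_level), term, fixed = TRUE)
  })
}

#' Random-effect indicator matrices for the nested design
#'
#' Returns one 0/1 indicator matrix per grouping factor (each row sums to 1),
#' after checking that the nesting is intact: every level of an inner factor
#' must sit under exactly one level of each outer factor. Degenerate
#' configurations (a single farm, or one plant per subplot) are allowed with
#' a warning, since they confound a variance component with the intercept or
#' the residual.
#'
#' @param data Analysis-ready tibble.
#' @param nesting Ordered grouping factor columns, outermost first.
#' @return Named list of sparse indicator matrices (`Matrix::sparseMatrix`).
#' @export
random_design <- function(data, nesting = c("farm_id", "plot_uid", "subplot_uid")) {
  out <- list()
  for (i in seq_along(nesting)) {
    gname <- nesting[i]
    gfac <- factor(data[[gname]])
    if (i > 1L) {
      outer_fac <- data[[nesting[i - 1L]]]
      tab <- tapply(as.character(outer_fac), gfac,
                    function(x) length(unique(x)))
      if (any(tab > 1L)) {
        abort(paste0("broken nesting: level(s) of ", gname,
                     " appear under multiple levels of ", nesting[i - 1L]),
              class = "te_integrity_error")
      }
    }
    if (nlevels(gfac) == 1L) {
      warn(paste0(gname, " has a single level; its variance component is ",
                  "confounded with the intercept"))
    }
    if (nlevels(gfac) == nrow(data)) {
      warn(paste0(gname, " indexes every row; its variance component is ",
                  "confounded with the residual"))
    }
    Z <- Matrix::sparseMatrix(
      i = seq_len(nrow(data)), j = as.integer(gfac), x = 1,
      dims = c(nrow(data), nlevels(gfac)),
      dimnames = list(NULL, levels(gfac))
    )
    out[[gname]] <- Z
  }
  out
}
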