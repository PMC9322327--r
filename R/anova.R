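# Type-II marginality ANOVA: each term is tested adjusted for every term
# that does not contain it, ignoring its higher-order relatives.
#
# For term A, partition the design columns into X1 (terms not containing A),
# X2 (A itself) and X3 (terms strictly containing A). With M1 the residual
# projector off X1, the type-II hypothesis in the full parameterization is
#   L = [ 0 | I | (X2'M1X2)^{-1} X2'M1X3 ],
# which reproduces the coefficient of A in the model that drops A's
# relatives: in orthogonal balanced designs it reduces to L = [0 | I | 0]
# and type-II sums of squares equal sequential (type-I) sums of squares.

type2_contrast <- function(obj, term) {
  cm <- obj$column_map
  graph <- obj$graph
  i2 <- cm$index[cm$term == term]
  if (!length(i2)) abort(paste0("term not in fitted model: ", term))
  relatives <- containers_of(graph, term)
  i3 <- cm$index[cm$term %in% relatives]
  i1 <- setdiff(cm$index, c(i2, i3))
  k <- obj$k_fixed
  L <- matrix(0, length(i2), k)
  L[, i2] <- diag(length(i2))
  if (length(i3)) {
    X <- obj$X
    X1 <- X[, i1, drop = FALSE]
    X2 <- X[, i2, drop = FALSE]
    X3 <- X[, i3, drop = FALSE]
    q1 <- qr(X1)
    M1X2 <- X2 - qr.fitted(q1, X2)
    M1X3 <- X3 - qr.fitted(q1, X3)
    G <- crossprod(X2, M1X2)
    if (rcond_safe(G) < 1e-12) {
      abort(paste0("aliasing within the type-II contrast for term ", term))
    }
    L[, i3] <- solve(G, crossprod(X2, M1X3))
  }
  L
}

#' Type-II analysis-of-variance table
#'
#' Per-term F-tests under the principle of marginality: each term is tested
#' after all terms that do not contain it, ignoring its higher-order
#' relatives. Denominator degrees of freedom follow the fit's configured
#' method (Kenward-Roger by default). Sum-of-squares columns are
#' presentational reconstructions `SS = F * ndf * sigma2_residual`,
#' consistent with the F statistic and the residual variance.
#'
#' @param obj A `te_lmm`.
#' @param method Degrees-of-freedom method override (see [f_test()]).
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble of class `te_anova`: term, sum_sq, mean_sq, ndf, ddf,
#'   statistic, p_value, significant.
#' @export
type2_anova <- function(obj, method = NULL, alpha = 0.05) {
  terms <- setdiff(obj$graph$label, "(Intercept)")
  rows <- purrr::map(terms, function(tm) {
    L <- type2_contrast(obj, tm)
    ft <- f_test(obj, L, method = method)
    tibble::tibble(
      term = tm,
      sum_sq = ft$statistic * ft$ndf * obj$sigma2,
      mean_sq = ft$statistic * obj$sigma2,
      ndf = ft$ndf, ddf = ft$ddf,
      statistic = ft$statistic, p_value = ft$p_value
    )
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_value < alpha
  class(out) <- c("te_anova", class(out))
  out
}

#' @export
print.te_anova <- function(x, ...) {
  cat("Type-II analysis of variance (marginality-respecting)\n")
  df <- as.data.frame(x)
  df$sum_sq <- signif(df$sum_sq, 4)
  df$mean_sq <- signif(df$mean_sq, 4)
  df$ddf <- round(df$ddf, 1)
  df$statistic <- signif(df$statistic, 4)
  df$p_value <- signif(df$p_value, 4)
  names(df) <- c("term", "Sum Sq", "Mean Sq", "NumDF", "DenDF", "F", "p", "sig")
  df$sig <- ifelse(df$sig, "*", "")
  print(df, row.names = FALSE)
  invisible(x)
}
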