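# Kenward-Roger small-sample adjustment for the nested-intercepts model.
#
# The covariance structure is linear in the variance parameters,
#   V = sigma2 * I + sum_r theta_r Z_r Z_r',
# so all second-derivative terms of V vanish and the adjustment reduces to
# first-order quantities. Solves with V use the Woodbury identity
#   V^{-1} = s^{-1} I - s^{-2} Z K Z',  K = (D^{-1} + s^{-1} Z'Z)^{-1},
# (s = sigma2, D = diag of theta per column), which keeps every object dense
# but small: K is m x m with m = total random-effect levels.
#
# Notation below follows the standard small-sample adjustment literature:
# Phi = (X'V^{-1}X)^{-1}; P_i = X'V^{-1} dV_i V^{-1} X;
# Q_ij = X'V^{-1} dV_i V^{-1} dV_j V^{-1} X; W = inverse expected REML
# information of the variance parameters; the adjusted covariance is
# Phi_A = Phi + 2 Phi [ sum_ij W_ij (Q_ij - P_i Phi P_j) ] Phi.

kr_core <- function(X, Zlist, theta, sigma2) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  R <- length(Zlist)
  Zlist <- purrr::map(Zlist, function(Z) as(Z, "CsparseMatrix"))

  dvec <- unlist(purrr::map2(theta, Zlist, function(th, Z) rep(th, ncol(Z))))
  Ztil <- if (R > 0) do.call(cbind, unname(Zlist)) else NULL
  act <- which(dvec > 1e-12 * max(sigma2, dvec, 1e-300))

  if (length(act)) {
    Za <- Ztil[, act, drop = FALSE]
    Ma <- as.matrix(Matrix::crossprod(Za))
    Kmat <- solve(diag(1 / dvec[act], length(act)) + Ma / sigma2)
    vsolve <- function(B) {
      B <- as.matrix(B)
      (B - as.matrix(Za %*% (Kmat %*% as.matrix(Matrix::crossprod(Za, B)))) /
          sigma2) / sigma2
    }
  } else {
    Ma <- NULL
    Kmat <- NULL
    vsolve <- function(B) as.matrix(B) / sigma2
  }

  Wx <- vsolve(X)
  XtViX <- crossprod(X, Wx)
  Phi <- solve((XtViX + t(XtViX)) / 2)

  # per-parameter quantities; component R+1 is the residual (dV = I)
  A <- vector("list", R + 1L)
  Tm <- vector("list", R + 1L) # Z_i' Wx (or Wx for residual)
  Uz <- vector("list", R) # V^{-1} Z_i, dense
  for (i in seq_len(R)) {
    Zi <- Zlist[[i]]
    Tm[[i]] <- as.matrix(Matrix::crossprod(Zi, Wx))
    A[[i]] <- as.matrix(Zi %*% Tm[[i]])
    Uz[[i]] <- vsolve(Zi)
  }
  A[[R + 1L]] <- Wx
  S <- purrr::map(A, vsolve)

  P <- purrr::map(A, function(Ai) {
    M <- crossprod(Wx, Ai)
    (M + t(M)) / 2
  })
  Q <- matrix(list(), R + 1L, R + 1L)
  for (i in seq_len(R + 1L)) for (j in seq_len(R + 1L)) {
    Q[[i, j]] <- crossprod(A[[i]], S[[j]])
  }

  # expected REML information of (theta_1..theta_R, sigma2):
  # I_ij = tr(P dV_i P dV_j) / 2 with P = V^{-1} - Wx Phi Wx'
  info <- matrix(0, R + 1L, R + 1L)
  for (i in seq_len(R)) {
    for (j in i:R) {
      Bij <- as.matrix(Matrix::crossprod(Zlist[[i]], Uz[[j]])) -
        Tm[[i]] %*% Phi %*% t(Tm[[j]])
      info[i, j] <- info[j, i] <- sum(Bij^2) / 2
    }
    PZi <- Uz[[i]] - Wx %*% (Phi %*% t(Tm[[i]]))
    info[i, R + 1L] <- info[R + 1L, i] <- sum(PZi^2) / 2
  }
  if (length(act)) {
    KM <- Kmat %*% Ma
    trVinv2 <- (n - 2 * sum(diag(KM)) / sigma2 +
                  sum(KM * t(KM)) / sigma2^2) / sigma2^2
  } else {
    trVinv2 <- n / sigma2^2
  }
  trVWPW <- sum(Phi * crossprod(Wx, S[[R + 1L]]))
  Nw <- Phi %*% crossprod(Wx)
  info[R + 1L, R + 1L] <- (trVinv2 - 2 * trVWPW + sum(Nw * t(Nw))) / 2

  Wg <- tryCatch(solve(info), error = function(e) pseudo_inverse(info))

  Mid <- matrix(0, k, k)
  for (i in seq_len(R + 1L)) for (j in seq_len(R + 1L)) {
    if (Wg[i, j] == 0) next
    Mid <- Mid + Wg[i, j] * (Q[[i, j]] - P[[i]] %*% Phi %*% P[[j]])
  }
  Phi_adj <- Phi + 2 * Phi %*% Mid %*% Phi
  Phi_adj <- (Phi_adj + t(Phi_adj)) / 2
  if (any(diag(Phi_adj) < 0)) {
    warn("negative adjusted variance; falling back to unadjusted covariance")
    Phi_adj <- Phi
  }

  H <- purrr::map(P, function(Pi) Phi %*% Pi %*% Phi)

  list(
    Phi = structure(Phi, dimnames = list(colnames(X), colnames(X))),
    Phi_adj = structure(Phi_adj, dimnames = list(colnames(X), colnames(X))),
    W = Wg, H = H, P = P, n = n, k = k, R = R, sigma2 = sigma2, theta = theta
  )
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# the scaled F statistic and its approximate denominator df
kr_f_test <- function(core, L, beta) {
  if (is.vector(L)) L <- matrix(L, nrow = 1L)
  l <- nrow(L)
  Phi <- core$Phi
  C0 <- solve(L %*% Phi %*% t(L))
  np <- core$R + 1L

  trM <- numeric(np)
  Gl <- vector("list", np)
  for (i in seq_len(np)) {
    Gl[[i]] <- L %*% core$H[[i]] %*% t(L)
    trM[i] <- sum(C0 * t(Gl[[i]]))
  }
  A1 <- 0
  A2 <- 0
  for (i in seq_len(np)) for (j in seq_len(np)) {
    w <- core$W[i, j]
    if (w == 0) next
    A1 <- A1 + w * trM[i] * trM[j]
    A2 <- A2 + w * sum((C0 %*% Gl[[i]]) * t(C0 %*% Gl[[j]]))
  }

  B <- (A1 + 6 * A2) / (2 * l)
  g <- ((l + 1) * A1 - (l + 4) * A2) / ((l + 2) * A2)
  c1 <- g / (3 * l + 2 * (1 - g))
  c2 <- (l - g) / (3 * l + 2 * (1 - g))
  c3 <- (l + 2 - g) / (3 * l + 2 * (1 - g))
  Estar <- 1 / (1 - A2 / l)
  Vstar <- (2 / l) * (1 + c1 * B) / ((1 - c2 * B)^2 * (1 - c3 * B))
  rho <- Vstar / (2 * Estar^2)
  m <- 4 + (l + 2) / (l * rho - 1)
  lambda <- m / (Estar * (m - 2))
  if (!is.finite(m) || m <= 2 || A2 <= 0) {
    m <- core$n - core$k
    lambda <- 1
  }

  CA <- L %*% core$Phi_adj %*% t(L)
  Lb <- L %*% beta
  Fraw <- drop(crossprod(Lb, solve(CA, Lb))) / l
  Fstat <- lambda * Fraw
  tibble::tibble(
    statistic = Fstat, ndf = l, ddf = m,
    p_value = pf(Fstat, l, m, lower.tail = FALSE),
    method = "kenward_roger"
  )
}

# per-contrast KR denominator df (1-df case of the above)
kr_contrast_df <- function(core, cvec) {
  kr_f_test(core, matrix(cvec, nrow = 1L), rep(0, core$k))$ddf
}

# Satterthwaite df for a single linear combination:
# df = 2 c(theta)^2 / Var(c(theta)), c(theta) = c' Phi c, by the delta method
sat_df <- function(core, cvec) {
  cv <- drop(crossprod(cvec, core$Phi %*% cvec))
  grad <- purrr::map_dbl(core$H, function(Hi) drop(crossprod(cvec, Hi %*% cvec)))
  denom <- drop(crossprod(grad, core$W %*% grad))
  if (denom <= 0) return(core$n - core$k)
  2 * cv^2 / denom
}

sat_f_test <- function(core, cvec, beta) {
  est <- drop(crossprod(cvec, beta))
  se <- sqrt(drop(crossprod(cvec, core$Phi_adj %*% cvec)))
  df <- sat_df(core, cvec)
  Fstat <- (est / se)^2
  tibble::tibble(
    statistic = Fstat, ndf = 1L, ddf = df,
    p_value = pf(Fstat, 1, df, lower.tail = FALSE),
    method = "satterthwaite"
  )
}
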