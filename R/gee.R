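## Linear GEE with AR(1) working correlation, fitted by iterated
## (generalized) estimating equations with a moment update for the working
## autocorrelation, and a Liang-Zeger robust sandwich covariance.
## The working correlation for observations t, m within a state is
## R[t, m] = rho^|t - m|.

#' Fit a linear GEE with AR(1) working correlation
#'
#' Iterates between a generalized-least-squares solve for the coefficients
#' given the working correlation and a moment (lag-1 Pearson residual)
#' update of the autocorrelation parameter, until the coefficient and rho
#' changes fall below `tol` or `maxit` iterations are reached. Analytic
#' weights (e.g. state population) enter the working covariance as
#' `V_i = phi * diag(1/w)^{1/2} R(rho) diag(1/w)^{1/2}`. The reported
#' covariance is the robust sandwich
#' `M^{-1} (sum_i X_i' V_i^{-1} e_i e_i' V_i^{-1} X_i) M^{-1}` with
#' `M = sum_i X_i' V_i^{-1} X_i`.
#'
#' @param formula model formula (identity link).
#' @param data data.frame.
#' @param id cluster (state) identifier, one per row.
#' @param weights optional positive analytic weights.
#' @param rho optional fixed working autocorrelation; when `NULL`
#'   (default) it is estimated by the moment update each iteration.
#' @param maxit,tol iteration cap (default 100) and convergence tolerance.
#' @return A `gee_fit` list: `coefficients`, `vcov_robust`, `rho`, `phi`,
#'   `converged`, `iterations`, `n`, `n_clusters`.
#' @export
fit_gee_ar1 <- function(formula, data, id, weights = NULL, rho = NULL,
                        maxit = 100, tol = 1e-8) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(mf), mf)
  n <- length(y)
  p <- ncol(X)
  if (length(id) != nrow(data)) stop_arg("id must have one entry per row")
  id <- factor(id)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w <= 0)) stop_arg("weights must be positive")

  idx_by <- split(seq_len(n), id)
  fixed_rho <- !is.null(rho)
  rho_hat <- if (fixed_rho) rho else 0

  ## initial weighted OLS
  beta <- stats::lm.wfit(X, y, w)$coefficients
  if (anyNA(beta)) stop_arg("singular design in GEE fit")

  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    e <- y - drop(X %*% beta)
    phi <- sum(w * e^2) / (n - p)
    r <- e * sqrt(w) / sqrt(phi)
    if (!fixed_rho) {
      num <- 0; npairs <- 0
      for (ix in idx_by) {
        ri <- r[ix]
        if (length(ri) > 1) {
          num <- num + sum(ri[-length(ri)] * ri[-1])
          npairs <- npairs + length(ri) - 1
        }
      }
      rho_new <- if (npairs > p) num / (npairs - p) else num / max(npairs, 1)
      rho_new <- max(min(rho_new, 0.99), -0.99)
    } else {
      rho_new <- rho_hat
    }

    M <- matrix(0, p, p)
    u <- numeric(p)
    for (ix in idx_by) {
      ni <- length(ix)
      R <- rho_new^abs(outer(seq_len(ni), seq_len(ni), "-"))
      sw <- sqrt(w[ix])
      ## V^{-1} up to 1/phi (phi cancels in the solve)
      Vinv <- (sw %o% sw) * solve(R)
      Xi <- X[ix, , drop = FALSE]
      M <- M + crossprod(Xi, Vinv %*% Xi)
      u <- u + crossprod(Xi, Vinv %*% y[ix])
    }
    beta_new <- drop(solve(M, u))
    delta <- max(abs(beta_new - beta), abs(rho_new - rho_hat))
    beta <- beta_new
    rho_hat <- rho_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
  }

  e <- y - drop(X %*% beta)
  phi <- sum(w * e^2) / (n - p)
  M <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (ix in idx_by) {
    ni <- length(ix)
    R <- rho_hat^abs(outer(seq_len(ni), seq_len(ni), "-"))
    sw <- sqrt(w[ix])
    Vinv <- (sw %o% sw) * solve(R) / phi
    Xi <- X[ix, , drop = FALSE]
    M <- M + crossprod(Xi, Vinv %*% Xi)
    s_i <- crossprod(Xi, Vinv %*% e[ix])
    B <- B + s_i %*% t(s_i)
  }
  Minv <- solve(M)
  V <- Minv %*% B %*% Minv
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(
    coefficients = beta, vcov_robust = V, rho = rho_hat, phi = phi,
    converged = converged, iterations = iter, n = n,
    n_clusters = length(idx_by)
  ), class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("linear AR(1) GEE: n = %d, clusters = %d, rho = %.3f, %s after %d iter\n",
              x$n, x$n_clusters, x$rho,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(x$coefficients)
  invisible(x)
}
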