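#' Raw varimax rotation by pairwise planar rotations
#'
#' Rotates an orthonormal loading matrix to maximize the varimax criterion
#' (sum over columns of the variance of squared loadings), the classical
#' "simple structure" objective. Uses Kaiser's pairwise planar rotations
#' without row (Kaiser) normalization: each sweep visits every column pair
#' and applies the angle that exactly maximizes the pair's contribution, so
#' the criterion is non-decreasing across sweeps by construction.
#'
#' @param loadings Numeric matrix (variables x K) with orthonormal columns.
#' @param tol Convergence tolerance: a sweep that improves the criterion
#'   by less than `tol * max(criterion, 1e-12)` (relative, so the test is
#'   invariant to the criterion's scale, which shrinks as 1/n_genes^2)
#'   ends the iteration.
#' @param max_iter Maximum number of sweeps; if reached without
#'   convergence a warning is issued and the best iterate is returned with
#'   `converged = FALSE`.
#' @return A list with `loadings` (rotated matrix), `rotation` (K x K
#'   orthogonal matrix such that `loadings_in %*% rotation == loadings`),
#'   `iterations`, `converged`, and `criterion` (final objective value).
#' @examples
#' L <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
#' r <- varimax_rotate(L)
#' max(abs(crossprod(r$rotation) - diag(4))) # orthogonal
#' @export
varimax_rotate <- function(loadings, tol = 1e-6, max_iter = 1000) {
  L <- as.matrix(loadings)
  K <- ncol(L)
  n <- nrow(L)
  if (K < 1) abort("loadings must have at least one column")
  gram <- crossprod(L)
  if (max(abs(gram - diag(K))) > 1e-8) {
    abort("loading columns must be orthonormal")
  }
  R <- diag(K)
  if (K == 1) {
    return(list(loadings = L, rotation = R, iterations = 0L,
                converged = TRUE, criterion = varimax_criterion(L)))
  }
  crit <- varimax_criterion(L)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (p in 1:(K - 1)) {
      for (q in (p + 1):K) {
        x <- L[, p]; y <- L[, q]
        u <- x * x - y * y
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u * u - v * v)
        D <- 2 * sum(u * v)
        num <- D - 2 * A * B / n
        den <- C - (A * A - B * B) / n
        if (num == 0 && den == 0) next
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-12) next
        cs <- cos(phi); sn <- sin(phi)
        L[, p] <- cs * x + sn * y
        L[, q] <- -sn * x + cs * y
        rp <- R[, p]; rq <- R[, q]
        R[, p] <- cs * rp + sn * rq
        R[, q] <- -sn * rp + cs * rq
      }
    }
    new_crit <- varimax_criterion(L)
    if (new_crit - crit < tol * max(new_crit, 1e-12)) {
      crit <- new_crit
      converged <- TRUE
      break
    }
    crit <- new_crit
  }
  if (!converged) {
    warn(sprintf("varimax did not converge in %d sweeps", max_iter))
  }
  list(loadings = L, rotation = R, iterations = iter,
       converged = converged, criterion = crit)
}

#' Varimax criterion of a loading matrix
#'
#' Sum over columns of the (population) variance of the squared loadings.
#'
#' @param loadings Numeric matrix (variables x K).
#' @return A single number; larger means simpler structure.
#' @export
varimax_criterion <- function(loadings) {
  L2 <- loadings^2
  sum(colMeans(L2^2) - colMeans(L2)^2)
}
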