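#' Nonnegative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0`. This is the constrained
#' solver behind both background fitting and the biomolecular component
#' decomposition. At the solution the Karush-Kuhn-Tucker conditions hold:
#' the residual is orthogonal to every active (positive-weight) column, and
#' the gradient is nonnegative on the zero set.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector (length m).
#' @param tol Dual-feasibility tolerance; default scales with the design.
#' @param free Optional logical vector of length n marking columns whose
#'   coefficients are unconstrained in sign (used for the smooth baseline);
#'   implemented by splitting each free column into a +/- pair.
#' @return List with `x` (coefficients), `fitted`, `residual`,
#'   `deviance` (residual sum of squares).
#' @export
nnls_solve <- function(A, b, tol = NULL, free = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  if (!is.null(free) && any(free)) {
    stopifnot(length(free) == n)
    A2 <- cbind(A, -A[, free, drop = FALSE])
    res <- nnls_solve(A2, b, tol = tol)
    x <- res$x[seq_len(n)]
    x[free] <- x[free] - res$x[-seq_len(n)]
    return(list(x = x, fitted = drop(A %*% x),
                residual = b - drop(A %*% x),
                deviance = sum((b - drop(A %*% x))^2)))
  }
  if (is.null(tol)) {
    tol <- 10 * .Machine$double.eps * max(colSums(abs(A))) * max(dim(A))
  }
  x <- numeric(n)
  passive <- rep(FALSE, n)
  resid <- b
  w <- drop(crossprod(A, resid))
  iter <- 0L
  max_iter <- 3L * n + 30L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z > 0)) {
        x[] <- 0
        x[passive] <- z
        break
      }
      # step back along the segment to the feasible boundary
      xp <- x[passive]
      neg <- z <= 0
      alpha <- min(xp[neg] / (xp[neg] - z[neg]))
      xp <- xp + alpha * (z - xp)
      x[] <- 0
      x[passive] <- xp
      passive[passive] <- xp > tol
      x[!passive] <- 0
      if (!any(passive)) break
    }
    resid <- b - drop(A %*% x)
    w <- drop(crossprod(A, resid))
  }
  list(x = x, fitted = drop(A %*% x), residual = b - drop(A %*% x),
       deviance = sum((b - drop(A %*% x))^2))
}
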