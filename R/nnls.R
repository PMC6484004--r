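#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0` by the classical
#' Lawson-Hanson algorithm. Handles rank-deficient and underdetermined
#' systems (the passive-set subproblem is solved by a pivoted QR least
#' squares). No pre-installed R package in this environment provides NNLS,
#' and the weight optimization it serves is central to the package, so the
#' solver lives here; tests cross-check it against an independent
#' quadratic-programming oracle.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric response vector (length m).
#' @param tol dual-feasibility tolerance; default scales with the problem.
#' @param max_iter iteration cap.
#' @return list with `x` (solution, length n), `fitted` (`A %*% x`),
#'   `residual` (`b - fitted`), and `deviance` (residual sum of squares).
#' @export
nnls_fit <- function(A, b, tol = NULL, max_iter = 10 * ncol(A) + 50) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (length(b) != m) stopf("length(b) (%d) != nrow(A) (%d)", length(b), m)
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(crossprod(A, b)), 1) * max(m, n))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))          # gradient of the fit at x = 0
  iter <- 0L
  ls_solve <- function(cols) {
    z <- qr.coef(qr(A[, cols, drop = FALSE]), b)
    z[is.na(z)] <- 0
    z
  }
  repeat {
    w <- drop(crossprod(A, b - A %*% x))
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stopf("nnls_fit failed to converge in %d iterations", max_iter)
      z <- numeric(n)
      z[passive] <- ls_solve(passive)
      if (all(z[passive] > 0)) { x <- z; break }
      neg <- passive & z <= 0
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  fitted <- drop(A %*% x)
  list(x = x, fitted = fitted, residual = b - fitted,
       deviance = sum((b - fitted)^2))
}
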