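#' Non-negative least squares by the Lawson-Hanson active-set algorithm
#'
#' Minimizes \eqn{\|Ax - b\|^2} subject to \eqn{x \ge 0}. At return the
#' Karush-Kuhn-Tucker conditions hold: the dual (gradient) component of
#' every positive coefficient is ~0 (|w| <= `tol`) and of every zero
#' coefficient is <= `tol`.
#'
#' The algorithm maintains a passive set of coefficients allowed to be
#' positive. Each outer iteration moves into the passive set the zero
#' coefficient with the largest positive dual component (ties broken toward
#' the lowest column index, so the solve is deterministic), then repeatedly
#' solves the unconstrained least-squares subproblem on the passive set,
#' stepping back to the feasible boundary whenever a passive coefficient
#' would go negative.
#'
#' @param A Numeric matrix (rows = observations/markers, columns =
#'   components). Fewer rows than columns triggers a warning.
#' @param b Numeric target vector of length `nrow(A)`.
#' @param tol Tolerance on the dual vector (default 1e-10).
#' @param max_iter Cap on outer iterations (default `3 * ncol(A)`).
#' @return An object of class `nnls_fit`: list with elements `x`
#'   (coefficients, named after `A`'s columns), `fitted`, `residual_ss`,
#'   `dual` (gradient at the solution) and `iterations`.
#' @examples
#' A <- cbind(feed = c(1.18, 1.59, 2.58), alfalfa = c(8.12, 44.3, 289))
#' nnls(A, A %*% c(0.7, 0.3))$x
#' @export
nnls <- function(A, b, tol = 1e-10, max_iter = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  b <- as.numeric(b)
  if (any(!is.finite(A)) || any(!is.finite(b)))
    stop_validation("nnls: A and b must be finite")
  m <- nrow(A); n <- ncol(A)
  if (n < 1) stop_validation("nnls: A must have at least one column")
  if (length(b) != m) stop_validation("nnls: length(b) != nrow(A)")
  if (m < n)
    warning("nnls: fewer rows than columns; solution may be non-unique")
  if (is.null(max_iter)) max_iter <- 3L * n

  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L

  ls_passive <- function(passive) {
    z <- numeric(n)
    fit <- qr(A[, passive, drop = FALSE])
    if (fit$rank < sum(passive))
      stop_numerical("nnls: rank-deficient design on the active set",
                     data = list(x = x, passive = passive))
    z[passive] <- qr.coef(fit, b)
    z
  }

  while (!all(passive) && max(w[!passive]) > tol) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop_numerical(sprintf("nnls: no convergence within %d iterations",
                             max_iter),
                     data = list(x = x, dual = w))
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]   # first max = lowest index on ties
    passive[j] <- TRUE
    repeat {
      z <- ls_passive(passive)
      if (all(z[passive] > 0)) {
        x <- z
        break
      }
      neg <- passive & (z <= 0)
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio[!is.finite(ratio)] <- 0  # x = z = 0: step straight to the boundary
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      x[x < tol & passive] <- 0
      passive <- passive & (x > 0)
      if (!any(passive)) {
        x[] <- 0
        break
      }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }

  resid <- b - drop(A %*% x)
  names(x) <- colnames(A)
  structure(list(x = x, fitted = drop(A %*% x),
                 residual_ss = sum(resid^2), dual = w, iterations = iter),
            class = "nnls_fit")
}

#' @export
print.nnls_fit <- function(x, ...) {
  cat("<nnls_fit>\n  coefficients:\n")
  print(signif(x$x, 6))
  cat(sprintf("  residual sum of squares: %.6g (%d iterations)\n",
              x$residual_ss, x$iterations))
  invisible(x)
}
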