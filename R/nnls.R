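#' Weighted non-negative least squares
#'
#' Solves `argmin_{c >= 0} sum_g w_g (y_g - sum_k A_gk c_k)^2` by the
#' Lawson-Hanson active-set algorithm on the row-rescaled problem
#' (`sqrt(w) A`, `sqrt(w) y`). The active-set method terminates at an
#' exact KKT point, so the solution is deterministic -- there is no
#' step-size or initialization to tune.
#'
#' @param design genes x K matrix; no all-zero column.
#' @param response genes vector.
#' @param weights non-negative per-gene weights (default all 1); scaling
#'   all weights by a positive constant leaves the solution unchanged.
#' @return Named K-vector of non-negative coefficients.
#' @export
weighted_nnls <- function(design, response, weights = NULL) {
  A <- as.matrix(design)
  y <- as.numeric(response)
  if (nrow(A) != length(y)) stop("design/response dimension mismatch")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (length(weights) != length(y)) stop("weights/response dimension mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("all-zero weights")
  if (any(colSums(abs(A)) == 0)) stop("design has an all-zero column")
  sw <- sqrt(weights)
  x <- nnls_lawson_hanson(A * sw, y * sw)
  names(x) <- colnames(A)
  x
}

# Lawson & Hanson active-set NNLS. Returns the exact KKT-satisfying
# minimizer of ||Ax - y||^2 subject to x >= 0.
nnls_lawson_hanson <- function(A, y, tol = NULL) {
  K <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(abs(crossprod(A, y)), 1)
  passive <- rep(FALSE, K)
  x <- numeric(K)
  w <- as.vector(crossprod(A, y - A %*% x))
  iter <- 0L
  max_outer <- 30L * K
  while (any(!passive) && any(w[!passive] > tol) && iter < max_outer) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(K)
      P <- which(passive)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), y)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) break
      # backtrack along the segment x -> z to the first zero crossing
      bad <- P[z[P] <= tol]
      alpha <- min(x[bad] / (x[bad] - z[bad]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- as.vector(crossprod(A, y - A %*% x))
  }
  pmax(x, 0)
}
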