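#' Options controlling the deconvolution iteration
#'
#' The iteration re-implements the documented default behavior of the
#' cross-subject weighted-NNLS deconvolution design: a small variance
#' floor `nu`, convergence judged on the maximum absolute change of the
#' estimated proportions, a generous iteration cap, and no extra
#' normalization of the design (bulk inputs are non-log counts and are
#' only converted to relative expression).
#'
#' @param nu variance floor in the per-gene weights (default 1e-4).
#' @param convergence_tol maximum absolute proportion change declaring
#'   convergence (default 0.01).
#' @param max_iter maximum re-weighted solves (default 1000); `0` returns
#'   the initial unweighted NNLS solution.
#' @param min_common_genes minimum genes shared between bulk and atlas
#'   (default 100).
#' @param normalize when `TRUE`, design and response are additionally
#'   scaled by their global standard deviation before solving; kept
#'   `FALSE` by default.
#' @return A list of class `deconvolution_options`.
#' @export
deconvolution_options <- function(nu = 1e-4, convergence_tol = 0.01,
                                  max_iter = 1000, min_common_genes = 100,
                                  normalize = FALSE) {
  stopifnot(nu > 0, convergence_tol > 0, max_iter >= 0, min_common_genes >= 1)
  structure(list(nu = nu, convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter),
                 min_common_genes = as.integer(min_common_genes),
                 normalize = isTRUE(normalize)),
            class = "deconvolution_options")
}

#' Construct an ECC (estimated cell composition) matrix
#'
#' @param proportions samples x K matrix; entries in `[0, 1]`, rows sum
#'   to 1 within 1e-6, columns ordered like the reference atlas types.
#' @param converged,n_iter optional per-sample convergence diagnostics.
#' @param tol row-sum tolerance (default 1e-6; readers of rounded TSV
#'   output use a looser one).
#' @return An object of class `ecc_matrix`.
#' @export
ecc_matrix <- function(proportions, converged = NULL, n_iter = NULL,
                       tol = 1e-6) {
  p <- as.matrix(proportions)
  if (any(p < -1e-9) || any(p > 1 + 1e-9))
    stop("proportions must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > tol))
    stop("each ECC row must sum to 1 within ", format(tol))
  if (is.null(rownames(p)))
    rownames(p) <- sprintf("sample_%03d", seq_len(nrow(p)))
  structure(list(proportions = p,
                 converged = converged %||% rep(TRUE, nrow(p)),
                 n_iter = n_iter %||% rep(NA_integer_, nrow(p))),
            class = "ecc_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ecc_proportions <- function(x) {
  if (inherits(x, "ecc_matrix")) x$proportions else as.matrix(x)
}

#' @export
print.ecc_matrix <- function(x, ...) {
  cat(sprintf("ecc_matrix: %d samples x %d cell types (%d converged)\n",
              nrow(x$proportions), ncol(x$proportions), sum(x$converged)))
  invisible(x)
}

#' Deconvolute bulk samples into cell-type proportions
#'
#' Estimates, for every bulk sample, the proportions of the reference cell
#' types whose signature mixture best explains the sample, by iteratively
#' re-weighted non-negative least squares:
#' \enumerate{
#'   \item restrict bulk and atlas to their shared genes (case-sensitive
#'     symbol intersection; its size is logged) and convert the bulk
#'     column to relative expression on a percent-like scale;
#'   \item design column `k` is `theta[, k] * cell_size[k]` -- relative
#'     expression scaled by average per-cell mRNA content;
#'   \item solve an initial unweighted NNLS;
#'   \item re-weight each gene by the inverse of
#'     `nu + residual^2 + sum_k c_k^2 cell_size_k^2 sigma2[g, k]` (the
#'     cross-subject variance of the fitted value plus the squared
#'     residual, floored at `nu`) and re-solve, until the maximum absolute
#'     proportion change drops below `convergence_tol` or `max_iter` is
#'     reached;
#'   \item divide the coefficients by `cell_size` and normalize to sum 1,
#'     giving cell-count proportions.
#' }
#' Samples that do not converge still return the last iterate, flagged in
#' `converged`. Because the bulk column is first normalized to relative
#' expression, scaling a sample's library has no effect on its ECC.
#'
#' @param bulk a [bulk_expression_set()] or genes x samples matrix of
#'   non-log counts.
#' @param atlas a [build_reference()] atlas.
#' @param opts a [deconvolution_options()].
#' @return An `ecc_matrix` with per-sample `converged` and `n_iter`.
#' @export
deconvolute <- function(bulk, atlas, opts = deconvolution_options()) {
  stopifnot(inherits(atlas, "reference_atlas"),
            inherits(opts, "deconvolution_options"))
  m <- if (inherits(bulk, "bulk_expression_set")) bulk$counts else as.matrix(bulk)
  shared <- intersect(rownames(m), atlas$gene_ids)
  ecc_log(length(shared), " genes shared between bulk and atlas")
  if (length(shared) < opts$min_common_genes)
    stop("only ", length(shared), " shared genes (need >= ",
         opts$min_common_genes, ")")
  K <- length(atlas$cell_types)
  S <- atlas$cell_size
  D <- sweep(atlas$theta[shared, , drop = FALSE], 2, S, "*")
  Sg2 <- atlas$sigma2[shared, , drop = FALSE]
  if (opts$normalize) {
    sc <- sd(as.vector(D))
    D <- D / sc
    Sg2 <- Sg2 / sc^2
  }

  n <- ncol(m)
  P <- matrix(0, n, K, dimnames = list(colnames(m), atlas$cell_types))
  converged <- logical(n)
  n_iter <- integer(n)
  for (i in seq_len(n)) {
    y <- m[shared, i]
    tot <- sum(y)
    if (tot <= 0) stop("sample with zero library over shared genes: ",
                       colnames(m)[i])
    # percent-like scale so residuals are commensurate with the floor nu
    y <- y / tot * 100
    fit <- one_sample_ecc(y, D, S, Sg2, opts)
    P[i, ] <- fit$p
    converged[i] <- fit$converged
    n_iter[i] <- fit$n_iter
  }
  if (!all(converged))
    warning(sum(!converged), " sample(s) hit max_iter without converging; ",
            "last iterate returned")
  ecc_matrix(P, converged = converged, n_iter = n_iter)
}

one_sample_ecc <- function(y, D, S, Sg2, opts) {
  coef_to_prop <- function(cf) {
    q <- cf / S
    if (sum(q) == 0) rep(1 / length(q), length(q)) else q / sum(q)
  }
  cf <- weighted_nnls(D, y)
  p <- coef_to_prop(cf)
  converged <- opts$max_iter == 0L
  it <- 0L
  while (it < opts$max_iter) {
    it <- it + 1L
    r <- y - as.vector(D %*% cf)
    w <- 1 / (opts$nu + r^2 + as.vector(Sg2 %*% (cf^2 * S^2)))
    cf_new <- weighted_nnls(D, y, w)
    p_new <- coef_to_prop(cf_new)
    done <- max(abs(p_new - p)) < opts$convergence_tol
    cf <- cf_new
    p <- p_new
    if (done) { converged <- TRUE; break }
  }
  list(p = p, converged = converged, n_iter = it)
}

#' Assign each sample its dominant phenotype
#'
#' The maturation phenotype of a sample is its most abundant estimated
#' cell type (row argmax). On an exact tie the first type in atlas order
#' is chosen and the tie is flagged.
#'
#' @param ecc an `ecc_matrix` or samples x types proportion matrix.
#' @return data.frame (`sample_id`, `phenotype`, `dominance`, `tie`).
#' @export
assign_phenotype <- function(ecc) {
  p <- ecc_proportions(ecc)
  idx <- apply(p, 1, which.max)
  mx <- p[cbind(seq_len(nrow(p)), idx)]
  tie <- rowSums(p == matrix(mx, nrow(p), ncol(p))) > 1
  data.frame(sample_id = rownames(p),
             phenotype = colnames(p)[idx],
             dominance = mx, tie = tie,
             stringsAsFactors = FALSE, row.names = NULL)
}
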