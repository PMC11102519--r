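#' Min-max normalize a vector to [0, 1]
#'
#' Drug-resistance AUCs are put on a common `[0, 1]` scale per drug before
#' prediction and association: `(x - min) / (max - min)`. Invariant to
#' positive affine transforms of the input.
#'
#' @param values numeric vector with at least two distinct values.
#' @return Vector in `[0, 1]`; the minimum maps to 0, the maximum to 1.
#' @export
minmax_normalize <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) stop("cannot min-max normalize a constant vector")
  (values - rng[1]) / diff(rng)
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of mid-ranks (ties receive their average rank),
#' with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df, or from an
#' explicit permutation null when `method = "permutation"`.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, non-constant.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations for the permutation p-value.
#' @param seed RNG seed for the permutation null.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y, method = c("t", "permutation"),
                         n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)
  p <- if (method == "t") {
    if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    set.seed(seed)
    null <- replicate(n_perm, cor(rx, sample(ry)))
    (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
  }
  list(rho = rho, p_value = p, n = n)
}

# Deterministic per-fold seed from the global seed and the held-out
# sample id, so LOOCV predictions do not depend on sample order.
fold_seed <- function(seed, sample_id) {
  h <- sum(utf8ToInt(as.character(sample_id)) *
             (seq_along(utf8ToInt(as.character(sample_id))) + 31))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

#' Leave-one-out random-forest prediction of drug resistance from ECCs
#'
#' For every sample `i`, a random-forest regressor (default 500 trees,
#' `floor(K / 3)` candidate features per split, the conventions of the
#' classical randomForest implementation) is trained on all samples
#' except `i` -- with its own deterministic seed derived from the global
#' seed and the held-out sample's identifier -- and predicts sample `i`.
#' Predictive power is summarized as the Spearman rho between the held-out
#' predictions and the observations.
#'
#' By default each fold's prediction is reported relative to its training
#' baseline (`prediction - mean(training response) + mean(response)`).
#' Leave-one-out training means are anti-correlated with the held-out
#' value, which biases the naive predictions towards spurious negative
#' correlation when the model carries no signal; removing the per-fold
#' baseline shift restores calibration and is a monotone constant shift
#' within each fold, so genuine signal is unaffected.
#'
#' @param ecc an `ecc_matrix` or samples x K proportion matrix (features).
#' @param response per-sample normalized drug resistance (`auc_norm`),
#'   named by sample or aligned with the ECC rows.
#' @param n_trees trees per forest (default 500).
#' @param seed global seed.
#' @param drug drug name carried through to the result.
#' @param center_folds remove the per-fold training-mean shift from each
#'   held-out prediction (default `TRUE`); `FALSE` reports the raw
#'   forest predictions.
#' @return list of class `drug_prediction_result`: `drug`, `predicted`
#'   (named vector), `observed`, `spearman_rho`, `p_value`, `n_samples`,
#'   `model_config`.
#' @export
loocv_predict <- function(ecc, response, n_trees = 500, seed = 1L,
                          drug = "drug", center_folds = TRUE) {
  X <- ecc_proportions(ecc)
  if (!is.null(names(response))) {
    common <- intersect(rownames(X), names(response))
    X <- X[common, , drop = FALSE]
    response <- response[common]
  }
  n <- nrow(X)
  if (n < 10) stop("need at least 10 matched samples")
  if (length(response) != n) stop("response/ECC dimension mismatch")
  if (sd(response) == 0) stop("constant response")
  # canonical row order by sample id: fits are order-invariant
  ord <- order(rownames(X))
  X <- X[ord, , drop = FALSE]
  response <- response[ord]
  mtry <- max(1L, ncol(X) %/% 3L)
  pred <- setNames(numeric(n), rownames(X))
  for (i in seq_len(n)) {
    set.seed(fold_seed(seed, rownames(X)[i]))
    rf <- randomForest::randomForest(X[-i, , drop = FALSE], response[-i],
                                     ntree = n_trees, mtry = mtry)
    pred[i] <- predict(rf, X[i, , drop = FALSE])
    if (center_folds)
      pred[i] <- pred[i] - mean(response[-i]) + mean(response)
  }
  sp <- spearman_rho(pred, response)
  structure(list(drug = drug, predicted = pred, observed = response,
                 spearman_rho = sp$rho, p_value = sp$p_value,
                 n_samples = n,
                 model_config = list(n_trees = n_trees, mtry = mtry,
                                     seed = seed)),
            class = "drug_prediction_result")
}

#' @export
print.drug_prediction_result <- function(x, ...) {
  cat(sprintf("drug_prediction_result: %s, n = %d, Spearman rho = %.3f (p = %.3g)\n",
              x$drug, x$n_samples, x$spearman_rho, x$p_value))
  invisible(x)
}

#' Per-diagnosis association of observed with predicted resistance
#'
#' Within each diagnosis class (e.g. WHO group), observed normalized
#' resistance is regressed on the held-out prediction; classes with fewer
#' than `min_n` samples are skipped with a log entry.
#'
#' @param pred a [loocv_predict()] result.
#' @param class_labels per-sample class labels (named by sample id or
#'   aligned with the prediction order).
#' @param min_n minimum class size to report (default 4).
#' @return data.frame (`class`, `n`, `r_squared`, `p_value`).
#' @export
stratified_association <- function(pred, class_labels, min_n = 4) {
  stopifnot(inherits(pred, "drug_prediction_result"))
  ids <- names(pred$predicted)
  lab <- if (!is.null(names(class_labels))) class_labels[ids] else class_labels
  out <- list()
  for (cl in unique(lab[!is.na(lab)])) {
    sel <- !is.na(lab) & lab == cl
    if (sum(sel) < min_n) {
      ecc_log("class '", cl, "' skipped (n = ", sum(sel), " < ", min_n, ")")
      next
    }
    fit <- summary(lm(pred$observed[sel] ~ pred$predicted[sel]))
    out[[cl]] <- data.frame(class = cl, n = sum(sel),
                            r_squared = fit$r.squared,
                            p_value = fit$coefficients[2, 4],
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(class = character(), n = integer(),
                      r_squared = numeric(), p_value = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Associate each (cell type, drug) pair
#'
#' Per drug, the min-max-normalized AUC is regressed on each ECC column
#' separately; slopes, correlations and p-values are collected and
#' Benjamini-Hochberg adjusted across all (type, drug) pairs. The table
#' drives dot-plot style summaries (size = |correlation|, sign = slope).
#'
#' @param ecc an `ecc_matrix` or samples x K proportion matrix.
#' @param drugs data.frame (`sample_id`, `drug`, `auc`) as produced by
#'   [generate_drug_response()] or read from a CSV.
#' @return data.frame (`cell_type`, `drug`, `estimate`, `correlation`,
#'   `p_value`, `fdr`, `n`).
#' @export
ecc_drug_association <- function(ecc, drugs) {
  p <- ecc_proportions(ecc)
  out <- list()
  for (d in unique(drugs$drug)) {
    sub <- drugs[drugs$drug == d, ]
    common <- intersect(rownames(p), sub$sample_id)
    if (length(common) < 3) next
    auc_norm <- minmax_normalize(sub$auc[match(common, sub$sample_id)])
    for (k in colnames(p)) {
      xk <- p[common, k]
      if (sd(xk) == 0) next
      fit <- summary(lm(auc_norm ~ xk))
      out[[paste(d, k)]] <- data.frame(
        cell_type = k, drug = d,
        estimate = fit$coefficients[2, 1],
        correlation = cor(xk, auc_norm),
        p_value = fit$coefficients[2, 4],
        n = length(common), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res[, c("cell_type", "drug", "estimate", "correlation",
          "p_value", "fdr", "n")]
}
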