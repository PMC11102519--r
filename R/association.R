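# One-hot encode a mixed attribute table: numerics pass through, factors /
# characters are expanded against their first level as the reference.
encode_attributes <- function(attributes) {
  attributes <- as.data.frame(attributes)
  cols <- list()
  for (nm in names(attributes)) {
    v <- attributes[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- v
    } else {
      f <- factor(v)
      for (lv in levels(f)[-1])
        cols[[paste(nm, lv, sep = ":")]] <- as.numeric(f == lv)
    }
  }
  as.data.frame(cols, check.names = FALSE)
}

#' Univariate association ledger
#'
#' Regresses a min-max-normalized response (e.g. Venetoclax resistance)
#' on each attribute separately; the slope estimate and its t-test
#' p-value are reported per attribute and Benjamini-Hochberg adjusted
#' across attributes. Categorical attributes are one-hot encoded against
#' their first level; zero-variance attributes are skipped with a
#' warning.
#'
#' @param attributes data.frame of per-sample attributes (numeric, or
#'   categorical to be one-hot encoded).
#' @param response numeric per-sample response, already min-max
#'   normalized.
#' @return data.frame (`term`, `estimate`, `p_value`, `fdr`, `n`).
#' @export
univariate_assoc <- function(attributes, response) {
  X <- encode_attributes(attributes)
  if (nrow(X) != length(response))
    stop("attributes/response dimension mismatch")
  out <- list()
  for (nm in names(X)) {
    ok <- complete.cases(X[[nm]], response)
    if (sd(X[[nm]][ok]) == 0) {
      warning("attribute '", nm, "' has zero variance; skipped")
      next
    }
    fit <- summary(lm(response[ok] ~ X[[nm]][ok]))
    out[[nm]] <- data.frame(term = nm,
                            estimate = fit$coefficients[2, 1],
                            p_value = fit$coefficients[2, 4],
                            n = sum(ok), stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no usable attribute")
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res[, c("term", "estimate", "p_value", "fdr", "n")]
}

#' Multivariate association model
#'
#' One joint linear model of the response on all retained attributes
#' (after one-hot encoding and dropping `exclusions`). The design must be
#' full rank. Excluded terms are recorded in the result's
#' `"excluded"` attribute.
#'
#' @param attributes data.frame of per-sample attributes.
#' @param response numeric per-sample response (min-max normalized).
#' @param exclusions attribute names to drop before fitting (e.g. FAB
#'   class and all ECC columns except CD14+ Monocyte when asking whether
#'   monocytic composition is independently predictive).
#' @return data.frame (`term`, `estimate`, `p_value`, `n`) with attribute
#'   `"excluded"`.
#' @export
multivariate_assoc <- function(attributes, response, exclusions = NULL) {
  attributes <- as.data.frame(attributes)
  excluded <- intersect(exclusions, names(attributes))
  attributes <- attributes[, setdiff(names(attributes), excluded),
                           drop = FALSE]
  X <- as.matrix(encode_attributes(attributes))
  if (nrow(X) != length(response))
    stop("attributes/response dimension mismatch")
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("rank-deficient design: exactly collinear attributes")
  fit <- summary(lm(response ~ X))
  cf <- fit$coefficients[-1, , drop = FALSE]
  res <- data.frame(term = colnames(X), estimate = cf[, 1],
                    p_value = cf[, 4], n = length(response),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "excluded") <- excluded
  res
}

#' Weighted gene-signature score on cpm-normalized expression
#'
#' A per-sample signature score (e.g. a stemness score) computed as
#' `score_s = sum_g w_g * log2(cpm[g, s] + 1)` over the signature genes
#' present in the matrix; missing signature genes are dropped with a
#' warning. Because cpm normalization removes depth, doubling a library
#' leaves the score unchanged.
#'
#' @param cpm genes x samples cpm matrix (see [cpm_normalize()]).
#' @param weights named numeric vector `gene -> weight`.
#' @param log_transform apply `log2(cpm + 1)` (default `TRUE`); `FALSE`
#'   scores raw cpm.
#' @return Named per-sample score vector.
#' @export
signature_score <- function(cpm, weights, log_transform = TRUE) {
  present <- intersect(names(weights), rownames(cpm))
  if (!length(present)) stop("no signature gene present in the matrix")
  if (length(present) < length(weights))
    warning(length(weights) - length(present),
            " signature gene(s) absent from the matrix; dropped")
  x <- cpm[present, , drop = FALSE]
  if (log_transform) x <- log2(x + 1)
  colSums(x * weights[present])
}

#' Remove additive batch effects from a log-scale expression matrix
#'
#' Per feature, the batch means are computed and each sample's value is
#' shifted by its batch's deviation from the feature's grand mean; the
#' per-feature grand mean is preserved. With a single batch the matrix is
#' returned unchanged with a warning.
#'
#' @param log_expression features x samples matrix (log scale, e.g.
#'   log-cpm protein or transcript abundance).
#' @param batch per-sample batch labels (>= 2 samples per batch).
#' @return Corrected matrix of the same shape.
#' @export
batch_correct <- function(log_expression, batch) {
  m <- as.matrix(log_expression)
  batch <- as.character(batch)
  if (length(batch) != ncol(m)) stop("one batch label per sample required")
  if (length(unique(batch)) < 2) {
    warning("single batch: nothing to correct")
    return(m)
  }
  if (any(table(batch) < 2)) stop("every batch needs at least 2 samples")
  grand <- rowMeans(m)
  for (b in unique(batch)) {
    sel <- batch == b
    dev <- rowMeans(m[, sel, drop = FALSE]) - grand
    m[, sel] <- m[, sel] - dev
  }
  m
}

#' Split scores into low/high at the median
#'
#' `score > median` is `"high"`, `score <= median` is `"low"` (ties at
#' the median go to `"low"`, keeping the split deterministic).
#'
#' @param scores numeric vector, non-constant, length >= 2.
#' @return Character vector of `"low"` / `"high"` labels (names kept).
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples")
  if (sd(scores) == 0) stop("constant scores cannot be split")
  med <- median(scores)
  setNames(ifelse(scores > med, "high", "low"), names(scores))
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per group and the standard
#' (unstratified) log-rank chi-square over the distinct event times, with
#' a two-sided p-value on `groups - 1` degrees of freedom. Fitting is
#' delegated to the survival package; the returned curves are plain
#' data.frames for plotting.
#'
#' @param survival_table data.frame with columns `time` (>= 0), `event`
#'   (1 = event, 0 = censored) and `group`.
#' @return list: `curves` (data.frame `group`, `time`, `n_risk`,
#'   `estimate`), `chisq`, `df`, `p_value`, `n`.
#' @export
km_logrank <- function(survival_table) {
  st <- as.data.frame(survival_table)
  stopifnot(all(c("time", "event", "group") %in% names(st)))
  if (any(st$time < 0)) stop("negative survival time")
  if (!all(st$event %in% c(0, 1))) stop("event must be 0/1")
  if (length(unique(st$group)) < 2) stop("need at least 2 groups")
  if (sum(st$event) == 0) stop("no event in the table")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = st)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, n_risk = fit$n.risk,
                       estimate = fit$surv, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = st)
  df <- length(sd_$n) - 1
  p <- pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd_$chisq), df = df,
       p_value = p, n = nrow(st))
}
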