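#' Configuration for the synthetic single-cell atlas generator
#'
#' Describes a multi-subject, multi-cell-type negative-binomial single-cell
#' count matrix with marker-gene structure, donor-level variability and
#' library-size variation -- a controllable stand-in for a healthy
#' bone-marrow atlas, so that deconvolution accuracy can be measured
#' against known ground truth.
#'
#' Defaults describe the benchmark atlas used throughout the package's
#' validation: 8 cell types, 3 subjects, 400 genes with 10 dedicated
#' markers per type up-regulated by `2^3 = 8` fold, 40 cells per type per
#' subject, moderate donor effects and overdispersion typical of UMI data.
#'
#' @param n_types number of cell types `K`.
#' @param n_subjects number of donors `S`.
#' @param n_genes number of genes `G`.
#' @param markers_per_type dedicated marker genes per type `m`
#'   (requires `m * K <= G`).
#' @param marker_log2_foldchange marker up-regulation `f` (log2).
#' @param subject_sd SD of the per-(gene, subject) multiplicative
#'   log-normal donor effect, on the natural-log scale.
#' @param nb_dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param library_size_mean mean total counts per cell.
#' @param library_size_sd SD (natural-log scale) of the log-normal
#'   per-cell library-size factor.
#' @param cells_per_type_per_subject cells drawn per (type, subject).
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return A list of class `atlas_sim_config`.
#' @export
atlas_sim_config <- function(n_types = 8, n_subjects = 3, n_genes = 400,
                             markers_per_type = 10,
                             marker_log2_foldchange = 3,
                             subject_sd = 0.3, nb_dispersion = 0.2,
                             library_size_mean = 2000,
                             library_size_sd = 0.3,
                             cells_per_type_per_subject = 40,
                             seed = 1L) {
  cfg <- list(n_types = n_types, n_subjects = n_subjects, n_genes = n_genes,
              markers_per_type = markers_per_type,
              marker_log2_foldchange = marker_log2_foldchange,
              subject_sd = subject_sd, nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              library_size_sd = library_size_sd,
              cells_per_type_per_subject = cells_per_type_per_subject,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_types >= 2, n_subjects >= 1, n_genes >= 1,
              markers_per_type >= 0, subject_sd >= 0, nb_dispersion > 0,
              library_size_mean > 0, library_size_sd >= 0,
              cells_per_type_per_subject >= 1)
    if (markers_per_type * n_types > n_genes)
      stop("markers_per_type * n_types exceeds n_genes")
  })
  class(cfg) <- "atlas_sim_config"
  cfg
}

#' Generate a synthetic annotated single-cell atlas
#'
#' Per type `k`, baseline gene means are log-normal, with the type's `m`
#' dedicated marker genes up-scaled by `2^f`. Each (gene, subject) pair
#' receives a multiplicative log-normal donor effect. Each cell draws a
#' log-normal library-size factor and its counts are negative-binomial
#' around the type/subject profile scaled to that library size.
#'
#' @param config an [atlas_sim_config()].
#' @return An [annotated_cell_matrix()]; the generative parameters
#'   (config, per-type marker gene ids) are stored in attribute
#'   `"sim_params"`.
#' @export
generate_synthetic_atlas <- function(config = atlas_sim_config()) {
  stopifnot(inherits(config, "atlas_sim_config"))
  set.seed(config$seed)
  G <- config$n_genes; K <- config$n_types; S <- config$n_subjects
  m <- config$markers_per_type
  genes <- sprintf("g%04d", seq_len(G))
  types <- sprintf("type_%02d", seq_len(K))
  subjects <- sprintf("subject_%02d", seq_len(S))

  base <- rlnorm(G, meanlog = 0, sdlog = 1)
  markers <- lapply(seq_len(K), function(k) genes[((k - 1) * m + seq_len(m))])
  names(markers) <- types
  # type_mean[g, k]: baseline, with type-k markers up-scaled by 2^f
  type_mean <- matrix(base, G, K, dimnames = list(genes, types))
  for (k in seq_len(K))
    type_mean[markers[[k]], k] <- type_mean[markers[[k]], k] *
      2^config$marker_log2_foldchange
  # donor effect per (gene, subject), shared across types
  subj_eff <- matrix(rlnorm(G * S, 0, config$subject_sd), G, S,
                     dimnames = list(genes, subjects))

  n_per <- config$cells_per_type_per_subject
  n_cells <- K * S * n_per
  counts <- matrix(0L, G, n_cells, dimnames = list(genes, NULL))
  cell_type <- character(n_cells); cell_subject <- character(n_cells)
  # mean library size = library_size_mean (log-normal mean correction)
  mulog <- log(config$library_size_mean) - config$library_size_sd^2 / 2
  i <- 0L
  for (k in seq_len(K)) for (s in seq_len(S)) {
    prof <- type_mean[, k] * subj_eff[, s]
    prof <- prof / sum(prof)
    for (cc in seq_len(n_per)) {
      i <- i + 1L
      lib <- rlnorm(1, mulog, config$library_size_sd)
      counts[, i] <- rnbinom(G, mu = prof * lib,
                             size = 1 / config$nb_dispersion)
      cell_type[i] <- types[k]; cell_subject[i] <- subjects[s]
    }
  }
  colnames(counts) <- sprintf("cell_%05d", seq_len(n_cells))
  out <- annotated_cell_matrix(counts, cell_type, cell_subject)
  attr(out, "sim_params") <- list(config = config, markers = markers,
                                  type_mean = type_mean)
  out
}

#' Simulate an overabundant-cell-type pseudobulk
#'
#' Builds an artificial bulk profile with known composition: a fraction
#' `frac` of the `n_cells` drawn cells comes from `target_type` (sampled
#' with replacement) and the remaining cells are distributed over the
#' other types with weights proportional to the inverse of each type's
#' available cell count (largest-remainder rounding so the total is
#' exact). The drawn cells' counts are summed into the pseudobulk.
#'
#' @param cells an [annotated_cell_matrix()]; log-integrated values are
#'   exponentiated first.
#' @param target_type the overabundant cell type.
#' @param n_cells total cells per pseudobulk (default 1000).
#' @param frac fraction of cells from `target_type` (default 0.8).
#' @param seed optional RNG seed.
#' @param log_base see [build_reference()].
#' @return A list of class `pseudobulk_truth`: `bulk_counts` (named
#'   per-gene sums), `true_proportions` (cell-count fractions, sum 1,
#'   ordered like the atlas types) and `n_cells_drawn`.
#' @export
simulate_overabundant_pseudobulk <- function(cells, target_type,
                                             n_cells = 1000, frac = 0.8,
                                             seed = NULL,
                                             log_base = exp(1)) {
  stopifnot(inherits(cells, "annotated_cell_matrix"))
  if (!is.null(seed)) set.seed(seed)
  types <- cell_types_of(cells)
  if (!target_type %in% types) stop("unknown target_type: ", target_type)
  if (length(types) < 2) stop("at least two cell types required")
  m <- cells$counts
  if (cells$is_log_integrated) m <- unlog_counts(m, log_base)

  n_target <- round(frac * n_cells)
  rest <- setdiff(types, target_type)
  avail <- vapply(rest, function(k) sum(cells$cell_type == k), integer(1))
  w <- (1 / avail) / sum(1 / avail)
  n_rest <- largest_remainder(w * (n_cells - n_target))
  n_drawn <- setNames(integer(length(types)), types)
  n_drawn[target_type] <- n_target
  n_drawn[rest] <- n_rest

  bulk <- numeric(nrow(m))
  for (k in types) {
    if (n_drawn[k] == 0) next
    idx <- sample(which(cells$cell_type == k), n_drawn[k], replace = TRUE)
    bulk <- bulk + rowSums(m[, idx, drop = FALSE])
  }
  names(bulk) <- rownames(m)
  structure(list(bulk_counts = bulk,
                 true_proportions = n_drawn / n_cells,
                 n_cells_drawn = n_drawn),
            class = "pseudobulk_truth")
}

# Round non-negative reals to integers conserving the (integral) total:
# floor everything, then hand the remainder to the largest fractional
# parts (ties broken by position).
largest_remainder <- function(x) {
  stopifnot(all(x >= 0))
  n <- floor(x)
  short <- round(sum(x)) - sum(n)
  if (short > 0) {
    ord <- order(x - n, decreasing = TRUE)
    n[ord[seq_len(short)]] <- n[ord[seq_len(short)]] + 1
  }
  as.integer(n)
}

#' Individual-based pseudobulk: sum one subject's cells
#'
#' @param cells an [annotated_cell_matrix()].
#' @param subject donor label.
#' @return Named per-gene vector of summed counts.
#' @export
aggregate_individual <- function(cells, subject) {
  stopifnot(inherits(cells, "annotated_cell_matrix"))
  sel <- cells$subject == subject
  if (!any(sel)) stop("unknown subject: ", subject)
  rowSums(cells$counts[, sel, drop = FALSE])
}

#' Simulate ECC-linked drug response AUCs
#'
#' Generates a per-sample drug resistance AUC as a linear function of the
#' sample's estimated cell composition plus Gaussian noise:
#' `auc_i = sum_k beta_k * ecc[i, k] + eps`, `eps ~ N(0, noise_sd^2)`.
#'
#' @param ecc an `ecc_matrix` or samples x types proportion matrix.
#' @param beta K-vector of per-type effects (named or atlas order).
#' @param noise_sd Gaussian noise SD.
#' @param seed optional RNG seed.
#' @param drug drug name recorded in the table.
#' @return data.frame (`sample_id`, `drug`, `auc`) with the generative
#'   `beta` in attribute `"beta"`.
#' @export
generate_drug_response <- function(ecc, beta, noise_sd = 0, seed = NULL,
                                   drug = "drug_1") {
  p <- ecc_proportions(ecc)
  if (length(beta) != ncol(p)) stop("beta length must equal number of types")
  if (!is.null(names(beta))) beta <- beta[colnames(p)]
  if (!is.null(seed)) set.seed(seed)
  auc <- as.vector(p %*% beta) + rnorm(nrow(p), 0, noise_sd)
  out <- data.frame(sample_id = rownames(p), drug = drug, auc = auc,
                    stringsAsFactors = FALSE)
  attr(out, "beta") <- beta
  out
}

#' Simulate group-dependent survival times
#'
#' Exponential event times with a per-group hazard, administratively
#' censored at `censor_time` (event = 0).
#'
#' @param groups character vector of group labels, one per sample.
#' @param hazard_by_group named positive vector of hazards.
#' @param censor_time administrative censoring time (default `Inf`).
#' @param seed optional RNG seed.
#' @return data.frame (`sample_id`, `time`, `event`, `group`).
#' @export
generate_survival <- function(groups, hazard_by_group, censor_time = Inf,
                              seed = NULL) {
  stopifnot(all(hazard_by_group > 0))
  unknown <- setdiff(unique(groups), names(hazard_by_group))
  if (length(unknown)) stop("unknown group label(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  t_event <- rexp(length(groups), rate = hazard_by_group[groups])
  event <- as.integer(t_event <= censor_time)
  data.frame(sample_id = sprintf("s%04d", seq_along(groups)),
             time = pmin(t_event, censor_time), event = event,
             group = as.character(groups), stringsAsFactors = FALSE)
}
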