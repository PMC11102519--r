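#' Merge cell-type labels
#'
#' Collapses fine-grained cell-type labels into coarser groups (e.g. all T
#' and B subsets into single T-cell / B-cell types) before building the
#' reference. Counts are untouched; only the labels change.
#'
#' @param cells an [annotated_cell_matrix()].
#' @param mapping named character vector `old label -> new label`.
#' @param strict when `TRUE`, a label absent from the mapping is an error;
#'   otherwise unmapped labels pass through unchanged.
#' @return An [annotated_cell_matrix()] with relabelled cells.
#' @export
merge_celltype_labels <- function(cells, mapping, strict = FALSE) {
  stopifnot(inherits(cells, "annotated_cell_matrix"))
  lab <- cells$cell_type
  unmapped <- setdiff(unique(lab), names(mapping))
  if (strict && length(unmapped))
    stop("unmapped cell-type label(s): ", paste(unmapped, collapse = ", "))
  hit <- lab %in% names(mapping)
  lab[hit] <- unname(mapping[lab[hit]])
  out <- cells
  out$cell_type <- lab
  out
}

#' Build a deconvolution reference atlas from annotated single cells
#'
#' Turns a multi-subject annotated single-cell count matrix into the design
#' quantities weighted deconvolution needs. For every subject `s` and cell
#' type `k`, the subject-level mean expression per gene (average count over
#' that subject's type-`k` cells) is converted to a relative profile by
#' dividing by its sum. Then per type:
#' \itemize{
#'   \item `theta[, k]`: across-subject mean of the relative profiles
#'     (columns sum to 1);
#'   \item `sigma2[, k]`: across-subject variance of the relative profiles
#'     (unbiased, denominator S-1; 0 when a single subject contributes);
#'   \item `cell_size[k]`: mean total counts per type-`k` cell -- the
#'     average mRNA content that converts expression coefficients back to
#'     cell-count proportions.
#' }
#' Cross-subject profiles (rather than pooled cells) are used so that
#' `sigma2` measures the between-donor variability that downweights
#' unstable genes during deconvolution.
#'
#' @param cells an [annotated_cell_matrix()]; log-integrated values are
#'   exponentiated first (see `log_base`).
#' @param min_cells_per_type types with fewer cells are dropped with a
#'   warning; default 10 guards degenerate variance estimates.
#' @param pooled when `TRUE`, `theta` is instead computed from the pooled
#'   mean over all cells of a type (comparison mode); `sigma2` is still
#'   the cross-subject variance.
#' @param log_base base of the log1p transform undone when
#'   `is_log_integrated` is set; default `exp(1)` (natural `log1p`, the
#'   convention of the common integration toolchains).
#' @return An object of class `reference_atlas` with fields `gene_ids`,
#'   `cell_types`, `theta`, `sigma2`, `cell_size`, `n_cells`, `n_subjects`.
#' @export
build_reference <- function(cells, min_cells_per_type = 10, pooled = FALSE,
                            log_base = exp(1)) {
  stopifnot(inherits(cells, "annotated_cell_matrix"))
  m <- cells$counts
  if (cells$is_log_integrated) m <- unlog_counts(m, log_base)
  types <- cell_types_of(cells)
  n_cells <- vapply(types, function(k) sum(cells$cell_type == k), integer(1))
  drop <- n_cells < min_cells_per_type
  if (any(drop)) {
    warning("dropping ", sum(drop), " cell type(s) with fewer than ",
            min_cells_per_type, " cells: ",
            paste(types[drop], collapse = ", "))
    types <- types[!drop]
    n_cells <- n_cells[!drop]
  }
  if (length(types) < 2) stop("fewer than 2 cell types after filtering")

  # drop genes with zero expression everywhere: no design information
  keep_cells <- cells$cell_type %in% types
  m <- m[, keep_cells, drop = FALSE]
  ct <- cells$cell_type[keep_cells]
  subj <- cells$subject[keep_cells]
  nz <- rowSums(m) > 0
  m <- m[nz, , drop = FALSE]
  if (nrow(m) == 0) stop("no expressed gene left")

  subjects <- unique(subj)
  K <- length(types)
  G <- nrow(m)
  theta <- sigma2 <- matrix(0, G, K, dimnames = list(rownames(m), types))
  cell_size <- setNames(numeric(K), types)
  for (k in types) {
    sel <- ct == k
    if (sum(m[, sel]) == 0) stop("cell type with zero total counts: ", k)
    cell_size[k] <- mean(colSums(m[, sel, drop = FALSE]))
    # subject-level relative profiles (subjects contributing >= 1 cell)
    profs <- lapply(subjects, function(s) {
      cs <- sel & subj == s
      if (!any(cs)) return(NULL)
      mu <- rowMeans(m[, cs, drop = FALSE])
      tot <- sum(mu)
      if (tot == 0) return(NULL)
      mu / tot
    })
    profs <- do.call(cbind, profs[!vapply(profs, is.null, logical(1))])
    theta[, k] <- if (pooled) {
      mu <- rowMeans(m[, sel, drop = FALSE]); mu / sum(mu)
    } else rowMeans(profs)
    sigma2[, k] <- if (ncol(profs) > 1) apply(profs, 1, var) else 0
  }
  structure(
    list(gene_ids = rownames(m), cell_types = types, theta = theta,
         sigma2 = sigma2, cell_size = cell_size, n_cells = n_cells,
         n_subjects = length(subjects)),
    class = "reference_atlas")
}

unlog_counts <- function(m, log_base = exp(1)) {
  if (abs(log_base - exp(1)) < 1e-12) expm1(m) else log_base^m - 1
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf("reference_atlas: %d genes x %d cell types (%d subjects)\n",
              length(x$gene_ids), length(x$cell_types), x$n_subjects))
  cat("  types:", paste(head(x$cell_types, 8), collapse = ", "),
      if (length(x$cell_types) > 8) "..." else "", "\n")
  invisible(x)
}

#' Serialize / load a reference atlas
#'
#' One structured TSV: `#`-prefixed header lines carry `n_subjects` and the
#' per-type `cell_size` / `n_cells` vectors; the body is a long table with
#' columns `gene`, `cell_type`, `theta`, `sigma2` (full precision).
#'
#' @param atlas a `reference_atlas`.
#' @param path output path.
#' @export
write_atlas <- function(atlas, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_subjects\t%d", atlas$n_subjects), con)
  writeLines(paste0("# cell_size\t", paste(atlas$cell_types,
             format(atlas$cell_size, digits = 17), sep = "=", collapse = "\t")), con)
  writeLines(paste0("# n_cells\t", paste(atlas$cell_types,
             atlas$n_cells, sep = "=", collapse = "\t")), con)
  df <- data.frame(
    gene = rep(atlas$gene_ids, times = length(atlas$cell_types)),
    cell_type = rep(atlas$cell_types, each = length(atlas$gene_ids)),
    theta = as.vector(atlas$theta),
    sigma2 = as.vector(atlas$sigma2))
  df$theta <- format(df$theta, digits = 17, scientific = TRUE)
  df$sigma2 <- format(df$sigma2, digits = 17, scientific = TRUE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @return `read_atlas()` returns a `reference_atlas`.
#' @export
read_atlas <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  parse_kv <- function(tag) {
    ln <- sub(paste0("^# ", tag, "\t"), "", hdr[startsWith(hdr, paste0("# ", tag))])
    parts <- strsplit(ln, "\t")[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    setNames(as.numeric(vapply(kv, `[`, "", 2)), vapply(kv, `[`, "", 1))
  }
  n_subjects <- as.integer(sub("^# n_subjects\t", "",
                               hdr[startsWith(hdr, "# n_subjects")]))
  cell_size <- parse_kv("cell_size")
  n_cells <- parse_kv("n_cells")
  df <- read.delim(textConnection(lines[!startsWith(lines, "# ")]),
                   stringsAsFactors = FALSE)
  types <- names(cell_size)
  genes <- unique(df$gene)
  theta <- matrix(df$theta, length(genes), length(types),
                  dimnames = list(genes, types))
  sigma2 <- matrix(df$sigma2, length(genes), length(types),
                   dimnames = list(genes, types))
  structure(list(gene_ids = genes, cell_types = types, theta = theta,
                 sigma2 = sigma2, cell_size = cell_size,
                 n_cells = setNames(as.integer(n_cells), names(n_cells)),
                 n_subjects = n_subjects),
            class = "reference_atlas")
}
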