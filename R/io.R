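#' @importFrom stats sd var median rexp rnorm rnbinom rlnorm runif lm
#'   pchisq pt coef cor quantile setNames complete.cases model.matrix
#'   p.adjust predict
#' @importFrom utils read.delim write.table head
NULL

# Internal logger: all diagnostics go through message()/warning(), never stdout.
ecc_log <- function(...) message("[eccdeconv] ", ...)

#' Construct an annotated single-cell count matrix
#'
#' The container every reference-building and simulation step consumes:
#' a genes x cells matrix of non-negative counts with one cell-type label
#' and one subject (donor) label per cell.
#'
#' @param counts genes x cells numeric matrix, non-negative unless
#'   `is_log_integrated` is `TRUE` (then values are log-scale integrated
#'   expression that downstream steps exponentiate).
#' @param cell_type character vector, one label per cell.
#' @param subject character vector, one donor label per cell.
#' @param is_log_integrated flag; `TRUE` means values are `log1p`-scale
#'   integrated expression rather than raw counts.
#' @return An object of class `annotated_cell_matrix`.
#' @export
annotated_cell_matrix <- function(counts, cell_type, subject,
                                  is_log_integrated = FALSE) {
  counts <- as.matrix(counts)
  if (length(cell_type) == 1) cell_type <- rep(cell_type, ncol(counts))
  if (length(subject) == 1) subject <- rep(subject, ncol(counts))
  if (ncol(counts) != length(cell_type) || ncol(counts) != length(subject))
    stop("one cell_type and one subject label is required per cell")
  if (anyNA(counts)) stop("counts contain NA")
  if (!is_log_integrated && any(counts < 0))
    stop("counts must be non-negative")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell_%04d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
  structure(
    list(counts = counts,
         cell_type = as.character(cell_type),
         subject = as.character(subject),
         is_log_integrated = isTRUE(is_log_integrated)),
    class = "annotated_cell_matrix")
}

#' @export
print.annotated_cell_matrix <- function(x, ...) {
  cat(sprintf("annotated_cell_matrix: %d genes x %d cells, %d types, %d subjects%s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_type)), length(unique(x$subject)),
              if (x$is_log_integrated) " (log-integrated)" else ""))
  invisible(x)
}

# Canonical (sorted) cell-type order used everywhere downstream (atlas
# columns, truth vectors), so results never depend on cell order.
cell_types_of <- function(cells) sort(unique(cells$cell_type))

#' Read an annotated single-cell matrix from MatrixMarket triplet files
#'
#' Reads the conventional `matrix.mtx` / `features.tsv` / `barcodes.tsv`
#' triplet (genes x cells) plus a per-barcode annotation table carrying
#' `barcode`, `cell_type` and `subject` columns. Barcodes missing from the
#' annotation are dropped with a logged count.
#'
#' @param mtx_path path to the MatrixMarket file.
#' @param features_path TSV whose first column holds gene identifiers.
#' @param barcodes_path TSV/one-column file of cell barcodes.
#' @param annotation_path TSV with columns `barcode`, `cell_type`, `subject`.
#' @return An [annotated_cell_matrix()].
#' @export
read_cell_matrix <- function(mtx_path, features_path, barcodes_path,
                             annotation_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  features <- read.delim(features_path, header = FALSE,
                         stringsAsFactors = FALSE)
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(features) != nrow(m))
    stop(sprintf("MTX header says %d genes but features file has %d rows",
                 nrow(m), nrow(features)))
  if (nrow(barcodes) != ncol(m))
    stop(sprintf("MTX header says %d cells but barcodes file has %d rows",
                 ncol(m), nrow(barcodes)))
  rownames(m) <- features[[1]]
  colnames(m) <- barcodes[[1]]
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("barcode", "cell_type", "subject")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  keep <- colnames(m) %in% ann$barcode
  if (!all(keep))
    ecc_log(sum(!keep), " barcode(s) absent from annotation were dropped")
  if (!any(keep)) stop("no barcode overlaps the annotation")
  m <- m[, keep, drop = FALSE]
  ann <- ann[match(colnames(m), ann$barcode), ]
  annotated_cell_matrix(m, ann$cell_type, ann$subject)
}

#' Construct a bulk expression set
#'
#' @param counts genes x samples matrix of non-negative raw counts with
#'   gene identifiers as rownames and sample identifiers as colnames.
#' @param sample_meta optional data.frame of per-sample metadata, one row
#'   per sample (`sample_id` column or rownames), e.g. FAB/WHO/ELN class
#'   and blast percentage.
#' @return An object of class `bulk_expression_set`.
#' @export
bulk_expression_set <- function(counts, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || !is.numeric(counts)) stop("counts must be numeric")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample_%03d", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts))) stop("sample identifiers must be unique")
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (!"sample_id" %in% names(sample_meta))
      sample_meta$sample_id <- rownames(sample_meta)
    extra <- setdiff(sample_meta$sample_id, colnames(counts))
    if (length(extra))
      ecc_log(length(extra), " metadata row(s) without a matching sample ignored")
    sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                               drop = FALSE]
    rownames(sample_meta) <- colnames(counts)
  }
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "bulk_expression_set")
}

#' @export
print.bulk_expression_set <- function(x, ...) {
  cat(sprintf("bulk_expression_set: %d genes x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$sample_meta)) "" else
                sprintf(", %d metadata fields", ncol(x$sample_meta))))
  invisible(x)
}

#' Read a bulk count matrix (and optional sample metadata) from TSV
#'
#' @param tsv_path TSV whose first column is the gene identifier and whose
#'   remaining columns are numeric per-sample counts.
#' @param meta_path optional CSV/TSV with a `sample_id` column; joined on
#'   sample identifier, unmatched rows logged.
#' @return A [bulk_expression_set()].
#' @export
read_bulk_counts <- function(tsv_path, meta_path = NULL) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE, check.names = FALSE)
  gene_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cells in count matrix")
  if (any(mat < 0)) stop("negative counts are not allowed")
  rownames(mat) <- gene_ids
  meta <- if (!is.null(meta_path)) read_table_auto(meta_path) else NULL
  bulk_expression_set(mat, meta)
}

# Sniff delimiter (comma vs tab) on the header line.
read_table_auto <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Build per-gene metadata flags for preprocessing
#'
#' Flags ERCC spike-ins and mitochondrial genes and (optionally) maps gene
#' identifiers to symbols. When no explicit flags are supplied the
#' conventional prefix rules apply: identifiers or symbols starting with
#' `ERCC-` are spike-ins and those starting with `MT-` are mitochondrial,
#' case-insensitively.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param mapping optional named character vector `id -> symbol`; an
#'   identifier mapped to two different symbols is an error.
#' @param is_spikein,is_mitochondrial optional logical overrides.
#' @return data.frame with columns `gene_id`, `symbol`, `is_spikein`,
#'   `is_mitochondrial`.
#' @export
gene_metadata <- function(gene_ids, mapping = NULL,
                          is_spikein = NULL, is_mitochondrial = NULL) {
  gene_ids <- as.character(gene_ids)
  symbol <- gene_ids
  if (!is.null(mapping)) {
    if (anyDuplicated(names(mapping))) {
      conflict <- vapply(split(unname(mapping), names(mapping)),
                         function(v) length(unique(v)) > 1, logical(1))
      if (any(conflict))
        stop("conflicting duplicate in id -> symbol mapping: ",
             paste(names(conflict)[conflict], collapse = ", "))
      mapping <- mapping[!duplicated(names(mapping))]
    }
    hit <- gene_ids %in% names(mapping)
    symbol[hit] <- unname(mapping[gene_ids[hit]])
  }
  if (is.null(is_spikein))
    is_spikein <- grepl("^ERCC-", symbol, ignore.case = TRUE) |
      grepl("^ERCC-", gene_ids, ignore.case = TRUE)
  if (is.null(is_mitochondrial))
    is_mitochondrial <- grepl("^MT-", symbol, ignore.case = TRUE) |
      grepl("^MT-", gene_ids, ignore.case = TRUE)
  data.frame(gene_id = gene_ids, symbol = symbol,
             is_spikein = as.logical(is_spikein),
             is_mitochondrial = as.logical(is_mitochondrial),
             stringsAsFactors = FALSE)
}

#' Preprocess a bulk count matrix for deconvolution
#'
#' Applies the standard cleanup performed on AML cohort count matrices
#' before deconvolution: ERCC spike-ins and mitochondrial genes are
#' removed, identifiers are mapped to gene symbols where a mapping exists,
#' and among rows sharing a symbol only the most variable row (largest
#' per-gene standard deviation across samples) is retained -- duplicated
#' low-variance rows carry less information.
#'
#' @param bulk a [bulk_expression_set()].
#' @param meta a [gene_metadata()] table; built from the bulk's gene
#'   identifiers with prefix rules when `NULL`.
#' @param sd_scale scale on which the deduplication SD is computed:
#'   `"counts"` (raw counts, the default) or `"cpm"`. Population SD
#'   (denominator n).
#' @return A [bulk_expression_set()] with symbols as rownames, no
#'   spike-in/mitochondrial rows and no duplicated symbol.
#' @export
preprocess_bulk <- function(bulk, meta = NULL, sd_scale = c("counts", "cpm")) {
  sd_scale <- match.arg(sd_scale)
  stopifnot(inherits(bulk, "bulk_expression_set"))
  if (ncol(bulk$counts) < 1) stop("at least one sample required")
  if (is.null(meta)) meta <- gene_metadata(rownames(bulk$counts))
  meta <- meta[match(rownames(bulk$counts), meta$gene_id), ]
  if (anyNA(meta$gene_id))
    stop("gene identifiers not resolvable against metadata")
  keep <- !(meta$is_spikein | meta$is_mitochondrial)
  m <- bulk$counts[keep, , drop = FALSE]
  sym <- meta$symbol[keep]
  if (nrow(m) == 0) stop("empty matrix after spike-in/mitochondrial filtering")
  base <- if (sd_scale == "cpm") cpm_normalize(m) else m
  sds <- apply(base, 1, sd_pop)
  # within each symbol keep the row with the largest SD (first on exact tie)
  ord <- order(sym, -sds)
  keep2 <- ord[!duplicated(sym[ord])]
  keep2 <- sort(keep2)
  m <- m[keep2, , drop = FALSE]
  rownames(m) <- sym[keep2]
  bulk_expression_set(m, bulk$sample_meta)
}

# population standard deviation (denominator n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Counts-per-million normalization
#'
#' Scales every sample (column) to a library size of one million:
#' `cpm[g, s] = counts[g, s] / sum(counts[, s]) * 1e6`.
#'
#' @param x a [bulk_expression_set()] or a genes x samples matrix.
#' @return genes x samples matrix of cpm values; every column sums to 1e6.
#' @export
cpm_normalize <- function(x) {
  m <- if (inherits(x, "bulk_expression_set")) x$counts else as.matrix(x)
  libs <- colSums(m)
  if (any(libs <= 0)) stop("every sample must have a positive library size")
  sweep(m, 2, libs, "/") * 1e6
}

# ---- tabular serialization ----------------------------------------------
# All numeric TSV output is written with 6 significant digits so that a
# write/read round trip reproduces the written values bit-for-bit.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

write_tsv_signif <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an ECC matrix as TSV
#'
#' One row per sample: `sample_id`, one column per cell type, then
#' `phenotype`, `dominance`, `converged`, `n_iter`. Floating point is
#' written with 6 significant digits; re-reading reproduces the written
#' values exactly.
#'
#' @param ecc an `ecc_matrix` as returned by [deconvolute()].
#' @param path output path.
#' @export
write_ecc <- function(ecc, path) {
  ph <- assign_phenotype(ecc)
  df <- data.frame(sample_id = rownames(ecc$proportions),
                   as.data.frame(ecc$proportions, check.names = FALSE),
                   phenotype = ph$phenotype, dominance = ph$dominance,
                   converged = ecc$converged, n_iter = ecc$n_iter,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_signif(df, path)
}

#' @rdname write_ecc
#' @return `read_ecc()` returns an `ecc_matrix`.
#' @export
read_ecc <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  types <- setdiff(names(df), c("sample_id", "phenotype", "dominance",
                                "converged", "n_iter"))
  p <- as.matrix(df[, types, drop = FALSE])
  rownames(p) <- df$sample_id
  # 6-significant-digit TSV output can perturb row sums by ~1e-6
  ecc_matrix(p, converged = df$converged, n_iter = df$n_iter, tol = 1e-4)
}

#' Read a per-sample drug response AUC table
#'
#' @param path CSV/TSV with columns `sample_id`, `drug`, `auc`.
#' @return data.frame with those columns.
#' @export
read_drug_response <- function(path) {
  df <- read_table_auto(path)
  need <- c("sample_id", "drug", "auc")
  if (!all(need %in% names(df)))
    stop("drug table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$auc)) stop("auc must be numeric")
  df[, need]
}

#' Read a survival table
#'
#' @param path CSV/TSV with columns `sample_id`, `time`, `event` and
#'   optionally `group`.
#' @return data.frame with `time >= 0` and `event` in 0/1.
#' @export
read_survival <- function(path) {
  df <- read_table_auto(path)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  if (any(df$time < 0)) stop("negative survival time")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df
}

#' Write an association result table as TSV
#'
#' @param tbl a data.frame (e.g. from [univariate_assoc()] or
#'   [ecc_drug_association()]).
#' @param path output path.
#' @export
write_association <- function(tbl, path) write_tsv_signif(tbl, path)
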