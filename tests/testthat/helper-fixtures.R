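# Shared fixtures, all generated in code.

quiet_deconvolute <- function(...) suppressMessages(deconvolute(...))

# small, fast synthetic atlas for unit tests
small_cells <- function(seed = 42L)
  generate_synthetic_atlas(atlas_sim_config(
    n_types = 4, n_subjects = 2, n_genes = 120, markers_per_type = 6,
    cells_per_type_per_subject = 15, seed = seed))

# bind pseudobulk count vectors into a genes x samples matrix
pb_matrix <- function(pbs) {
  m <- do.call(cbind, lapply(pbs, `[[`, "bulk_counts"))
  colnames(m) <- sprintf("pb_%03d", seq_along(pbs))
  m
}

# hand-built atlas with disjoint-support (orthogonal) signatures
orthogonal_atlas <- function(K = 3, g_per_type = 5, cell_size = 1000) {
  G <- K * g_per_type
  genes <- sprintf("g%03d", seq_len(G))
  types <- sprintf("T%d", seq_len(K))
  theta <- matrix(0, G, K, dimnames = list(genes, types))
  for (k in seq_len(K))
    theta[(k - 1) * g_per_type + seq_len(g_per_type), k] <- 1 / g_per_type
  structure(list(gene_ids = genes, cell_types = types, theta = theta,
                 sigma2 = matrix(0, G, K, dimnames = list(genes, types)),
                 cell_size = setNames(rep(cell_size, K), types),
                 n_cells = setNames(rep(50L, K), types), n_subjects = 1L),
            class = "reference_atlas")
}

# independent textbook step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
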