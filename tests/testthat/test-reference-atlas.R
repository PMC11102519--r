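toy_cells <- function() {
  # 2 genes, 2 types, 2 subjects, 2 cells per (type, subject)
  counts <- cbind(c(10, 30), c(20, 40),   # A, s1
                  c(30, 10), c(50, 10),   # A, s2
                  c(5, 5),  c(15, 25),    # B, s1
                  c(0, 40), c(20, 20))    # B, s2
  rownames(counts) <- c("g1", "g2")
  annotated_cell_matrix(counts,
                        cell_type = rep(c("A", "B"), each = 4),
                        subject = rep(rep(c("s1", "s2"), each = 2), 2))
}

test_that("label merging relabels without touching counts", {
  cells <- small_cells()
  map <- c(type_01 = "T cell", type_02 = "T cell")
  merged <- merge_celltype_labels(cells, map)
  expect_identical(merged$counts, cells$counts)
  expect_equal(length(unique(merged$cell_type)),
               length(unique(cells$cell_type)) - 1)
  # identity mapping is a no-op
  idm <- setNames(unique(cells$cell_type), unique(cells$cell_type))
  expect_identical(merge_celltype_labels(cells, idm), cells)
  expect_error(merge_celltype_labels(cells, map[1], strict = TRUE),
               "unmapped")
})

test_that("collapsing fine labels yields the mapped number of types", {
  # 30 fine labels collapsed into 22 groups
  fine <- sprintf("fine_%02d", 1:30)
  coarse <- sprintf("coarse_%02d", c(1:22, 1:8))
  map <- setNames(coarse, fine)
  counts <- matrix(rpois(5 * 60, 5), 5, 60)
  cells <- annotated_cell_matrix(counts, rep(fine, each = 2), "s1")
  merged <- merge_celltype_labels(cells, map, strict = TRUE)
  expect_equal(length(unique(merged$cell_type)), 22L)
})

test_that("single-subject reference is degenerate: sigma2 = 0, theta = normalized means", {
  counts <- cbind(c(2, 8), c(4, 6), c(9, 1), c(7, 3))
  rownames(counts) <- c("g1", "g2")
  cells <- annotated_cell_matrix(counts, rep(c("A", "B"), each = 2), "s1")
  atl <- build_reference(cells, min_cells_per_type = 1)
  expect_true(all(atl$sigma2 == 0))
  mu_a <- rowMeans(counts[, 1:2])
  expect_equal(unname(atl$theta[, "A"]), unname(mu_a / sum(mu_a)))
  expect_equal(colSums(atl$theta), c(A = 1, B = 1))
})

test_that("two-subject reference equals direct mean/variance arithmetic", {
  cells <- toy_cells()
  atl <- build_reference(cells, min_cells_per_type = 1)
  # subject-level relative profiles of type A, by hand
  pa_s1 <- c(15, 35) / 50   # mean of (10,30),(20,40) normalized
  pa_s2 <- c(40, 10) / 50
  expect_equal(unname(atl$theta[, "A"]), unname((pa_s1 + pa_s2) / 2))
  expect_equal(unname(atl$sigma2[, "A"]),
               unname(apply(cbind(pa_s1, pa_s2), 1, var)))
  # cell_size: mean per-cell total counts
  expect_equal(unname(atl$cell_size["A"]), mean(c(40, 60, 40, 60)))
})

test_that("cell size averages per-cell library sizes", {
  counts <- cbind(c(60, 40), c(200, 100), c(30, 30), c(30, 30))
  rownames(counts) <- c("g1", "g2")
  cells <- annotated_cell_matrix(counts, rep(c("A", "B"), each = 2), "s1")
  atl <- build_reference(cells, min_cells_per_type = 1)
  expect_equal(unname(atl$cell_size["A"]), 200)
})

test_that("atlas is invariant to cell order and duplicated subjects kill sigma2", {
  cells <- small_cells()
  atl <- build_reference(cells)
  set.seed(9)
  perm <- sample(ncol(cells$counts))
  shuffled <- annotated_cell_matrix(cells$counts[, perm],
                                    cells$cell_type[perm],
                                    cells$subject[perm])
  atl2 <- build_reference(shuffled)
  expect_equal(atl2$theta, atl$theta)
  expect_equal(atl2$sigma2, atl$sigma2)
  expect_equal(atl2$cell_size, atl$cell_size)

  # identical subjects (duplicated cells) -> zero cross-subject variance
  dup <- annotated_cell_matrix(cbind(cells$counts, cells$counts),
                               rep(cells$cell_type, 2),
                               c(rep("d1", ncol(cells$counts)),
                                 rep("d2", ncol(cells$counts))))
  expect_true(all(build_reference(dup)$sigma2 < 1e-12))
})

test_that("gene subsetting commutes with building after renormalization", {
  # exact for a single-subject atlas (one relative profile per type);
  # with several subjects the per-subject renormalization makes the
  # identity hold only approximately
  cells <- small_cells()
  one <- annotated_cell_matrix(cells$counts, cells$cell_type, "s1")
  atl <- build_reference(one)
  keep <- rownames(cells$counts)[1:60]
  sub_cells <- annotated_cell_matrix(cells$counts[keep, ],
                                     cells$cell_type, "s1")
  atl_sub <- build_reference(sub_cells)
  shared <- atl_sub$gene_ids
  renorm <- sweep(atl$theta[shared, ], 2, colSums(atl$theta[shared, ]), "/")
  expect_equal(atl_sub$theta, renorm, tolerance = 1e-12)

  atl_m <- build_reference(cells)
  sub_m <- build_reference(annotated_cell_matrix(cells$counts[keep, ],
                                                 cells$cell_type,
                                                 cells$subject))
  renorm_m <- sweep(atl_m$theta[shared, ], 2,
                    colSums(atl_m$theta[shared, ]), "/")
  expect_equal(sub_m$theta, renorm_m, tolerance = 0.05)
})

test_that("small types are dropped with a warning and K >= 2 is enforced", {
  cells <- small_cells()
  ct <- cells$cell_type
  ct[ct == "type_04"][-(1:3)] <- "type_01"  # leave 3 cells of type_04
  few <- annotated_cell_matrix(cells$counts, ct, cells$subject)
  expect_warning(atl <- build_reference(few, min_cells_per_type = 10),
                 "type_04")
  expect_false("type_04" %in% atl$cell_types)
  one <- annotated_cell_matrix(cells$counts, rep("A", ncol(cells$counts)),
                               cells$subject)
  expect_error(build_reference(one), "fewer than 2")
})

test_that("atlas serialization round-trips", {
  atl <- build_reference(small_cells())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(atl, path)
  back <- read_atlas(path)
  expect_equal(back$theta, atl$theta)
  expect_equal(back$sigma2, atl$sigma2)
  expect_equal(back$cell_size, atl$cell_size)
  expect_equal(back$n_subjects, atl$n_subjects)
})
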