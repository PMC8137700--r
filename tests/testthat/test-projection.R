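test_that("aligning the atlas's own cells needs almost no correction", {
  built <- test_atlas()
  atlas <- built$atlas
  set.seed(44)
  cells <- sample(colnames(atlas$integrated), 120)
  qry <- expression_dataset(
    pmax(atlas$integrated[, cells], 0),
    species = "mouse")
  qry$normalized <- as(atlas$integrated[, cells], "CsparseMatrix")
  al <- with_quiet(align_query(qry, atlas))
  corr <- abs(al$corrected - as.matrix(qry$normalized[atlas$var_genes, ]))
  expect_lt(mean(corr), 0.05)
})

test_that("atlas genes missing from the query are zero-filled and the atlas is immutable", {
  built <- test_atlas()
  atlas <- built$atlas
  raw <- test_raw_datasets()[["dataset4"]]
  drop <- atlas$var_genes[1:10]
  q <- subset_dataset(raw, genes = setdiff(rownames(raw$counts), drop))
  q <- with_quiet(normalize_counts(q))
  before <- atlas_checksum(atlas)
  al <- with_quiet(align_query(q, atlas))
  expect_true(all(al$corrected[drop, ] == 0))
  expect_identical(atlas_checksum(atlas), before)
  expect_identical(atlas$pca_embeddings, test_atlas()$atlas$pca_embeddings)
})

test_that("embedding is an exact linear map with a deterministic UMAP transform", {
  atlas <- test_atlas()$atlas
  cells <- colnames(atlas$integrated)[1:25]
  emb <- embed_query(atlas$integrated[, cells], atlas)
  expect_lt(max(abs(emb$pca_coords - atlas$pca_embeddings[cells, ])), 1e-6)
  expect_lt(max(abs(emb$ica_coords - atlas$ica_embeddings[cells, ])), 1e-6)

  # degenerate all-zero profile: defined and finite
  zero <- matrix(0, length(atlas$var_genes), 1,
                 dimnames = list(atlas$var_genes, "empty"))
  ez <- embed_query(zero, atlas)
  expected <- t(-atlas$center / atlas$scale) %*% atlas$pca_rotation
  expect_equal(as.numeric(ez$pca_coords), as.numeric(expected),
               tolerance = 1e-8)
  expect_true(all(is.finite(ez$umap_coords)))

  # repeated transform of the same query is identical
  e2 <- embed_query(atlas$integrated[, cells], atlas)
  expect_identical(emb$umap_coords, e2$umap_coords)

  bad <- zero[1:50, , drop = FALSE]
  expect_error(embed_query(bad, atlas), "gene space")
})

test_that("projection is stable under query cell permutation", {
  atlas <- test_atlas()$atlas
  raw <- test_raw_datasets()[["dataset5"]]
  q <- subset_dataset(raw, cells = colnames(raw$counts)[1:80])
  res <- with_quiet(project(q, atlas, filter = FALSE))
  set.seed(9)
  perm <- sample(colnames(q$counts))
  res_p <- with_quiet(project(subset_dataset(q, cells = perm), atlas,
                              filter = FALSE))
  expect_equal(res_p$pca_coords[rownames(res$pca_coords), ],
               res$pca_coords, tolerance = 1e-8)
  expect_equal(
    res_p$predicted_label[match(rownames(res$pca_coords),
                                rownames(res_p$pca_coords))],
    res$predicted_label)
})

test_that("direct mode handles tiny queries and mode guards fire", {
  atlas <- test_atlas()$atlas
  raw <- test_raw_datasets()[["dataset6"]]
  tiny <- subset_dataset(raw, cells = colnames(raw$counts)[1:20])
  res <- with_quiet(project(tiny, atlas, direct = TRUE, filter = FALSE))
  expect_equal(nrow(res$pca_coords), 20)
  expect_true(all(res$predicted_label %in% atlas$subtype_order))
  expect_true(res$direct)

  expect_error(with_quiet(project(tiny, atlas, ortho = TRUE, filter = FALSE)),
               "human")

  # cell count is conserved when the filter is off
  res2 <- with_quiet(project(subset_dataset(raw,
                                            cells = colnames(raw$counts)[1:60]),
                             atlas, filter = FALSE))
  expect_equal(nrow(res2$pca_coords), 60)
})

test_that("classification follows the majority vote with stated tie-breaks", {
  emb <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(5, 5))
  rownames(emb) <- paste0("r", 1:4)
  atlas <- stub_atlas(emb, c("Tex", "Tex", "Tpex", "Treg"),
                      subtype_order = c("Tex", "Tpex", "Treg"))
  # coincident query, k = 1: that cell's label with confidence 1
  q1 <- matrix(c(5, 5), 1, 2, dimnames = list("q1", NULL))
  out1 <- classify_cells(q1, atlas, k = 1)
  expect_equal(out1$label, "Treg")
  expect_equal(out1$confidence, 1)

  # neighbors (Tex, Tex, Tpex) at k = 3: Tex with confidence 2/3
  q2 <- matrix(c(0.05, 0.03), 1, 2, dimnames = list("q2", NULL))
  out2 <- classify_cells(q2, atlas, k = 3)
  expect_equal(out2$label, "Tex")
  expect_equal(out2$confidence, 2 / 3)

  # 2-2 tie between Tex and Tpex: broken towards smaller mean distance
  emb3 <- rbind(c(0, 0), c(0.4, 0), c(0.1, 0.1), c(0.5, 0.1))
  rownames(emb3) <- paste0("r", 1:4)
  atlas3 <- stub_atlas(emb3, c("Tex", "Tex", "Tpex", "Tpex"),
                       subtype_order = c("Tpex", "Tex"))
  out3 <- classify_cells(matrix(c(0.05, 0.02), 1, 2,
                                dimnames = list("q", NULL)),
                         atlas3, k = 4)
  expect_equal(out3$label, "Tex")

  expect_error(classify_cells(q1, atlas, k = 10), "k exceeds")

  # low-confidence cells become unassigned when a floor is set
  out4 <- classify_cells(q2, atlas, k = 3, min_conf = 0.9)
  expect_equal(out4$label, "unassigned")
})

test_that("cells drawn from one subtype's distribution classify to it", {
  built <- test_atlas()
  atlas <- built$atlas
  # a fresh 500-cell batch generated from a single subtype's distribution
  # (same gene structure as the atlas, its own batch offset)
  qcfg <- simulation_config(
    seed = 42, n_datasets = 1, cells_per_dataset = 500,
    samples_per_dataset = 1,
    missing_subtype_map = list(dataset1 = paste0("subtype", c(1, 3, 4, 5))))
  q <- generate_synthetic_atlas_inputs(qcfg)[[1]]
  res <- with_quiet(project(q, atlas, filter = FALSE))
  expect_gte(mean(res$predicted_label == "subtype2"), 0.95)
})
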