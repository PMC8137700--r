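test_that("variable-gene selection enforces frequency and exclusion rules", {
  raw <- test_raw_datasets()[["dataset1"]]
  ds <- with_quiet(normalize_counts(raw))
  vg <- select_variable_genes(ds, n = 200)
  expect_length(vg, 200)
  det <- Matrix::rowSums(ds$counts[vg, ] > 0) / ncol(ds$counts)
  expect_true(all(det <= 0.90 & det >= 0.001))

  # a ubiquitous gene (detected in >90% of cells) never enters the list
  ubiquitous <- names(which(
    Matrix::rowSums(ds$counts > 0) / ncol(ds$counts) > 0.95))
  expect_length(intersect(vg, ubiquitous), 0)

  # explicit exclusion wins regardless of dispersion
  vg2 <- select_variable_genes(ds, n = 200, exclude_genes = vg[1:5])
  expect_length(intersect(vg2, vg[1:5]), 0)
})

test_that("variable-gene ranking follows standardized variance", {
  set.seed(3)
  n <- 500
  # gene A: strongly bimodal; gene B: flat; padding genes span a range of
  # means so the mean-variance trend is well determined
  a <- rpois(n, ifelse(seq_len(n) %% 2 == 0, 100, 2))
  b <- rpois(n, 10)
  pad <- t(sapply(1:60, function(i) rpois(n, 2 + i)))
  m <- rbind(A = a, B = b, pad)
  rownames(m) <- c("A", "B", paste0("p", 1:60))
  colnames(m) <- paste0("c", 1:n)
  ds <- with_quiet(normalize_counts(expression_dataset(m)))
  vg <- select_variable_genes(ds, n = 1, min_frac = 0, max_frac = 1)
  expect_equal(vg, "A")
})

test_that("consensus ranking prioritizes shared genes, then dataset size", {
  l1 <- c("a", "b", "c"); l2 <- c("b", "c", "d"); l3 <- c("c", "e", "f")
  out <- consensus_variable_genes(list(l1, l2, l3), c(100, 200, 50), n = 4)
  expect_equal(out[1], "c")               # in 3 lists
  expect_equal(out[2], "b")               # in 2 lists
  # count ties broken by total cells of the supporting datasets:
  # d (200) beats e/f (50) and a (100) beats e/f
  expect_equal(out[3:4], c("d", "a"))

  two <- consensus_variable_genes(list(l1, l1), c(10, 10), n = 800)
  expect_equal(sort(two), sort(l1))
})

test_that("anchors score copies at 1 and reject disjoint populations", {
  set.seed(11)
  A <- block_batch(list(c(2, 0), c(0, 2)), 300, 150, "a")
  B <- A; colnames(B) <- paste0("b", 1:150)
  anc <- find_anchors(A, B, rownames(A))
  # every cell anchored to its copy, and only to its copy, with score 1
  expect_equal(nrow(anc$pairs), 150)
  expect_true(all(anc$pairs$cell_a == sub("^b", "a", anc$pairs$cell_b)))
  expect_true(all(anc$pairs$score == 1))

  # batches drawn from disjoint subtype means >= 5 log-units apart
  set.seed(12)
  Ad <- block_batch(list(c(5, 0, 0, 0), c(0, 5, 0, 0)), 300, 150, "a")
  Bd <- block_batch(list(c(0, 0, 5, 0), c(0, 0, 0, 5)), 300, 150, "b")
  ad <- find_anchors(Ad, Bd, rownames(Ad))
  fd <- with_quiet(filter_anchors(ad, 0.8))
  expect_gte(1 - nrow(fd$pairs) / max(1, nrow(ad$pairs)), 0.90)
  if (nrow(fd$pairs) > 0) expect_gte(min(fd$pairs$score), 0.8)

  # percentile mode cuts at the requested quantile of observed scores
  fp <- with_quiet(filter_anchors(ad, 0.8, mode = "percentile"))
  expect_lte(nrow(fp$pairs), ceiling(0.2 * nrow(ad$pairs)) + 1)
})

test_that("integration leaves identical batches untouched and removes additive shifts", {
  set.seed(21)
  base <- rnorm(300, 1, 1)
  A <- matrix(base, 300, 150) + matrix(rnorm(300 * 150, 0, 0.3), 300, 150)
  dimnames(A) <- list(paste0("g", 1:300), paste0("a", 1:150))
  B <- A; colnames(B) <- paste0("b", 1:150)
  genes <- rownames(A)
  batches <- list(A = A, B = B)
  anc <- with_quiet(pairwise_anchors(batches, genes))
  intg <- with_quiet(integrate_datasets(batches, anc, genes))
  expect_lt(max(abs(intg[, colnames(B)] - B)), 1e-6)
  expect_equal(nrow(intg), length(genes))

  # additive per-gene shift is removed to well under 5% of its size
  set.seed(22)
  A2 <- matrix(base, 300, 150) + matrix(rnorm(300 * 150, 0, 0.05), 300, 150)
  dimnames(A2) <- dimnames(A)
  delta <- 1
  B2 <- A2 + delta + matrix(rnorm(300 * 150, 0, 0.05), 300, 150)
  colnames(B2) <- paste0("b", 1:150)
  b2 <- list(A = A2, B = B2)
  intg2 <- with_quiet(integrate_datasets(b2, with_quiet(pairwise_anchors(b2, genes)),
                                         genes))
  mean_diff <- abs(rowMeans(intg2[, colnames(A2)]) -
                     rowMeans(intg2[, colnames(B2)]))
  expect_lt(max(mean_diff), 0.05 * delta)

  # a batch with no surviving anchors aborts with its name
  empty <- anc
  empty[[1]]$pairs <- empty[[1]]$pairs[0, ]
  expect_error(with_quiet(integrate_datasets(batches, empty, genes)), "B")
})

test_that("the fitted reference reproduces its own embeddings and recovers planted programs", {
  atlas <- test_atlas()$atlas
  Xs <- t((atlas$integrated - atlas$center) / atlas$scale)
  expect_lt(max(abs(Xs %*% atlas$pca_rotation - atlas$pca_embeddings)), 1e-6)
  # per-component means of reference embeddings are zero
  expect_lt(max(abs(colMeans(atlas$pca_embeddings))), 1e-8)
  expect_equal(ncol(atlas$ica_rotation), 50)
  # sign convention: the largest-|loading| gene of each component is positive
  tops <- apply(atlas$ica_rotation, 2, function(v) v[which.max(abs(v))])
  expect_true(all(tops > 0))

  # blind-source separation: 5 sparse gene programs mixed linearly
  set.seed(7)
  n_cells <- 600; n_genes <- 300
  S <- matrix(rnorm(n_cells * 5)^3, n_cells, 5)
  L <- matrix(0, 5, n_genes)
  for (k in 1:5) L[k, ((k - 1) * 30 + 1):(k * 30)] <- runif(30, 0.5, 1.5)
  X <- S %*% L + matrix(rnorm(n_cells * n_genes, 0, 0.05), n_cells, n_genes)
  mat <- t(X)
  dimnames(mat) <- list(paste0("g", 1:n_genes), paste0("c", 1:n_cells))
  fit <- fit_reference(mat, n_pc = 20, n_ica = 5, umap_seed = 1)
  cors <- abs(cor(fit$ica_embeddings, S))
  perm <- numeric(5); used <- integer(0)
  for (i in order(-apply(cors, 1, max))) {
    j <- setdiff(order(-cors[i, ]), used)[1]
    perm[i] <- j; used <- c(used, j)
  }
  expect_gt(mean(cors[cbind(1:5, perm)]), 0.9)
})

test_that("the stored UMAP transform reproduces the atlas's own layout", {
  atlas <- test_atlas()$atlas
  st <- embed_query(atlas$integrated, atlas)
  d <- sqrt(rowSums((st$umap_coords - atlas$umap_embeddings)^2))
  expect_gte(mean(d <= 0.5), 0.95)
})

test_that("reference fitting is deterministic given a seed", {
  set.seed(5)
  m <- named_matrix(rnorm(200 * 80, 2, 1), 200, 80)
  a1 <- fit_reference(m, n_pc = 10, n_ica = 5, umap_seed = 3)
  a2 <- fit_reference(m, n_pc = 10, n_ica = 5, umap_seed = 3)
  expect_identical(atlas_checksum(a1), atlas_checksum(a2))
})

test_that("SNN clustering separates well-spaced blobs and is seed-stable", {
  set.seed(31)
  emb <- rbind(matrix(rnorm(300 * 2, 0, 1), 300, 2),
               matrix(rnorm(300 * 2, 10, 1), 300, 2))
  rownames(emb) <- paste0("c", 1:600)
  stub <- structure(list(pca_embeddings = emb), class = "reference_atlas")
  cl <- cluster_snn(stub, resolution = 0.1, k_param = 20, reduction = "pca")
  expect_equal(length(unique(cl)), 2)
  # ids are 0-based and ordered by decreasing size
  expect_setequal(unique(cl), c(0L, 1L))
  # the split matches the generating blobs exactly
  expect_equal(length(unique(cl[1:300])), 1)
  expect_equal(length(unique(cl[301:600])), 1)
  cl2 <- cluster_snn(stub, resolution = 0.1, k_param = 20, reduction = "pca")
  expect_identical(cl, cl2)
  expect_error(cluster_snn(stub, k_param = 600, reduction = "pca"), "k_param")
})

test_that("ICA annotation sums loadings with an absolute value", {
  rot <- matrix(c(2, -1, 0.5, 0.2), 2, 2,
                dimnames = list(c("g1", "g2"), c("ICA1", "ICA2")))
  stub <- structure(list(ica_rotation = rot), class = "reference_atlas")
  sigs <- list(both = c("g1", "g2"), single = "g1",
               absent = c("nope1", "nope2"))
  tab <- suppressWarnings(annotate_ica(stub, sigs, top = 3))
  expect_equal(tab$score[tab$component == "ICA1" & tab$signature == "both"], 1)
  expect_equal(tab$score[tab$component == "ICA1" & tab$signature == "single"], 2)
  expect_false("absent" %in% tab$signature)
  # sign-flipping a component leaves scores unchanged
  stub2 <- stub; stub2$ica_rotation[, 1] <- -rot[, 1]
  tab2 <- suppressWarnings(annotate_ica(stub2, sigs["both"], top = 3))
  expect_equal(tab2$score[tab2$component == "ICA1"],
               tab$score[tab$component == "ICA1" & tab$signature == "both"])
})

test_that("integration reduces batch structure while preserving subtypes", {
  skip_if_not_installed("cluster")
  built <- test_atlas()
  truth <- built$truth
  genes <- built$atlas$var_genes
  merged_raw <- with_quiet(merge_datasets(built$datasets,
                                          layer = "normalized"))
  cells <- truth$cell_id
  raw_mat <- t(as.matrix(merged_raw$normalized[genes, cells]))
  int_mat <- t(built$atlas$integrated[, cells])
  pc_raw <- prcomp(raw_mat, rank. = 20)$x
  pc_int <- prcomp(int_mat, rank. = 20)$x
  sil <- function(emb, labels) {
    mean(cluster::silhouette(as.integer(factor(labels)), dist(emb))[, 3])
  }
  idx <- seq(1, length(cells), by = 3)   # subsample for the distance matrix
  batch_before <- sil(pc_raw[idx, ], truth$dataset_id[idx])
  batch_after <- sil(pc_int[idx, ], truth$dataset_id[idx])
  sub_before <- sil(pc_raw[idx, ], truth$true_subtype[idx])
  sub_after <- sil(pc_int[idx, ], truth$true_subtype[idx])
  expect_lt(batch_after, batch_before)
  expect_gte(sub_after, 0.9 * sub_before)
})
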