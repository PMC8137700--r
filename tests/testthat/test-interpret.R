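test_that("composition tables report fractions, zeros, and sum to one", {
  labs <- list(WT = c(rep("Tex", 90), rep("Tpex", 10)),
               KO = c(rep("Tex", 30), rep("Naive", 70)))
  comp <- subtype_composition(labs, subtypes = c("Tex", "Tpex", "Naive", "Treg"))
  wt <- comp[comp$condition == "WT", ]
  expect_equal(wt$fraction[wt$subtype == "Tex"], 0.9)
  expect_equal(wt$fraction[wt$subtype == "Tpex"], 0.1)
  expect_equal(wt$n[wt$subtype == "Treg"], 0L)
  sums <- tapply(comp$fraction, comp$condition, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(subtype_composition(list(WT = character(0))), "empty")
})

test_that("fold changes follow the min-cell rule and flag infinities", {
  labs <- list(case = c(rep("Tex", 50), rep("Tpex", 20), rep("Rare", 10),
                        rep("New", 20)),
               control = c(rep("Tex", 20), rep("Tpex", 60), rep("Rare", 15)))
  comp <- subtype_composition(labs,
                              subtypes = c("Tex", "Tpex", "Rare", "New"))
  fc <- composition_fold_change(comp, "case", "control")
  expect_equal(fc$fold_change[fc$subtype == "Tex"], 0.5 / 0.210526315789474,
               tolerance = 1e-9)
  expect_equal(fc$status[fc$subtype == "Rare"], "omitted_min_cells")
  expect_true(is.na(fc$fold_change[fc$subtype == "Rare"]))
  expect_equal(fc$status[fc$subtype == "New"], "omitted_min_cells")

  # a subtype present only in the case is flagged infinite, not an error
  labs2 <- list(case = c(rep("Tex", 60), rep("Only", 60)),
                control = rep("Tex", 120))
  fc2 <- composition_fold_change(
    subtype_composition(labs2, subtypes = c("Tex", "Only")), "case", "control")
  expect_equal(fc2$status[fc2$subtype == "Only"], "infinite")
  expect_true(is.infinite(fc2$fold_change[fc2$subtype == "Only"]))

  # identical conditions give fold change 1 everywhere
  labs3 <- list(a = rep(c("Tex", "Tpex"), 50), b = rep(c("Tex", "Tpex"), 50))
  fc3 <- composition_fold_change(subtype_composition(labs3), "a", "b")
  expect_true(all(fc3$fold_change == 1))

  # arithmetic check: 0.5 vs 0.2 -> 2.5
  labs4 <- list(case = c(rep("A", 50), rep("B", 50)),
                control = c(rep("A", 20), rep("B", 80)))
  fc4 <- composition_fold_change(subtype_composition(labs4), "case", "control")
  expect_equal(fc4$fold_change[fc4$subtype == "A"], 2.5)
})

test_that("discriminant dimensions are ranked, corrected, and symmetric", {
  set.seed(1)
  ref <- matrix(rnorm(1000 * 50), 1000, 50,
                dimnames = list(paste0("r", 1:1000), paste0("ICA", 1:50)))
  qry <- matrix(rnorm(500 * 50), 500, 50,
                dimnames = list(paste0("q", 1:500), paste0("ICA", 1:50)))

  # identical sides: all statistics zero, corrected p = 1
  same <- find_discriminant_dimensions(ref, ref)
  expect_true(all(same$statistic == 0))
  expect_true(all(same$p_adjusted == 1))

  # a 3-unit shift of one dimension ranks first with the closed-form KS D
  shifted <- qry; shifted[, 7] <- shifted[, 7] + 3
  tab <- find_discriminant_dimensions(shifted, ref)
  expect_equal(tab$dimension[1], "ICA7")
  expect_lt(abs(tab$statistic[1] - (2 * pnorm(1.5) - 1)), 0.05)
  expect_lt(tab$p_adjusted[1], 0.05)
  expect_true(tab$flagged[1])

  # KS statistic is symmetric in query/baseline
  rev <- find_discriminant_dimensions(ref, shifted)
  expect_equal(sort(rev$statistic), sort(tab$statistic))

  # Bonferroni correction is monotone and capped at 1
  expect_true(all(tab$p_adjusted <= 1))
  expect_true(all(diff(tab$p_adjusted[order(tab$p_value)]) >= 0))

  # Welch t variant runs and flags the same planted dimension
  tt <- find_discriminant_dimensions(shifted, ref, test = "t")
  expect_equal(tt$dimension[1], "ICA7")

  expect_error(find_discriminant_dimensions(qry[1:5, ], ref), "query")
})

test_that("subtype-restricted dimension tests use predicted labels", {
  set.seed(2)
  ica_q <- matrix(rnorm(200 * 10), 200, 10,
                  dimnames = list(paste0("q", 1:200), paste0("ICA", 1:10)))
  ica_b <- matrix(rnorm(200 * 10), 200, 10,
                  dimnames = list(paste0("b", 1:200), paste0("ICA", 1:10)))
  lab_q <- rep(c("Tex", "Tpex"), each = 100)
  lab_b <- rep(c("Tex", "Tpex"), each = 100)
  ica_q[lab_q == "Tex", 3] <- ica_q[lab_q == "Tex", 3] + 3
  qres <- stub_result(ica = ica_q, labels = lab_q)
  bres <- stub_result(ica = ica_b, labels = lab_b)
  tex <- find_discriminant_dimensions(qres, bres, subset = "Tex")
  tpex <- find_discriminant_dimensions(qres, bres, subset = "Tpex")
  expect_equal(tex$dimension[1], "ICA3")
  expect_true(tex$flagged[1])
  expect_false(any(tpex$flagged))
})

test_that("discriminant genes control the null and find a planted shift", {
  set.seed(3)
  n_genes <- 200; n_cells <- 300
  base <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells)
  dimnames(base) <- list(paste0("g", 1:n_genes), paste0("c", 1:n_cells))
  norm <- with_quiet(normalize_counts(expression_dataset(base)))$normalized

  null_hits <- vapply(1:20, function(s) {
    set.seed(s)
    pick <- sample(n_cells, n_cells / 2)
    a <- stub_result(normalized = norm[, pick],
                     labels = rep("Tex", length(pick)))
    b <- stub_result(normalized = norm[, -pick],
                     labels = rep("Tex", n_cells - length(pick)))
    tab <- find_discriminant_genes(a, b, "Tex", min_cells = 25)
    sum(tab$p_adjusted < 0.05)
  }, numeric(1))
  expect_gte(mean(null_hits == 0), 0.95)

  # one gene shifted +2 log-units ranks first, adjusted p < 1e-6,
  # with a positive logFC (higher in cond_a)
  set.seed(4)
  na <- 200
  ma <- with_quiet(normalize_counts(expression_dataset(
    named_matrix(rpois(n_genes * na, 5), n_genes, na))))$normalized
  mb <- with_quiet(normalize_counts(expression_dataset(
    named_matrix(rpois(n_genes * na, 5), n_genes, na,
                 cell_prefix = "d"))))$normalized
  ma_d <- as.matrix(ma); ma_d["g7", ] <- ma_d["g7", ] + 2
  a <- stub_result(normalized = as(ma_d, "CsparseMatrix"),
                   labels = rep("Tex", na))
  b <- stub_result(normalized = mb, labels = rep("Tex", na))
  tab <- find_discriminant_genes(a, b, "Tex")
  expect_equal(tab$gene[1], "g7")
  expect_lt(tab$p_adjusted[1], 1e-6)
  expect_gt(tab$logFC[1], 0)

  expect_error(find_discriminant_genes(
    stub_result(normalized = ma[, 1:5], labels = rep("Tex", 5)), b, "Tex"),
    "min_cells")
})

test_that("marker consensus attributes genes, caps panels, and clusters by subtype", {
  studies <- paste0("study", 1:6)
  subtypes <- c("Tex", "Tpex", "Treg")
  markers <- list(Tex = paste0("tex", 1:10), Tpex = paste0("tpex", 1:10),
                  Treg = paste0("treg", 1:10))
  de <- purrr::map_dfr(studies, function(s)
    purrr::map_dfr(subtypes, function(st)
      tibble::tibble(study = s, subtype = st, gene = markers[[st]],
                     p_adjusted = 1e-4, n_cells = 100)))
  # a gene supported for Treg in 5 studies but Tex in 3 goes to Treg
  de <- dplyr::bind_rows(
    de,
    tibble::tibble(study = studies[1:5], subtype = "Treg", gene = "shared",
                   p_adjusted = 1e-4, n_cells = 100),
    tibble::tibble(study = studies[1:3], subtype = "Tex", gene = "shared",
                   p_adjusted = 1e-5, n_cells = 100),
    tibble::tibble(study = studies[1:3], subtype = "Tex", gene = "weak",
                   p_adjusted = 1e-4, n_cells = 100))
  all_genes <- c(unlist(markers), "shared", "weak")
  expr <- purrr::map_dfr(studies, function(s)
    purrr::map_dfr(subtypes, function(st)
      tibble::tibble(study = s, subtype = st, gene = all_genes,
                     mean_expr = ifelse(all_genes %in% markers[[st]], 3, 0.3) +
                       rnorm(length(all_genes), 0, 0.01))))
  out <- marker_consensus(de, expr, atlas_var_genes = all_genes)
  expect_equal(out$panel$subtype[out$panel$gene == "shared"], "Treg")
  expect_false("weak" %in% out$panel$gene)   # only 3 supporting studies
  expect_true(all(table(out$panel$subtype) <= 25))

  # columns cluster perfectly by subtype at the C = 3 cut
  skip_if_not_installed("mclust")
  col_subtype <- sub("\\..*$", "", colnames(out$profile))
  ari <- mclust::adjustedRandIndex(out$col_clusters[colnames(out$profile)],
                                   col_subtype)
  expect_equal(ari, 1)

  # result is invariant to the input order of DE tables
  out2 <- marker_consensus(de[sample(nrow(de)), ], expr,
                           atlas_var_genes = all_genes)
  expect_identical(out$panel, out2$panel)
  expect_equal(out$profile, out2$profile)
})

test_that("marker profiles rescale each gene by its maximum", {
  m <- rbind(a = c(2, 4, 1, 0), b = c(0, 0, 0, 0), c = c(1, 1, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  out <- normalized_marker_profile(m)
  expect_equal(unname(out["a", ]), c(0.5, 1, 0.25, 0))
  expect_equal(unname(out["b", ]), rep(0, 4))
  expect_true(all(apply(out[c("a", "c"), ], 1, max) == 1))
  expect_false(anyNA(out))
  sub <- normalized_marker_profile(m, subtypes = c("s1", "s2"))
  expect_equal(unname(sub["a", ]), c(0.5, 1))
})
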