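# tiny handcrafted sparse dataset for exact QC-boundary checks
mk_sn <- function(counts, meta = NULL) {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  m <- methods::as(m, "CsparseMatrix")
  if (is.null(meta))
    meta <- data.frame(barcode = rownames(counts),
                       sample = "S1", diagnosis = "case", sex = "M", age = 70,
                       row.names = rownames(counts))
  structure(list(counts = m, nucleus_meta = meta), class = "sn_dataset")
}

test_that("nucleus and gene QC enforce the stated bounds", {
  set.seed(30)
  n_nuc <- 60; n_g <- 40
  base <- matrix(rpois(n_nuc * n_g, 40), n_nuc,
                 dimnames = list(sprintf("BC%02d", 1:n_nuc),
                                 c(sprintf("g%02d", 1:(n_g - 2)),
                                   "MT-ND1", "MT-CO1")))
  # nucleus 1: just under the UMI bound
  base[1, ] <- 0; base[1, 1:20] <- 50; base[1, 1] <- 49 + 1    # 999 + rest
  base[1, ] <- 0; base[1, 1:10] <- 99; base[1, 11] <- 9        # total 999
  # nucleus 2: 12% mitochondrial
  base[2, c("MT-ND1", "MT-CO1")] <- round(0.12 / 0.88 * sum(base[2, 1:38]))
  # gene g01 detected in exactly 5 nuclei, g02 in 6 (beyond always-on rows)
  base[, "g01"] <- 0; base[3:7, "g01"] <- 5
  base[, "g02"] <- 0; base[3:8, "g02"] <- 5
  sn <- mk_sn(base)
  out <- qc_nuclei(sn, umi_lower = 1000, genes_lower = 10, min_nuclei = 6,
                   upper_quantile = 1)
  expect_false("BC01" %in% rownames(out$counts))   # 999 UMIs
  expect_false("BC02" %in% rownames(out$counts))   # >10% mito
  expect_false("g01" %in% colnames(out$counts))    # seen in 5 nuclei
  expect_true("g02" %in% colnames(out$counts))     # seen in 6 nuclei
  expect_true(all(Matrix::rowSums(out$counts) >= 1000))
})

test_that("normalization is depth-invariant and the embedding deterministic", {
  set.seed(31)
  counts <- matrix(rpois(30 * 50, 5), 30,
                   dimnames = list(sprintf("BC%02d", 1:30),
                                   sprintf("g%02d", 1:50)))
  counts[2, ] <- counts[1, ] * 3          # proportional nucleus
  sn <- mk_sn(counts)
  sn <- normalize_and_embed(sn, n_pcs = 5, n_hvg = 30)
  expect_equal(as.numeric(sn$norm[1, ]), as.numeric(sn$norm[2, ]),
               tolerance = 1e-10)
  sn2 <- mk_sn(counts)
  sn2 <- normalize_and_embed(sn2, n_pcs = 5, n_hvg = 30)
  expect_identical(sn$embedding, sn2$embedding)
  expect_error(normalize_and_embed(mk_sn(counts), n_pcs = 100), "n_pcs")
})

test_that("per-sample centering removes planted sample offsets", {
  fx <- small_gen()
  cfg <- fx$cfg
  cfg$sn_batch_sd <- 1.0       # strong planted per-sample offsets
  sn <- generate_snrna(cfg, fx$gen$truth)
  sn <- qc_nuclei(sn, genes_lower = 150)
  cdist <- function(emb) {
    cent <- apply(emb, 2, tapply, sn$nucleus_meta$sample, mean)
    mean(dist(cent))
  }
  off <- normalize_and_embed(sn, n_pcs = 10, integrate = FALSE)
  on <- normalize_and_embed(sn, n_pcs = 10, integrate = TRUE)
  expect_gt(cdist(off$embedding), 5 * cdist(on$embedding))
})

test_that("graph clustering resolves planted blobs and respects resolution", {
  set.seed(32)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.05), rnorm(n, cy, 0.05))
  emb <- rbind(blob(0, 0, 60), blob(5, 0, 60), blob(0, 5, 60))
  rownames(emb) <- sprintf("BC%03d", 1:180)
  truth <- rep(1:3, each = 60)
  cl <- cluster_nuclei(emb, k_neighbors = 15, resolution = 0.4, seed = 1)
  expect_equal(ari(cl, truth), 1)
  expect_equal(length(unique(cl)), 3)
  # labels ordered by decreasing size
  cl2 <- cluster_nuclei(rbind(blob(0, 0, 100), blob(5, 0, 30)),
                        k_neighbors = 10, seed = 1)
  expect_gt(sum(cl2 == "CL0"), sum(cl2 == "CL1"))
  # vanishing resolution collapses a connected graph to one community
  cloud <- matrix(rnorm(400), 200, dimnames = list(sprintf("N%03d", 1:200),
                                                   NULL))
  cl3 <- cluster_nuclei(cloud, k_neighbors = 15, resolution = 1e-4, seed = 1)
  expect_equal(length(unique(cl3)), 1)
  expect_identical(cluster_nuclei(emb, seed = 9), cluster_nuclei(emb, seed = 9))
  expect_error(cluster_nuclei(emb[1:10, ], k_neighbors = 10), "k_neighbors")
})

test_that("composition flags require both fold and significance", {
  set.seed(33)
  n <- 1000
  meta <- data.frame(sample = sample(paste0("S", 1:20), n, TRUE),
                     diagnosis = sample(c("case", "control"), n, TRUE),
                     sex = sample(c("M", "F"), n, TRUE))
  # cluster A drawn exclusively from one sample that is ~5% of nuclei
  meta$sample[1:50] <- "S1"
  meta$sample[51:n] <- sample(paste0("S", 2:20), n - 50, TRUE)
  labels <- c(rep("A", 50), rep("B", n - 50))
  res <- test_cluster_composition(labels, meta)
  row <- res[res$cluster == "A" & res$variable == "sample" & res$level == "S1", ]
  expect_gt(row$fold, 5)
  expect_true(row$flag)
  # balanced cluster: fold 1, unflagged
  row_b <- res[res$cluster == "B" & res$variable == "sex", ]
  expect_true(all(!row_b$flag))
  # large fold with non-significant p is not flagged (conjunction)
  meta2 <- data.frame(sample = c("X", "S1", rep(c("X", paste0("S", 1:19)),
                                                length.out = 398)),
                      diagnosis = "case", sex = "M")
  labels2 <- c("tiny", "tiny", rep("big", 398))
  res2 <- test_cluster_composition(labels2, meta2, vars = "sample")
  r2 <- res2[res2$cluster == "tiny" & res2$level == "X", ]
  expect_gt(r2$fold, 5)
  expect_gt(r2$p, 0.05)
  expect_false(r2$flag)
})

test_that("marker detection applies all three thresholds", {
  fx <- small_sn()
  mk <- find_cluster_markers(fx$sn, fx$clusters)
  expect_gt(sum(mk$is_marker), 0)
  expect_true(all(mk$fdr[mk$is_marker] < 0.05))
  expect_true(all(mk$logfc[mk$is_marker] > 0.5))
  expect_true(all(mk$pct_in[mk$is_marker] > 0.7))
  # planted markers of the dominant type are found
  ann <- annotate_clusters(mk, fx$truth$marker_sets,
                           background = colnames(fx$sn$norm))
  # every planted module cell type is found; cell types without planted
  # markers (endothelia/microglia nuclei here) stay unassigned
  expect_true(all(unique(fx$truth$module_celltype) %in% ann))
  expect_true(all(ann %in% c(unique(fx$truth$module_celltype), "unassigned")))
})

test_that("cluster annotation falls back to unassigned and breaks ties", {
  mt <- data.frame(cluster = rep(c("CL0", "CL1"), each = 3),
                   gene = c("a", "b", "c", "x", "y", "z"),
                   is_marker = TRUE)
  refs <- list(typeA = c("a", "b", "c"), typeB = c("zz1", "zz2"))
  bg <- c(letters, "x", "y", "z", "zz1", "zz2")
  ann <- annotate_clusters(mt, refs, background = bg)
  expect_equal(unname(ann["CL0"]), "typeA")
  expect_equal(unname(ann["CL1"]), "unassigned")
  # exact tie resolved alphabetically
  refs2 <- list(beta = c("a", "b"), alpha = c("a", "b"))
  ann2 <- annotate_clusters(mt[mt$cluster == "CL0", ], refs2,
                            background = bg)
  expect_equal(unname(ann2["CL0"]), "alpha")
})

test_that("hurdle DE tests only sufficiently detected genes and finds signal", {
  fx <- small_sn()
  truth <- fx$truth
  ann <- annotate_clusters(find_cluster_markers(fx$sn, fx$clusters),
                           truth$marker_sets,
                           background = colnames(fx$sn$norm))
  astro_cl <- names(ann)[ann == "astrocyte"][1]
  de <- hurdle_de(fx$sn, fx$clusters, astro_cl)
  in_cl <- names(fx$clusters)[fx$clusters == astro_cl]
  det <- Matrix::colMeans(fx$sn$norm[in_cl, ] > 0)
  expect_true(all(det[de$gene] >= 0.2))
  expect_false(any(names(det)[det < 0.2] %in% de$gene))
  # planted astrocyte DEGs recovered with the correct (positive) sign
  astro_genes <- names(truth$module_labels)[
    truth$module_labels %in% which(truth$module_celltype == "astrocyte")]
  planted <- names(truth$dx_effects$sn)[truth$dx_effects$sn > 0]
  planted <- intersect(intersect(planted, astro_genes), de$gene)
  sig <- de[planted, ]
  hits <- sig$fdr < 0.05 & sig$logfc > 0
  expect_gt(mean(hits), 0.7)
  expect_true(all(de$chisq >= 0))
})

test_that("pseudobulk summation is split-merge invariant and needs replicates", {
  fx <- small_sn()
  sn <- fx$sn
  labels <- fx$clusters
  cl <- names(sort(table(labels), decreasing = TRUE))[1]
  nuc <- names(labels)[labels == cl]
  meta <- sn$nucleus_meta[nuc, ]
  samples <- sort(unique(meta$sample))
  ind <- Matrix::sparseMatrix(i = match(meta$sample, samples),
                              j = seq_along(nuc), x = 1,
                              dims = c(length(samples), length(nuc)))
  pb <- as.matrix(ind %*% sn$counts[nuc, ])
  # splitting a sample's nuclei in two halves and re-merging is exact
  half <- seq_along(nuc) %% 2 == 0
  pb_split <- as.matrix(ind[, half, drop = FALSE] %*%
                          sn$counts[nuc[half], ]) +
    as.matrix(ind[, !half, drop = FALSE] %*% sn$counts[nuc[!half], ])
  expect_identical(pb, pb_split)
  # one-diagnosis input errors
  sn_bad <- sn
  sn_bad$nucleus_meta$diagnosis <- "case"
  expect_error(pseudobulk_de(sn_bad, labels, cl), "per diagnosis")
})

test_that("module scores separate planted programs across cell types", {
  fx <- small_sn()
  truth <- fx$truth
  astro <- names(truth$module_labels)[
    truth$module_celltype[truth$module_labels] == "astrocyte"]
  astro <- intersect(astro, colnames(fx$sn$norm))
  sc <- module_score(fx$sn, astro, seed = 4)
  expect_identical(sc, module_score(fx$sn, astro, seed = 4))
  tt <- fx$sn$nucleus_meta$true_type
  expect_gt(mean(sc[tt == "astrocyte"]), mean(sc[tt == "neuron"]))
  a <- aov(sc ~ factor(fx$clusters))
  expect_lt(summary(a)[[1]][["Pr(>F)"]][1], 1e-6)
  # plain mode over all genes is the per-nucleus mean expression
  sc_all <- module_score(fx$sn, colnames(fx$sn$norm), method = "plain")
  expect_equal(unname(sc_all), unname(Matrix::rowMeans(fx$sn$norm)))
  expect_error(module_score(fx$sn, c("nope1", "nope2")), "no detected genes")
})

test_that("module-DEG overlap equals the hypergeometric oracle", {
  set.seed(34)
  bg <- paste0("g", 1:500)
  degs <- data.frame(gene = sample(bg, 60),
                     logfc = rnorm(60), fdr = runif(60, 0, 0.04))
  mod <- sample(bg, 80)
  res <- overlap_module_cluster_degs(mod, degs, bg)
  expect_equal(res$p, hyper_brute(res$overlap, 80, 60, 500), tolerance = 1e-12)
  expect_equal(res$n_up + res$n_down, res$overlap)
  # disjoint: p = 1, split undefined
  degs2 <- data.frame(gene = bg[1:10], logfc = 1, fdr = 0.01)
  res2 <- overlap_module_cluster_degs(bg[11:20], degs2, bg)
  expect_equal(res2$p, 1)
  expect_true(is.na(res2$up_fraction))
  expect_error(overlap_module_cluster_degs(mod, degs, character(0)),
               "background")
})
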