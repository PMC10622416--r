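#' Reference cell-type marker panels
#'
#' Canonical human brain marker panel used for cluster annotation on real
#' data. For synthetic data, the planted marker sets from the generator's
#' ground truth play the same role.
#'
#' @return named list of character vectors.
#' @export
reference_marker_sets <- function() {
  list(astrocyte = c("GFAP", "AQP4"),
       endothelia = c("VWF", "PECAM1", "FLT1"),
       excitatory = c("NRGN", "SLC17A7"),
       inhibitory = c("GAD1", "GAD2"),
       microglia = c("C3", "CD74", "CSF1R"),
       neuron = c("GRIN1", "SNAP25", "SYT1"),
       oligodendrocyte = c("MBP", "MOBP", "PLP1"),
       OPC = c("CSPG4", "PDGFRA", "VCAN"),
       pericyte = c("PDE5A", "PDGFRB"))
}

#' Nucleus- and gene-level quality control
#'
#' Removes nuclei with total UMI below `umi_lower` or above the dataset's
#' 98th percentile, detected genes below `genes_lower` or above the 98th
#' percentile, or mitochondrial fraction above `mito_max`; then removes genes
#' expressed (count > 0) in fewer than `min_nuclei` retained nuclei, and
#' re-checks the nucleus bounds once against the thresholds computed on the
#' input (a fixed point in at most two passes). Samples whose chrY median
#' expression contradicts the recorded sex are flagged, never dropped.
#'
#' @param sn an `sn_dataset` (sparse nuclei x genes counts + metadata).
#' @param mito_genes,chry_genes character vectors of mitochondrial / chrY
#'   gene names.
#' @param umi_lower,genes_lower lower bounds (defaults 1000 and 500).
#' @param upper_quantile percentile for the upper bounds (default 0.98).
#' @param mito_max maximum mitochondrial fraction (default 0.10).
#' @param min_nuclei minimum number of nuclei a gene must be detected in
#'   (default 6).
#' @return the filtered `sn_dataset` with `qc_log` (data.frame of removal
#'   counts by reason) and `sample_sex_flags` attached.
#' @export
qc_nuclei <- function(sn, mito_genes = mito_gene_names(),
                      chry_genes = chry_gene_names(),
                      umi_lower = 1000, genes_lower = 500,
                      upper_quantile = 0.98, mito_max = 0.10,
                      min_nuclei = 6L) {
  counts <- sn$counts
  umi <- Matrix::rowSums(counts)
  ngene <- Matrix::rowSums(counts > 0)
  mito <- intersect(mito_genes, colnames(counts))
  mito_frac <- if (length(mito)) Matrix::rowSums(counts[, mito, drop = FALSE]) / umi
               else rep(0, nrow(counts))
  umi_hi <- quantile(umi, upper_quantile)
  ngene_hi <- quantile(ngene, upper_quantile)

  nucleus_pass <- function(u, g, mf)
    u >= umi_lower & u <= umi_hi & g >= genes_lower & g <= ngene_hi &
      mf <= mito_max
  keep_nuc <- nucleus_pass(umi, ngene, mito_frac)
  log_rows <- data.frame(
    step = c("umi_low", "umi_high", "genes_low", "genes_high", "mito_high"),
    removed = c(sum(umi < umi_lower), sum(umi > umi_hi),
                sum(ngene < genes_lower), sum(ngene > ngene_hi),
                sum(mito_frac > mito_max)), stringsAsFactors = FALSE)

  sub <- counts[keep_nuc, , drop = FALSE]
  gene_det <- Matrix::colSums(sub > 0)
  keep_gene <- gene_det >= min_nuclei
  log_rows <- rbind(log_rows, data.frame(step = "genes_lt_min_nuclei",
                                         removed = sum(!keep_gene)))
  sub <- sub[, keep_gene, drop = FALSE]
  # one re-check of nucleus bounds on the reduced gene set (fixed thresholds)
  umi2 <- Matrix::rowSums(sub)
  ng2 <- Matrix::rowSums(sub > 0)
  mito2 <- intersect(mito, colnames(sub))
  mf2 <- if (length(mito2)) Matrix::rowSums(sub[, mito2, drop = FALSE]) / umi2
         else rep(0, nrow(sub))
  keep2 <- umi2 >= umi_lower & ng2 >= genes_lower & mf2 <= mito_max
  log_rows <- rbind(log_rows, data.frame(step = "recheck", removed = sum(!keep2)))
  sub <- sub[keep2, , drop = FALSE]
  if (nrow(sub) == 0L || ncol(sub) == 0L) stop("QC removed all nuclei or genes")

  meta <- sn$nucleus_meta[rownames(sub), , drop = FALSE]
  # sample-level sex concordance from chrY medians
  chry <- intersect(chry_genes, colnames(sub))
  sex_flags <- NULL
  if (length(chry) && !is.null(meta$sex)) {
    norm_y <- as.matrix(sub[, chry, drop = FALSE] /
                          Matrix::rowSums(sub) * 1e4)
    med_y <- tapply(apply(norm_y, 1, median), meta$sample, mean)
    rec <- tapply(meta$sex, meta$sample, function(s) s[1])
    if (diff(range(med_y)) > 0) {
      cutpt <- mean(range(med_y))
      est <- ifelse(med_y > cutpt, "M", "F")
      sex_flags <- data.frame(sample = names(med_y), recorded = as.character(rec),
                              estimated = est,
                              flag = est != as.character(rec),
                              stringsAsFactors = FALSE)
    }
  }
  sn$counts <- sub
  sn$nucleus_meta <- meta
  sn$qc_log <- log_rows
  sn$sample_sex_flags <- sex_flags
  sn
}

#' Library-size normalization, variable genes, and PC embedding
#'
#' Scales each nucleus to the median library size, applies `log1p`, selects
#' the top variable genes by within-mean-bin standardized dispersion, scales
#' them, and computes a PCA embedding. PC signs are fixed so each component's
#' largest-magnitude gene loading is positive. With `integrate = TRUE` the PC
#' scores are centred per sample, a light-weight integration that removes
#' additive per-sample offsets.
#'
#' @param sn a QC'ed `sn_dataset`.
#' @param n_pcs number of principal components (default 30).
#' @param n_hvg number of variable genes (default 500).
#' @param integrate logical; per-sample centering of PC scores.
#' @return `sn` with `norm` (sparse log-normalized nuclei x genes) and
#'   `embedding` (nuclei x PCs) filled.
#' @export
normalize_and_embed <- function(sn, n_pcs = 30L, n_hvg = 500L,
                                integrate = TRUE) {
  counts <- sn$counts
  lib <- Matrix::rowSums(counts)
  sf <- median(lib) / lib
  norm <- methods::as(Matrix::Diagonal(x = sf) %*% counts, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)

  mu <- Matrix::colMeans(norm)
  ex2 <- Matrix::colMeans(norm^2)
  v <- pmax(ex2 - mu^2, 0) * nrow(norm) / max(1, nrow(norm) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = 20, labels = FALSE)
  zdisp <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(disp[i]); if (is.na(s) || s == 0) s <- 1
    zdisp[i] <- (disp[i] - mean(disp[i])) / s
  }
  hvg <- colnames(norm)[order(zdisp, decreasing = TRUE)][seq_len(min(n_hvg, ncol(norm)))]

  x <- as.matrix(norm[, hvg, drop = FALSE])
  x <- scale(x)
  x[is.na(x)] <- 0
  x[x > 10] <- 10
  if (n_pcs > min(dim(x)) - 1L) stop("n_pcs exceeds data dimensions")
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]; sign(l[which.max(abs(l))])
  }, numeric(1))
  emb <- sweep(pc$x, 2, flip, `*`)
  rownames(emb) <- rownames(norm)
  if (integrate) {
    samp <- sn$nucleus_meta$sample
    for (s in unique(samp)) {
      i <- samp == s
      emb[i, ] <- sweep(emb[i, , drop = FALSE], 2,
                        colMeans(emb[i, , drop = FALSE]))
    }
  }
  sn$norm <- norm
  sn$embedding <- emb
  sn$hvg <- hvg
  sn
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph on the embedding, weights edges by the
#' Jaccard overlap of the two nuclei's neighbor sets (pruning weights below
#' `prune`), and runs Louvain community detection at the given resolution
#' with a fixed seed. Clusters are labelled CL0, CL1, ... by decreasing size.
#'
#' @param embedding nuclei x PCs matrix.
#' @param k_neighbors neighborhood size (default 20).
#' @param resolution Louvain resolution (default 0.4).
#' @param prune minimum Jaccard weight retained (default 1/15).
#' @param seed RNG seed for Louvain.
#' @return character vector of cluster labels, named by nucleus.
#' @export
cluster_nuclei <- function(embedding, k_neighbors = 20L, resolution = 0.4,
                           prune = 1 / 15, seed = 0L) {
  n <- nrow(embedding)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of nuclei")
  d <- as.matrix(dist(embedding))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))  # includes self
  N <- Matrix::sparseMatrix(i = rep(seq_len(n), k_neighbors),
                            j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(N)
  jac <- shared
  jac@x <- jac@x / (2 * k_neighbors - jac@x)
  jac <- jac * (jac >= prune)
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(paste0("CL", seq_along(sizes) - 1L), names(sizes))
  setNames(unname(relab[as.character(memb)]), rownames(embedding))
}

#' Test clusters for metadata composition bias
#'
#' For each cluster and each level of each metadata variable, computes the
#' fold-enrichment of the level inside the cluster relative to its overall
#' frequency and a two-sided Fisher exact p; a cluster is flagged when
#' fold > `fold_cut` AND p < `p_cut` (both required).
#'
#' @param cluster_labels named character vector.
#' @param nucleus_meta data.frame aligned with the labels.
#' @param vars metadata columns to test.
#' @param fold_cut,p_cut flag thresholds (defaults 5 and 0.05).
#' @return data.frame: cluster, variable, level, fold, p, flag.
#' @export
test_cluster_composition <- function(cluster_labels, nucleus_meta,
                                     vars = c("diagnosis", "sex", "sample"),
                                     fold_cut = 5, p_cut = 0.05) {
  out <- list()
  n <- length(cluster_labels)
  for (cl in sort(unique(cluster_labels))) {
    in_cl <- cluster_labels == cl
    for (v in vars) {
      x <- as.character(nucleus_meta[[v]])
      for (lev in unique(x)) {
        a <- sum(in_cl & x == lev); b <- sum(in_cl & x != lev)
        c_ <- sum(!in_cl & x == lev); d_ <- sum(!in_cl & x != lev)
        fold <- (a / max(1, a + b)) / ((a + c_) / n)
        p <- fisher.test(matrix(c(a, b, c_, d_), 2))$p.value
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, variable = v, level = lev, fold = fold, p = p,
          flag = fold > fold_cut & p < p_cut, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# vectorized rank-sum test of group 1 vs rest for every gene (column);
# exact mean/variance of the rank sum under sampling without replacement,
# which accounts for ties (mid-ranks) automatically
ranksum_all_genes <- function(x, in_group) {
  x <- as.matrix(x)
  n <- nrow(x); n1 <- sum(in_group); n2 <- n - n1
  R <- apply(x, 2, rank)
  W <- colSums(R[in_group, , drop = FALSE])
  rbar <- (n + 1) / 2
  varr <- colSums((R - rbar)^2) / n
  ew <- n1 * rbar
  vw <- n1 * n2 / (n - 1) * varr
  z <- (W - ew) / sqrt(pmax(vw, 1e-300))
  p <- 2 * pnorm(-abs(z))
  p[vw == 0] <- 1
  p
}

#' Per-cluster marker genes
#'
#' Rank-sum test of each gene in the cluster versus all other nuclei, on
#' log-normalized expression. Markers are genes with FDR < `fdr_cut`,
#' log fold change (difference of mean log-normalized expression) above
#' `logfc_cut`, and detection in more than `pct_cut` of the cluster's nuclei.
#'
#' @param sn an `sn_dataset` with `norm` filled.
#' @param cluster_labels named character vector.
#' @param fdr_cut,logfc_cut,pct_cut marker thresholds (defaults 0.05, 0.5,
#'   0.70).
#' @return data.frame: cluster, gene, logfc, pct_in, pct_out, p, fdr,
#'   is_marker.
#' @export
find_cluster_markers <- function(sn, cluster_labels, fdr_cut = 0.05,
                                 logfc_cut = 0.5, pct_cut = 0.70) {
  norm <- sn$norm
  out <- list()
  for (cl in sort(unique(cluster_labels))) {
    in_cl <- cluster_labels == cl
    if (sum(in_cl) < 3L) {
      warning("cluster ", cl, " has fewer than 3 nuclei; skipped")
      next
    }
    p <- ranksum_all_genes(norm, in_cl)
    m_in <- Matrix::colMeans(norm[in_cl, , drop = FALSE])
    m_out <- Matrix::colMeans(norm[!in_cl, , drop = FALSE])
    pct_in <- Matrix::colMeans(norm[in_cl, , drop = FALSE] > 0)
    pct_out <- Matrix::colMeans(norm[!in_cl, , drop = FALSE] > 0)
    fdr <- adjust_bh(p)
    logfc <- m_in - m_out
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, gene = colnames(norm), logfc = logfc, pct_in = pct_in,
      pct_out = pct_out, p = p, fdr = fdr,
      is_marker = fdr < fdr_cut & logfc > logfc_cut & pct_in > pct_cut,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Annotate clusters by marker-overlap enrichment
#'
#' Each cluster is assigned the reference cell type whose marker panel is
#' most significantly enriched (one-sided hypergeometric) in the cluster's
#' detected markers; clusters with no enrichment below the Bonferroni
#' adjusted threshold are "unassigned". Ties break by smaller p, then
#' alphabetically.
#'
#' @param marker_table output of [find_cluster_markers()].
#' @param reference_sets named list of reference marker panels.
#' @param background all genes eligible (defaults to all genes in the table).
#' @param alpha adjusted-p threshold for assignment (default 0.05).
#' @return named character vector: cluster -> cell type.
#' @export
annotate_clusters <- function(marker_table, reference_sets, background = NULL,
                              alpha = 0.05) {
  if (is.null(background)) background <- unique(marker_table$gene)
  clusters <- sort(unique(marker_table$cluster))
  ann <- setNames(rep("unassigned", length(clusters)), clusters)
  if (nrow(marker_table) == 0L) return(ann)
  n_tests <- length(reference_sets)
  for (cl in clusters) {
    mk <- marker_table$gene[marker_table$cluster == cl & marker_table$is_marker]
    if (length(mk) == 0L) next
    ps <- vapply(names(reference_sets), function(t) {
      set <- intersect(reference_sets[[t]], background)
      if (length(set) == 0L) return(1)
      hyper_enrich_p(length(intersect(mk, set)), length(mk), length(set),
                     length(background))
    }, numeric(1))
    ps_adj <- pmin(1, ps * n_tests)
    if (min(ps_adj) < alpha) {
      best <- names(ps)[ps == min(ps)]
      ann[cl] <- sort(best)[1]
    }
  }
  ann
}

# ridge-penalized logistic deviance for separation fallback
penalized_logistic_dev <- function(X, y, lambda = 1e-3) {
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(eta))) - sum(y * eta) + lambda * sum(b[-1]^2)
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "BFGS")
  eta <- X %*% fit$par
  mu <- 1 / (1 + exp(-eta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

logistic_dev <- function(X, y) {
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities", conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep) penalized_logistic_dev(X, y) else fit$deviance
}

#' Hurdle-model differential expression within a cluster
#'
#' Two-part model per gene passing the detection threshold: a logistic
#' regression of detection (count > 0) on diagnosis plus covariates, and a
#' Gaussian regression of log-normalized expression among detected nuclei on
#' the same design. The diagnosis term is tested by a 2-df likelihood-ratio
#' chi-square combining the two parts. Complete separation in the logistic
#' part triggers a ridge-penalized refit (logged in the `fallback` column).
#' Fold changes are differences of mean log-normalized expression over all
#' nuclei (zeros included). BH FDR within the cluster.
#'
#' @param sn an `sn_dataset` with `norm` filled.
#' @param cluster_labels named character labels.
#' @param cluster cluster id to test.
#' @param covariates columns of `nucleus_meta` used as covariates
#'   (default sex and age).
#' @param detect_threshold minimum detection fraction (default 0.20).
#' @return data.frame: gene, logfc, pct_case, pct_control, chisq, p, fdr,
#'   fallback.
#' @export
hurdle_de <- function(sn, cluster_labels, cluster,
                      covariates = c("sex", "age"), detect_threshold = 0.20) {
  in_cl <- names(cluster_labels)[cluster_labels == cluster]
  meta <- sn$nucleus_meta[in_cl, , drop = FALSE]
  if (length(unique(meta$diagnosis)) < 2L)
    stop("cluster must contain nuclei from both diagnoses")
  norm <- sn$norm[in_cl, , drop = FALSE]
  det_frac <- Matrix::colMeans(norm > 0)
  genes <- colnames(norm)[det_frac >= detect_threshold]

  dx <- as.numeric(meta$diagnosis == "case")
  covs <- meta[, intersect(covariates, colnames(meta)), drop = FALSE]
  X_red <- model.matrix(~ ., data = covs)
  X_full <- cbind(X_red, dx = dx)

  res <- lapply(genes, function(g) {
    z <- as.numeric(norm[, g])
    d <- as.numeric(z > 0)
    fb <- FALSE
    # discrete part
    if (all(d == 1) || all(d == 0)) {
      lr_disc <- 0
    } else {
      dev_full <- tryCatch(logistic_dev(X_full, d), error = function(e) NA)
      dev_red <- tryCatch(logistic_dev(X_red, d), error = function(e) NA)
      fb <- is.na(dev_full) || is.na(dev_red)
      lr_disc <- if (fb) 0 else max(0, dev_red - dev_full)
    }
    # continuous part among detected nuclei
    idx <- d == 1
    lr_cont <- 0
    if (sum(idx) > ncol(X_full) + 1L && length(unique(dx[idx])) == 2L) {
      y <- z[idx]
      rss_full <- sum(qr.resid(qr(X_full[idx, , drop = FALSE]), y)^2)
      rss_red <- sum(qr.resid(qr(X_red[idx, , drop = FALSE]), y)^2)
      if (rss_full > 0) lr_cont <- sum(idx) * log(rss_red / rss_full)
    }
    chisq <- lr_disc + lr_cont
    c(chisq = chisq, fb = as.numeric(fb))
  })
  chisq <- vapply(res, `[[`, numeric(1), "chisq")
  fallback <- vapply(res, `[[`, numeric(1), "fb") > 0
  p <- pchisq(chisq, df = 2, lower.tail = FALSE)
  m_case <- Matrix::colMeans(norm[dx == 1, genes, drop = FALSE])
  m_ctrl <- Matrix::colMeans(norm[dx == 0, genes, drop = FALSE])
  data.frame(gene = genes, logfc = m_case - m_ctrl,
             pct_case = Matrix::colMeans(norm[dx == 1, genes, drop = FALSE] > 0),
             pct_control = Matrix::colMeans(norm[dx == 0, genes, drop = FALSE] > 0),
             chisq = chisq, p = p, fdr = adjust_bh(p), fallback = fallback,
             row.names = genes, stringsAsFactors = FALSE)
}

#' Negative-binomial GLM differential expression (shared core)
#'
#' Wald test on per-sample counts with a log link, library-size
#' normalization, and per-gene dispersions moderated toward a mean-dispersion
#' trend; delegated to DESeq2 with independent filtering and outlier
#' replacement disabled so results are a deterministic function of the
#' inputs.
#'
#' @param counts genes x samples integer matrix.
#' @param coldata data.frame of sample covariates.
#' @param test_var name of the factor tested (last design term).
#' @param ref_level reference level of `test_var`.
#' @param covariates further columns of `coldata` to adjust for.
#' @return data.frame: gene, logfc (log2), se, p, fdr (NA for untestable
#'   genes).
#' @export
nb_glm_de <- function(counts, coldata, test_var, ref_level,
                      covariates = character(0)) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) > 0
  for (v in covariates) {
    if (is.numeric(coldata[[v]])) coldata[[v]] <- as.numeric(scale(coldata[[v]]))
    else coldata[[v]] <- factor(coldata[[v]])
  }
  coldata[[test_var]] <- stats::relevel(factor(coldata[[test_var]]), ref_level)
  if (length(unique(coldata[[test_var]])) < 2L)
    stop("test variable must have two levels present")
  design <- stats::as.formula(paste("~", paste(c(covariates, test_var),
                                               collapse = " + ")))
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = counts[keep, , drop = FALSE],
                                        colData = S4Vectors::DataFrame(coldata),
                                        design = design)
  dds <- DESeq2::estimateSizeFactors(dds, type = "poscounts")
  dds <- suppressMessages(DESeq2::DESeq(dds, test = "Wald", quiet = TRUE,
                                        minReplicatesForReplace = Inf))
  cn <- DESeq2::resultsNames(dds)
  cn <- cn[grepl(paste0("^", test_var, "_"), cn)][1]
  r <- DESeq2::results(dds, name = cn, independentFiltering = FALSE,
                       cooksCutoff = FALSE)
  out <- data.frame(gene = rownames(counts),
                    logfc = NA_real_, se = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE, row.names = rownames(counts))
  out[rownames(r), c("logfc", "se", "p")] <-
    data.frame(r$log2FoldChange, r$lfcSE, r$pvalue)
  ok <- !is.na(out$p)
  out$fdr <- NA_real_
  out$fdr[ok] <- adjust_bh(out$p[ok])
  out
}

#' Pseudobulk differential expression for a cell type
#'
#' Sums UMI counts over all nuclei of the same sample within the given
#' clusters, then fits the shared negative-binomial GLM (diagnosis adjusted
#' for sex and age) per gene.
#'
#' @param sn an `sn_dataset`.
#' @param cluster_labels named character labels.
#' @param clusters cluster ids pooled into the pseudobulk (e.g. all clusters
#'   of one cell type).
#' @param covariates sample-level covariates (default sex, age).
#' @return data.frame from [nb_glm_de()].
#' @export
pseudobulk_de <- function(sn, cluster_labels, clusters,
                          covariates = c("sex", "age")) {
  nuc <- names(cluster_labels)[cluster_labels %in% clusters]
  meta <- sn$nucleus_meta[nuc, , drop = FALSE]
  samples <- sort(unique(meta$sample))
  ind <- Matrix::sparseMatrix(i = match(meta$sample, samples),
                              j = seq_along(nuc), x = 1,
                              dims = c(length(samples), length(nuc)))
  pb <- as.matrix(ind %*% sn$counts[nuc, , drop = FALSE])
  rownames(pb) <- samples
  pb <- t(pb)                                   # genes x samples
  smeta <- unique(meta[, c("sample", "diagnosis", intersect(covariates,
                                                            colnames(meta)))])
  smeta <- smeta[match(samples, smeta$sample), , drop = FALSE]
  rownames(smeta) <- samples
  if (length(unique(smeta$diagnosis)) < 2L || min(table(smeta$diagnosis)) < 2L)
    stop("need at least 2 samples per diagnosis in the pooled clusters")
  nb_glm_de(pb, smeta, test_var = "diagnosis", ref_level = "control",
            covariates = intersect(covariates, colnames(smeta)))
}

#' Per-nucleus module score
#'
#' Mean log-normalized expression of a gene set, minus (in the default
#' control-subtracted mode) the mean of size-matched control genes sampled
#' from expression bins matching the set.
#'
#' @param sn an `sn_dataset` with `norm`.
#' @param gene_set character vector.
#' @param method "control" (bin-matched control subtraction) or "plain".
#' @param n_bins,n_ctrl control-sampling parameters.
#' @param seed RNG seed for control sampling.
#' @return numeric vector, one score per nucleus.
#' @export
module_score <- function(sn, gene_set, method = c("control", "plain"),
                         n_bins = 25L, n_ctrl = 50L, seed = 1L) {
  method <- match.arg(method)
  norm <- sn$norm
  gene_set <- intersect(gene_set, colnames(norm))
  if (length(gene_set) == 0L) stop("gene set has no detected genes")
  sc <- Matrix::rowMeans(norm[, gene_set, drop = FALSE])
  if (method == "plain") return(setNames(as.numeric(sc), rownames(norm)))
  set.seed(seed)
  mu <- Matrix::colMeans(norm)
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- colnames(norm)
  ctrl <- unique(unlist(lapply(gene_set, function(g) {
    pool <- names(bins)[bins == bins[g]]
    sample(pool, min(n_ctrl, length(pool)))
  })))
  ctrl_sc <- Matrix::rowMeans(norm[, ctrl, drop = FALSE])
  setNames(as.numeric(sc - ctrl_sc), rownames(norm))
}

#' Enrichment of cluster DEGs in a bulk expression module
#'
#' One-sided Fisher/hypergeometric overlap of a module's genes with a
#' cluster's significant DEGs over the background of genes detected in both
#' modalities; also reports the up/down split of the overlapping DEGs.
#'
#' @param module_genes character vector.
#' @param cluster_degs data.frame with columns gene, logfc, fdr.
#' @param background genes detected in both bulk and single-nucleus data.
#' @param fdr_cut DEG significance threshold (default 0.05).
#' @return one-row data.frame: overlap, n_module, n_deg, p, n_up, n_down,
#'   up_fraction (NA if no overlap).
#' @export
overlap_module_cluster_degs <- function(module_genes, cluster_degs, background,
                                        fdr_cut = 0.05) {
  if (length(background) == 0L) stop("empty background")
  mod <- intersect(module_genes, background)
  degs <- cluster_degs[!is.na(cluster_degs$fdr) & cluster_degs$fdr < fdr_cut, ]
  degs <- degs[degs$gene %in% background, ]
  ov_genes <- intersect(mod, degs$gene)
  p <- hyper_enrich_p(length(ov_genes), length(mod), nrow(degs),
                      length(background))
  n_up <- sum(degs$logfc[degs$gene %in% ov_genes] > 0)
  n_down <- sum(degs$logfc[degs$gene %in% ov_genes] < 0)
  data.frame(overlap = length(ov_genes), n_module = length(mod),
             n_deg = nrow(degs), p = p, n_up = n_up, n_down = n_down,
             up_fraction = if (length(ov_genes)) n_up / length(ov_genes)
                           else NA_real_)
}
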