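#' Normalize bulk counts for library size, gene length and GC content
#'
#' Produces log2-scale expression adjusted for the three systematic effects
#' that dominate bulk RNA-seq: sequencing depth, gene length, and GC content.
#' Sequencing depth is estimated by median-of-ratios size factors (the median
#' across genes of each sample's ratio to the per-gene geometric mean), which
#' stays unbiased when an asymmetric fraction of genes is differentially
#' expressed, unlike total-count scaling. Expression is
#' `log2(counts / size_factor + 0.5)`, followed by per-sample removal of
#' smooth (windowed-median) trends of expression on GC fraction and on log
#' length, re-centred so the per-sample median adjustment is zero.
#' Conditional-quantile machinery is deliberately not reproduced; this
#' substitute removes the same three systematic effects and is easy to reason
#' about (see the methods vignette).
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param gene_annot data.frame with columns `gc` (fraction in \[0,1\]) and
#'   `length` (bp); rownames or a `gene` column matching `rownames(counts)`.
#' @param adjust_gc_length logical; set `FALSE` to skip the GC/length trends.
#' @return numeric matrix of log2-scale normalized expression, same dim as
#'   `counts`.
#' @export
normalize_bulk <- function(counts, gene_annot, adjust_gc_length = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  if (!is.null(gene_annot$gene)) rownames(gene_annot) <- gene_annot$gene
  if (!all(rownames(counts) %in% rownames(gene_annot)))
    stop("gene_annot does not cover all genes in counts")
  ann <- gene_annot[rownames(counts), ]

  sf <- size_factors_mor(counts)
  expr <- log2(sweep(counts, 2, sf, `/`) + 0.5)
  if (!adjust_gc_length) return(expr)

  gc <- ann$gc
  loglen <- log2(ann$length)
  for (v in list(gc, loglen)) {
    trend <- windowed_median_trend(v, expr)
    expr <- expr - trend
  }
  expr
}

# Median-of-ratios size factors against a per-gene median-CPM reference
# profile. The reference is scale-invariant in every sample (CPM), so scaling
# one sample's counts scales exactly its own factor and no other; the median
# over genes keeps the factors unbiased when an asymmetric minority of genes
# is differentially expressed. Factors are in "per-million" units, so
# counts / sf is on the CPM scale.
size_factors_mor <- function(counts) {
  cpm <- sweep(counts, 2, colSums(counts) / 1e6, `/`)
  ref <- apply(cpm, 1, median)
  use <- ref > 0
  if (sum(use) < 10L) return(colSums(counts) / 1e6)
  apply(counts[use, , drop = FALSE] / ref[use], 2, median)
}

# Per-sample windowed-median trend of expression on a per-gene covariate.
# Genes are ranked by the covariate and split into equal-occupancy windows;
# the per-window median (centred on the sample's global median) is linearly
# interpolated at each gene's covariate value.
windowed_median_trend <- function(covariate, expr, n_windows = 20L) {
  ord <- order(covariate)
  n <- length(covariate)
  n_windows <- max(3L, min(n_windows, n %/% 20L))
  if (n_windows < 3L) return(matrix(0, nrow(expr), ncol(expr)))
  bins <- cut(seq_len(n), breaks = n_windows, labels = FALSE)
  centers <- tapply(covariate[ord], bins, median)
  trend <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (s in seq_len(ncol(expr))) {
    med_bin <- tapply(expr[ord, s], bins, median)
    med_bin <- med_bin - median(expr[, s])
    if (length(unique(centers)) < 2L) next
    trend[, s] <- approx(centers, med_bin, xout = covariate, rule = 2)$y
  }
  trend
}

#' Filter genes expressed in both cohorts
#'
#' A gene is retained only if its per-cohort summary (median across samples)
#' meets the cohort-specific threshold in *both* cohorts; genes failing either
#' cohort are removed from both. Gene order is preserved.
#'
#' @param expr1,expr2 normalized log2 expression matrices (same gene rows).
#' @param thresholds numeric length-2: minimum median log2 expression for
#'   study 1 and study 2 (default `c(2, -1)`).
#' @return character vector of retained genes.
#' @export
filter_low_expressed <- function(expr1, expr2, thresholds = c(2, -1)) {
  common <- intersect(rownames(expr1), rownames(expr2))
  if (length(common) == 0L) return(character(0))
  m1 <- apply(expr1[common, , drop = FALSE], 1, median)
  m2 <- apply(expr2[common, , drop = FALSE], 1, median)
  common[m1 >= thresholds[1] & m2 >= thresholds[2]]
}

#' Location-scale batch correction
#'
#' Homogenizes per-gene batch means and variances. The default
#' (`method = "moment"`) standardizes each gene within batch and restores the
#' pooled gene mean and variance, which is exactly idempotent. `method = "eb"`
#' applies parametric empirical-Bayes shrinkage of the per-batch location and
#' scale estimates across genes (ComBat-style) before adjusting, which is more
#' stable for small batches but only approximately idempotent.
#'
#' @param expr numeric matrix, genes x samples.
#' @param batch factor/character of batch labels, one per sample.
#' @param method "moment" (default) or "eb".
#' @return corrected matrix with per-gene grand means preserved.
#' @export
correct_batch <- function(expr, batch, method = c("moment", "eb")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  batch <- as.factor(as.character(batch))
  if (length(batch) != ncol(expr)) stop("one batch label per sample required")
  tab <- table(batch)
  if (any(tab < 2L))
    stop("singleton batch(es): ", paste(names(tab)[tab < 2], collapse = ", "))
  if (nlevels(batch) == 1L) return(expr)

  grand_mean <- rowMeans(expr)
  centered <- expr - grand_mean
  nb <- nlevels(batch)
  bm <- vapply(levels(batch), function(b)
    rowMeans(centered[, batch == b, drop = FALSE]), numeric(nrow(expr)))
  bv <- vapply(levels(batch), function(b)
    apply(centered[, batch == b, drop = FALSE], 1, var), numeric(nrow(expr)))
  bv[bv < 1e-12] <- 1e-12

  if (method == "eb") {
    # shrink batch means toward their across-gene prior, variances toward
    # inverse-gamma prior (method-of-moments hyperparameters)
    for (j in seq_len(nb)) {
      g_bar <- mean(bm[, j]); t2 <- max(var(bm[, j]) , 1e-12)
      n_j <- tab[j]
      s2 <- bv[, j]
      bm[, j] <- (n_j * t2 * bm[, j] + s2 * g_bar) / (n_j * t2 + s2)
      v_bar <- mean(bv[, j]); v_var <- max(var(bv[, j]), 1e-12)
      a_pr <- (2 * v_var + v_bar^2) / v_var
      b_pr <- (v_bar * v_var + v_bar^3) / v_var
      bv[, j] <- (b_pr + 0.5 * (n_j - 1) * bv[, j]) / (a_pr - 1 + 0.5 * (n_j - 1))
    }
  }
  # pooled (weighted) target variance per gene
  w <- as.numeric(tab[levels(batch)]) / length(batch)
  target_var <- as.numeric(bv %*% w)
  out <- centered
  for (j in seq_len(nb)) {
    sel <- batch == levels(batch)[j]
    out[, sel] <- (centered[, sel, drop = FALSE] - bm[, j]) *
      sqrt(target_var / bv[, j])
  }
  out + grand_mean
}

#' Sample-level quality control for bulk expression
#'
#' Flags samples whose first or second principal-component score lies outside
#' mean +/- 3 SD, and samples whose chromosome-Y expression (median over chrY
#' genes) contradicts the recorded sex. Sex is estimated by thresholding the
#' per-sample chrY median at the midpoint between the male and female cluster
#' centres of its (bimodal) distribution. Samples without a recorded sex are
#' reported as unevaluable, never silently dropped.
#'
#' @param expr normalized log2 expression, genes x samples.
#' @param sample_meta data.frame with a `sex` column ("M"/"F"), rows aligned
#'   with `expr` columns.
#' @param gene_annot data.frame with a `chromosome` column ("Y" rows define
#'   the chrY panel).
#' @param sd_cutoff outlier cutoff in PC-score SD units (default 3).
#' @return list: `retained` (character), `report` (data.frame: sample, flag,
#'   reason), `pc_scores`.
#' @export
qc_samples <- function(expr, sample_meta, gene_annot, sd_cutoff = 3) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples for QC")
  pcs <- prcomp(t(expr), center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  z <- scale(pcs)
  z[is.nan(z)] <- 0                        # degenerate axis: no outliers
  pc_flag <- abs(z[, 1]) > sd_cutoff | abs(z[, 2]) > sd_cutoff

  if (!is.null(gene_annot$gene)) rownames(gene_annot) <- gene_annot$gene
  chry <- intersect(rownames(gene_annot)[gene_annot$chromosome == "Y"],
                    rownames(expr))
  reasons <- rep("", ncol(expr))
  sex_flag <- rep(FALSE, ncol(expr))
  uneval <- rep(FALSE, ncol(expr))
  if (length(chry) >= 1L) {
    y_med <- apply(expr[chry, , drop = FALSE], 2, median)
    recorded <- as.character(sample_meta$sex)
    uneval <- is.na(recorded) | !(recorded %in% c("M", "F"))
    if (diff(range(y_med)) >= 1) {
      # midpoint between the two cluster centres of the bimodal chrY summary
      km <- suppressWarnings(stats::kmeans(y_med, centers = matrix(range(y_med))))
      cutpt <- mean(km$centers)
      est <- ifelse(y_med > cutpt, "M", "F")
      sex_flag <- !uneval & est != recorded
    }
  }
  for (i in seq_len(ncol(expr))) {
    r <- character(0)
    if (pc_flag[i]) r <- c(r, sprintf("PC_outlier(|z|>%g)", sd_cutoff))
    if (sex_flag[i]) r <- c(r, "sex_discordant")
    if (uneval[i]) r <- c(r, "sex_unevaluable")
    reasons[i] <- paste(r, collapse = ";")
  }
  flagged <- pc_flag | sex_flag
  report <- data.frame(sample = colnames(expr), flag = flagged,
                       reason = reasons, stringsAsFactors = FALSE)
  list(retained = colnames(expr)[!flagged], report = report, pc_scores = pcs)
}

#' Marker-based cell-type deconvolution (digital-sorting style)
#'
#' Estimates per-sample proportions of the five major brain cell types from
#' bulk expression using mutually exclusive marker sets. The linear model is
#' that a type's marker signal (linear-scale mean over its markers) is
#' proportional to the type's proportion; the per-type proportionality
#' constants are solved from the constraint that proportions sum to one in
#' every sample, by non-negative least squares (projected gradient, tolerance
#' 1e-8), and each sample's proportions are then projected to the simplex.
#'
#' @param expr log2-scale expression, genes x samples.
#' @param marker_sets named list of character vectors (one per cell type),
#'   mutually exclusive.
#' @return matrix samples x cell types; rows on the probability simplex.
#' @export
estimate_cell_proportions <- function(expr, marker_sets) {
  expr <- as.matrix(expr)
  if (anyDuplicated(unlist(marker_sets)))
    stop("marker sets must be mutually exclusive across types")
  sig <- vapply(names(marker_sets), function(t) {
    mk <- intersect(marker_sets[[t]], rownames(expr))
    if (length(mk) == 0L) stop("no detected markers for cell type: ", t)
    colMeans(2^expr[mk, , drop = FALSE])
  }, numeric(ncol(expr)))                      # samples x types
  # scale each type's signal to mean 1 so the NNLS is well conditioned
  sig_sc <- sweep(sig, 2, colMeans(sig), `/`)
  c_hat <- nnls_pg(sig_sc, rep(1, nrow(sig_sc)))
  p <- sweep(sig_sc, 2, c_hat, `*`)
  p <- t(apply(p, 1, project_simplex))
  dimnames(p) <- list(colnames(expr), names(marker_sets))
  p
}

# non-negative least squares by projected gradient descent
nnls_pg <- function(A, b, tol = 1e-8, max_iter = 5000L) {
  AtA <- crossprod(A); Atb <- crossprod(A, b)
  L <- max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
  x <- rep(1 / ncol(A), ncol(A))
  for (it in seq_len(max_iter)) {
    g <- AtA %*% x - Atb
    x_new <- pmax(0, x - as.numeric(g) / L)
    if (max(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  as.numeric(x)
}

# Euclidean projection onto the probability simplex
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Full bulk preprocessing for one cohort
#'
#' Convenience wrapper: normalize, QC (drop flagged samples), batch-correct by
#' flowcell. Filtering to the joint gene set is done across cohorts with
#' [filter_low_expressed()].
#'
#' @param study a `bulk_study` (counts, gene_annot, sample_meta, traits).
#' @param batch_var column of `sample_meta` used as batch (default flowcell).
#' @return the study with `expr` filled, QC-failing samples removed, and a
#'   `qc_report` element added.
#' @export
preprocess_bulk_study <- function(study, batch_var = "flowcell") {
  expr <- normalize_bulk(study$counts, study$gene_annot)
  qc <- qc_samples(expr, study$sample_meta, study$gene_annot)
  keep <- qc$retained
  expr <- expr[, keep, drop = FALSE]
  meta <- study$sample_meta[keep, , drop = FALSE]
  expr <- correct_batch(expr, meta[[batch_var]])
  study$expr <- expr
  study$sample_meta <- meta
  study$traits <- study$traits[keep, , drop = FALSE]
  study$qc_report <- qc$report
  study
}
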