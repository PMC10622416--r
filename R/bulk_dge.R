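#' Per-gene association of expression with a trait
#'
#' Ordinary least squares per gene: log2 expression as response, the trait of
#' interest plus covariates as predictors. For the binary diagnosis contrast
#' (case = 1, control = 0) the trait coefficient is the log2 fold change.
#' Quantitative tau-pathology traits are analyzed within cases only
#' (`case_only = TRUE`). When cell-type proportions are supplied, all but one
#' proportion column is added to the design (one type is dropped to break the
#' sum-to-one collinearity; the dropped type is the one with the largest
#' average proportion, typically neurons).
#'
#' @param expr normalized (and batch-corrected) log2 expression, genes x
#'   samples.
#' @param trait numeric vector (binary 0/1 diagnosis or continuous pathology
#'   score), aligned with samples; NAs allowed (those samples are dropped).
#' @param covariates data.frame of covariates (e.g. sex, age_at_death, rin,
#'   flowcell), aligned with samples.
#' @param case_only logical; restrict to samples with non-missing trait and
#'   `diagnosis == "case"` rows of `covariates` if a diagnosis column exists.
#' @param proportions optional samples x cell-type matrix on the simplex.
#' @return data.frame per gene: beta, se, t, p.
#' @export
fit_gene_trait <- function(expr, trait, covariates = NULL, case_only = FALSE,
                           proportions = NULL) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  keep <- !is.na(trait)
  if (case_only && !is.null(covariates$diagnosis))
    keep <- keep & covariates$diagnosis == "case"
  X <- data.frame(trait = trait)
  if (!is.null(covariates)) {
    cov <- covariates[, setdiff(colnames(covariates),
                                c("sample", "diagnosis", "qc_truth", "source")),
                      drop = FALSE]
    X <- cbind(X, cov)
  }
  if (!is.null(proportions)) {
    drop_type <- colnames(proportions)[which.max(colMeans(proportions))]
    X <- cbind(X, as.data.frame(proportions[, setdiff(colnames(proportions),
                                                      drop_type), drop = FALSE]))
  }
  X <- X[keep, , drop = FALSE]
  Y <- t(expr[, keep, drop = FALSE])
  mm <- model.matrix(~ ., data = X)
  if (nrow(mm) <= ncol(mm))
    stop("not enough samples for the design (n <= p)")
  qr_x <- qr(mm)
  if (qr_x$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_x$pivot[(qr_x$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  coefs <- qr.coef(qr_x, Y)
  dimnames(coefs) <- list(colnames(mm), colnames(Y))
  fitted <- mm %*% coefs
  res <- Y - fitted
  df <- nrow(mm) - ncol(mm)
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qr_x)))
  k <- which(colnames(mm) == "trait")
  beta <- coefs[k, ]
  se <- sqrt(sigma2 * xtx_inv_diag[k])
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  data.frame(gene = rownames(expr), beta = beta, se = se, t = tstat, p = p,
             row.names = rownames(expr), stringsAsFactors = FALSE)
}

#' Inverse-variance meta-analysis of two study-level associations
#'
#' Fixed-effect estimate with weights `1/se^2`; Cochran's Q and
#' Higgins-Thompson I^2 = max(0, (Q - df)/Q) with df = n_studies - 1. When
#' I^2 < `i2_threshold` the fixed-effect result is reported; otherwise the
#' DerSimonian-Laird random-effects estimate with
#' tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w))) and weights
#' `1/(se^2 + tau^2)`. Two-sided p-values come from the normal approximation
#' on `beta_meta / se_meta`. Genes present in only one study are excluded
#' (and listed in the `dropped` attribute).
#'
#' @param assoc1,assoc2 data.frames from [fit_gene_trait()] with columns
#'   gene, beta, se.
#' @param i2_threshold heterogeneity threshold for model switching
#'   (default 0.3; strict comparison, I^2 < threshold selects fixed).
#' @return data.frame per gene: beta_meta, se_meta, p, fdr, Q, I2, tau2,
#'   model.
#' @export
meta_analyze <- function(assoc1, assoc2, i2_threshold = 0.3) {
  common <- intersect(assoc1$gene, assoc2$gene)
  dropped <- setdiff(union(assoc1$gene, assoc2$gene), common)
  a1 <- assoc1[match(common, assoc1$gene), ]
  a2 <- assoc2[match(common, assoc2$gene), ]
  b <- cbind(a1$beta, a2$beta)
  se <- cbind(a1$se, a2$se)
  if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  w <- 1 / se^2
  sw <- rowSums(w)
  beta_fix <- rowSums(w * b) / sw
  se_fix <- sqrt(1 / sw)
  Q <- rowSums(w * (b - beta_fix)^2)
  df <- ncol(b) - 1L
  I2 <- pmax(0, (Q - df) / Q)
  I2[Q == 0] <- 0
  tau2 <- pmax(0, (Q - df) / (sw - rowSums(w^2) / sw))
  use_fixed <- I2 < i2_threshold
  wr <- 1 / (se^2 + tau2)
  beta_ran <- rowSums(wr * b) / rowSums(wr)
  se_ran <- sqrt(1 / rowSums(wr))
  beta_meta <- ifelse(use_fixed, beta_fix, beta_ran)
  se_meta <- ifelse(use_fixed, se_fix, se_ran)
  tau2_rep <- ifelse(use_fixed, 0, tau2)
  p <- 2 * pnorm(-abs(beta_meta / se_meta))
  out <- data.frame(gene = common, beta_meta = beta_meta, se_meta = se_meta,
                    p = p, fdr = adjust_bh(p), Q = Q, I2 = I2, tau2 = tau2_rep,
                    model = ifelse(use_fixed, "fixed", "random"),
                    row.names = common, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p))) stop("NaN/NA p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select top genes by joint FDR and effect-size percentile
#'
#' Genes simultaneously in the lowest 5% of FDR and the top 5% of
#' |meta effect| among tested genes. Percentile boundaries are inclusive:
#' ties at either boundary are all included.
#'
#' @param meta data.frame from [meta_analyze()] (diagnosis trait).
#' @param fdr_quantile,lfc_quantile the percentile cutoffs (defaults 0.05).
#' @return character vector of selected genes (empty, with a warning, for
#'   fewer than 20 genes).
#' @export
select_top_genes <- function(meta, fdr_quantile = 0.05, lfc_quantile = 0.05) {
  if (nrow(meta) < 20L) {
    warning("fewer than 20 genes; returning empty selection")
    return(character(0))
  }
  fdr_cut <- quantile(meta$fdr, fdr_quantile, type = 1)
  lfc_cut <- quantile(abs(meta$beta_meta), 1 - lfc_quantile, type = 1)
  meta$gene[meta$fdr <= fdr_cut & abs(meta$beta_meta) >= lfc_cut]
}

#' Cell-type marker enrichment of DEG sets
#'
#' One-sided (enrichment) Fisher exact test of each directional DEG set
#' against each cell type's marker list, over a common background.
#'
#' @param deg_up,deg_down character vectors of up-/down-regulated genes.
#' @param marker_sets named list of marker gene vectors.
#' @param background character vector, all tested genes.
#' @return data.frame: direction, celltype, overlap, set_size, p.
#' @export
deg_celltype_enrichment <- function(deg_up, deg_down, marker_sets, background) {
  res <- list()
  for (dir in c("up", "down")) {
    degs <- intersect(if (dir == "up") deg_up else deg_down, background)
    for (ct in names(marker_sets)) {
      mk <- intersect(marker_sets[[ct]], background)
      ov <- length(intersect(degs, mk))
      p <- if (length(degs) == 0L) 1 else
        hyper_enrich_p(ov, length(degs), length(mk), length(background))
      res[[length(res) + 1L]] <- data.frame(
        direction = dir, celltype = ct, overlap = ov,
        deg_size = length(degs), marker_size = length(mk), p = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# upper-tail hypergeometric P(X >= overlap)
hyper_enrich_p <- function(overlap, n_set, n_markers, n_background) {
  phyper(overlap - 1, n_markers, n_background - n_markers, n_set,
         lower.tail = FALSE)
}
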