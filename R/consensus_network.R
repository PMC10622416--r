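#' Biweight midcorrelation
#'
#' Robust correlation based on Tukey biweights around the median: for each
#' variable, deviations from the median are scaled by 9 times the (unscaled)
#' median absolute deviation, observations beyond that cutoff get zero weight,
#' and the remaining observations are weighted by `(1 - u^2)^2`. Variables
#' with zero MAD (no robust scale) fall back to Pearson standardization; the
#' fallback is recorded in the `fallback` attribute.
#'
#' @param x numeric matrix with variables in rows (e.g. genes x samples).
#' @param y optional second matrix with the same number of columns; if given,
#'   the cross-correlation matrix `vars(x) x vars(y)` is returned.
#' @return correlation matrix with entries in \[-1, 1\].
#' @export
bicor_matrix <- function(x, y = NULL) {
  tx <- bicor_transform(x)
  if (is.null(y)) {
    out <- tcrossprod(tx$mat)
    out[out > 1] <- 1; out[out < -1] <- -1
    diag(out) <- 1
  } else {
    ty <- bicor_transform(y)
    out <- tcrossprod(tx$mat, ty$mat)
    out[out > 1] <- 1; out[out < -1] <- -1
    attr(out, "fallback_y") <- ty$fallback
  }
  attr(out, "fallback") <- tx$fallback
  out
}

# rows transformed to biweight-weighted, unit-norm deviations
bicor_transform <- function(x) {
  x <- as.matrix(x)
  med <- apply(x, 1, median)
  madv <- vapply(seq_len(nrow(x)), function(i) median(abs(x[i, ] - med[i])),
                 numeric(1))
  fallback <- setNames(madv == 0, rownames(x))
  dev <- x - med
  u <- dev / (9 * madv)
  u[fallback, ] <- 0
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- dev * w
  if (any(fallback)) {
    # Pearson fallback: mean-centred values
    xm <- x[fallback, , drop = FALSE]
    xt[fallback, ] <- xm - rowMeans(xm)
  }
  nrm <- sqrt(rowSums(xt^2))
  nrm[nrm == 0] <- 1
  list(mat = xt / nrm, fallback = fallback)
}

#' Scalar biweight midcorrelation of two vectors
#' @param x,y numeric vectors of equal length.
#' @return correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  as.numeric(bicor_matrix(rbind(x), rbind(y)))
}

#' Residualize expression on technical and biological covariates
#'
#' Per-gene OLS residuals against the supplied covariates (typically sex,
#' age, RIN, flowcell). With no covariates, returns mean-centred rows.
#'
#' @param expr genes x samples matrix.
#' @param covariates data.frame aligned with samples, or NULL.
#' @return matrix of residuals, same dimensions.
#' @export
residualize <- function(expr, covariates = NULL) {
  expr <- as.matrix(expr)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    return(expr - rowMeans(expr))
  mm <- model.matrix(~ ., data = as.data.frame(covariates))
  qr_x <- qr(mm)
  if (qr_x$rank < ncol(mm)) stop("covariate design is rank deficient")
  t(qr.resid(qr_x, t(expr)))
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + c_ij) / 2) ^ beta_power`, the standard signed transform; the
#' diagonal is set to zero for TOM purposes.
#'
#' @param C correlation matrix.
#' @param beta_power soft-threshold exponent (default 12).
#' @return adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
signed_adjacency <- function(C, beta_power = 12) {
  if (beta_power <= 0) stop("beta_power must be positive")
  A <- ((1 + C) / 2)^beta_power
  diag(A) <- 0
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`; the diagonal is 1.
#'
#' @param A symmetric adjacency with zero diagonal.
#' @return TOM in \[0, 1\].
#' @export
compute_tom <- function(A) {
  A <- as.matrix(A)
  k <- rowSums(A)
  L <- A %*% A
  den <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / den
  diag(tom) <- 1
  tom
}

#' Quantile-scaled consensus TOM
#'
#' Each non-reference TOM is power-rescaled so that its `scale_quantile`
#' off-diagonal quantile matches the reference's
#' (`tom ^ (log(q_ref)/log(q_own))`), then the consensus is the element-wise
#' minimum. The first TOM in the list is the reference.
#'
#' @param tom_list list of TOMs on an identical gene set.
#' @param scale_quantile quantile used for calibration (default 0.95), must
#'   lie strictly inside (0, 1).
#' @return list: `consensus`, `scaled` (list of scaled inputs).
#' @export
consensus_tom <- function(tom_list, scale_quantile = 0.95) {
  if (scale_quantile <= 0 || scale_quantile >= 1)
    stop("scale_quantile must lie strictly between 0 and 1")
  stopifnot(length(tom_list) >= 2L)
  off <- upper.tri(tom_list[[1]])
  q_ref <- quantile(tom_list[[1]][off], scale_quantile)
  scaled <- tom_list
  for (i in seq_along(tom_list)[-1]) {
    q_own <- quantile(tom_list[[i]][off], scale_quantile)
    if (q_own > 0 && q_own < 1 && q_ref > 0 && q_ref < 1) {
      s <- tom_list[[i]]^(log(q_ref) / log(q_own))
      diag(s) <- 1
      scaled[[i]] <- s
    }
  }
  cons <- Reduce(pmin, scaled)
  list(consensus = cons, scaled = scaled)
}

#' Detect modules by hierarchical clustering and tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed fraction of the maximum merge height (the simple tree-shape
#' variant of dynamic tree cut: background genes join the tree only in its
#' topmost merges, so cutting just below the top isolates the dense
#' branches); clusters smaller than `min_module_size` become background
#' (module 0). Modules are labelled 1..k by decreasing size.
#'
#' @param tom consensus TOM.
#' @param min_module_size minimum cluster size (default 30).
#' @param cut_height fraction of the maximum merge height at which the tree
#'   is cut (default 0.99).
#' @return named integer vector of labels (0 = background).
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_height = 0.99) {
  genes <- rownames(tom) %||% paste0("g", seq_len(nrow(tom)))
  if (nrow(tom) < min_module_size) {
    warning("fewer genes than min_module_size; all background")
    return(setNames(integer(nrow(tom)), genes))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  # tied merge heights can be returned a hair out of order; monotonize
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  cl <- cutree(hc, h = cut_height * max(hc$height))
  relabel_by_size(cl, min_module_size, genes)
}

relabel_by_size <- function(cl, min_module_size, genes) {
  tab <- sort(table(cl), decreasing = TRUE)
  big <- names(tab)[tab >= min_module_size]
  out <- integer(length(cl))
  for (i in seq_along(big)) out[cl == as.integer(big[i])] <- i
  setNames(out, genes)
}

#' Module eigengenes
#'
#' Per module, the signed first principal component of the module's
#' standardized gene x sample submatrix: the leading right singular vector,
#' unit norm, with the sign chosen so the average correlation with module
#' genes is positive. A single-gene module's eigengene is that gene's
#' standardized profile (unit norm).
#'
#' @param expr genes x samples matrix (residualized expression).
#' @param labels named integer labels from [detect_modules()].
#' @return samples x modules matrix; columns named `ME<id>`.
#' @export
module_eigengenes <- function(expr, labels) {
  expr <- as.matrix(expr)
  mods <- sort(unique(labels[labels > 0]))
  me <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  xs <- row_standardize(expr)
  for (i in seq_along(mods)) {
    members <- names(labels)[labels == mods[i]]
    sub <- xs[members, , drop = FALSE]
    if (nrow(sub) == 1L) {
      v <- sub[1, ] / sqrt(sum(sub[1, ]^2))
    } else {
      sv <- svd(sub, nu = 0, nv = 1)
      v <- sv$v[, 1]
    }
    if (mean(as.numeric(sub %*% v)) < 0) v <- -v
    me[, i] <- v
  }
  me
}

row_standardize <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1, sd)
  s[s == 0] <- 1
  (x - m) / s
}

#' Module membership (kME)
#'
#' Biweight midcorrelation of each gene's expression with each module
#' eigengene.
#'
#' @param expr genes x samples matrix.
#' @param me samples x modules eigengene matrix.
#' @return genes x modules matrix of correlations.
#' @export
module_membership <- function(expr, me) {
  mm <- bicor_matrix(expr, t(me))
  dimnames(mm) <- list(rownames(expr), colnames(me))
  mm
}

#' Merge correlated modules and reassign genes by membership
#'
#' Iterates the following until the labels reach a fixed point (at most
#' `max_iter` rounds): (1) merge the closest module pair whose eigengene
#' bicor exceeds `merge_threshold` (ties broken by smaller module id),
#' recomputing eigengenes after each merge; (2) move genes with negative
#' membership in their own module to the background; (3) move background
#' genes whose maximum membership exceeds `reassign_in` to the argmax module;
#' (4) recompute eigengenes and memberships. Iterating to the fixed point
#' makes a second call a no-op.
#'
#' @param labels initial labels from [detect_modules()].
#' @param expr genes x samples residualized expression.
#' @param merge_threshold eigengene correlation above which modules merge
#'   (default 0.8).
#' @param reassign_in membership above which a background gene joins a module
#'   (default 0.5).
#' @param max_iter safety bound on fixed-point iterations.
#' @return list of class `module_set`: `labels`, `me`, `mm`,
#'   `merge_threshold`, `reassign_in`.
#' @export
merge_and_reassign <- function(labels, expr, merge_threshold = 0.8,
                               reassign_in = 0.5, max_iter = 10L) {
  labels <- labels[rownames(expr)]
  for (iter in seq_len(max_iter)) {
    prev <- labels
    # (1) iterative closest-pair merging
    repeat {
      mods <- sort(unique(labels[labels > 0]))
      if (length(mods) < 2L) break
      me <- module_eigengenes(expr, labels)
      cc <- bicor_matrix(t(me))
      diag(cc) <- -Inf
      best <- which(cc == max(cc), arr.ind = TRUE)
      if (max(cc) <= merge_threshold) break
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      m_keep <- mods[min(best)]; m_drop <- mods[max(best)]
      labels[labels == m_drop] <- m_keep
    }
    labels <- renumber_labels(labels)
    me <- module_eigengenes(expr, labels)
    mm <- module_membership(expr, me)
    # (2) own-module negative membership -> background
    own <- labels > 0
    if (any(own)) {
      own_mm <- mm[cbind(which(own), match(paste0("ME", labels[own]),
                                           colnames(mm)))]
      labels[which(own)[own_mm < 0]] <- 0L
    }
    # (3) background genes with strong membership join the argmax module
    bg <- which(labels == 0L)
    if (length(bg) && ncol(mm) > 0) {
      mx <- apply(mm[bg, , drop = FALSE], 1, max)
      arg <- apply(mm[bg, , drop = FALSE], 1, which.max)
      move <- mx > reassign_in
      labels[bg[move]] <- as.integer(sub("ME", "", colnames(mm)))[arg[move]]
    }
    labels <- renumber_labels(labels)
    if (identical(labels, prev)) break
  }
  me <- module_eigengenes(expr, labels)
  mm <- module_membership(expr, me)
  structure(list(labels = labels, me = me, mm = mm,
                 merge_threshold = merge_threshold, reassign_in = reassign_in),
            class = "module_set")
}

renumber_labels <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  out <- labels
  for (i in seq_along(mods)) out[labels == mods[i]] <- i
  out
}

#' Module-trait association
#'
#' Biweight midcorrelation between each module eigengene and each trait, with
#' a two-sided t-approximation p-value and Bonferroni adjustment over the
#' number of modules. Traits with missing values (e.g. pathology scores
#' defined only in cases) are evaluated on their non-missing samples.
#'
#' @param me samples x modules eigengene matrix.
#' @param traits data.frame of numeric traits aligned with samples.
#' @return data.frame: module, trait, r, p, p_bonferroni, n.
#' @export
module_trait_association <- function(me, traits) {
  traits <- as.data.frame(traits)
  n_mod <- ncol(me)
  out <- list()
  for (tr in colnames(traits)) {
    v <- traits[[tr]]
    keep <- !is.na(v)
    if (sd(v[keep]) == 0) stop("trait has zero variance: ", tr)
    for (m in colnames(me)) {
      r <- bicor(me[keep, m], v[keep])
      n <- sum(keep)
      tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
      p <- 2 * pt(-abs(tt), n - 2)
      out[[length(out) + 1L]] <- data.frame(
        module = m, trait = tr, r = r, p = p,
        p_bonferroni = min(1, p * n_mod), n = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric p per set with fold enrichment
#' `(overlap / length(genes)) / (set size / background size)`. In `"marker"`
#' mode all sets are tested and p-values are Bonferroni-adjusted; in `"set"`
#' mode sets with overlap below `min_overlap` (default 2) are excluded and
#' BH adjustment is applied.
#'
#' @param genes query gene set (e.g. a module).
#' @param sets named list of gene sets, each a subset of `background`.
#' @param background all eligible genes.
#' @param mode "marker" or "set".
#' @param min_overlap minimum overlap in set mode.
#' @return data.frame: set, overlap, set_size, fold, p, p_adj.
#' @export
gene_set_enrichment <- function(genes, sets, background,
                                mode = c("marker", "set"), min_overlap = 2L) {
  mode <- match.arg(mode)
  genes <- intersect(genes, background)
  rows <- lapply(names(sets), function(s) {
    set <- sets[[s]]
    if (!all(set %in% background))
      stop("set not contained in background: ", s)
    ov <- length(intersect(genes, set))
    fold <- if (length(genes) == 0 || length(set) == 0) NA_real_ else
      (ov / length(genes)) / (length(set) / length(background))
    p <- hyper_enrich_p(ov, length(genes), length(set), length(background))
    data.frame(set = s, overlap = ov, set_size = length(set), fold = fold,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (mode == "set") {
    out <- out[out$overlap >= min_overlap, , drop = FALSE]
    out$p_adj <- if (nrow(out)) adjust_bh(out$p) else numeric(0)
  } else {
    out$p_adj <- pmin(1, out$p * nrow(out))
  }
  out
}

#' Simplified permutation preservation Z statistics
#'
#' For each module, the observed statistic is the mean of (a) the correlation
#' between intramodular connectivities computed in study 1 and study 2 and
#' (b) the mean intramodular adjacency in study 2. The null distribution
#' comes from `n_perm` random gene sets of the same size; Z = (observed -
#' permutation mean) / permutation SD. This is a two-statistic simplification
#' of the full multi-statistic Z-summary.
#'
#' @param expr1,expr2 genes x samples residualized expression (same genes).
#' @param labels module labels.
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @param beta_power soft power for within-module adjacency.
#' @return data.frame: module, size, observed, perm_mean, perm_sd, Z.
#' @export
module_preservation <- function(expr1, expr2, labels, n_perm = 100L,
                                seed = 1L, beta_power = 12) {
  set.seed(seed)
  genes <- intersect(rownames(expr1), rownames(expr2))
  labels <- labels[genes]
  mods <- sort(unique(labels[labels > 0]))
  stat_for <- function(members) {
    a1 <- signed_adjacency(bicor_matrix(expr1[members, , drop = FALSE]),
                           beta_power)
    a2 <- signed_adjacency(bicor_matrix(expr2[members, , drop = FALSE]),
                           beta_power)
    k1 <- rowSums(a1); k2 <- rowSums(a2)
    ck <- if (sd(k1) == 0 || sd(k2) == 0) 0 else cor(k1, k2)
    mean(c(ck, mean(a2[upper.tri(a2)])))
  }
  out <- list()
  for (m in mods) {
    members <- names(labels)[labels == m]
    if (length(members) < 3L) {
      warning("module ", m, " smaller than 3 genes; skipped")
      next
    }
    obs <- stat_for(members)
    perm <- vapply(seq_len(n_perm), function(i)
      stat_for(sample(genes, length(members))), numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      module = m, size = length(members), observed = obs,
      perm_mean = mean(perm), perm_sd = sd(perm),
      Z = (obs - mean(perm)) / sd(perm), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Consensus co-expression network across two cohorts
#'
#' Full network arm: residualize each cohort on its covariates, compute
#' biweight midcorrelations, signed adjacencies (soft power 12), per-study
#' TOMs, the quantile-scaled consensus TOM (component-wise minimum), detect
#' modules by tree cut, then merge and reassign. Eigengenes and memberships
#' are computed on the column-bound per-cohort standardized residuals.
#'
#' @param expr1,expr2 genes x samples normalized expression (same gene set).
#' @param covariates1,covariates2 covariate data.frames (or NULL).
#' @param beta_power soft power (default 12).
#' @param min_module_size,cut_height tree-cut parameters.
#' @param merge_threshold,reassign_in merge/reassignment thresholds.
#' @param scale_quantile consensus calibration quantile.
#' @return list of class `consensus_network`: `modules` (a `module_set`),
#'   `consensus_tom`, `resid1`, `resid2`, `combined` (standardized residuals,
#'   genes x all samples), `n_samples`.
#' @export
build_consensus_network <- function(expr1, expr2, covariates1 = NULL,
                                    covariates2 = NULL, beta_power = 12,
                                    min_module_size = 30L, cut_height = 0.99,
                                    merge_threshold = 0.8, reassign_in = 0.5,
                                    scale_quantile = 0.95) {
  genes <- intersect(rownames(expr1), rownames(expr2))
  r1 <- residualize(expr1[genes, , drop = FALSE], covariates1)
  r2 <- residualize(expr2[genes, , drop = FALSE], covariates2)
  toms <- lapply(list(r1, r2), function(r)
    compute_tom(signed_adjacency(bicor_matrix(r), beta_power)))
  cons <- consensus_tom(toms, scale_quantile)$consensus
  dimnames(cons) <- list(genes, genes)
  labels0 <- detect_modules(cons, min_module_size, cut_height)
  combined <- cbind(row_standardize(r1), row_standardize(r2))
  modules <- merge_and_reassign(labels0, combined, merge_threshold, reassign_in)
  structure(list(modules = modules, consensus_tom = cons, resid1 = r1,
                 resid2 = r2, combined = combined,
                 n_samples = c(ncol(r1), ncol(r2))),
            class = "consensus_network")
}
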