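#' Mouse differential expression by age group
#'
#' Per age group, fits the shared negative-binomial GLM of genotype
#' (rTg4510 vs nonTg) adjusted for sex and RIN; FDR is computed within each
#' age group.
#'
#' @param mouse a `mouse_study` (counts, sample_meta).
#' @return named list of data.frames (one per age group) from [nb_glm_de()].
#' @export
mouse_de <- function(mouse) {
  out <- list()
  for (ag in sort(unique(mouse$sample_meta$age_group))) {
    sel <- mouse$sample_meta$age_group == ag
    meta <- mouse$sample_meta[sel, , drop = FALSE]
    if (length(unique(meta$genotype)) < 2L)
      stop("age group ", ag, " lacks one genotype")
    out[[as.character(ag)]] <- nb_glm_de(
      mouse$counts[, rownames(meta), drop = FALSE], meta,
      test_var = "genotype", ref_level = "nonTg",
      covariates = c("sex", "rin"))
  }
  out
}

#' Validate human hits in the mouse model
#'
#' A human gene is validated when any of its mouse orthologs is significant
#' (FDR < `fdr_cut`) in either age group with the same direction of change as
#' the human meta-analysis effect. One-to-many orthologs: any concordant
#' ortholog suffices.
#'
#' @param human_hits data.frame with columns `gene` and `beta_meta` (signed).
#' @param mouse_results list of per-age-group results from [mouse_de()].
#' @param ortholog_map data.frame (human_gene, species, ortholog_gene, ...).
#' @param fdr_cut significance threshold (default 0.05).
#' @return data.frame: gene, validated, reason
#'   ("ok", "no_ortholog", "not_significant", "mouse_discordant").
#' @export
validate_in_mouse <- function(human_hits, mouse_results, ortholog_map,
                              fdr_cut = 0.05) {
  mm <- ortholog_map[ortholog_map$species == "mouse", , drop = FALSE]
  res <- lapply(seq_len(nrow(human_hits)), function(i) {
    g <- human_hits$gene[i]
    sgn <- sign(human_hits$beta_meta[i])
    orth <- mm$ortholog_gene[mm$human_gene == g]
    if (length(orth) == 0L)
      return(data.frame(gene = g, validated = FALSE, reason = "no_ortholog"))
    any_sig <- FALSE; any_conc <- FALSE
    for (ag in names(mouse_results)) {
      r <- mouse_results[[ag]]
      r <- r[r$gene %in% orth & !is.na(r$fdr) & r$fdr < fdr_cut, , drop = FALSE]
      if (nrow(r)) {
        any_sig <- TRUE
        if (any(sign(r$logfc) == sgn)) any_conc <- TRUE
      }
    }
    reason <- if (any_conc) "ok" else if (any_sig) "mouse_discordant"
              else "not_significant"
    data.frame(gene = g, validated = any_conc, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify fly-screen outcomes
#'
#' Maps the semi-quantitative -4..4 eye-degeneration score (or the
#' categorical "lethal" outcome) to a modifier class: scores below -1.5 are
#' top suppressors, negative scores down to -1.5 are suppressors, 0 is no
#' change, positive scores are enhancers.
#'
#' @param score numeric vector in \[-4, 4\], or the string "lethal" (a
#'   character vector mixing numbers and "lethal" is accepted).
#' @return character vector of classifications.
#' @export
screen_classify <- function(score) {
  vapply(as.list(score), function(s) {
    if (identical(as.character(s), "lethal")) return("lethal")
    x <- suppressWarnings(as.numeric(s))
    if (is.na(x)) stop("score must be numeric in [-4, 4] or \"lethal\"")
    if (x < -4 || x > 4) stop("score out of range [-4, 4]: ", x)
    if (x < -1.5) "suppressor_top" else if (x < 0) "suppressor"
    else if (x == 0) "no_change" else "enhancer"
  }, character(1))
}

#' Total and evaluator-averaged fly eye scores
#'
#' Validates the blinded eye-score rubric (loss of bristle 0-1, size 0-1,
#' color 0-2, necrotic patterns 0-2, eye collapse 0-2, loss of ommatidia
#' 0-2; total 0-10) and returns the per-fly final score as the mean of the
#' evaluators' totals.
#'
#' @param scores data.frame with columns fly, genotype, evaluator, bristle,
#'   size, color, necrotic, collapse, ommatidia.
#' @return data.frame: fly, genotype, final (mean of evaluator totals).
#' @export
eye_score_totals <- function(scores) {
  lims <- c(bristle = 1, size = 1, color = 2, necrotic = 2, collapse = 2,
            ommatidia = 2)
  for (v in names(lims)) {
    if (any(scores[[v]] < 0 | scores[[v]] > lims[v]))
      stop("sub-score out of range: ", v)
  }
  total <- rowSums(scores[, names(lims)])
  agg <- stats::aggregate(total, by = list(fly = scores$fly,
                                           genotype = scores$genotype), mean)
  names(agg)[3] <- "final"
  agg
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' For group sizes up to `exact_max` per group, computes the exact
#' permutation distribution of the rank sum (mid-ranks for ties) by dynamic
#' programming over subset sums, and returns the two-sided p-value
#' P(|W - E(W)| >= |w_obs - E(W)|). For larger groups a normal approximation
#' with the exact (tie-corrected) permutation variance is used.
#'
#' @param x,y numeric vectors (non-empty).
#' @param exact_max largest per-group size for exact enumeration (default
#'   25).
#' @return list: p, W (rank sum of `x`), exact (logical).
#' @export
exact_wilcoxon <- function(x, y, exact_max = 25L) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    d <- as.integer(round(2 * r))            # mid-ranks doubled to integers
    S <- sum(d)
    # dp[j+1, s+1] = number of size-j subsets of d with sum s
    dp <- matrix(0, n1 + 1L, S + 1L)
    dp[1, 1] <- 1
    for (v in d) {
      jmax <- n1
      for (j in jmax:1) {
        nz <- which(dp[j, ] > 0)
        if (length(nz))
          dp[j + 1L, nz + v] <- dp[j + 1L, nz + v] + dp[j, nz]
      }
    }
    counts <- dp[n1 + 1L, ]
    sums <- (seq_along(counts) - 1L) / 2       # back to rank-sum scale
    dev <- abs(sums - EW)
    p <- sum(counts[dev >= abs(W - EW) - 1e-9]) / choose(n, n1)
    return(list(p = min(1, p), W = W, exact = TRUE))
  }
  varr <- sum((r - (n + 1) / 2)^2) / n
  VW <- n1 * n2 / (n - 1) * varr
  z <- (W - EW) / sqrt(VW)
  list(p = if (VW == 0) 1 else 2 * pnorm(-abs(z)), W = W, exact = FALSE)
}

#' Compare eye scores between two genotypes
#'
#' Two-sided exact Wilcoxon rank-sum test on evaluator-averaged per-fly
#' scores.
#'
#' @param eye_scores output of [eye_score_totals()].
#' @param group_a,group_b genotype labels to compare.
#' @return list: p, W, exact, n (group sizes).
#' @export
analyze_eye_scores <- function(eye_scores, group_a, group_b) {
  a <- eye_scores$final[eye_scores$genotype == group_a]
  b <- eye_scores$final[eye_scores$genotype == group_b]
  res <- exact_wilcoxon(a, b)
  res$n <- c(length(a), length(b))
  res
}

#' Evidence-cascade prioritization funnel
#'
#' Applies the nested filters: (1) genes in disease-associated, cell-type
#' mapped modules that are bulk meta-analysis DEGs (FDR < `fdr_cut`);
#' (2) hub genes (own-module membership > `mm_cut`); (3) a significant
#' single-nucleus DEG with the module's required direction in any cluster
#' annotated to the module's cell types; (4) mouse-validated (significant
#' with the human direction in either age group); (5) fly ortholog with
#' available RNAi; (6) top suppressor in the screen (score < -1.5). Stage
#' sets are nested by construction; per-gene reason codes record the first
#' failing stage.
#'
#' @param meta meta-analysis results (gene, beta_meta, fdr).
#' @param modules a `module_set` (labels, mm).
#' @param module_config named list: module id (as character) ->
#'   `list(celltypes = c(...), direction = +1 or -1)`; only listed modules
#'   enter the funnel.
#' @param sn_degs named list: cluster id -> [hurdle_de()] data.frame.
#' @param cluster_annotation named character: cluster id -> cell type.
#' @param mouse_results list from [mouse_de()].
#' @param ortholog_map data.frame (human_gene, species, ortholog_gene,
#'   rnai_available).
#' @param screen data.frame (human_gene, screen_score, outcome).
#' @param fdr_cut,mm_cut,screen_cut thresholds (0.05, 0.7, -1.5).
#' @return object of class `funnel_result`: `stages` (named list of gene
#'   vectors), `counts`, `flags` (per-gene logical matrix), `reasons`.
#' @export
run_funnel <- function(meta, modules, module_config, sn_degs,
                       cluster_annotation, mouse_results, ortholog_map,
                       screen, fdr_cut = 0.05, mm_cut = 0.7,
                       screen_cut = -1.5) {
  labels <- modules$labels
  mm <- modules$mm
  if (length(module_config) == 0L) stop("module_config must map at least one module")
  bad <- setdiff(names(module_config), as.character(unique(labels[labels > 0])))
  if (length(bad))
    stop("module_config refers to unknown module(s): ", paste(bad, collapse = ", "))

  genes <- meta$gene
  in_funnel_module <- labels[genes] > 0 &
    as.character(labels[genes]) %in% names(module_config)
  is_deg <- !is.na(meta$fdr) & meta$fdr < fdr_cut
  s1 <- genes[in_funnel_module & is_deg]

  own_mm <- rep(NA_real_, length(genes)); names(own_mm) <- genes
  has_mod <- labels[genes] > 0
  own_mm[has_mod] <- mm[cbind(match(genes[has_mod], rownames(mm)),
                              match(paste0("ME", labels[genes[has_mod]]),
                                    colnames(mm)))]
  s2 <- s1[own_mm[s1] > mm_cut]

  sn_ok <- function(g) {
    cfg <- module_config[[as.character(labels[g])]]
    cls <- names(cluster_annotation)[cluster_annotation %in% cfg$celltypes]
    for (cl in intersect(cls, names(sn_degs))) {
      de <- sn_degs[[cl]]
      row <- de[de$gene == g, , drop = FALSE]
      if (nrow(row) && !is.na(row$fdr[1]) && row$fdr[1] < fdr_cut &&
          sign(row$logfc[1]) == cfg$direction)
        return(TRUE)
    }
    FALSE
  }
  s3 <- s2[vapply(s2, sn_ok, logical(1))]

  mv <- if (length(s3)) validate_in_mouse(meta[match(s3, meta$gene),
                                               c("gene", "beta_meta")],
                                          mouse_results, ortholog_map, fdr_cut)
        else data.frame(gene = character(0), validated = logical(0),
                        reason = character(0))
  s4 <- mv$gene[mv$validated]

  fly <- ortholog_map[ortholog_map$species == "fly" &
                        ortholog_map$rnai_available %in% TRUE, , drop = FALSE]
  s5 <- s4[s4 %in% fly$human_gene]

  scr <- screen[screen$outcome == "scored", , drop = FALSE]
  top <- scr$human_gene[screen_classify(scr$screen_score) == "suppressor_top"]
  s6 <- s5[s5 %in% top]

  stages <- list(module_deg = s1, hub = s2, sn_concordant = s3,
                 mouse_validated = s4, fly_rnai = s5, screen_top = s6)
  reasons <- setNames(rep("pass", length(genes)), genes)
  reasons[!in_funnel_module] <- "not_in_funnel_module"
  reasons[in_funnel_module & !is_deg] <- "not_bulk_deg"
  reasons[setdiff(s1, s2)] <- "not_hub"
  reasons[setdiff(s2, s3)] <- "sn_not_concordant"
  fail4 <- mv$gene[!mv$validated]
  reasons[fail4] <- paste0("mouse_", sub("^(mouse_)?", "",
                                         mv$reason[!mv$validated]))
  reasons[setdiff(s4, s5)] <- "no_fly_rnai"
  reasons[setdiff(s5, s6)] <- "not_top_suppressor"

  flags <- data.frame(gene = genes,
                      funnel_module = in_funnel_module, bulk_deg = is_deg,
                      hub = !is.na(own_mm) & own_mm > mm_cut,
                      sn_concordant = genes %in% s3,
                      mouse_validated = genes %in% s4,
                      fly_rnai = genes %in% fly$human_gene,
                      screen_top = genes %in% top,
                      stringsAsFactors = FALSE)
  structure(list(stages = stages, counts = lengths(stages), flags = flags,
                 reasons = reasons), class = "funnel_result")
}
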