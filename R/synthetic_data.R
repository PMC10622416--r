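#' Simulation configuration with planted ground truth
#'
#' Builds the configuration object that drives every synthetic generator in
#' the package. The defaults define the reference desk-scale study: two bulk
#' cohorts of 100 samples each over 2,000 genes carrying six planted
#' co-expression modules (two neuronal, one each oligodendrocyte, astrocyte,
#' endothelial, microglial), a clustered zero-inflated single-nucleus dataset,
#' a two-age-group tauopathy mouse study, ortholog maps with dropouts, and a
#' fly modifier screen whose top suppressors are the planted targets.
#'
#' Module genes double as cell-type marker genes: their expression tracks the
#' sample's (planted) cell-type proportion on the log2 scale plus a shared
#' module factor, which is what makes both module detection and marker-based
#' deconvolution recoverable from the same data. Diagnosis effects are planted
#' with a fixed magnitude `effect_size_dx` and a cell-type-determined sign
#' (glial modules up in cases, neuronal and oligodendrocyte modules down),
#' mirroring the directionality the pipeline's funnel expects.
#'
#' @param seed integer; fully determines all generated data.
#' @param n_genes total number of genes (includes small chrY and
#'   mitochondrial panels used by QC).
#' @param n_samples_per_cohort integer pair, samples in cohort 1 and 2
#'   (half cases, half controls each).
#' @param n_modules number of planted co-expression modules.
#' @param module_sizes integer vector of length `n_modules`.
#' @param module_celltype character vector of length `n_modules`; values in
#'   astrocyte, endothelia, microglia, neuron, oligodendrocyte.
#' @param effect_size_dx planted case-vs-control effect on module DEGs,
#'   log2 units.
#' @param deg_fraction fraction of each module's genes planted as diagnosis
#'   DEGs (planted targets always are).
#' @param pathology_effect slope of module-gene expression on the
#'   standardized overall tau-pathology score within cases, log2 units per SD.
#' @param noise_sd per-gene residual SD on the log2 scale.
#' @param module_factor_sd SD of the shared per-module latent factor.
#' @param sn_n_nuclei,sn_n_samples single-nucleus scale.
#' @param sn_dropout extra zero-inflation probability applied to UMI counts.
#' @param sn_batch_sd SD of independent per-sample, per-gene log2 offsets in
#'   the single-nucleus data (sample-level batch structure).
#' @param sn_marker_fold fold-elevation of a cell type's marker genes in
#'   nuclei of that type.
#' @param sn_effect_size planted case-vs-control log2 effect in the nuclei of
#'   a module's cell type.
#' @param mouse_concordance_rate probability that a planted human effect is
#'   transferred to the mouse ortholog with the same sign (planted targets are
#'   always concordant).
#' @param mouse_n_per_group mice per genotype per age group.
#' @param mouse_effect_size transgene effect magnitude, log2 units.
#' @param ortholog_dropout probability an ortholog row is missing (never for
#'   planted targets).
#' @param n_planted_targets number of genes planted to survive every evidence
#'   layer of the funnel.
#' @param plant_qc_outliers logical; plant one expression-profile outlier and
#'   one sex-swapped sample per bulk cohort, and a small set of QC-failing
#'   nuclei, so QC stages have true positives.
#'
#' @return object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_genes = 300, n_samples_per_cohort = c(40, 40),
#'                          n_modules = 3, module_sizes = c(40, 40, 40),
#'                          module_celltype = c("neuron", "astrocyte", "oligodendrocyte"))
simulation_config <- function(seed = 1L,
                              n_genes = 2000L,
                              n_samples_per_cohort = c(100L, 100L),
                              n_modules = 6L,
                              module_sizes = c(200L, 180L, 160L, 150L, 120L, 90L),
                              module_celltype = c("neuron", "neuron", "oligodendrocyte",
                                                  "astrocyte", "endothelia", "microglia"),
                              effect_size_dx = 1.0,
                              deg_fraction = 0.5,
                              pathology_effect = 0.5,
                              noise_sd = 1.0,
                              module_factor_sd = 1.0,
                              sn_n_nuclei = 2000L,
                              sn_n_samples = 10L,
                              sn_dropout = 0.3,
                              sn_batch_sd = 0.25,
                              sn_marker_fold = 10,
                              sn_effect_size = 1.0,
                              mouse_concordance_rate = 0.7,
                              mouse_n_per_group = 5L,
                              mouse_effect_size = 1.5,
                              ortholog_dropout = 0.1,
                              n_planted_targets = 5L,
                              plant_qc_outliers = TRUE) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_samples_per_cohort = as.integer(n_samples_per_cohort),
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              module_celltype = as.character(module_celltype),
              effect_size_dx = effect_size_dx, deg_fraction = deg_fraction,
              pathology_effect = pathology_effect,
              noise_sd = noise_sd, module_factor_sd = module_factor_sd,
              sn_n_nuclei = as.integer(sn_n_nuclei), sn_n_samples = as.integer(sn_n_samples),
              sn_dropout = sn_dropout, sn_batch_sd = sn_batch_sd,
              sn_marker_fold = sn_marker_fold,
              sn_effect_size = sn_effect_size,
              mouse_concordance_rate = mouse_concordance_rate,
              mouse_n_per_group = as.integer(mouse_n_per_group),
              mouse_effect_size = mouse_effect_size,
              ortholog_dropout = ortholog_dropout,
              n_planted_targets = as.integer(n_planted_targets),
              plant_qc_outliers = isTRUE(plant_qc_outliers))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

chry_gene_names <- function() c("RPS4Y1", "EIF1AY", "DDX3Y", "KDM5D",
                                "UTY", "USP9Y", "NLGN4Y", "ZFY")
mito_gene_names <- function() c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-CO3",
                                "MT-ATP6", "MT-CYB", "MT-ND4", "MT-ND5", "MT-RNR2")

celltype_universe <- function() c("astrocyte", "endothelia", "microglia",
                                  "neuron", "oligodendrocyte")

# Case-vs-control sign per cell type: neuronal/oligodendrocyte programs lost,
# reactive glial/vascular programs gained.
celltype_dx_sign <- function(types) {
  ifelse(types %in% c("neuron", "oligodendrocyte"), -1, 1)
}

validate_simulation_config <- function(cfg) {
  n_special <- length(chry_gene_names()) + length(mito_gene_names())
  if (length(cfg$module_sizes) != cfg$n_modules ||
      length(cfg$module_celltype) != cfg$n_modules)
    stop("module_sizes and module_celltype must have length n_modules")
  if (sum(cfg$module_sizes) + n_special > cfg$n_genes)
    stop("sum(module_sizes) plus reserved QC genes exceeds n_genes")
  if (!all(cfg$module_celltype %in% celltype_universe()))
    stop("module_celltype values must be one of: ",
         paste(celltype_universe(), collapse = ", "))
  probs <- c(cfg$sn_dropout, cfg$mouse_concordance_rate, cfg$ortholog_dropout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(cfg$n_samples_per_cohort) != 2L)
    stop("n_samples_per_cohort must be a pair")
  invisible(cfg)
}

gene_names_for <- function(cfg) {
  n_special <- length(chry_gene_names()) + length(mito_gene_names())
  c(sprintf("G%05d", seq_len(cfg$n_genes - n_special)),
    chry_gene_names(), mito_gene_names())
}

#' Ortholog naming conventions used by the generators
#' @noRd
mouse_ortholog_name <- function(g) paste0("Mm.", g)
fly_ortholog_name <- function(g) paste0("Dm.", g)

# Dirichlet draw via gamma normalization
rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  p <- g / rowSums(g)
  colnames(p) <- names(alpha)
  p
}

#' Generate two bulk RNA-seq cohorts with planted ground truth
#'
#' Simulates gene-level counts for two independent case/control cohorts that
#' share planted co-expression modules and diagnosis effects but differ in
#' batch structure (flowcell offsets, GC trends, library sizes) and covariate
#' distributions. Module genes load on (i) the log2 cell-type proportion of
#' the module's cell type, which makes them usable as deconvolution markers,
#' and (ii) a shared Gaussian module factor. Counts arise by Poisson sampling
#' of exponentiated Gaussian log2 means (log-normal-Poisson), so they are
#' over-dispersed and the normalization stage has real work to do.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `study1`, `study2` (class `bulk_study`: `counts`,
#'   `gene_annot`, `sample_meta`, `traits`) and `truth` (class `ground_truth`).
#' @export
generate_bulk_cohorts <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  genes <- gene_names_for(cfg)
  n_genes <- cfg$n_genes
  chry <- chry_gene_names(); mito <- mito_gene_names()

  # module labels: modules occupy the leading genes; specials are never in modules
  module_labels <- setNames(integer(n_genes), genes)
  idx <- 1L
  for (m in seq_len(cfg$n_modules)) {
    module_labels[idx:(idx + cfg$module_sizes[m] - 1L)] <- m
    idx <- idx + cfg$module_sizes[m]
  }
  module_sign <- celltype_dx_sign(cfg$module_celltype)

  # planted targets: high-loading genes in glial modules, spread round-robin
  glial_modules <- which(cfg$module_celltype != "neuron")
  if (length(glial_modules) == 0L) glial_modules <- seq_len(cfg$n_modules)
  target_pool <- rep(glial_modules, length.out = cfg$n_planted_targets)
  planted_targets <- character(0)
  taken <- integer(cfg$n_modules)
  for (m in target_pool) {
    taken[m] <- taken[m] + 1L
    members <- names(module_labels)[module_labels == m]
    planted_targets <- c(planted_targets, members[taken[m]])
  }

  dx_bulk <- setNames(numeric(n_genes), genes)
  in_module <- module_labels > 0L
  is_deg <- in_module & runif(n_genes) < cfg$deg_fraction
  is_deg[names(module_labels) %in% planted_targets] <- TRUE
  dx_bulk[is_deg] <- module_sign[module_labels[is_deg]] * cfg$effect_size_dx
  # targets are strong DEGs: robust to the noisy I^2-based model switch
  dx_bulk[planted_targets] <- dx_bulk[planted_targets] * 1.5
  path_slope <- setNames(numeric(n_genes), genes)
  path_slope[is_deg] <- module_sign[module_labels[is_deg]] * cfg$pathology_effect

  gene_annot <- data.frame(
    gene = genes,
    gc = round(runif(n_genes, 0.35, 0.65), 4),
    length = pmax(200L, as.integer(round(rlnorm(n_genes, log(2000), 0.5)))),
    chromosome = sample(as.character(1:22), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  gene_annot$chromosome[match(chry, genes)] <- "Y"
  gene_annot$chromosome[match(mito, genes)] <- "MT"
  rownames(gene_annot) <- genes

  base <- setNames(rnorm(n_genes, 5, 1.2), genes)
  base[chry] <- 1.0   # low female background; +5 in males
  loadings <- setNames(runif(n_genes, 0.7, 1.3), genes)
  loadings[planted_targets] <- 1.3
  noise_scale <- setNames(rep(1, n_genes), genes)
  noise_scale[planted_targets] <- 0.6

  alpha <- c(astrocyte = 4, endothelia = 1.5, microglia = 2,
             neuron = 10, oligodendrocyte = 6)

  make_cohort <- function(study_id, n_samples, n_flowcells, source_label) {
    n_case <- n_samples %/% 2L
    diagnosis <- rep(c("case", "control"), c(n_case, n_samples - n_case))
    sex <- sample(c("M", "F"), n_samples, replace = TRUE)
    true_sex <- sex
    age <- round(rnorm(n_samples, 72, 8), 1)
    rin <- round(runif(n_samples, 5.5, 9.5), 1)
    flowcell <- paste0("FC", study_id, "_", sample(seq_len(n_flowcells),
                                                   n_samples, replace = TRUE))
    sample_ids <- sprintf("S%d_%03d", study_id, seq_len(n_samples))

    props <- rdirichlet_rows(n_samples, alpha)
    rownames(props) <- sample_ids
    if (cfg$plant_qc_outliers && n_samples >= 8L) {
      # composition outlier: a near-pure neuronal sample, far out on the
      # dominant (cell-composition) axis of expression variation
      props[n_samples, ] <- c(astrocyte = 0.02, endothelia = 0.01,
                              microglia = 0.02, neuron = 0.92,
                              oligodendrocyte = 0.03)[colnames(props)]
    }

    # pathology: defined for cases only; overall drives 4 lesion scores
    overall <- pmax(0.2, rnorm(n_samples, 3, 1))
    overall[diagnosis != "case"] <- NA
    lesion <- function() pmax(0, overall + rnorm(n_samples, 0, 0.6))
    traits <- data.frame(TA = lesion(), CB = lesion(), NFT = lesion(),
                         TauTh = lesion(), overall = overall,
                         row.names = sample_ids)
    path_z <- (overall - mean(overall, na.rm = TRUE)) / sd(overall, na.rm = TRUE)
    path_z[is.na(path_z)] <- 0

    # per-module latent factors (orthogonalized to diagnosis so the planted
    # case/control effect is exactly the configured value, not confounded by
    # chance factor-diagnosis correlation) and marker (log-proportion) terms
    h <- matrix(rnorm(cfg$n_modules * n_samples, 0, 1), nrow = cfg$n_modules)
    dx_ind <- as.numeric(diagnosis == "case")
    for (m in seq_len(cfg$n_modules)) {
      r <- lm(h[m, ] ~ dx_ind)$residuals
      h[m, ] <- r / sd(r) * cfg$module_factor_sd
    }
    logp <- t(log2(props))                       # celltype x sample
    logp <- logp - rowMeans(logp)

    mu <- matrix(base, nrow = n_genes, ncol = n_samples,
                 dimnames = list(genes, sample_ids))
    for (m in seq_len(cfg$n_modules)) {
      members <- which(module_labels == m)
      mu[members, ] <- mu[members, ] +
        matrix(logp[cfg$module_celltype[m], ], length(members), n_samples, byrow = TRUE) +
        outer(loadings[members], h[m, ])
    }
    is_case <- as.numeric(diagnosis == "case")
    mu <- mu + outer(dx_bulk, is_case) + outer(path_slope, path_z)

    # batch (flowcell) additive offsets + per-sample GC trend tied to flowcell
    fcs <- sort(unique(flowcell))
    batch_fx <- matrix(rnorm(n_genes * length(fcs), 0, 0.3), n_genes,
                       dimnames = list(genes, fcs))
    batch_fx[, 1] <- 0
    mu <- mu + batch_fx[, flowcell]
    gc_slope <- rnorm(length(fcs), 0, 1.5)[match(flowcell, fcs)] +
      rnorm(n_samples, 0, 0.3)
    mu <- mu + outer(gene_annot$gc - mean(gene_annot$gc), gc_slope)
    len_slope <- rnorm(n_samples, 0, 0.3)
    loglen <- log2(gene_annot$length) - mean(log2(gene_annot$length))
    mu <- mu + outer(loglen, len_slope)

    # sex: chrY genes expressed in (true) males only
    mu[chry, ] <- mu[chry, ] + 5 * matrix(as.numeric(true_sex == "M"),
                                          length(chry), n_samples, byrow = TRUE)

    mu <- mu + matrix(rnorm(n_genes * n_samples, 0, cfg$noise_sd), n_genes) *
      noise_scale

    qc_truth <- rep("ok", n_samples)
    if (cfg$plant_qc_outliers && n_samples >= 8L) {
      # outlier: the near-pure-neuron sample planted above, with its whole
      # expression deviation amplified (global technical aberration), so it
      # sits far out on the leading principal components
      out_s <- n_samples
      mu[, out_s] <- rowMeans(mu) + 3 * (mu[, out_s] - rowMeans(mu))
      qc_truth[out_s] <- "pc_outlier"
      swap_s <- which(true_sex == "M" & seq_len(n_samples) < out_s)
      if (length(swap_s)) {
        swap_s <- swap_s[length(swap_s)]
        sex[swap_s] <- "F"             # recorded sex wrong; chrY stays male
        qc_truth[swap_s] <- "sex_swap"
      }
    }

    libfac <- rlnorm(n_samples, 0, 0.25)
    lambda <- sweep(2^mu, 2, libfac, `*`)
    counts <- matrix(rpois(length(lambda), lambda), nrow = n_genes,
                     dimnames = dimnames(mu))

    meta <- data.frame(sample = sample_ids, diagnosis = diagnosis, sex = sex,
                       age_at_death = age, rin = rin, flowcell = flowcell,
                       source = source_label, qc_truth = qc_truth,
                       row.names = sample_ids, stringsAsFactors = FALSE)
    list(study = structure(list(counts = counts, gene_annot = gene_annot,
                                sample_meta = meta, traits = traits,
                                expr = NULL, study_id = study_id),
                           class = "bulk_study"),
         props = props)
  }

  c1 <- make_cohort(1L, cfg$n_samples_per_cohort[1], 2L, "bankA")
  c2 <- make_cohort(2L, cfg$n_samples_per_cohort[2], 3L, "bankB")

  # cross-species planted effects (realized here so all arms share one truth)
  dx_sn <- setNames(numeric(n_genes), genes)
  dx_sn[is_deg] <- module_sign[module_labels[is_deg]] * cfg$sn_effect_size
  dx_mouse <- setNames(numeric(n_genes), genes)
  mod_genes <- names(module_labels)[is_deg]
  conc <- runif(length(mod_genes)) < cfg$mouse_concordance_rate
  flip <- runif(length(mod_genes)) < 0.5
  dx_mouse[mod_genes] <- ifelse(conc, dx_bulk[mod_genes] / cfg$effect_size_dx,
                                ifelse(flip, -sign(dx_bulk[mod_genes]), 0)) *
    cfg$mouse_effect_size
  dx_mouse[planted_targets] <- sign(dx_bulk[planted_targets]) * cfg$mouse_effect_size

  fly_effects <- setNames(numeric(n_genes), genes)
  fly_effects[planted_targets] <- -1

  truth <- structure(list(
    module_labels = module_labels,
    module_celltype = setNames(cfg$module_celltype, seq_len(cfg$n_modules)),
    module_sign = setNames(module_sign, seq_len(cfg$n_modules)),
    dx_effects = list(bulk = dx_bulk, sn = dx_sn, mouse = dx_mouse),
    planted_targets = planted_targets,
    true_proportions = list(study1 = c1$props, study2 = c2$props),
    fly_effects = fly_effects,
    marker_sets = split(names(module_labels)[in_module],
                        cfg$module_celltype[module_labels[in_module]])),
    class = "ground_truth")

  list(study1 = c1$study, study2 = c2$study, truth = truth)
}

#' Generate a clustered, zero-inflated single-nucleus dataset
#'
#' Nuclei are drawn from a mixture over the cell types present in the planted
#' modules (plus neurons), with each type's marker genes (its modules' member
#' genes) elevated `sn_marker_fold`-fold, per-sample batch offsets, extra
#' Bernoulli dropout at rate `sn_dropout`, and planted case/control effects
#' applied in nuclei of the module's cell type with the sign planted in
#' `truth`. A small set of nuclei deliberately violates QC bounds (low UMI,
#' high mitochondrial fraction) when `plant_qc_outliers` is set.
#'
#' @param cfg a [simulation_config()].
#' @param truth the `ground_truth` from [generate_bulk_cohorts()].
#' @return object of class `sn_dataset`: sparse `counts` (nuclei x genes,
#'   `dgCMatrix`), `nucleus_meta` (sample, diagnosis, sex, age, true_type).
#' @export
generate_snrna <- function(cfg, truth) {
  validate_simulation_config(cfg)
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(cfg$seed + 1000L)
  genes <- names(truth$module_labels)
  n_genes <- length(genes)
  types <- celltype_universe()
  type_props <- c(astrocyte = 0.15, endothelia = 0.10, microglia = 0.10,
                  neuron = 0.40, oligodendrocyte = 0.25)
  n_nuc <- cfg$sn_n_nuclei
  if (n_nuc < length(types)) stop("sn_n_nuclei smaller than the number of cell types")

  n_samp <- cfg$sn_n_samples
  samp_ids <- sprintf("SN_%02d", seq_len(n_samp))
  samp_dx <- rep(c("case", "control"), length.out = n_samp)
  samp_sex <- sample(c("M", "F"), n_samp, replace = TRUE)
  samp_age <- round(rnorm(n_samp, 70, 7), 1)

  nuc_sample <- sample(samp_ids, n_nuc, replace = TRUE)
  nuc_type <- sample(types, n_nuc, replace = TRUE, prob = type_props[types])
  nuc_dx <- samp_dx[match(nuc_sample, samp_ids)]

  base_rate <- setNames(2^rnorm(n_genes, 0, 1), genes)
  # planted targets are well-expressed in every modality by construction
  base_rate[truth$planted_targets] <- pmax(base_rate[truth$planted_targets], 2^1.5)
  base_rate[mito_gene_names()] <- sum(base_rate) * 0.05 / length(mito_gene_names())
  base_rate[chry_gene_names()] <- base_rate[chry_gene_names()] * 0.5

  # marker genes of each type = member genes of that type's modules
  marker_of <- lapply(types, function(t) {
    mods <- which(truth$module_celltype == t)
    which(truth$module_labels %in% mods)
  })
  names(marker_of) <- types

  # per-sample batch: independent gene-level log2 offsets per sample
  batch_fx <- matrix(rnorm(n_samp * n_genes, 0, cfg$sn_batch_sd), n_samp)

  lib <- pmax(1500, round(rlnorm(n_nuc, log(3000), 0.3)))
  qc_truth <- rep("ok", n_nuc)
  if (cfg$plant_qc_outliers && n_nuc >= 50L) {
    n_bad <- max(2L, n_nuc %/% 100L)
    bad <- (n_nuc - 2L * n_bad + 1L):n_nuc
    low <- bad[seq_len(n_bad)]; hi_mito <- bad[-seq_len(n_bad)]
    lib[low] <- round(runif(n_bad, 300, 800))
    qc_truth[low] <- "low_umi"
    qc_truth[hi_mito] <- "high_mito"
  } else hi_mito <- integer(0)

  male_samples <- samp_ids[samp_sex == "M"]
  trip_i <- vector("list", n_nuc); trip_x <- vector("list", n_nuc)
  for (n in seq_len(n_nuc)) {
    rate <- base_rate
    t <- nuc_type[n]
    rate[marker_of[[t]]] <- rate[marker_of[[t]]] * cfg$sn_marker_fold
    if (nuc_dx[n] == "case") {
      eff <- truth$dx_effects$sn[marker_of[[t]]]
      rate[marker_of[[t]]] <- rate[marker_of[[t]]] * 2^eff
    }
    if (!(nuc_sample[n] %in% male_samples)) rate[chry_gene_names()] <- 1e-8
    if (n %in% hi_mito) {
      # force the mitochondrial share to ~18% of the final rate mass
      mito <- mito_gene_names()
      rate[mito] <- rate[mito] / sum(rate[mito]) * 0.18 / 0.82 *
        sum(rate[setdiff(genes, mito)])
    }
    rate <- rate * 2^batch_fx[match(nuc_sample[n], samp_ids), ]
    lam <- lib[n] * rate / sum(rate)
    x <- rpois(n_genes, lam)
    if (cfg$sn_dropout > 0) {
      nz <- which(x > 0)
      keep <- runif(length(nz)) >= cfg$sn_dropout
      x[nz[!keep]] <- 0L
    }
    nz <- which(x > 0)
    trip_i[[n]] <- nz; trip_x[[n]] <- x[nz]
  }
  counts <- Matrix::sparseMatrix(
    i = rep(seq_len(n_nuc), lengths(trip_i)),
    j = unlist(trip_i), x = unlist(trip_x),
    dims = c(n_nuc, n_genes),
    dimnames = list(sprintf("BC%05d", seq_len(n_nuc)), genes))

  meta <- data.frame(barcode = rownames(counts), sample = nuc_sample,
                     diagnosis = nuc_dx,
                     sex = samp_sex[match(nuc_sample, samp_ids)],
                     age = samp_age[match(nuc_sample, samp_ids)],
                     true_type = nuc_type, qc_truth = qc_truth,
                     row.names = rownames(counts), stringsAsFactors = FALSE)
  structure(list(counts = methods::as(counts, "CsparseMatrix"),
                 nucleus_meta = meta, qc_log = NULL,
                 embedding = NULL, snn = NULL, cluster_labels = NULL,
                 cluster_annotation = NULL, norm = NULL),
            class = "sn_dataset")
}

#' Generate the tauopathy-mouse validation study
#'
#' Two age groups (4.5 and 6 months), transgenic (rTg4510) versus
#' non-transgenic animals, with sex and RIN covariates. Each planted human
#' effect is transferred to the mouse ortholog according to the concordance
#' already realized in `truth$dx_effects$mouse` (same sign with probability
#' `mouse_concordance_rate`, otherwise absent or sign-flipped; planted targets
#' always concordant). Counts are log-normal-Poisson.
#'
#' @inheritParams generate_snrna
#' @return object of class `mouse_study`: `counts` (mouse genes x samples) and
#'   `sample_meta` (genotype, age_group, sex, rin).
#' @export
generate_mouse_study <- function(cfg, truth) {
  validate_simulation_config(cfg)
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(cfg$seed + 2000L)
  hgenes <- names(truth$module_labels)
  mgenes <- mouse_ortholog_name(hgenes)
  n_genes <- length(mgenes)
  n_per <- cfg$mouse_n_per_group
  groups <- expand.grid(genotype = c("rTg4510", "nonTg"),
                        age_group = c("4.5", "6"), rep = seq_len(n_per),
                        stringsAsFactors = FALSE)
  n_samples <- nrow(groups)
  ids <- sprintf("MS_%02d", seq_len(n_samples))
  sex <- sample(c("M", "F"), n_samples, replace = TRUE)
  rin <- round(runif(n_samples, 6, 9.5), 1)

  base <- rnorm(n_genes, 5, 1.2)
  base[match(truth$planted_targets, hgenes)] <-
    pmax(base[match(truth$planted_targets, hgenes)], 7)   # targets well expressed
  eff <- truth$dx_effects$mouse[hgenes]           # log2, signed, 0 if absent
  age_scale <- ifelse(groups$age_group == "6", 1.2, 1)
  is_tg <- as.numeric(groups$genotype == "rTg4510")
  mu <- matrix(base, n_genes, n_samples, dimnames = list(mgenes, ids)) +
    outer(eff, is_tg * age_scale) +
    outer(rnorm(n_genes, 0, 0.05), as.numeric(sex == "M")) +
    matrix(rnorm(n_genes * n_samples, 0, 0.4), n_genes)
  libfac <- rlnorm(n_samples, 0, 0.2)
  counts <- matrix(rpois(length(mu), sweep(2^mu, 2, libfac, `*`)),
                   n_genes, dimnames = dimnames(mu))
  meta <- data.frame(sample = ids, genotype = groups$genotype,
                     age_group = groups$age_group, sex = sex, rin = rin,
                     row.names = ids, stringsAsFactors = FALSE)
  structure(list(counts = counts, sample_meta = meta), class = "mouse_study")
}

#' Generate ortholog maps and the fly modifier screen
#'
#' Human-to-mouse and human-to-fly ortholog rows are dropped independently
#' with probability `ortholog_dropout` (never for planted targets). Fly RNAi
#' stock availability is a per-gene flag (always available for targets).
#' Screen scores are on the semi-quantitative -4..4 scale: planted targets
#' receive scores below -1.5 (top suppressors), all other screened genes
#' receive scores centred at 0 and bounded above -1.5, and a small fraction of
#' screened lines is lethal (a categorical outcome, no numeric score).
#'
#' @inheritParams generate_snrna
#' @return list with `ortholog_map` (data.frame: human_gene, species,
#'   ortholog_gene, rnai_available) and `fly_screen` (data.frame: human_gene,
#'   fly_gene, screen_score, outcome).
#' @export
generate_cross_species_maps <- function(cfg, truth) {
  validate_simulation_config(cfg)
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(cfg$seed + 3000L)
  genes <- names(truth$module_labels)
  targets <- truth$planted_targets

  keep_mouse <- runif(length(genes)) >= cfg$ortholog_dropout | genes %in% targets
  keep_fly <- runif(length(genes)) >= cfg$ortholog_dropout | genes %in% targets
  rnai <- runif(length(genes)) < 0.7 | genes %in% targets

  map <- rbind(
    data.frame(human_gene = genes[keep_mouse], species = "mouse",
               ortholog_gene = mouse_ortholog_name(genes[keep_mouse]),
               rnai_available = NA, stringsAsFactors = FALSE),
    data.frame(human_gene = genes[keep_fly], species = "fly",
               ortholog_gene = fly_ortholog_name(genes[keep_fly]),
               rnai_available = rnai[keep_fly], stringsAsFactors = FALSE))

  screened <- genes[keep_fly & rnai]
  is_target <- screened %in% targets
  score <- numeric(length(screened))
  score[is_target] <- round(runif(sum(is_target), -3.5, -2) * 2) / 2
  nt <- sum(!is_target)
  score[!is_target] <- pmax(-1.5, pmin(4, round(rnorm(nt, 0, 0.6) * 2) / 2))
  outcome <- rep("scored", length(screened))
  lethal <- !is_target & runif(length(screened)) < 0.03
  outcome[lethal] <- "lethal"
  score[lethal] <- NA_real_
  fly <- data.frame(human_gene = screened, fly_gene = fly_ortholog_name(screened),
                    screen_score = score, outcome = outcome,
                    stringsAsFactors = FALSE)
  list(ortholog_map = map, fly_screen = fly)
}
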