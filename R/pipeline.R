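#' Read a TSV with contextual parse errors
#' @param path file path.
#' @param ... passed to [utils::read.delim()].
#' @return data.frame.
#' @export
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  tryCatch(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, ...),
           error = function(e) stop("parse error in ", path, ": ",
                                    conditionMessage(e)),
           warning = function(w) stop("parse error in ", path, ": ",
                                      conditionMessage(w)))
}

#' Write a matrix or data.frame as TSV
#' @param x matrix (written with rownames in a `gene`/first column) or
#'   data.frame.
#' @param path output path.
#' @param rowname_col name of the first column when `x` has rownames.
#' @export
write_tsv_out <- function(x, path, rowname_col = "gene") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- rowname_col
    x <- df
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric gene x sample TSV written by [write_tsv_out()]
#' @param path file path.
#' @return numeric matrix with rownames from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_strict(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a single-nucleus dataset in 10x-style MatrixMarket layout
#'
#' Writes `matrix.mtx` (genes x nuclei triplets), `features.tsv`,
#' `barcodes.tsv` and `meta.tsv` under `dir`.
#'
#' @param sn an `sn_dataset`.
#' @param dir output directory.
#' @export
write_sn_dataset <- function(sn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::t(sn$counts)                    # genes x nuclei, 10x layout
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  write_tsv_out(sn$nucleus_meta, file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Read a single-nucleus dataset written by [write_sn_dataset()]
#' @param dir directory with matrix.mtx, features.tsv, barcodes.tsv, meta.tsv.
#' @return an `sn_dataset`.
#' @export
read_sn_dataset <- function(dir) {
  m <- tryCatch(Matrix::readMM(file.path(dir, "matrix.mtx")),
                error = function(e) stop("parse error in ",
                                         file.path(dir, "matrix.mtx"), ": ",
                                         conditionMessage(e)))
  feats <- readLines(file.path(dir, "features.tsv"))
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(feats, bcs)
  counts <- methods::as(Matrix::t(m), "CsparseMatrix")
  meta <- read_tsv_strict(file.path(dir, "meta.tsv"))
  rownames(meta) <- meta$barcode
  structure(list(counts = counts, nucleus_meta = meta[rownames(counts), ],
                 qc_log = NULL, embedding = NULL, snn = NULL,
                 cluster_labels = NULL, cluster_annotation = NULL,
                 norm = NULL), class = "sn_dataset")
}

#' Pipeline configuration
#'
#' Collects the synthetic-data configuration, every analysis threshold (all
#' defaulting to the values the method prescribes), and the seed into one
#' object consumed by [run_pipeline()].
#'
#' @param sim a [simulation_config()].
#' @param fdr_cut DEG significance threshold (0.05).
#' @param mm_hub_cut hub module-membership threshold (0.7).
#' @param merge_threshold,reassign_in module merge/reassignment thresholds
#'   (0.8, 0.5).
#' @param screen_cut top-suppressor screen threshold (-1.5).
#' @param detect_threshold single-nucleus detection fraction (0.20).
#' @param resolution,subcluster_resolution Louvain resolutions (0.4, 0.3).
#' @param beta_power soft power (12).
#' @param min_module_size,cut_height tree-cut parameters (30, 0.99).
#' @param n_perm preservation permutations (100).
#' @param filter_thresholds per-cohort low-expression thresholds (c(2, -1)).
#' @param n_pcs,k_neighbors embedding/graph parameters (30, 20).
#' @param qc_umi_lower,qc_genes_lower nucleus QC lower bounds (1000, 500);
#'   reduce for small simulated gene universes.
#' @param do_preservation compute preservation Z statistics (default TRUE).
#' @param hurdle_clusters "funnel" (only clusters annotated to funnel cell
#'   types; the ones the cascade consumes) or "all".
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            fdr_cut = 0.05, mm_hub_cut = 0.7,
                            merge_threshold = 0.8, reassign_in = 0.5,
                            screen_cut = -1.5, detect_threshold = 0.20,
                            resolution = 0.4, subcluster_resolution = 0.3,
                            beta_power = 12, min_module_size = 30L,
                            cut_height = 0.99, n_perm = 100L,
                            filter_thresholds = c(2, -1),
                            n_pcs = 30L, k_neighbors = 20L,
                            qc_umi_lower = 1000, qc_genes_lower = 500,
                            do_preservation = TRUE,
                            hurdle_clusters = c("funnel", "all")) {
  structure(list(sim = sim, fdr_cut = fdr_cut, mm_hub_cut = mm_hub_cut,
                 merge_threshold = merge_threshold, reassign_in = reassign_in,
                 screen_cut = screen_cut, detect_threshold = detect_threshold,
                 resolution = resolution,
                 subcluster_resolution = subcluster_resolution,
                 beta_power = beta_power, min_module_size = min_module_size,
                 cut_height = cut_height, n_perm = n_perm,
                 filter_thresholds = filter_thresholds, n_pcs = n_pcs,
                 k_neighbors = k_neighbors, qc_umi_lower = qc_umi_lower,
                 qc_genes_lower = qc_genes_lower,
                 do_preservation = isTRUE(do_preservation),
                 hurdle_clusters = match.arg(hurdle_clusters)),
            class = "pipeline_config")
}

#' Annotate detected modules with cell types and disease direction
#'
#' Each module is assigned the cell type whose marker set is most enriched
#' (Bonferroni-adjusted hypergeometric p < alpha) among its genes, and a
#' disease direction from the sign of its eigengene's diagnosis association.
#'
#' @param modules a `module_set`.
#' @param marker_sets named list of cell-type marker genes.
#' @param diagnosis numeric 0/1 vector aligned with the eigengene rows.
#' @param alpha enrichment threshold (default 0.05).
#' @return data.frame: module, celltype ("unassigned" if none), direction,
#'   r_dx.
#' @export
annotate_modules <- function(modules, marker_sets, diagnosis, alpha = 0.05) {
  labels <- modules$labels
  background <- names(labels)
  mods <- sort(unique(labels[labels > 0]))
  rows <- lapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    enr <- gene_set_enrichment(genes, marker_sets, background, mode = "marker")
    best <- enr[order(enr$p, enr$set), ][1, ]
    ct <- if (best$p_adj < alpha) best$set else "unassigned"
    r <- bicor(modules$me[, paste0("ME", m)], diagnosis)
    data.frame(module = m, celltype = ct, direction = sign(r), r_dx = r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full synthetic pipeline
#'
#' Generates all inputs from the configuration's simulation block, then
#' executes preprocessing, two-study DGE and meta-analysis, the consensus
#' network, the single-nucleus arm, the mouse and fly arms, and the
#' prioritization funnel. Fully deterministic given the simulation seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV/MatrixMarket files.
#' @param verbose print stage progress.
#' @return list of class `pipeline_result` with all stage artifacts and a
#'   `manifest` of per-stage row counts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$sim$seed)
  tick <- function(stage, n) manifest[[stage]] <<- n

  vmsg(verbose, "generating bulk cohorts")
  gen <- generate_bulk_cohorts(config$sim)
  truth <- gen$truth

  vmsg(verbose, "preprocessing")
  s1 <- preprocess_bulk_study(gen$study1)
  s2 <- preprocess_bulk_study(gen$study2)
  keep_genes <- filter_low_expressed(s1$expr, s2$expr,
                                     config$filter_thresholds)
  s1$expr <- s1$expr[keep_genes, , drop = FALSE]
  s2$expr <- s2$expr[keep_genes, , drop = FALSE]
  tick("genes_after_filter", length(keep_genes))
  tick("samples_study1", ncol(s1$expr)); tick("samples_study2", ncol(s2$expr))

  marker_sets <- lapply(truth$marker_sets, intersect, keep_genes)
  props1 <- estimate_cell_proportions(s1$expr, marker_sets)
  props2 <- estimate_cell_proportions(s2$expr, marker_sets)

  vmsg(verbose, "differential expression + meta-analysis")
  covar_cols <- c("sex", "age_at_death", "rin", "flowcell")
  dx1 <- as.numeric(s1$sample_meta$diagnosis == "case")
  dx2 <- as.numeric(s2$sample_meta$diagnosis == "case")
  a1 <- fit_gene_trait(s1$expr, dx1, s1$sample_meta[, covar_cols])
  a2 <- fit_gene_trait(s2$expr, dx2, s2$sample_meta[, covar_cols])
  meta <- meta_analyze(a1, a2)
  tick("meta_genes", nrow(meta))
  tick("bulk_degs", sum(meta$fdr < config$fdr_cut))
  top_genes <- suppressWarnings(select_top_genes(meta))
  deg_up <- meta$gene[meta$fdr < config$fdr_cut & meta$beta_meta > 0]
  deg_down <- meta$gene[meta$fdr < config$fdr_cut & meta$beta_meta < 0]
  deg_enrichment <- deg_celltype_enrichment(deg_up, deg_down,
                                            marker_sets, meta$gene)

  # quantitative tau-pathology traits, within cases, meta-analyzed
  path_meta <- list()
  cov_dx <- c(covar_cols, "diagnosis")
  for (tr in c("TA", "CB", "NFT", "TauTh", "overall")) {
    p1 <- fit_gene_trait(s1$expr, s1$traits[[tr]],
                         s1$sample_meta[, cov_dx], case_only = TRUE)
    p2 <- fit_gene_trait(s2$expr, s2$traits[[tr]],
                         s2$sample_meta[, cov_dx], case_only = TRUE)
    path_meta[[tr]] <- meta_analyze(p1, p2)
  }

  vmsg(verbose, "consensus network")
  net <- build_consensus_network(
    s1$expr, s2$expr,
    s1$sample_meta[, covar_cols], s2$sample_meta[, covar_cols],
    beta_power = config$beta_power,
    min_module_size = config$min_module_size,
    cut_height = config$cut_height,
    merge_threshold = config$merge_threshold,
    reassign_in = config$reassign_in)
  modules <- net$modules
  tick("n_modules", length(unique(modules$labels[modules$labels > 0])))

  dx_all <- c(dx1, dx2)
  mod_annot <- annotate_modules(modules, marker_sets, dx_all)
  traits_all <- rbind(s1$traits, s2$traits)
  traits_all$diagnosis <- dx_all
  mta <- module_trait_association(modules$me, traits_all)

  preservation <- NULL
  if (config$do_preservation)
    preservation <- module_preservation(net$resid1, net$resid2,
                                        modules$labels,
                                        n_perm = config$n_perm,
                                        seed = config$sim$seed)

  vmsg(verbose, "single-nucleus arm")
  sn <- generate_snrna(config$sim, truth)
  sn <- qc_nuclei(sn, umi_lower = config$qc_umi_lower,
                  genes_lower = config$qc_genes_lower)
  sn <- normalize_and_embed(sn, n_pcs = min(config$n_pcs,
                                            nrow(sn$counts) - 1L))
  clusters <- cluster_nuclei(sn$embedding, k_neighbors = config$k_neighbors,
                             resolution = config$resolution,
                             seed = config$sim$seed)
  tick("n_nuclei", nrow(sn$counts))
  tick("n_sn_clusters", length(unique(clusters)))
  composition <- test_cluster_composition(clusters, sn$nucleus_meta)
  markers <- find_cluster_markers(sn, clusters)
  cl_annot <- annotate_clusters(markers, marker_sets,
                                background = colnames(sn$norm))

  # funnel module map: glial modules with a confident cell type
  glial <- c("astrocyte", "endothelia", "microglia", "oligodendrocyte",
             "pericyte")
  fm <- mod_annot[mod_annot$celltype %in% glial & mod_annot$direction != 0, ]
  module_config <- setNames(lapply(seq_len(nrow(fm)), function(i)
    list(celltypes = fm$celltype[i], direction = fm$direction[i])),
    as.character(fm$module))

  de_clusters <- sort(unique(clusters))
  if (config$hurdle_clusters == "funnel") {
    ct_needed <- unique(unlist(lapply(module_config, `[[`, "celltypes")))
    de_clusters <- names(cl_annot)[cl_annot %in% ct_needed]
  }
  sn_degs <- list()
  for (cl in de_clusters) {
    nuc <- names(clusters)[clusters == cl]
    if (length(unique(sn$nucleus_meta[nuc, "diagnosis"])) < 2L) next
    if (length(nuc) < 20L) next
    sn_degs[[cl]] <- hurdle_de(sn, clusters, cl,
                               detect_threshold = config$detect_threshold)
  }
  tick("sn_de_clusters", length(sn_degs))

  # module scores per nucleus and module <-> cluster-DEG overlap tables
  sn_background <- intersect(keep_genes, colnames(sn$norm))
  module_scores <- sapply(names(module_config), function(m) {
    genes <- names(modules$labels)[modules$labels == as.integer(m)]
    module_score(sn, intersect(genes, colnames(sn$norm)),
                 seed = config$sim$seed)
  })
  module_cluster_overlap <- do.call(rbind, lapply(names(module_config),
    function(m) {
      genes <- names(modules$labels)[modules$labels == as.integer(m)]
      do.call(rbind, lapply(names(sn_degs), function(cl) {
        cbind(module = m, cluster = cl,
              overlap_module_cluster_degs(genes, sn_degs[[cl]],
                                          sn_background))
      }))
    }))

  vmsg(verbose, "mouse + fly arms")
  mouse <- generate_mouse_study(config$sim, truth)
  mres <- mouse_de(mouse)
  maps <- generate_cross_species_maps(config$sim, truth)

  vmsg(verbose, "funnel")
  funnel <- run_funnel(meta, modules, module_config, sn_degs, cl_annot,
                       mres, maps$ortholog_map, maps$fly_screen,
                       fdr_cut = config$fdr_cut, mm_cut = config$mm_hub_cut,
                       screen_cut = config$screen_cut)
  for (s in names(funnel$stages))
    tick(paste0("funnel_", s), length(funnel$stages[[s]]))

  result <- structure(list(
    truth = truth, study1 = s1, study2 = s2, proportions = list(props1, props2),
    assoc = list(a1, a2), meta = meta, top_genes = top_genes,
    deg_enrichment = deg_enrichment, pathology_meta = path_meta,
    module_scores = module_scores,
    module_cluster_overlap = module_cluster_overlap,
    network = net, modules = modules,
    module_annotation = mod_annot, module_trait = mta,
    preservation = preservation, sn = sn, clusters = clusters,
    composition = composition, markers = markers,
    cluster_annotation = cl_annot, sn_degs = sn_degs, mouse = mouse,
    mouse_results = mres, ortholog_map = maps$ortholog_map,
    fly_screen = maps$fly_screen, funnel = funnel,
    manifest = manifest, config = config), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write all tabular pipeline outputs under a directory
#' @param result a `pipeline_result`.
#' @param out_dir output directory.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_out(result$meta, file.path(out_dir, "meta_dge.tsv"))
  labels_df <- data.frame(gene = names(result$modules$labels),
                          module = unname(result$modules$labels))
  write_tsv_out(labels_df, file.path(out_dir, "module_labels.tsv"))
  write_tsv_out(result$modules$me, file.path(out_dir, "module_eigengenes.tsv"),
                rowname_col = "sample")
  write_tsv_out(result$modules$mm, file.path(out_dir, "module_membership.tsv"))
  write_tsv_out(result$module_trait, file.path(out_dir, "module_trait.tsv"))
  cl_df <- data.frame(barcode = names(result$clusters),
                      cluster = unname(result$clusters),
                      celltype = unname(result$cluster_annotation[result$clusters]))
  write_tsv_out(cl_df, file.path(out_dir, "sn_clusters.tsv"))
  for (cl in names(result$sn_degs))
    write_tsv_out(result$sn_degs[[cl]],
                  file.path(out_dir, sprintf("sn_degs_%s.tsv", cl)))
  write_tsv_out(result$ortholog_map, file.path(out_dir, "ortholog_map.tsv"))
  write_tsv_out(result$fly_screen, file.path(out_dir, "fly_screen.tsv"))
  write_tsv_out(result$funnel$flags, file.path(out_dir, "funnel_flags.tsv"))
  counts_df <- data.frame(stage = names(result$funnel$counts),
                          n = unname(result$funnel$counts))
  write_tsv_out(counts_df, file.path(out_dir, "funnel_counts.tsv"))
  mani <- data.frame(key = names(result$manifest),
                     value = vapply(result$manifest, as.character, ""))
  write_tsv_out(mani, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("Evidence-cascade funnel\n")
  for (s in names(x$stages))
    cat(sprintf("  %-16s %d\n", s, length(x$stages[[s]])))
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("gliafunnel pipeline result (seed", x$manifest$seed, ")\n")
  cat("  genes:", x$manifest$genes_after_filter,
      " modules:", x$manifest$n_modules,
      " nuclei:", x$manifest$n_nuclei,
      " clusters:", x$manifest$n_sn_clusters, "\n")
  print(x$funnel)
  invisible(x)
}
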