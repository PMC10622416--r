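test_that("configuration is validated", {
  expect_error(simulation_config(n_genes = 100, module_sizes = c(60, 60, 60),
                                 n_modules = 3,
                                 module_celltype = rep("neuron", 3)),
               "exceeds n_genes")
  expect_error(simulation_config(sn_dropout = 1.5), "probabilities")
  expect_error(simulation_config(module_celltype = c("x", rep("neuron", 5))),
               "module_celltype")
})

test_that("all generators are pure functions of the seed", {
  cfg <- simulation_config(seed = 42, n_genes = 200,
                           n_samples_per_cohort = c(20, 20), n_modules = 2,
                           module_sizes = c(40, 30),
                           module_celltype = c("neuron", "astrocyte"),
                           sn_n_nuclei = 150, sn_n_samples = 4,
                           n_planted_targets = 1)
  a <- generate_bulk_cohorts(cfg)
  b <- generate_bulk_cohorts(cfg)
  expect_identical(a$study1$counts, b$study1$counts)
  expect_identical(a$study2$counts, b$study2$counts)
  expect_identical(a$truth$dx_effects, b$truth$dx_effects)
  sna <- generate_snrna(cfg, a$truth)
  snb <- generate_snrna(cfg, b$truth)
  expect_identical(sna$counts@x, snb$counts@x)
  expect_identical(sna$counts@i, snb$counts@i)
  ma <- generate_mouse_study(cfg, a$truth)
  mb <- generate_mouse_study(cfg, b$truth)
  expect_identical(ma$counts, mb$counts)
  xa <- generate_cross_species_maps(cfg, a$truth)
  xb <- generate_cross_species_maps(cfg, b$truth)
  expect_identical(xa$fly_screen, xb$fly_screen)
})

test_that("ground truth respects its invariants", {
  fx <- small_gen()
  truth <- fx$gen$truth
  for (p in list(truth$true_proportions$study1, truth$true_proportions$study2))
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  # targets carry concordant nonzero effects in all arms
  tg <- truth$planted_targets
  expect_true(all(truth$dx_effects$bulk[tg] != 0))
  expect_true(all(sign(truth$dx_effects$sn[tg]) ==
                    sign(truth$dx_effects$bulk[tg])))
  expect_true(all(sign(truth$dx_effects$mouse[tg]) ==
                    sign(truth$dx_effects$bulk[tg])))
  expect_true(all(truth$fly_effects[tg] == -1))
})

test_that("zero effect size yields a calibrated null", {
  cfg <- simulation_config(seed = 3, n_genes = 600,
                           n_samples_per_cohort = c(50, 50), n_modules = 2,
                           module_sizes = c(60, 60),
                           module_celltype = c("neuron", "astrocyte"),
                           effect_size_dx = 0, pathology_effect = 0,
                           n_planted_targets = 1, plant_qc_outliers = FALSE)
  gen <- generate_bulk_cohorts(cfg)
  expect_true(all(gen$truth$dx_effects$bulk == 0))
  st <- preprocess_bulk_study(gen$study1)
  dx <- as.numeric(st$sample_meta$diagnosis == "case")
  a <- fit_gene_trait(st$expr, dx,
                      st$sample_meta[, c("sex", "age_at_death", "rin",
                                         "flowcell")])
  # per-gene mean case/control difference near zero on average
  expect_lt(abs(mean(a$beta)), 0.05)
  # rejection close to nominal (3 Monte-Carlo SE)
  expect_lt(mean(a$p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(a)))
})

test_that("low-noise limit yields near-perfect module correlation structure", {
  # dominant-single-factor limit: a strong module factor, no planted
  # effects, tiny gene-level noise; Poisson count sampling (intrinsic to the
  # generator) bounds the attainable correlation below 1
  cfg <- simulation_config(seed = 5, n_genes = 200,
                           n_samples_per_cohort = c(40, 40), n_modules = 3,
                           module_sizes = c(50, 50, 50),
                           module_celltype = c("neuron", "astrocyte",
                                               "microglia"),
                           effect_size_dx = 0, noise_sd = 0.01,
                           module_factor_sd = 3,

                           n_planted_targets = 1, plant_qc_outliers = FALSE)
  gen <- generate_bulk_cohorts(cfg)
  expr <- normalize_bulk(gen$study1$counts, gen$study1$gene_annot)
  # well-expressed rows, where Poisson noise is negligible
  hi <- rowMeans(gen$study1$counts) > 100
  labels <- gen$truth$module_labels
  cmat <- cor(t(expr[hi, ]))
  labs <- labels[hi]
  within <- between <- c()
  for (m in 1:3) {
    idx <- which(labs == m)
    other <- which(labs > 0 & labs != m)
    cw <- cmat[idx, idx]
    within <- c(within, cw[upper.tri(cw)])
    between <- c(between, as.vector(cmat[idx, other]))
  }
  expect_gt(mean(within), 0.75)
  expect_lt(mean(abs(between)), 0.3)
  expect_gt(mean(within), 3 * mean(abs(between)))
})

test_that("mouse concordance rate controls sign transfer", {
  base_args <- list(seed = 9, n_genes = 300, n_samples_per_cohort = c(20, 20),
                    n_modules = 2, module_sizes = c(60, 60),
                    module_celltype = c("astrocyte", "microglia"),
                    deg_fraction = 1, sn_n_nuclei = 150, sn_n_samples = 4,
                    n_planted_targets = 2)
  cfg1 <- do.call(simulation_config, c(base_args, mouse_concordance_rate = 1))
  g1 <- generate_bulk_cohorts(cfg1)
  deg <- names(g1$truth$dx_effects$bulk)[g1$truth$dx_effects$bulk != 0]
  expect_true(all(sign(g1$truth$dx_effects$mouse[deg]) ==
                    sign(g1$truth$dx_effects$bulk[deg])))
  cfg0 <- do.call(simulation_config, c(base_args, mouse_concordance_rate = 0))
  g0 <- generate_bulk_cohorts(cfg0)
  nontarget <- setdiff(deg, g0$truth$planted_targets)
  concordant <- sign(g0$truth$dx_effects$mouse[nontarget]) ==
    sign(g0$truth$dx_effects$bulk[nontarget]) &
    g0$truth$dx_effects$mouse[nontarget] != 0
  expect_equal(sum(concordant), 0)
  # targets stay concordant even at rate 0 (ground-truth invariant)
  tg <- g0$truth$planted_targets
  expect_true(all(sign(g0$truth$dx_effects$mouse[tg]) ==
                    sign(g0$truth$dx_effects$bulk[tg])))
})

test_that("ortholog maps and fly screen respect the planted contract", {
  fx <- small_gen()
  cfg0 <- fx$cfg; cfg0$ortholog_dropout <- 0
  maps <- generate_cross_species_maps(cfg0, fx$gen$truth)
  genes <- names(fx$gen$truth$module_labels)
  for (sp in c("mouse", "fly"))
    expect_setequal(maps$ortholog_map$human_gene[
      maps$ortholog_map$species == sp], genes)
  # planted targets always screened with a top-suppressor score
  scr <- maps$fly_screen
  tg <- fx$gen$truth$planted_targets
  expect_true(all(tg %in% scr$human_gene))
  expect_true(all(scr$screen_score[scr$human_gene %in% tg] < -1.5))
  # lethal outcomes are categorical, not numeric scores
  expect_true(all(is.na(scr$screen_score[scr$outcome == "lethal"])))
  expect_true(all(scr$screen_score[scr$outcome == "scored"] >= -4 &
                    scr$screen_score[scr$outcome == "scored"] <= 4))
})

test_that("cell types are recoverable from markers without dropout", {
  fx <- small_gen()
  cfg <- fx$cfg
  cfg$sn_dropout <- 0
  cfg$plant_qc_outliers <- FALSE
  sn <- generate_snrna(cfg, fx$gen$truth)
  truth <- fx$gen$truth
  types <- unique(cfg$module_celltype)
  # oracle assignment: argmax over types of mean expression of true markers
  scores <- sapply(types, function(t) {
    mk <- names(truth$module_labels)[
      truth$module_labels %in% which(truth$module_celltype == t)]
    Matrix::rowMeans(sn$counts[, mk]) /
      pmax(Matrix::rowMeans(sn$counts), 1e-9)
  })
  assigned <- types[apply(scores, 1, which.max)]
  is_mod_type <- sn$nucleus_meta$true_type %in% types
  expect_equal(mean(assigned[is_mod_type] ==
                      sn$nucleus_meta$true_type[is_mod_type]), 1.0)
})

test_that("planted QC-violating nuclei are caught downstream", {
  fx <- small_gen()
  sn <- generate_snrna(fx$cfg, fx$gen$truth)
  expect_gt(sum(sn$nucleus_meta$qc_truth != "ok"), 0)
  kept <- qc_nuclei(sn, genes_lower = 150)
  expect_equal(sum(kept$nucleus_meta$qc_truth != "ok"), 0)
})
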