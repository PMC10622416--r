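# Independent oracles and shared fixtures for the test suite.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# literal BH step-up definition: q_(i) = min_{j >= i} m p_(j) / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force upper-tail hypergeometric: P(X >= ov) by direct tail summation
# of the point masses (log-scale binomial coefficients to avoid overflow)
hyper_brute <- function(ov, n_set, n_markers, n_bg) {
  ks <- ov:min(n_set, n_markers)
  ks <- ks[n_set - ks <= n_bg - n_markers]
  if (length(ks) == 0L) return(0)
  sum(exp(lchoose(n_markers, ks) + lchoose(n_bg - n_markers, n_set - ks) -
            lchoose(n_bg, n_set)))
}

# naive triple-loop TOM
tom_brute <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    out[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  out
}

# direct evaluation of the biweight midcorrelation formula for two vectors
bicor_brute <- function(x, y) {
  tr <- function(v) {
    med <- median(v); madv <- median(abs(v - med))
    u <- (v - med) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  a <- tr(x); b <- tr(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# exact two-sided rank-sum p by full enumeration of subsets (small groups)
wilcox_enum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (n + 1) / 2
  sets <- combn(n, n1)
  ws <- apply(sets, 2, function(i) sum(r[i]))
  mean(abs(ws - EW) >= abs(W - EW) - 1e-9)
}

# small bulk simulation shared by several tests (built once per test run)
.fixture_env <- new.env()
small_gen <- function() {
  if (is.null(.fixture_env$gen)) {
    cfg <- simulation_config(
      seed = 7, n_genes = 500, n_samples_per_cohort = c(60, 60),
      n_modules = 3, module_sizes = c(60, 50, 40),
      module_celltype = c("neuron", "astrocyte", "oligodendrocyte"),
      sn_n_nuclei = 900, sn_n_samples = 8, n_planted_targets = 2)
    .fixture_env$cfg <- cfg
    .fixture_env$gen <- generate_bulk_cohorts(cfg)
  }
  list(cfg = .fixture_env$cfg, gen = .fixture_env$gen)
}

# consensus network on the small fixture (built once)
.fixture_net <- function() {
  if (is.null(.fixture_env$net)) {
    fx <- small_gen()
    s1 <- preprocess_bulk_study(fx$gen$study1)
    s2 <- preprocess_bulk_study(fx$gen$study2)
    keep <- filter_low_expressed(s1$expr, s2$expr)
    cv <- c("sex", "age_at_death", "rin", "flowcell")
    .fixture_env$net <- build_consensus_network(
      s1$expr[keep, ], s2$expr[keep, ],
      s1$sample_meta[, cv], s2$sample_meta[, cv])
    .fixture_env$net_dx <- c(as.numeric(s1$sample_meta$diagnosis == "case"),
                             as.numeric(s2$sample_meta$diagnosis == "case"))
  }
  .fixture_env$net
}

# small single-nucleus dataset with planted structure, shared across tests
small_sn <- function() {
  if (is.null(.fixture_env$sn)) {
    fx <- small_gen()
    sn <- generate_snrna(fx$cfg, fx$gen$truth)
    sn <- qc_nuclei(sn, genes_lower = 150)
    sn <- normalize_and_embed(sn, n_pcs = 15)
    .fixture_env$sn <- sn
    .fixture_env$sn_clusters <- cluster_nuclei(sn$embedding, seed = 1)
  }
  list(sn = .fixture_env$sn, clusters = .fixture_env$sn_clusters,
       truth = small_gen()$gen$truth)
}
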