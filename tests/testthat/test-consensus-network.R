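test_that("bicor matches the direct biweight formula and its limits", {
  set.seed(12)
  x <- rnorm(10); x[3] <- 8   # gross outlier
  y <- rnorm(10)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  for (i in 1:10) {
    a <- rnorm(10); a[sample(10, 1)] <- rnorm(1, 0, 6)
    b <- rnorm(10)
    expect_equal(bicor(a, b), bicor_brute(a, b), tolerance = 1e-10)
  }
  # constant gene: Pearson fallback recorded
  m <- rbind(const = rep(2, 10), x = x)
  cm <- bicor_matrix(m)
  expect_true(attr(cm, "fallback")["const"])
  expect_false(attr(cm, "fallback")["x"])
})

test_that("residualization removes covariates exactly", {
  set.seed(13)
  n <- 30
  expr <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(residualize(expr), expr - rowMeans(expr))
  age <- rnorm(n)
  lin <- rbind(g1 = 2 * age + 3)
  expect_lt(max(abs(residualize(lin, data.frame(age = age)))), 1e-8)
  covs <- data.frame(age = age, sex = sample(c("M", "F"), n, TRUE))
  r <- residualize(expr + outer(rnorm(5), age), covs)
  expect_lt(max(abs(r %*% age)), 1e-8)
  expect_error(residualize(expr, data.frame(a = age, b = age)),
               "rank deficient")
})

test_that("signed adjacency follows its closed form", {
  C <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3)
  A <- signed_adjacency(C)
  expect_equal(A[1, 3], 0)
  expect_equal(A[1, 2], 0.5^12, tolerance = 1e-15)
  expect_equal(A[2, 3], 0.75^12, tolerance = 1e-15)
  expect_equal(diag(A), rep(0, 3))
  expect_equal(signed_adjacency(matrix(1, 2, 2))[1, 2], 1)
  expect_error(signed_adjacency(C, beta_power = 0), "positive")
})

test_that("TOM equals the naive triple-loop oracle", {
  # two-gene closed form
  for (a in c(0.1, 0.5, 0.9)) {
    A <- matrix(c(0, a, a, 0), 2)
    expect_equal(compute_tom(A)[1, 2], a, tolerance = 1e-12)
  }
  # identical, near-saturated rows approach overlap 1
  A <- matrix(0.995, 5, 5); diag(A) <- 0; A[1, 2] <- A[2, 1] <- 0.9999
  expect_gt(compute_tom(A)[1, 2], 0.99)
  set.seed(14)
  for (n in c(3, 7, 15, 30, 50)) {
    A <- matrix(runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
    expect_equal(compute_tom(A), tom_brute(A), tolerance = 1e-12)
  }
})

test_that("consensus TOM is a quantile-calibrated element-wise minimum", {
  set.seed(15)
  mk_tom <- function(n) {
    A <- matrix(runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
    compute_tom(A / 2)
  }
  t1 <- mk_tom(20); t2 <- mk_tom(20)
  res <- consensus_tom(list(t1, t2))
  off <- upper.tri(t1)
  expect_true(all(res$consensus[off] <= res$scaled[[1]][off] + 1e-12))
  expect_true(all(res$consensus[off] <= res$scaled[[2]][off] + 1e-12))
  expect_equal(quantile(res$scaled[[2]][off], 0.95),
               quantile(t1[off], 0.95), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(consensus_tom(list(t1, t1))$consensus, t1)
  smaller <- t1 * 0.9; diag(smaller) <- 1
  res2 <- consensus_tom(list(t1, smaller))
  expect_true(all(res2$consensus[off] <= res2$scaled[[1]][off] + 1e-12))
  expect_error(consensus_tom(list(t1, t2), scale_quantile = 1), "strictly")
})

test_that("module detection recovers planted blocks and degenerate inputs", {
  set.seed(16)
  n <- 90
  tom <- matrix(0.01, n, n)
  truth <- rep(1:3, each = 30)
  for (m in 1:3) tom[truth == m, truth == m] <- 0.9
  diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- paste0("g", 1:n)
  lab <- detect_modules(tom, min_module_size = 10)
  expect_equal(length(unique(lab)), 3)
  expect_equal(ari(lab, truth), 1)

  flat <- matrix(0.5, 40, 40); diag(flat) <- 1
  dimnames(flat) <- list(paste0("g", 1:40), paste0("g", 1:40))
  lab_flat <- detect_modules(flat, min_module_size = 10)
  expect_lte(length(unique(lab_flat[lab_flat > 0])), 1)

  expect_warning(detect_modules(flat[1:5, 1:5], min_module_size = 10),
                 "background")
})

test_that("eigengenes are signed, unit-norm, variance-maximal PCs", {
  set.seed(17)
  prof <- rnorm(40)
  expr <- rbind(g1 = prof, g2 = prof, g3 = prof) +
    matrix(rnorm(120, 0, 1e-6), 3)
  colnames(expr) <- paste0("s", 1:40)
  labels <- setNames(c(1L, 1L, 1L), rownames(expr))
  me <- module_eigengenes(expr, labels)
  expect_equal(sum(me[, 1]^2), 1)
  expect_gt(cor(me[, 1], prof), 0.999)
  # sign convention survives global negation
  me_neg <- module_eigengenes(-expr, labels)
  expect_gt(cor(me_neg[, 1], -prof), 0.999)
  # single-gene module
  labels2 <- setNames(c(1L, 2L, 2L), rownames(expr))
  me2 <- module_eigengenes(expr, labels2)
  expect_equal(ncol(me2), 2)
  # variance maximality against direct eigendecomposition
  x <- matrix(rnorm(8 * 30), 8, dimnames = list(paste0("g", 1:8), NULL))
  lab8 <- setNames(rep(1L, 8), rownames(x))
  me8 <- module_eigengenes(x, lab8)
  xs <- t(scale(t(x)))
  ev <- eigen(crossprod(xs))$values[1]
  expect_equal(as.numeric(crossprod(xs %*% me8[, 1])), ev, tolerance = 1e-8)
})

test_that("module membership behaves at its limits", {
  set.seed(18)
  fx <- small_gen()
  net <- .fixture_net()
  mm <- net$modules$mm
  labels <- net$modules$labels
  truth <- fx$gen$truth$module_labels[names(labels)]
  # genes independent of all modules have small membership
  null_genes <- names(truth)[truth == 0 & labels == 0]
  expect_lt(mean(abs(mm[null_genes, ])), 0.2)
  # a gene equal to the eigengene profile has membership 1
  me <- net$modules$me
  expr_aug <- rbind(net$combined, ME_PROFILE = me[, 1])
  mm_aug <- module_membership(expr_aug, me)
  expect_gt(mm_aug["ME_PROFILE", 1], 0.99)
})

test_that("merging and reassignment follow the thresholds and are idempotent", {
  set.seed(19)
  n <- 40
  f <- rnorm(n)
  expr <- rbind(
    t(sapply(1:10, function(i) f + rnorm(n, 0, 0.1))),       # module 1
    t(sapply(1:10, function(i) f + rnorm(n, 0, 0.1))),       # module 2 == 1
    t(sapply(1:10, function(i) rnorm(n))))                   # background
  rownames(expr) <- paste0("g", 1:30)
  labels <- setNames(c(rep(1L, 10), rep(2L, 10), rep(0L, 10)), rownames(expr))
  ms <- merge_and_reassign(labels, expr)
  # identical eigengenes merged into one module
  expect_equal(length(unique(ms$labels[ms$labels > 0])), 1)
  # strongly correlated background genes pulled in (MM > 0.5)
  expr2 <- expr
  expr2["g25", ] <- f + rnorm(n, 0, 0.2)
  ms2 <- merge_and_reassign(labels, expr2)
  expect_gt(ms2$labels["g25"], 0)
  # anti-correlated member pushed to background (negative own membership)
  expr3 <- expr
  expr3["g5", ] <- -f + rnorm(n, 0, 0.1)
  ms3 <- merge_and_reassign(labels, expr3)
  expect_equal(unname(ms3$labels["g5"]), 0L)
  # idempotence
  for (ms_i in list(ms, ms2, ms3)) {
    again <- merge_and_reassign(ms_i$labels, if (identical(ms_i, ms)) expr
                                else if (identical(ms_i, ms2)) expr2 else expr3)
    expect_identical(again$labels, ms_i$labels)
  }
})

test_that("module-trait association is calibrated and finds planted signal", {
  fx <- small_gen()
  net <- .fixture_net()
  me <- net$modules$me
  n <- nrow(me)
  dx <- .fixture_env$net_dx
  mta <- module_trait_association(me, data.frame(diagnosis = dx))
  expect_true(all(mta$p_bonferroni >= mta$p - 1e-15))
  expect_true(all(mta$p_bonferroni <= 1))
  # planted diagnosis association beats permuted traits
  set.seed(20)
  rej <- replicate(200, {
    any(module_trait_association(me, data.frame(x = sample(dx)))$p < 0.05 /
          ncol(me))
  })
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_error(module_trait_association(me, data.frame(z = rep(1, n))),
               "zero variance")
})

test_that("gene-set enrichment honors overlap rules and the oracle", {
  bg <- paste0("g", 1:1000)
  sets <- list(s100 = bg[1:100], tiny = bg[500:501])
  res <- gene_set_enrichment(bg[1:100], sets, bg, mode = "marker")
  expect_equal(res$fold[res$set == "s100"], 10)
  expect_lt(res$p[res$set == "s100"], 1e-10)
  expect_equal(res$p[res$set == "tiny"], 1)
  # set mode drops overlap < 2
  res2 <- gene_set_enrichment(c(bg[1], bg[500]), sets, bg, mode = "set")
  expect_false("s100" %in% res2$set)
  expect_error(gene_set_enrichment(bg[1:10], list(bad = c("zzz")), bg),
               "background")
  set.seed(21)
  for (i in 1:20) {
    q <- sample(bg, 50); s <- list(s = sample(bg, 80))
    r <- gene_set_enrichment(q, s, bg, mode = "marker")
    expect_equal(r$p, hyper_brute(r$overlap, 50, 80, 1000), tolerance = 1e-12)
  }
})

test_that("preservation Z separates planted modules from random labels", {
  fx <- small_gen()
  net <- .fixture_net()
  # identical studies: strong modules give large positive Z
  z <- module_preservation(net$resid1, net$resid1, net$modules$labels,
                           n_perm = 50, seed = 1)
  expect_true(all(z$Z > 10))
  z2 <- module_preservation(net$resid1, net$resid1, net$modules$labels,
                            n_perm = 50, seed = 1)
  expect_identical(z, z2)
  # random labels are not preserved
  set.seed(22)
  rand <- net$modules$labels
  names(rand) <- sample(names(rand))
  rand <- rand[rownames(net$resid1)]
  z3 <- module_preservation(net$resid1, net$resid2, rand, n_perm = 50,
                            seed = 2)
  expect_lt(median(abs(z3$Z)), 2)
})

test_that("the consensus network recovers the planted modules", {
  fx <- small_gen()
  net <- .fixture_net()
  truth <- fx$gen$truth$module_labels[names(net$modules$labels)]
  expect_gte(ari(net$modules$labels, truth), 0.85)
})
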