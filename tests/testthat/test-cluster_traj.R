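test_that("PCA embedding has the standard algebraic properties", {
  set.seed(2)
  # points on a line in gene space: PC1 captures essentially everything
  t <- seq(0, 1, length.out = 40)
  dir <- rnorm(6)
  m <- t(outer(t, dir))  # genes x cells
  rownames(m) <- sprintf("g%d", 1:6)
  emb <- pca_embed(m, d = 3)
  expect_gt(emb$var[1] / sum(emb$var), 0.999)
  # orthogonality of score columns
  g <- crossprod(emb$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # variances equal the covariance eigenvalues (dense oracle, 20 x 10)
  m2 <- matrix(rnorm(200), 10, 20)   # 10 genes x 20 cells
  emb2 <- pca_embed(m2, d = 5)
  ev <- eigen(cov(t(m2)))$values
  expect_equal(emb2$var, ev[1:5], tolerance = 1e-8)
  # deterministic sign: largest-magnitude loading positive
  expect_true(all(apply(emb2$rotation, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_error(pca_embed(matrix(1, 5, 5), d = 2), "constant")
})

test_that("SNN clustering separates planted blobs and ignores cell order", {
  fb <- fx_blobs(seed = 3, n = 100, sep = 10, sigma = 0.1)
  cl <- cluster_snn(fb$x, k = 20, d_use = 5)
  expect_equal(length(unique(cl)), 2)
  # zero misassignment: each planted blob maps to one cluster
  tab <- table(cl, fb$labels)
  expect_equal(sum(apply(tab, 1, max)), 200)
  # permuted input: identical partition up to label names
  perm <- withr::with_seed(9, sample(200))
  cl2 <- cluster_snn(fb$x[perm, ], k = 20, d_use = 5)
  tab2 <- table(cl[perm], cl2)
  expect_equal(sum(apply(tab2, 1, max)), 200)
  expect_error(cluster_snn(fb$x, k = 0), "positive")
})

test_that("a homogeneous blob fragments no worse than the reference SNN", {
  # modularity optimisation always splits homogeneous graphs; the contract
  # is parity with the established implementation, not a single cluster
  one <- fx_blobs(seed = 4, n = 120, sep = 0, sigma = 0.1)
  ours <- length(unique(cluster_snn(one$x, k = 20, d_use = 5)))
  ref <- length(unique(igraph::membership(igraph::cluster_louvain(
    scran::buildSNNGraph(t(one$x), k = 20, d = NA, type = "rank")))))
  expect_lte(ours, ref + 2)
  expect_gte(ours, 1)
})

test_that("principal curve recovers orderings on analytic shapes", {
  # straight line: zero residual, pseudotime monotone in the coordinate
  t <- seq(0, 5, length.out = 60)
  X <- cbind(t, 0.5 * t, -0.2 * t)
  fit <- fit_principal_curve(X, d_use = 3)
  expect_lt(fit$mse, 1e-6)
  expect_equal(abs(cor(fit$pseudotime, t, method = "spearman")), 1,
               tolerance = 1e-6)
  # noiseless semicircle: pseudotime reproduces the angle
  th <- seq(0, pi, length.out = 200)
  S <- cbind(cos(th), sin(th))
  fs <- fit_principal_curve(S, d_use = 2)
  expect_gte(abs(cor(fs$pseudotime, th, method = "spearman")), 0.999)
  # orientation: flipping early cells maps p to L - p
  early_hi <- which(fs$pseudotime > stats::median(fs$pseudotime))
  fr <- fit_principal_curve(S, d_use = 2, early = early_hi)
  expect_equal(as.numeric(fr$pseudotime),
               as.numeric(fs$length - fs$pseudotime), tolerance = 1e-9)
  expect_true(fr$reversed)
  expect_error(fit_principal_curve(X[1:5, ]), "at least 10")
})

test_that("genes_expressed counts positive entries per cell", {
  m <- matrix(c(0, 0, 0, 3, 0, 1), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  ge <- genes_expressed(m)
  expect_equal(ge$n_genes, c(0L, 2L))
  # per-stage medians reproduce the planted complexity ordering
  fx <- fx_cells()
  med <- tapply(genes_expressed(fx$counts)$n_genes, fx$stage, median)
  st <- fx$truth$config$stages
  expect_lt(med[["LZ"]], med[["SG"]])   # early-meiosis dip
  expect_lt(med[["LZ"]], med[["P"]])
  expect_gt(med[["D"]], med[["P"]])     # diplotene peak
  expect_lt(med[["ES"]], med[["RS"]])   # post-S7 decline
})

test_that("marker detection flags cluster-specific genes and nothing else", {
  set.seed(6)
  n <- 50
  m <- matrix(rnorm(20 * 2 * n, 1, 0.5), 20, 2 * n)
  rownames(m) <- sprintf("g%02d", 1:20)
  cl <- rep(c("A", "B"), each = n)
  m[3, cl == "A"] <- rnorm(n, 5, 0.5)   # expressed only in A
  m[3, cl == "B"] <- 0
  mk <- find_markers(m, cl)
  row <- mk[mk$gene == "g03" & mk$cluster == "A", ]
  expect_true(row$marker)
  expect_lt(row$fdr, 1e-6)
  expect_gt(row$summary_lfc, 3)
  # two identical clusters: nothing distinguishes them
  m2 <- cbind(m[, cl == "A"], m[, cl == "A"])
  mk2 <- find_markers(m2, rep(c("A", "B"), each = n))
  expect_equal(sum(mk2$marker), 0)
  # label permutation: near-zero false markers
  false_any <- vapply(1:5, function(i) {
    sum(find_markers(m[-3, ], sample(cl))$marker)
  }, numeric(1))
  expect_true(mean(false_any == 0) >= 0.8)
})

test_that("blocking drops blocks missing a cluster and still works", {
  set.seed(7)
  n <- 30
  m <- matrix(rnorm(10 * 3 * n, 1, 0.5), 10, 3 * n)
  rownames(m) <- sprintf("g%02d", 1:10)
  cl <- rep(c("A", "B", "A"), each = n)
  bl <- rep(c("x", "x", "y"), each = n)   # block y has only cluster A
  m[2, cl == "A"] <- m[2, cl == "A"] + 3
  mk <- find_markers(m, cl, blocks = bl)
  expect_true(mk$marker[mk$gene == "g02" & mk$cluster == "A"])
})
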