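test_that("qc_filter applies the gene-count and mitochondrial rules", {
  m <- matrix(0L, 20, 3, dimnames = list(NULL, c("b1", "b2", "b3")))
  m[1:12, 1] <- 5L     # 12 genes detected
  m[1:8, 2] <- 5L      # 8 genes
  m[1:15, 3] <- 5L     # 15 genes, heavy mito
  chrom <- c(rep("chr1", 19), "MT")
  m[20, ] <- c(1L, 1L, 40L)   # mito gene
  x <- toy_counts(m, chrom)
  qc <- qc_filter(x, min_genes = 10L, max_mito = 0.10)
  expect_equal(qc$report$keep, c(TRUE, FALSE, FALSE))
  expect_equal(qc$report$fail_rule, c(NA, "min_genes", "max_mito"))
  # boundary: mito fraction exactly at the threshold is retained
  m2 <- matrix(5L, 10, 1, dimnames = list(NULL, "b"))
  m2[10, 1] <- 5L
  x2 <- toy_counts(m2, c(rep("chr1", 9), "MT"))
  expect_equal(sum(x2$counts[10, ]) / sum(x2$counts), 0.10)
  expect_true(qc_filter(x2, min_genes = 1L, max_mito = 0.10)$report$keep)
  # permissive thresholds retain everything
  expect_true(all(qc_filter(x, min_genes = 0L, max_mito = 1)$report$keep))
  expect_error(qc_filter(x, min_genes = 100L), "exceeds")
})

test_that("estimate_ambient pools low-count barcodes", {
  m <- matrix(c(2, 2, 2, 2), 2, 2, dimnames = list(c("g1", "g2"), c("b1", "b2")))
  x <- toy_counts(m)
  p <- estimate_ambient(x, total_max = 100, alpha = 0, min_pool = 1)
  expect_equal(as.numeric(p), c(0.5, 0.5))
  # all-zero pool with alpha > 0 gives the uniform profile
  mz <- matrix(0L, 4, 120, dimnames = list(NULL, sprintf("b%03d", 1:120)))
  pz <- estimate_ambient(toy_counts(mz), total_max = 10, alpha = 0.5)
  expect_equal(as.numeric(pz), rep(0.25, 4))
  expect_error(estimate_ambient(toy_counts(m)), "too few low-count")
})

test_that("ambient profile estimate matches the planted truth", {
  # fixture sized so the estimator's sampling error sits below the
  # assertion: 5000 empties with totals up to 300 and a matching pool cap
  cfg <- sim_config(seed = 42L, stages = default_stages(n_cells = 50L),
                    n_empty = 5000L, ambient_lib_range = c(50L, 300L))
  sim <- simulate_droplets(cfg)
  amb <- estimate_ambient(sim$counts, total_max = 300, alpha = 0.1)
  tv <- 0.5 * sum(abs(as.numeric(amb) - as.numeric(sim$truth$ambient_profile)))
  expect_lt(tv, 0.02)
})

test_that("test_droplets calls structure and edge cases", {
  set.seed(21)
  G <- 300
  p <- rexp(G); p <- p / sum(p)
  emp <- vapply(sample(20:120, 400, TRUE),
                function(t) rmultinom(1, t, p)[, 1], numeric(G))
  zero <- matrix(0, G, 3)
  # a barcode equal to the most probable ambient draw: p-value near 1
  typical <- matrix(round(150 * p), G, 1)
  m <- cbind(emp, zero, typical)
  colnames(m) <- sprintf("b%04d", seq_len(ncol(m)))
  rownames(m) <- sprintf("g%04d", seq_len(G))
  x <- toy_counts(m)
  amb <- estimate_ambient(x, total_max = 100, alpha = 0.1)
  res <- test_droplets(x, amb, n_mc = 1000, retain_above_knee = FALSE, seed = 2)
  expect_true(all(res$call[res$total == 0] == "empty"))
  expect_gt(res$p_value[ncol(m)], 0.9)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  expect_error(test_droplets(x, amb, n_mc = 10), "n_mc")
})

test_that("size factors recover relative depth and obey exact identities", {
  # identical cells: all factors 1
  m <- matrix(rep(c(5L, 3L, 2L, 8L), 4), 4, 4,
              dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:4)))
  sf <- size_factors(m, clusters = rep(1, 4))
  expect_equal(as.numeric(sf), rep(1, 4))
  # a cell at exactly twice another: factor ratio exactly 2
  m2 <- cbind(a = c(5, 3, 2, 8), b = 2 * c(5, 3, 2, 8))
  rownames(m2) <- sprintf("g%d", 1:4)
  sf2 <- size_factors(m2, clusters = c(1, 1))
  expect_equal(sf2[["b"]] / sf2[["a"]], 2, tolerance = 1e-9)
  # gene permutation invariance
  perm <- sample(4)
  sf3 <- size_factors(m2[perm, ], clusters = c(1, 1))
  expect_equal(as.numeric(sf3), as.numeric(sf2))
  # equivariance under global depth scaling
  sf4 <- size_factors(m2 * 3, clusters = c(1, 1))
  expect_equal(as.numeric(sf4), as.numeric(sf2))
})

test_that("lognormalise maps zero to zero and applies factors", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(4, 6), dims = c(2, 2))
  lm <- lognormalise(m, c(2, 3))
  expect_equal(as.matrix(lm), matrix(c(log2(3), 0, 0, log2(3)), 2),
               ignore_attr = TRUE)
  expect_equal(sum(as.matrix(lm) == 0), 2)
  expect_error(lognormalise(m, c(1, -1)))
})

test_that("HVG selection decomposes variance against a smooth trend", {
  set.seed(4)
  n <- 300
  G <- 250
  mu <- runif(G, 1, 6)
  m <- matrix(rnorm(G * n, mu, 1), G, n)
  rownames(m) <- sprintf("g%03d", seq_len(G))
  # flat variance: biological component about zero for everyone
  hv <- select_hvg(m, n = 10)
  expect_lt(max(abs(hv$bio_var)), 0.35)
  # one gene with variance 10x the trend is ranked first
  m2 <- m
  m2[7, ] <- rnorm(n, mu[7], sqrt(10))
  hv2 <- select_hvg(m2, n = 10)
  expect_equal(hv2$gene_id[hv2$rank == 1], "g007")
  expect_error(select_hvg(m, n = 1000), "exceeds")
  # planted stage markers are highly variable in the default world
  fx <- fx_cells()
  hvg <- select_hvg(fx$logm, n = 1000)
  expect_gte(mean(fx$truth$markers$gene_id %in% hvg$gene_id[hvg$selected]), 0.8)
})
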