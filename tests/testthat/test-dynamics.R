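test_that("X:A ratio matches hand arithmetic on a toy", {
  # 4 autosomal genes at 3 each; X genes (4, 2) then (1, 1)
  chrom <- c(rep("chr1", 4), "X", "X")
  m1 <- matrix(c(3, 3, 3, 3, 4, 2), 6, 1)
  m2 <- matrix(c(3, 3, 3, 3, 1, 1), 6, 1)
  m <- cbind(m1, m2)
  colnames(m) <- c("c1", "c2")
  x <- toy_counts(m, chrom)
  xa <- xa_ratio(m, x$genes, group1 = 1, group2 = 2, frac = 0.3)
  expect_equal(xa$ratio_x, c(3 / 3, 1 / 3), tolerance = 1e-12)
  # identical means: ratio exactly 1; all-zero X: ratio 0
  m3 <- m; m3[5:6, 1] <- 3
  expect_equal(xa_ratio(m3, x$genes, 1, 2)$ratio_x[1], 1)
  m4 <- m; m4[5:6, 2] <- 0
  # keep the filter alive via cell 1, then cell 2 has ratio 0
  expect_equal(xa_ratio(m4, x$genes, 1, 1)$ratio_x[2], 0)
  # invariance under common rescaling of a cell
  m5 <- m; m5[, 1] <- m5[, 1] * 13
  expect_equal(xa_ratio(m5, x$genes, 1, 2)$ratio_x, xa$ratio_x)
})

test_that("correlation screen classifies planted and null genes correctly", {
  set.seed(3)
  n <- 400
  compl <- rpois(n, 800)
  G <- 200
  m <- matrix(rnbinom(G * n, mu = 3, size = 10), G, n)
  rownames(m) <- sprintf("g%03d", seq_len(G))
  logm <- log2(m + 1)
  # a gene identical to the complexity vector: rho 1, positive
  logm[1, ] <- compl
  cs <- correlation_screen(logm, compl, n_null = 2000, seed = 4)
  expect_equal(cs$rho[cs$gene == "g001"], 1, tolerance = 1e-12)
  expect_equal(cs$class[cs$gene == "g001"], "positive")
  # classification invariant holds
  expect_true(all((cs$class == "negative") ==
                    (cs$rho < -0.3 & cs$q < 0.1)))
  expect_true(all((cs$class == "positive") ==
                    (cs$rho > 0.3 & cs$q < 0.1)))
  # lowly expressed genes are excluded
  m2 <- m; m2[2, ] <- 0L
  cs2 <- correlation_screen(log2(m2 + 1), compl, n_null = 1000, seed = 4)
  expect_false("g002" %in% cs2$gene)
  expect_error(correlation_screen(logm, rep(5, n)), "constant")
})

test_that("stemness scores are detection fractions of the panels", {
  m <- matrix(0L, 13, 3, dimnames = list(NULL, c("a", "b", "c")))
  syms <- c("Id4", "Gfra1", "Lhx1", "Egr2", "Etv5", "Nanos2", "Ret", "Eomes",
            "Neurog3", "Rarg", "Nanos3", "Lin28a", "Upp1")
  rownames(m) <- syms
  m[1:8, 1] <- 1L          # every SSC gene
  m[c(1, 2), 2] <- 1L      # 2 of 8
  m[9:13, 3] <- 1L         # all progenitor genes
  x <- toy_counts(m)
  sc <- stemness_scores(x)
  expect_equal(sc$frac_ssc, c(1, 0.25, 0))
  expect_equal(sc$frac_prog, c(0, 0, 1))
  expect_warning(stemness_scores(x, ssc_panel = c("Id4", "NotAGene")),
                 "dropped")
  expect_error(suppressWarnings(stemness_scores(x, ssc_panel = "NotAGene")),
               "empty panel")
})

test_that("multi-copy family aggregation sums members and conserves mass", {
  m <- matrix(1:12, 4, 3, dimnames = list(c("g1", "g2", "g3", "g4"), NULL))
  fam <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        family = c("F1", "F1", "F2"))
  agg <- aggregate_multicopy(m, fam)
  expect_equal(unname(agg["F1", ]), unname(m["g1", ] + m["g2", ]))
  expect_equal(unname(agg["F2", ]), unname(m["g3", ]))   # singleton is identity
  # conservation: families + unassigned equal the column totals
  expect_equal(colSums(agg) + m["g4", ], colSums(m))
  expect_error(aggregate_multicopy(m, tibble::tibble(
    gene_id = c("g1", "g1"), family = c("F1", "F2"))), "two families")
})

test_that("gene sets are contiguous rho-ordered bins with remainder first", {
  corr <- tibble::tibble(gene = sprintf("g%02d", 1:9), rho = seq(-0.8, 0.8, length.out = 9))
  gs <- group_gene_sets(corr, n_sets = 9)
  expect_equal(gs$set, 1:9)   # order preserved, one per set
  corr10 <- tibble::tibble(gene = sprintf("g%02d", 1:10),
                           rho = seq(-0.9, 0.9, length.out = 10))
  gs10 <- group_gene_sets(corr10, n_sets = 9)
  expect_equal(as.numeric(table(gs10$set)), c(2, rep(1, 8)))
  expect_error(group_gene_sets(corr, n_sets = 0), "at least 1")
  # monotone planted expression: set-mean profile slopes are ordered
  set.seed(5)
  n <- 200
  pt <- seq(0, 1, length.out = n)
  slopes <- seq(-2, 2, length.out = 18)
  m <- t(vapply(slopes, function(s) s * pt + rnorm(n, 0, 0.05), numeric(n)))
  rownames(m) <- sprintf("g%02d", 1:18)
  corr18 <- tibble::tibble(gene = rownames(m),
                           rho = apply(m, 1, cor, y = pt, method = "spearman"))
  sets <- group_gene_sets(corr18, n_sets = 9)
  prof <- gene_set_profiles(m, sets, pt, n_bins = 10)
  slope_of <- vapply(1:9, function(s) {
    d <- prof[prof$set == s, ]
    coef(lm(mean_z ~ pseudotime, d))[2]
  }, numeric(1))
  # per-gene scaling compresses slope magnitudes, so adjacent sets can sit
  # on near-plateaus; the ordering must still run from falling to rising
  expect_true(all(diff(slope_of) > -0.05))
  expect_lt(slope_of[1], -0.5)
  expect_gt(slope_of[9], 0.5)
  expect_gt(cor(slope_of, 1:9), 0.9)
})
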