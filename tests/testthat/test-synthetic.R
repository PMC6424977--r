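test_that("droplet simulation is deterministic and conserves barcodes", {
  cfg <- sim_config(seed = 3L, stages = default_stages(n_cells = 50L),
                    n_empty = 200L)
  a <- simulate_droplets(cfg)
  b <- simulate_droplets(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth$cells, b$truth$cells)
  # planted cells + empties account for every emitted barcode
  expect_equal(ncol(a$counts$counts),
               sum(cfg$stages$n_cells) + cfg$n_empty)
  expect_equal(table(a$truth$cells$kind)[["empty"]], 200L)
})

test_that("a silencing factor of zero silences the X completely", {
  st <- default_stages(n_cells = 40L)
  st$s_x[st$name == "P"] <- 0
  cfg <- sim_config(seed = 5L, stages = st, n_empty = 0L, n_escape_genes = 0L)
  sim <- simulate_droplets(cfg)
  xg <- sim$counts$genes$class == "X"
  pach <- sim$truth$cells$stage == "P"
  expect_true(all(sim$counts$counts[xg, pach] == 0))
  # other stages still express X
  expect_gt(sum(sim$counts$counts[xg, !pach]), 0)
})

test_that("escape genes jump by the planted log2 fold-change at activation", {
  st <- default_stages(n_cells = 500L)
  cfg <- sim_config(seed = 8L, stages = st, n_empty = 0L,
                    n_escape_genes = 20L, escape_stage = "RS", escape_lfc = 6)
  sim <- simulate_droplets(cfg)
  tr <- sim$truth
  stage_idx <- match(tr$cells$stage, st$name)
  act <- match("RS", st$name)
  pre <- stage_idx < act
  m <- as.matrix(sim$counts$counts[tr$escape_genes, , drop = FALSE])
  obs_lfc <- log2(mean(m[, !pre]) / mean(m[, pre]))
  expect_lt(abs(obs_lfc - 6), 0.3)
})

test_that("bulk samples are multinomial draws from the mixed stage profiles", {
  cfg <- sim_config(seed = 9L, stages = default_stages(n_cells = 2L),
                    n_empty = 0L)
  tr <- simulate_droplets(cfg)$truth
  K <- ncol(tr$stage_profiles)
  # pure stage k: chi-square GOF against the planted profile
  comp <- diag(K)
  rownames(comp) <- paste0("pure_", colnames(tr$stage_profiles))
  colnames(comp) <- colnames(tr$stage_profiles)
  bulk <- simulate_bulk(tr, comp, depth = 1e6)
  for (k in c(1, K)) {
    p <- tr$stage_profiles[, k]
    use <- p > 1e-6
    gof <- suppressWarnings(
      chisq.test(bulk$counts[use, k], p = p[use] / sum(p[use]))
    )
    expect_gt(gof$p.value, 0.01)
  }
  # identical compositions, same seed: identical samples
  two <- matrix(rep(comp[1, ], 2), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), colnames(comp)))
  b2 <- simulate_bulk(tr, two, depth = 1e5, seed = 77L)
  b3 <- simulate_bulk(tr, two, depth = 1e5, seed = 77L)
  expect_identical(b2$counts, b3$counts)
  # 50/50 mixture: expectation is the arithmetic mean of the profiles
  mix <- matrix(0, 1, K, dimnames = list("mix", colnames(comp)))
  mix[1, 1] <- 0.5; mix[1, 2] <- 0.5
  bm <- simulate_bulk(tr, mix, depth = 2e6)
  expected <- 2e6 * (tr$stage_profiles[, 1] + tr$stage_profiles[, 2]) / 2
  # multinomial sampling error at expectation E is about 1/sqrt(E), so a 2%
  # relative-error assertion is only measurable for E >> 2500; overall
  # unbiasedness is checked on the wider set
  hi <- expected > 5000
  expect_gt(sum(hi), 20)
  rel_err <- abs(bm$counts[hi, 1] - expected[hi]) / expected[hi]
  expect_lt(median(rel_err), 0.02)
  mid <- expected > 100
  expect_lt(abs(mean((bm$counts[mid, 1] - expected[mid]) / expected[mid])), 0.01)
  # unnormalised composition errors
  bad <- mix; bad[1, 1] <- 0.6
  expect_error(simulate_bulk(tr, bad), "not normalised")
})

test_that("fragment simulation plants promoter enrichment on a flat background", {
  cfg <- sim_config(seed = 4L, stages = default_stages(n_cells = 2L),
                    n_empty = 0L, n_escape_genes = 20L)
  tr <- simulate_droplets(cfg)$truth
  # enrichment 1x everywhere: per-promoter counts consistent with Poisson
  plan1 <- tibble::tibble(mark = "H3K4me3", population = "p", replicate = "r1",
                          genes = list("escape"), fold = 1)
  fs1 <- simulate_fragments(tr, plan = plan1, background_density = 0.05,
                            x_block_fold = 1)
  prom <- fs1$promoters
  cnt <- count_fragments(fs1$fragments, prom)
  width <- prom$end[1] - prom$start[1]
  lam <- 0.05 * (width + mean(fs1$fragments$end - fs1$fragments$start))
  z <- (cnt$count - lam) / sqrt(lam)
  expect_gt(mean(abs(z) < 3), 0.99)
  # planted 8x at escape promoters: ratio of group means in [6, 10]
  fs8 <- simulate_fragments(tr, x_block_fold = 1)
  k9 <- fs8$fragments[fs8$fragments$mark == "H3K9me3" &
                        fs8$fragments$population == "spermatocytes", ]
  sig <- count_fragments(k9, prom)
  avg <- aggregate(count ~ region_id, sig, mean)
  esc <- avg$count[avg$region_id %in% tr$escape_genes]
  oth <- avg$count[avg$region_id %in%
                     setdiff(tr$genes$gene_id[tr$genes$class == "X"],
                             tr$escape_genes)]
  expect_gt(mean(esc) / mean(oth), 6)
  expect_lt(mean(esc) / mean(oth), 10)
  # zero background: every fragment lies in a planted region
  fs0 <- simulate_fragments(tr, background_density = 0, promoter_rate = 0.05)
  pr_esc <- prom[prom$gene_id %in% tr$escape_genes, ]
  planted <- rbind(pr_esc[, c("chrom", "start", "end")],
                   fs0$x_blocks[, c("chrom", "start", "end")])
  inside <- GenomicRanges::countOverlaps(
    spermdyn:::to_gr(fs0$fragments), spermdyn:::to_gr(planted),
    type = "within") > 0
  expect_true(all(inside))
})

test_that("invalid configurations are rejected", {
  st <- default_stages()
  st$s_x[1] <- 1.2
  expect_error(sim_config(stages = st), "silencing")
  st2 <- default_stages(); st2$lib_size[1] <- 0
  expect_error(sim_config(stages = st2), "library")
  expect_error(sim_config(escape_stage = "nope"), "unknown stage")
})

test_that("truth serialises to JSON", {
  cfg <- sim_config(seed = 2L, stages = default_stages(n_cells = 5L),
                    n_empty = 10L)
  tr <- simulate_droplets(cfg)$truth
  f <- tempfile(fileext = ".json")
  write_truth(tr, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$escape_genes, tr$escape_genes)
  expect_equal(back$config$seed, 2L)
  expect_equal(unname(unlist(back$ambient_profile[1:5])),
               unname(tr$ambient_profile[1:5]), tolerance = 1e-12)
})
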