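test_that("fragment filtering applies the published rules in order", {
  fr <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 0L, 100L, 5000L, 9000L, 20000L),
    end = c(1000L, 1000L, 1101L, 5600L, 9100L, 20050L),
    quality = c(30, 30, 30, 5, 30, 30),
    replicate = "r1"
  )
  bl <- tibble::tibble(chrom = "chr1", start = 9050L, end = 9500L)
  out <- filter_fragments(fr, bl, min_quality = 10, max_len = 1000)
  drops <- attr(out, "dropped")
  expect_equal(unname(drops), c(1, 1, 1, 1))
  # exactly 1000 bp kept, 1001 dropped; 1 bp blacklist overlap dropped
  expect_true(any(out$end - out$start == 1000))
  expect_false(any(out$end - out$start > 1000))
  expect_equal(nrow(out), 2)
  # same interval in another replicate is not a duplicate
  fr2 <- fr[1:2, ]; fr2$replicate <- c("r1", "r2")
  expect_equal(nrow(filter_fragments(fr2)), 2)
})

test_that("fragments count in every overlapped window", {
  frag <- tibble::tibble(chrom = "chrZ", start = c(100L, 950L),
                         end = c(200L, 1050L))
  win <- tile_windows(c(chrZ = 3000L), width = 1000L)
  cnt <- count_fragments(frag, win)
  expect_equal(cnt$count, c(2, 1, 0))    # boundary spanner counts twice
  expect_equal(sum(cnt$count), 3)        # >= number of fragments
  # brute-force oracle over random toys
  withr::with_seed(11, {
    for (i in 1:5) {
      fr <- tibble::tibble(chrom = "chrZ",
                           start = sample(0:2900, 40, TRUE))
      fr$end <- fr$start + sample(10:500, 40, TRUE)
      fr$end <- pmin(fr$end, 3000L)
      cc <- count_fragments(fr, win)
      oracle <- vapply(seq_len(nrow(win)), function(w) {
        sum(fr$start < win$end[w] & fr$end > win$start[w])
      }, numeric(1))
      expect_equal(cc$count, oracle)
    }
  })
  # midpoint mode assigns each fragment exactly once
  cm <- count_fragments(frag, win, mode = "midpoint")
  expect_equal(sum(cm$count), 2)
  # CPM columns sum to 1e6 over a partition when nothing spans a boundary
  fr3 <- tibble::tibble(chrom = "chrZ", start = c(10L, 1200L, 2100L),
                        end = c(200L, 1400L, 2200L))
  c3 <- count_fragments(fr3, win)
  expect_equal(sum(c3$cpm), 1e6)
})

test_that("promoter windows follow strand and clip to the chromosome", {
  ann <- tibble::tibble(
    gene_id = c("gp", "gm", "gc"),
    chrom = "chr1",
    start = c(5000L, 3000L, 100L),
    end = c(7000L, 5000L, 900L),
    strand = c("+", "-", "+")
  )
  pr <- promoter_regions(ann, chrom_lengths = c(chr1 = 100000L))
  expect_equal(pr$start[1], 3000L); expect_equal(pr$end[1], 5200L)
  expect_equal(pr$start[2], 4800L); expect_equal(pr$end[2], 7000L)
  expect_equal(pr$start[3], 0L); expect_equal(pr$end[3], 300L)
  ann$start[1] <- -5L
  expect_error(promoter_regions(dplyr::mutate(ann, start = c(200000L, 3000L, 100L)),
                                chrom_lengths = c(chr1 = 100000L)),
               "TSS outside")
})

test_that("promoter set comparison matches exact rank-sum enumeration", {
  sig <- tibble::tibble(
    region_id = sprintf("g%d", 1:6),
    chrom = "chr1", start = 0L, end = 1L,
    cpm = c(1, 2, 3, 4, 5, 6), count = 1
  )
  # {1,2,3} vs {4,5,6}: one-sided 1/20, two-sided 0.1 by enumeration
  res <- compare_promoter_sets(sig, sprintf("g%d", 1:3), sprintf("g%d", 4:6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  # full enumeration oracle over all C(6,3) assignments
  vals <- sig$cpm
  combos <- combn(6, 3)
  stat <- function(a) sum(rank(vals)[a]) - 6
  obs <- stat(1:3)
  null <- apply(combos, 2, stat)
  p_manual <- min(1, 2 * min(mean(null <= obs), mean(null >= obs)))
  expect_equal(res$p_value, p_manual)
  # identical sets of values: p = 1 with ties handled
  sig2 <- sig; sig2$cpm <- rep(c(1, 2, 3), 2)
  res2 <- compare_promoter_sets(sig2, sprintf("g%d", 1:3), sprintf("g%d", 4:6))
  expect_equal(res2$p_value, 1)
  expect_error(compare_promoter_sets(sig, sprintf("g%d", 1:3),
                                     sprintf("g%d", 3:6)), "disjoint")
})

test_that("high-signal regions merge like a union-find oracle", {
  w1 <- tibble::tibble(region_id = c("a", "b"), chrom = "chrX",
                       start = c(0L, 2000L), end = c(1000L, 3000L),
                       count = c(5, 7))
  hs <- high_signal_regions(w1, top_n = 2, tolerance = 1500)
  expect_equal(nrow(hs), 1)
  expect_equal(c(hs$start, hs$end), c(0L, 3000L))
  w2 <- w1; w2$start <- c(0L, 2600L); w2$end <- c(1000L, 3600L)
  expect_equal(nrow(high_signal_regions(w2, top_n = 2, tolerance = 1500)), 2)
  # oracle equivalence on random toys, including input order invariance
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- 100
      st <- sort(sample(seq(0, 200000, by = 1000), n))
      w <- tibble::tibble(region_id = as.character(seq_len(n)),
                          chrom = sample(c("c1", "c2"), n, TRUE),
                          start = st, end = st + 1000L,
                          count = rpois(n, 5))
      top_n <- 40
      got <- high_signal_regions(w, top_n = top_n, tolerance = 1500)
      got <- got[order(got$chrom, got$start), ]
      # union-find brute force over the same top windows
      ord <- order(-w$count, w$chrom, w$start)
      top <- w[ord[seq_len(top_n)], ]
      parent <- seq_len(top_n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (a in seq_len(top_n)) for (b in seq_len(top_n)) {
        if (a < b && top$chrom[a] == top$chrom[b]) {
          gap <- max(top$start[a], top$start[b]) - min(top$end[a], top$end[b])
          if (gap <= 1500) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[ra] <- rb
          }
        }
      }
      roots <- vapply(seq_len(top_n), find, numeric(1))
      oracle <- do.call(rbind, lapply(unique(roots), function(r) {
        grp <- top[roots == r, ]
        data.frame(chrom = grp$chrom[1], start = min(grp$start),
                   end = max(grp$end), total_count = sum(grp$count))
      }))
      oracle <- oracle[order(oracle$chrom, oracle$start), ]
      expect_equal(got$start, oracle$start)
      expect_equal(got$end, oracle$end)
      expect_equal(got$total_count, oracle$total_count)
      # input order invariance
      got2 <- high_signal_regions(w[sample(n), ], top_n = top_n, tolerance = 1500)
      got2 <- got2[order(got2$chrom, got2$start), ]
      expect_equal(got2$start, got$start)
    }
  })
  expect_error(high_signal_regions(w1, top_n = 10), "fewer windows")
})

test_that("repeat enrichment builds exact base-level 2x2 tables", {
  regions <- tibble::tibble(chrom = "X", start = 0L, end = 100L)
  reps <- tibble::tibble(
    chrom = "X",
    start = c(0L, 40L, 500L, 200L),
    end = c(30L, 50L, 510L, 210L),
    name = c("F1", "F1", "F1", "F2")
  )
  re <- repeat_enrichment(regions, reps, chrom_length = 1000L, exclude = NULL)
  f1 <- re[re$family == "F1", ]
  # F1: 40 bases in-region, 10 out; region 100, chromosome 1000
  expect_equal(f1$bases_in, 40)
  expect_equal(f1$bases_out, 10)
  a <- 40; b <- 10; cc <- 60; d <- 890
  expect_equal(f1$odds_ratio, (a * d) / (b * cc))
  # p equals the hypergeometric summation oracle
  oracle_p <- local({
    probs <- dhyper(0:50, 100, 900, 50)
    sum(probs[probs <= dhyper(a, 100, 900, 50) * (1 + 1e-7)])
  })
  expect_equal(f1$p_value, oracle_p, tolerance = 1e-9)
  # a family entirely outside the regions has odds ratio 0
  expect_equal(re$odds_ratio[re$family == "F2"], 0)
  # excluded families are dropped before testing
  re2 <- repeat_enrichment(regions, reps, 1000L, exclude = "F2")
  expect_false("F2" %in% re2$family)
  expect_error(repeat_enrichment(regions, reps, chrom_length = 50L), "past")
})

test_that("the spec's worked 2x2 example reproduces", {
  # (in-family/in 30, in-family/out 10, other/in 70, other/out 890)
  or <- (30 * 890) / (10 * 70)
  expect_equal(round(or, 1), 38.1)
  p_fisher <- fisher.test(matrix(c(30, 10, 70, 890), 2))$p.value
  probs <- dhyper(0:40, 100, 900, 40)
  p_oracle <- sum(probs[probs <= dhyper(30, 100, 900, 40) * (1 + 1e-7)])
  expect_equal(p_fisher, p_oracle, tolerance = 1e-9)
})

test_that("Fisher p agrees with hypergeometric summation for small margins", {
  withr::with_seed(17, {
    for (i in 1:25) {
      a <- sample(0:30, 1); b <- sample(0:30, 1)
      cc <- sample(0:30, 1); d <- sample(0:30, 1)
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
      p1 <- fisher.test(matrix(c(a, b, cc, d), 2))$p.value
      k <- a + b; n1 <- a + cc; n2 <- b + d
      xs <- max(0, k - n2):min(k, n1)
      probs <- dhyper(xs, n1, n2, k)
      p2 <- sum(probs[probs <= dhyper(a, n1, n2, k) * (1 + 1e-7)])
      expect_equal(p1, p2, tolerance = 1e-9)
    }
  })
})
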