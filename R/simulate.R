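#' Default stage table for the synthetic spermatogenesis trajectory
#'
#' Six ordered stages from spermatogonia (SG) through leptotene/zygotene
#' (LZ), pachytene (P) and diplotene (D) spermatocytes to round (RS) and
#' elongating (ES) spermatids. The planted structure mirrors the biology
#' the pipeline is built to recover: a transcriptional-complexity dip in
#' early meiosis (LZ: few genes on, tiny libraries), a peak in diplotene,
#' a decline in elongating spermatids, and meiotic sex chromosome
#' inactivation (X/Y silencing factors dropping sharply in pachytene with
#' partial spermatid reactivation).
#'
#' @param n_cells cells per stage.
#' @return tibble with one row per stage: `name`, `n_cells`, `lib_size`
#'   (mean UMI count), `n_on` (expected active genes, the complexity
#'   target), `s_x`, `s_y` (X / Y silencing factors in `[0, 1]`).
#' @export
default_stages <- function(n_cells = 500L) {
  tibble::tibble(
    name = c("SG", "LZ", "P", "D", "RS", "ES"),
    n_cells = as.integer(n_cells),
    lib_size = c(5000, 1200, 4000, 6000, 4000, 1500),
    n_on = c(1100L, 500L, 1200L, 1400L, 1000L, 450L),
    s_x = c(0.8, 0.6, 0.1, 0.1, 0.5, 0.5),
    s_y = c(0.8, 0.5, 0.05, 0.05, 0.3, 0.3)
  )
}

#' Simulation configuration
#'
#' Describes the planted world for the synthetic droplet experiment:
#' gene complement per chromosome class, the ordered stage programme,
#' marker genes, negative-binomial noise, X-linked escape genes activated
#' in spermatids, ambient RNA / empty droplets, and batch structure.
#'
#' @param seed integer; the whole simulation is a deterministic function
#'   of the config including this seed.
#' @param n_genes_per_class named integer vector: autosomal chromosomes by
#'   name plus `X`, `Y` and `MT`.
#' @param stages stage table as produced by [default_stages()].
#' @param n_markers,marker_lfc stage-specific autosomal marker genes per
#'   stage and their log2 up-shift within the stage.
#' @param off_factor residual expression (relative to baseline) of genes
#'   outside a stage's programme; soft attenuation rather than a hard
#'   zero, so complexity differences come from detection rates while the
#'   planted markers remain the strongest stage-specific signal.
#' @param dispersion negative-binomial gene dispersion (1/size).
#' @param baseline_sd log2-scale spread of per-gene baseline expression.
#' @param n_escape_genes,escape_stage,escape_lfc,escape_base X-linked
#'   escape genes: near-zero mean `escape_base` (expected counts/cell)
#'   before the activation stage, `escape_base * 2^escape_lfc` from the
#'   activation stage onwards; exempt from the silencing factor (that is
#'   what escaping means).
#' @param n_empty,ambient_lib_range empty droplets and their total-count
#'   range; empties are multinomial draws from the ambient profile (the
#'   library-size-weighted mean of all cell profiles).
#' @param mito_beta Beta(a, b) parameters for the per-cell mitochondrial
#'   fraction.
#' @param lib_sdlog log-normal spread of per-cell library size around the
#'   stage mean.
#' @param batches tibble with `batch` and `log2_shift`; the shift is
#'   applied to a fixed random half of the genes in that batch.
#' @param proportion_shift optional named vector of per-stage fold-changes
#'   applied to cell numbers of a second genotype (`"g2"`).
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_class = c(chr1 = 650L, chr2 = 650L, chr3 = 487L,
                                             X = 150L, Y = 50L, MT = 13L),
                       stages = default_stages(),
                       n_markers = 50L,
                       marker_lfc = 4,
                       off_factor = 0.15,
                       dispersion = 0.1,
                       baseline_sd = 1.5,
                       n_escape_genes = 20L,
                       escape_stage = "RS",
                       escape_lfc = 6,
                       escape_base = 0.05,
                       n_empty = 5000L,
                       ambient_lib_range = c(20L, 150L),
                       mito_beta = c(2, 60),
                       lib_sdlog = 0.3,
                       batches = tibble::tibble(batch = c("b1", "b2"), log2_shift = c(0, 0)),
                       proportion_shift = NULL) {
  if (any(n_genes_per_class < 0) || any(stages$n_cells < 0) || n_empty < 0) {
    stop("all counts must be non-negative")
  }
  if (!all(c("X", "Y", "MT") %in% names(n_genes_per_class))) {
    stop("n_genes_per_class needs X, Y and MT entries")
  }
  if (nrow(stages) == 0) stop("stage list must be non-empty")
  if (any(stages$s_x < 0 | stages$s_x > 1 | stages$s_y < 0 | stages$s_y > 1)) {
    stop("silencing factors must lie in [0, 1]")
  }
  if (any(stages$lib_size <= 0)) stop("non-positive library sizes")
  if (n_escape_genes > 0 && !escape_stage %in% stages$name) {
    stop("unknown stage reference in escape config: ", escape_stage)
  }
  structure(as.list(environment()), class = "sim_config")
}

# deterministic gene annotation for a config: genes laid on a grid so that
# promoters and windows have room; coordinates 0-based half-open
sim_annotation <- function(config) {
  cls <- config$n_genes_per_class
  chroms <- names(cls)
  out <- purrr::map2_dfr(chroms, as.integer(cls), function(ch, n) {
    if (n == 0) return(NULL)
    spacing <- if (ch == "MT") 1200L else 8000L
    glen <- if (ch == "MT") 900L else 2000L
    start <- 3000L + (seq_len(n) - 1L) * spacing
    tibble::tibble(
      chrom = ch,
      start = start,
      end = start + glen,
      strand = rep(c("+", "-"), length.out = n)
    )
  })
  out$gene_id <- sprintf("g%04d", seq_len(nrow(out)))
  out$symbol <- out$gene_id
  out$class <- chrom_class(out$chrom)
  out[, c("gene_id", "symbol", "chrom", "start", "end", "strand", "class")]
}

sim_chrom_lengths <- function(config) {
  cls <- config$n_genes_per_class
  len <- ifelse(names(cls) == "MT", 3000 + as.numeric(cls) * 1200 + 3000,
                3000 + as.numeric(cls) * 8000 + 3000)
  stats::setNames(as.integer(len), names(cls))
}

#' Simulate a droplet scRNA-seq experiment with planted truth
#'
#' Real cells are drawn gene-wise from a negative binomial whose mean
#' interpolates stage-specific programmes continuously along planted
#' pseudotime; X/Y means are multiplied by the assigned stage's silencing
#' factor (a step function, so a factor of 0 gives exactly zero counts);
#' escape genes jump by the planted log2 fold-change at their activation
#' stage; a per-cell mitochondrial fraction is planted; empty droplets are
#' multinomial draws from the ambient profile.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [sperm_counts] over cells + empties) and
#'   `truth` (planted per-cell stage/pseudotime, per-gene programme,
#'   escape set, ambient profile, stage expression profiles, config).
#' @export
simulate_droplets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_droplets_impl(config))
}

simulate_droplets_impl <- function(config) {
  ann <- sim_annotation(config)
  G <- nrow(ann)
  st <- config$stages
  K <- nrow(st)

  auto <- which(ann$class == "autosome")
  xg <- which(ann$class == "X")
  yg <- which(ann$class == "Y")
  mt <- which(ann$class == "MT")

  # stable per-gene baseline (log2 scale)
  b <- stats::rnorm(G, mean = 0, sd = config$baseline_sd)

  # stage-specific markers: disjoint autosomal sets
  n_mark <- min(config$n_markers, floor(length(auto) / K))
  markers <- rep(list(integer(0)), K)
  if (n_mark > 0) {
    marker_pool <- sample(auto)
    markers <- split(marker_pool[seq_len(n_mark * K)], rep(seq_len(K), each = n_mark))
    # canonical markers are well-expressed genes; give them a high baseline
    b[unlist(markers)] <- stats::rnorm(n_mark * K, 1.5, 0.5)
    # name the first-stage (spermatogonial) markers after the published
    # SSC / progenitor panels so the stemness scores have their genes
    panel_syms <- c("Id4", "Gfra1", "Lhx1", "Egr2", "Etv5", "Nanos2", "Ret",
                    "Eomes", "Neurog3", "Rarg", "Nanos3", "Lin28a", "Upp1")
    if (n_mark >= length(panel_syms)) {
      ann$symbol[markers[[1]][seq_along(panel_syms)]] <- panel_syms
    }
  }

  # escape genes on X, step-activated, exempt from silencing
  esc <- integer(0)
  if (config$n_escape_genes > 0) {
    esc <- sample(xg, min(config$n_escape_genes, length(xg)))
  }
  act_k <- if (length(esc)) match(config$escape_stage, st$name) else K + 1L

  # per-stage programme membership: markers are always on in their stage;
  # the rest of the programme is drawn uniformly over all nuclear genes,
  # so X genes share the autosomal on/off rate and the X:A statistic
  # reflects the silencing factor alone
  W <- matrix(0, G, K)
  for (k in seq_len(K)) {
    pool <- setdiff(c(auto, xg, yg), markers[[k]])
    n_extra <- max(0L, st$n_on[k] - length(markers[[k]]))
    on <- c(markers[[k]], sample(pool, min(n_extra, length(pool))))
    W[, k] <- 2^b * config$off_factor   # genes outside the stage programme
    W[on, k] <- 2^b[on]
    W[markers[[k]], k] <- W[markers[[k]], k] * 2^config$marker_lfc
  }
  W[mt, ] <- 0   # mitochondrial mass allocated per cell below
  if (length(esc)) W[esc, ] <- 0  # absolute means planted below

  # cells: stage assignment, pseudotime = stage rank scaled to [0,1] + jitter
  n_cells_k <- st$n_cells
  genotype <- rep("g1", sum(n_cells_k))
  stage_idx <- rep(seq_len(K), n_cells_k)
  if (!is.null(config$proportion_shift)) {
    shift <- rep(1, K)
    shift[match(names(config$proportion_shift), st$name)] <- config$proportion_shift
    n2 <- pmax(0L, as.integer(round(n_cells_k * shift)))
    stage_idx <- c(stage_idx, rep(seq_len(K), n2))
    genotype <- c(genotype, rep("g2", sum(n2)))
  }
  n <- length(stage_idx)
  pt <- (stage_idx - 1 + stats::runif(n)) / K

  # continuous programme: linear interpolation of stage weights between
  # stage centres (k - 0.5) / K, constant beyond the end centres
  if (K > 1) {
    centers <- (seq_len(K) - 0.5) / K
    kl <- pmin(pmax(findInterval(pt, centers), 1L), K - 1L)
    kr <- kl + 1L
    alpha <- pmin(pmax((pt - centers[kl]) / (centers[kr] - centers[kl]), 0), 1)
    A <- Matrix::sparseMatrix(
      i = c(kl, kr), j = c(seq_len(n), seq_len(n)),
      x = c(1 - alpha, alpha), dims = c(K, n)
    )
    Wc <- as.matrix(W %*% A)                       # genes x cells weights
  } else {
    Wc <- matrix(W[, 1], G, n)
  }

  # silencing: step function of the assigned stage
  Wc[xg, ] <- Wc[xg, ] * rep(st$s_x[stage_idx], each = length(xg))
  Wc[yg, ] <- Wc[yg, ] * rep(st$s_y[stage_idx], each = length(yg))

  # per-batch shift on a fixed half of genes
  batch <- sample(rep(config$batches$batch, length.out = n))
  shift_genes <- sample(G, floor(G / 2))
  for (bi in seq_len(nrow(config$batches))) {
    s <- config$batches$log2_shift[bi]
    if (s != 0) {
      idx <- which(batch == config$batches$batch[bi])
      Wc[shift_genes, idx] <- Wc[shift_genes, idx] * 2^s
    }
  }

  # library size and mitochondrial fraction
  lib <- stats::rlnorm(n, meanlog = log(st$lib_size[stage_idx]), sdlog = config$lib_sdlog)
  fmt <- stats::rbeta(n, config$mito_beta[1], config$mito_beta[2])

  colsum <- colSums(Wc)
  P <- sweep(Wc, 2, ifelse(colsum > 0, colsum, 1), "/")
  P <- sweep(P, 2, 1 - fmt, "*")
  if (length(mt)) P[mt, ] <- matrix(rep(fmt / length(mt), each = length(mt)), length(mt), n)
  Mu <- sweep(P, 2, lib, "*")
  if (length(esc)) {
    esc_mu <- config$escape_base * 2^(config$escape_lfc * (stage_idx >= act_k))
    Mu[esc, ] <- matrix(rep(esc_mu, each = length(esc)), length(esc), n)
  }

  counts <- matrix(stats::rnbinom(G * n, mu = Mu, size = 1 / config$dispersion), G, n)

  # ambient profile: library-size-weighted mean of cell profiles
  amb <- rowSums(Mu)
  amb <- amb / sum(amb)
  n_empty <- config$n_empty
  empt <- NULL
  if (n_empty > 0) {
    etot <- sample(seq(config$ambient_lib_range[1], config$ambient_lib_range[2]),
                   n_empty, replace = TRUE)
    empt <- vapply(etot, function(tt) stats::rmultinom(1, tt, amb)[, 1], numeric(G))
  }

  barcodes <- c(sprintf("cell_%05d", seq_len(n)),
                if (n_empty > 0) sprintf("empty_%05d", seq_len(n_empty)))
  all_counts <- cbind(counts, empt)
  dimnames(all_counts) <- list(ann$gene_id, barcodes)

  cells <- tibble::tibble(
    barcode = barcodes,
    kind = rep(c("cell", "empty"), c(n, n_empty)),
    stage = c(st$name[stage_idx], rep(NA_character_, n_empty)),
    pseudotime = c(pt, rep(NA_real_, n_empty)),
    batch = c(batch, sample(rep(config$batches$batch, length.out = n_empty))),
    genotype = c(genotype, rep(NA_character_, n_empty)),
    lib_size = c(lib, rep(NA_real_, n_empty)),
    mito_frac = c(fmt, rep(NA_real_, n_empty))
  )

  # expected relative profile of a cell at each stage centre (for bulk)
  mean_fmt <- config$mito_beta[1] / sum(config$mito_beta)
  prof <- matrix(0, G, K, dimnames = list(ann$gene_id, st$name))
  for (k in seq_len(K)) {
    w <- W[, k]
    w[xg] <- w[xg] * st$s_x[k]
    w[yg] <- w[yg] * st$s_y[k]
    p <- w / sum(w) * (1 - mean_fmt)
    if (length(mt)) p[mt] <- mean_fmt / length(mt)
    m <- p * st$lib_size[k]
    if (length(esc)) m[esc] <- config$escape_base * 2^(config$escape_lfc * (k >= act_k))
    prof[, k] <- m / sum(m)
  }

  truth <- structure(list(
    config = config,
    genes = dplyr::mutate(ann, base_log2_weight = b),
    cells = cells,
    markers = tibble::tibble(
      gene_id = ann$gene_id[unlist(markers)],
      stage = rep(st$name, each = n_mark)
    ),
    escape_genes = ann$gene_id[esc],
    escape_stage = config$escape_stage,
    escape_lfc = config$escape_lfc,
    stage_profiles = prof,
    ambient_profile = stats::setNames(amb, ann$gene_id),
    chrom_lengths = sim_chrom_lengths(config),
    batch_shift_genes = ann$gene_id[shift_genes]
  ), class = "sperm_truth")

  list(counts = sperm_counts(all_counts, ann, cells), truth = truth)
}

#' Serialise planted truth to JSON (and back)
#'
#' @param truth a `sperm_truth`; `path` a JSON file.
#' @export
write_truth <- function(truth, path) {
  x <- truth
  x$config <- unclass(x$config)
  x$config$stages <- as.data.frame(x$config$stages)
  x$config$batches <- as.data.frame(x$config$batches)
  x$stage_profiles <- list(
    genes = rownames(truth$stage_profiles),
    stages = colnames(truth$stage_profiles),
    values = unname(as.data.frame(truth$stage_profiles))
  )
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Simulate a bulk RNA-seq time course as stage mixtures
#'
#' Each bulk sample is a multinomial draw of `depth` reads from the
#' composition-weighted average of the planted stage expression profiles —
#' the model behind first-wave juvenile samples, where the wave front
#' truncates the stage spectrum at each postnatal day.
#'
#' @param truth planted truth from [simulate_droplets()].
#' @param compositions samples x stages matrix of mixture weights, each
#'   row summing to 1 (tolerance 1e-8); rownames are sample names,
#'   colnames must match the stage names.
#' @param depth reads per sample.
#' @param days optional numeric vector (postnatal day per sample) stored
#'   in the sample table; used by the escape-gene caller's early/late split.
#' @param seed random seed (defaults to the config seed + 1).
#' @return `bulk_series`: list with `counts` (genes x samples),
#'   `samples` (tibble), `genes` (annotation), `compositions`.
#' @export
simulate_bulk <- function(truth, compositions, depth = 1e6, days = NULL,
                          seed = truth$config$seed + 1L) {
  compositions <- as.matrix(compositions)
  if (is.null(colnames(compositions))) colnames(compositions) <- colnames(truth$stage_profiles)
  stopifnot(all(colnames(compositions) %in% colnames(truth$stage_profiles)))
  if (any(abs(rowSums(compositions) - 1) > 1e-8)) {
    stop("composition not normalised: rows must sum to 1")
  }
  if (is.null(rownames(compositions))) {
    rownames(compositions) <- sprintf("bulk_%02d", seq_len(nrow(compositions)))
  }
  P <- truth$stage_profiles[, colnames(compositions), drop = FALSE]
  counts <- withr::with_seed(seed, {
    vapply(seq_len(nrow(compositions)), function(i) {
      p <- as.numeric(P %*% compositions[i, ])
      stats::rmultinom(1, depth, p)[, 1]
    }, numeric(nrow(P)))
  })
  dimnames(counts) <- list(rownames(P), rownames(compositions))
  structure(list(
    counts = counts,
    samples = tibble::tibble(
      sample = rownames(compositions),
      day = if (is.null(days)) NA_real_ else days
    ),
    genes = truth$genes,
    compositions = compositions
  ), class = "bulk_series")
}

#' First-wave stage compositions for a series of postnatal days
#'
#' Models the synchronised first spermatogenic wave: stage `k` first
#' appears at a characteristic day and the most advanced available stage
#' dominates the tissue, with earlier stages contributing progressively
#' less.
#'
#' @param truth planted truth (for stage names).
#' @param days postnatal days to emulate.
#' @param onset named vector of first-appearance days per stage.
#' @return samples x stages composition matrix (rows sum to 1) with
#'   attribute `"days"`.
#' @export
first_wave_compositions <- function(truth,
                                    days = c(6, 8, 10, 12, 14, 16, 18, 20, 22, 24, 26, 28, 30),
                                    onset = c(SG = 3, LZ = 10, P = 14, D = 17, RS = 20, ES = 24)) {
  stages <- colnames(truth$stage_profiles)
  stopifnot(all(stages %in% names(onset)))
  onset <- onset[stages]
  comp <- t(vapply(days, function(d) {
    avail <- which(onset <= d)
    w <- numeric(length(stages))
    # the front (latest available stage) dominates; older stages decay
    w[avail] <- exp(-(max(avail) - avail) * 1.2)
    w / sum(w)
  }, numeric(length(stages))))
  dimnames(comp) <- list(sprintf("P%02d", days), stages)
  attr(comp, "days") <- days
  comp
}

#' Simulate chromatin fragments with planted promoter enrichment
#'
#' Background fragments are laid uniformly per chromosome at a configured
#' density; promoter-targeted fragments are added at planted
#' fold-enrichment for (mark, population, gene set) triples; broad X
#' blocks receive extra H3K9me3 and are overlapped by planted repeat
#' intervals. All intervals are 0-based half-open.
#'
#' @param truth planted truth from [simulate_droplets()].
#' @param plan tibble with `mark`, `population`, `replicate`, `genes`
#'   (list-column of gene ids, or the keyword `"escape"`), `fold`.
#'   `NULL` gives a default plan: 8x H3K9me3 at escape promoters in
#'   spermatocytes, 8x H3K4me3 and 4x H3K27ac at the same promoters in
#'   spermatids.
#' @param background_density background fragments per bp.
#' @param promoter_rate base rate used for planted promoter fragments;
#'   defaults to `background_density` (so enrichment is `fold`-times
#'   background), but can be set when the background is zero.
#' @param x_blocks tibble of broad X intervals given extra H3K9me3;
#'   `x_block_fold` their enrichment.
#' @param frag_len length range of fragments (within `[50, 1000]`).
#' @param seed random seed.
#' @return `fragment_sim`: list with `fragments` (tibble: chrom, start,
#'   end, quality, mark, population, replicate), `repeats`, `blacklist`,
#'   `chrom_lengths`, `promoters`, `plan`, `x_blocks`.
#' @export
simulate_fragments <- function(truth, plan = NULL,
                               background_density = 0.05,
                               promoter_rate = NULL,
                               x_blocks = NULL, x_block_fold = 5,
                               frag_len = c(50, 500),
                               seed = truth$config$seed + 2L) {
  ann <- truth$genes
  stopifnot(!is.null(ann$start))
  if (is.null(plan)) {
    plan <- tibble::tibble(
      mark = c("H3K9me3", "H3K9me3", "H3K4me3", "H3K4me3", "H3K27ac", "H3K27ac"),
      population = rep(c("spermatocytes", "spermatids", "spermatids"), each = 2),
      replicate = rep(c("r1", "r2"), 3),
      genes = list("escape", "escape", "escape", "escape", "escape", "escape"),
      fold = c(8, 8, 8, 8, 4, 4)
    )
  }
  clen <- truth$chrom_lengths
  prom <- promoter_regions(ann, chrom_lengths = clen)
  if (is.null(x_blocks)) {
    xl <- clen[["X"]]
    bs <- as.integer(seq(0.1, 0.7, length.out = 3) * xl)
    x_blocks <- tibble::tibble(chrom = "X", start = bs, end = pmin(bs + 30000L, xl))
  }
  base_rate <- if (is.null(promoter_rate)) background_density else promoter_rate
  flen <- function(n) {
    if (frag_len[1] == frag_len[2]) rep(frag_len[1], n)
    else sample(seq(frag_len[1], frag_len[2]), n, replace = TRUE)
  }

  withr::with_seed(seed, {
    combos <- unique(plan[, c("mark", "population", "replicate")])
    frags <- purrr::pmap_dfr(combos, function(mark, population, replicate) {
      # uniform background per chromosome
      bg <- purrr::map_dfr(names(clen), function(ch) {
        nfr <- stats::rpois(1, background_density * clen[[ch]])
        if (nfr == 0) return(NULL)
        len <- flen(nfr)
        start <- floor(stats::runif(nfr, 0, clen[[ch]] - len))
        tibble::tibble(chrom = ch, start = as.integer(start),
                       end = as.integer(start + len))
      })
      # planted promoter enrichment for this (mark, population)
      rows <- which(plan$mark == mark & plan$population == population &
                    plan$replicate == replicate)
      pl <- purrr::map_dfr(rows, function(i) {
        gs <- plan$genes[[i]]
        if (identical(gs, "escape")) gs <- truth$escape_genes
        pr <- prom[prom$gene_id %in% gs, ]
        if (nrow(pr) == 0) stop("plan gene set matches no promoters")
        purrr::map_dfr(seq_len(nrow(pr)), function(j) {
          wdt <- pr$end[j] - pr$start[j]
          nfr <- stats::rpois(1, (plan$fold[i] - 1) * base_rate * wdt)
          if (nfr == 0) return(NULL)
          len <- pmin(flen(nfr), wdt)
          start <- floor(stats::runif(nfr, pr$start[j], pr$end[j] - len))
          tibble::tibble(chrom = pr$chrom[j], start = as.integer(start),
                         end = as.integer(start + len))
        })
      })
      # broad X blocks: repressive mark only
      bl <- NULL
      if (mark == "H3K9me3" && nrow(x_blocks) > 0 && x_block_fold > 1) {
        bl <- purrr::map_dfr(seq_len(nrow(x_blocks)), function(j) {
          wdt <- x_blocks$end[j] - x_blocks$start[j]
          nfr <- stats::rpois(1, (x_block_fold - 1) * base_rate * wdt)
          if (nfr == 0) return(NULL)
          len <- pmin(flen(nfr), wdt)
          start <- floor(stats::runif(nfr, x_blocks$start[j], x_blocks$end[j] - len))
          tibble::tibble(chrom = x_blocks$chrom[j], start = as.integer(start),
                         end = as.integer(start + len))
        })
      }
      out <- dplyr::bind_rows(bg, pl, bl)
      if (nrow(out) == 0) return(NULL)
      out$quality <- 30
      out$mark <- mark
      out$population <- population
      out$replicate <- replicate
      out
    })

    # planted repeats: families tiling the X blocks plus scattered background
    reps <- purrr::map_dfr(seq_len(nrow(x_blocks)), function(j) {
      s <- seq(x_blocks$start[j], x_blocks$end[j] - 1500L, by = 2500L)
      tibble::tibble(chrom = x_blocks$chrom[j], start = as.integer(s),
                     end = as.integer(s + 1500L),
                     name = rep(c("L1", "ERVK"), length.out = length(s)))
    })
    xl <- clen[["X"]]
    sc_start <- as.integer(floor(stats::runif(200, 0, xl - 400)))
    reps <- dplyr::bind_rows(reps, tibble::tibble(
      chrom = "X", start = sc_start, end = sc_start + 300L,
      name = sample(c("B1_SINE", "Simple_repeat", "L1"), 200, replace = TRUE)
    ))
    blacklist <- tibble::tibble(chrom = "chr1",
                                start = c(0L, 10000L), end = c(2000L, 12000L))

    structure(list(
      fragments = frags, repeats = reps, blacklist = blacklist,
      chrom_lengths = clen, promoters = prom, plan = plan, x_blocks = x_blocks
    ), class = "fragment_sim")
  })
}
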