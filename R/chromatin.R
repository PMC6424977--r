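# interval tibbles are 0-based half-open; GRanges (1-based closed) only
# ever exist inside these two converters
to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}
from_gr <- function(gr) {
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr))
}

#' Filter chromatin fragments
#'
#' Applies, in order: duplicate removal (identical chrom/start/end within
#' a replicate), the minimum quality score, the maximum fragment length
#' (the published rule removed read pairs mapped more than 1000 bp
#' apart, so exactly 1000 bp is kept), and removal of fragments
#' overlapping any blacklist interval by at least 1 bp.
#'
#' @param frags tibble with `chrom`, `start`, `end` and optionally
#'   `quality`, `replicate` (plus any grouping columns, preserved).
#' @param blacklist optional tibble of intervals.
#' @param min_quality minimum quality kept (fragments below are dropped).
#' @param max_len maximum fragment length kept (strict > dropped).
#' @return filtered tibble with a `dropped` attribute counting removals
#'   per rule.
#' @export
filter_fragments <- function(frags, blacklist = NULL, min_quality = 10,
                             max_len = 1000L) {
  if (!is.null(blacklist) && nrow(blacklist) &&
      any(blacklist$start >= blacklist$end)) stop("invalid blacklist interval")
  dropped <- c(duplicate = 0L, quality = 0L, length = 0L, blacklist = 0L)
  rep_key <- if ("replicate" %in% names(frags)) frags$replicate else ""
  if ("mark" %in% names(frags)) rep_key <- paste(rep_key, frags$mark)
  if ("population" %in% names(frags)) rep_key <- paste(rep_key, frags$population)
  dup <- duplicated(paste(frags$chrom, frags$start, frags$end, rep_key))
  dropped["duplicate"] <- sum(dup)
  frags <- frags[!dup, , drop = FALSE]
  if ("quality" %in% names(frags)) {
    bad <- frags$quality < min_quality
    dropped["quality"] <- sum(bad)
    frags <- frags[!bad, , drop = FALSE]
  }
  long <- (frags$end - frags$start) > max_len
  dropped["length"] <- sum(long)
  frags <- frags[!long, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist) && nrow(frags)) {
    hits <- GenomicRanges::countOverlaps(to_gr(frags), to_gr(blacklist),
                                         minoverlap = 1L) > 0
    dropped["blacklist"] <- sum(hits)
    frags <- frags[!hits, , drop = FALSE]
  }
  attr(frags, "dropped") <- dropped
  frags
}

#' Tile a genome into fixed-width windows
#'
#' Windows tile `[0, chrom_length)` with the last window truncated.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param width window width (default 1000).
#' @return tibble: region_id, chrom, start, end.
#' @export
tile_windows <- function(chrom_lengths, width = 1000L) {
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    start <- seq(0L, len - 1L, by = width)
    tibble::tibble(chrom = ch, start = as.integer(start),
                   end = as.integer(pmin(start + width, len)))
  }) |>
    dplyr::mutate(region_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
                  .before = 1)
}

#' Whole chromosomes as counting regions
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @return tibble: region_id, chrom, start, end.
#' @export
chromosome_regions <- function(chrom_lengths) {
  tibble::tibble(region_id = names(chrom_lengths),
                 chrom = names(chrom_lengths),
                 start = 0L, end = as.integer(chrom_lengths))
}

#' Count fragments in regions with CPM / FPKM normalisation
#'
#' A fragment is counted in every region it overlaps by at least 1 bp
#' (so a fragment spanning a window boundary counts in both windows);
#' `mode = "midpoint"` assigns each fragment to the single region
#' containing its midpoint instead. When the fragment table carries
#' `mark` / `population` / `replicate` columns, counting is per group and
#' the library size is the group's total fragment count.
#'
#' @param frags fragment tibble (after [filter_fragments()]).
#' @param regions region tibble with `region_id`, `chrom`, `start`,
#'   `end` — from [tile_windows()], [chromosome_regions()],
#'   [promoter_regions()] or custom.
#' @param mode `"overlap"` (default) or `"midpoint"`.
#' @return tibble: region_id, chrom, start, end, group columns, count,
#'   cpm (`count * 1e6 / library`), fpkm (cpm further divided by region
#'   length in kb).
#' @export
count_fragments <- function(frags, regions, mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)))
  grp_cols <- intersect(c("mark", "population", "replicate"), names(frags))
  key <- if (length(grp_cols)) do.call(paste, c(frags[grp_cols], sep = "|")) else rep("all", nrow(frags))
  rg <- to_gr(regions)
  purrr::map_dfr(unique(key), function(k) {
    sub <- frags[key == k, , drop = FALSE]
    lib <- nrow(sub)
    fg <- if (mode == "overlap") to_gr(sub) else {
      mid <- floor((sub$start + sub$end) / 2)
      GenomicRanges::GRanges(sub$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
    }
    cnt <- GenomicRanges::countOverlaps(rg, fg, minoverlap = 1L)
    out <- dplyr::bind_cols(
      regions[, c("region_id", "chrom", "start", "end")],
      if (length(grp_cols)) sub[rep(1, nrow(regions)), grp_cols] else NULL
    )
    out$count <- as.numeric(cnt)
    out$cpm <- cnt * 1e6 / lib
    out$fpkm <- out$cpm / ((regions$end - regions$start) / 1000)
    out
  })
}

#' Promoter regions from gene annotation
#'
#' For a + strand gene the promoter is `[TSS - upstream, TSS + downstream)`
#' with the TSS at the gene start; for a - strand gene the TSS is the
#' gene end and the window is mirrored. Windows are clipped to the
#' chromosome.
#'
#' @param annotation tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param upstream,downstream window extents (defaults 2000 / 200).
#' @param chrom_lengths optional named vector for clipping; the TSS
#'   itself must lie inside the chromosome.
#' @return tibble: region_id (= gene_id), gene_id, chrom, start, end,
#'   strand.
#' @export
promoter_regions <- function(annotation, upstream = 2000L, downstream = 200L,
                             chrom_lengths = NULL) {
  stopifnot(all(annotation$strand %in% c("+", "-")))
  plus <- annotation$strand == "+"
  tss <- ifelse(plus, annotation$start, annotation$end)
  start <- ifelse(plus, tss - upstream, tss - downstream)
  end <- ifelse(plus, tss + downstream, tss + upstream)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[annotation$chrom]
    if (any(is.na(len))) stop("unknown chromosome in annotation")
    if (any(tss < 0 | tss > len)) stop("TSS outside chromosome")
    start <- pmax(start, 0)
    end <- pmin(end, len)
  } else {
    start <- pmax(start, 0)
  }
  tibble::tibble(region_id = annotation$gene_id, gene_id = annotation$gene_id,
                 chrom = annotation$chrom, start = as.integer(start),
                 end = as.integer(end), strand = annotation$strand)
}

#' Compare promoter signal between two gene sets
#'
#' CPM is averaged across replicates per promoter, then the two sets are
#' compared with a two-sample Wilcoxon rank-sum test: exact when both
#' sets have at most 12 promoters and there are no ties, otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param signal promoter [count_fragments()] output for one mark and
#'   population (any number of replicates).
#' @param set_a,set_b disjoint vectors of region/gene ids.
#' @param expressed optional vector of ids passing the caller's
#'   expression filter (e.g. bulk mean count >= 10); both sets are
#'   intersected with it.
#' @return one-row tibble: statistic (W), p_value, median_a, median_b,
#'   n_a, n_b, method.
#' @export
compare_promoter_sets <- function(signal, set_a, set_b, expressed = NULL) {
  if (length(intersect(set_a, set_b))) stop("sets must be disjoint")
  if (!is.null(expressed)) {
    set_a <- intersect(set_a, expressed)
    set_b <- intersect(set_b, expressed)
  }
  avg <- signal |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(cpm = mean(.data$cpm), .groups = "drop")
  va <- avg$cpm[avg$region_id %in% set_a]
  vb <- avg$cpm[avg$region_id %in% set_b]
  if (length(va) < 3 || length(vb) < 3) stop("each set needs at least 3 promoters after filtering")
  wt <- rank_sum_test(va, vb)
  tibble::tibble(statistic = wt$W, p_value = wt$p,
                 median_a = stats::median(va), median_b = stats::median(vb),
                 n_a = length(va), n_b = length(vb), method = wt$method)
}

# two-sample Wilcoxon rank-sum: exact (no ties, both n <= max_exact) or
# normal approximation with tie correction and continuity correction
rank_sum_test <- function(a, b, max_exact = 12L) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && na <= max_exact && nb <= max_exact) {
    p_le <- stats::pwilcox(W, na, nb)
    p_ge <- stats::pwilcox(W - 1, na, nb, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    sigma <- sqrt((na * nb / 12) *
                  ((na + nb + 1) - sum(tie_tab^3 - tie_tab) /
                     ((na + nb) * (na + nb - 1))))
    if (sigma == 0 || W == mu) {
      p <- 1
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(W = W, p = p, method = method)
}

#' Merge the top windows into high-signal regions
#'
#' Selects the `top_n` windows by count (ties broken by genomic order)
#' and merges same-chromosome windows whose gap is at most `tolerance`
#' bp into maximal regions. The result does not depend on the input
#' window order.
#'
#' @param signal window [count_fragments()] output (one group).
#' @param top_n windows to keep (default 1000).
#' @param tolerance maximum merge gap in bp (default 1500).
#' @return tibble: chrom, start, end, total_count, n_windows.
#' @export
high_signal_regions <- function(signal, top_n = 1000L, tolerance = 1500L) {
  if (nrow(signal) < top_n) stop("fewer windows than top_n")
  ord <- order(-signal$count, signal$chrom, signal$start)
  top <- signal[ord[seq_len(top_n)], , drop = FALSE]
  top <- top[order(top$chrom, top$start), , drop = FALSE]
  purrr::map_dfr(unique(top$chrom), function(ch) {
    w <- top[top$chrom == ch, , drop = FALSE]
    grp <- cumsum(c(1, (w$start[-1] - w$end[-nrow(w)]) > tolerance))
    w |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$.grp) |>
      dplyr::summarise(chrom = ch, start = min(.data$start), end = max(.data$end),
                       total_count = sum(.data$count), n_windows = dplyr::n(),
                       .groups = "drop") |>
      dplyr::select(-".grp")
  })
}

#' Repeat-family enrichment inside high-signal regions
#'
#' For each repeat family, builds a base-level 2x2 table — bases
#' {inside high-signal regions vs rest of the chromosome} x {family vs
#' non-family} — and tests it with Fisher's exact test (two-sided).
#' Overlapping annotations of one family are collapsed so each base
#' counts once per family; different families are counted independently.
#' Excluded families (simple/telomeric/centromeric by default) are
#' dropped before testing.
#'
#' @param regions high-signal regions (tibble chrom/start/end) on one
#'   chromosome.
#' @param repeats repeat tibble: chrom, start, end, name (family).
#' @param chrom_length length of the chromosome analysed.
#' @param exclude families removed before testing.
#' @return tibble: family, bases_in, bases_out, region_bases,
#'   chrom_bases, odds_ratio (sample odds ratio), p_value, fdr.
#' @export
repeat_enrichment <- function(regions, repeats, chrom_length,
                              exclude = c("Simple_repeat", "Low_complexity",
                                          "Satellite", "telomeric", "centromeric")) {
  ch <- unique(regions$chrom)
  if (length(ch) != 1) stop("regions must lie on a single chromosome")
  if (any(regions$end > chrom_length)) stop("region extends past chromosome length")
  reps <- repeats[repeats$chrom == ch & !(repeats$name %in% exclude), , drop = FALSE]
  rgr <- IRanges::reduce(to_gr(regions))
  r_bases <- sum(IRanges::width(rgr))
  purrr::map_dfr(unique(reps$name), function(fam) {
    fgr <- IRanges::reduce(to_gr(reps[reps$name == fam, , drop = FALSE]))
    fam_bases <- sum(IRanges::width(fgr))
    a <- as.numeric(sum(IRanges::width(GenomicRanges::intersect(fgr, rgr))))
    b <- fam_bases - a
    cc <- r_bases - a
    d <- chrom_length - r_bases - b
    tab <- matrix(c(a, b, cc, d), 2)
    tibble::tibble(
      family = fam, bases_in = a, bases_out = b,
      region_bases = r_bases, chrom_bases = chrom_length,
      odds_ratio = (a * d) / (b * cc),
      p_value = stats::fisher.test(tab)$p.value
    )
  }) |>
    dplyr::mutate(fdr = stats::p.adjust(.data$p_value, method = "BH"))
}
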