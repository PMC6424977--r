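#' X-to-autosome (and Y-to-autosome) expression ratios
#'
#' Implements the per-cell MSCI statistic: restrict to genes expressed
#' (count > 0) in more than `frac` of either reference group (the study
#' used spermatogonia and spermatids, the two stages with detectable X
#' activity), compute each cell's mean normalised expression per
#' chromosome over the filtered genes, and divide the X, Y and a control
#' autosome's mean by the mean over all filtered autosomal genes.
#'
#' @param norm genes x cells matrix of normalised (non-log) expression;
#'   the ratio is invariant to any per-cell rescaling. Set
#'   `log_scale = TRUE` for a sensitivity variant on `log2(x + 1)`.
#' @param annotation gene annotation with `gene_id` and `class` (and
#'   `chrom` for the control autosome).
#' @param group1,group2 logical or integer indices of the two reference
#'   cell groups used for the expressed-gene filter.
#' @param frac expressed-fraction threshold (strict >; default 0.3).
#' @param control_chrom autosome reported alongside X and Y (default the
#'   first autosome in the annotation; the study used chromosome 9).
#' @param log_scale compute on log2(norm + 1) instead.
#' @return tibble: barcode, ratio_auto, ratio_x, ratio_y; the filtered
#'   gene set is attached as attribute `"filter_genes"`.
#' @export
xa_ratio <- function(norm, annotation, group1, group2, frac = 0.3,
                     control_chrom = NULL, log_scale = FALSE) {
  m <- as.matrix(norm)
  stopifnot(nrow(m) == nrow(annotation))
  if (log_scale) m <- log2(m + 1)
  det1 <- rowMeans(m[, group1, drop = FALSE] > 0)
  det2 <- rowMeans(m[, group2, drop = FALSE] > 0)
  keep <- det1 > frac | det2 > frac
  if (!any(keep)) stop("expressed-gene filter removed every gene")
  cls <- annotation$class
  if (is.null(control_chrom)) {
    control_chrom <- annotation$chrom[cls == "autosome"][1]
  }
  mean_over <- function(idx) {
    if (!any(idx)) return(rep(NA_real_, ncol(m)))
    colMeans(m[idx, , drop = FALSE])
  }
  a_mean <- mean_over(keep & cls == "autosome")
  x_mean <- mean_over(keep & cls == "X")
  y_mean <- mean_over(keep & cls == "Y")
  c_mean <- mean_over(keep & annotation$chrom == control_chrom)
  for (nm in c("x", "y")) {
    v <- get(paste0(nm, "_mean"))
    if (all(is.na(v))) warning("no filtered genes on ", toupper(nm), "; ratio undefined")
  }
  out <- tibble::tibble(
    barcode = colnames(m) %||% as.character(seq_len(ncol(m))),
    ratio_auto = unname(c_mean / a_mean),
    ratio_x = unname(x_mean / a_mean),
    ratio_y = unname(y_mean / a_mean)
  )
  attr(out, "filter_genes") <- annotation$gene_id[keep]
  out
}

#' Transcriptional-complexity correlation screen with an empirical null
#'
#' Computes Spearman's rho between each gene's log-normalised expression
#' and the per-cell number of genes expressed, and compares it with an
#' empirical null of `n_null` rho values, each obtained by correlating a
#' random permutation of the complexity vector with a randomly chosen
#' gene. Genes with rho beyond the +/- `rho_threshold` and BH-corrected
#' empirical p below `alpha` are classified positive / negative.
#'
#' @param logm genes x cells log-normalised matrix.
#' @param complexity per-cell complexity (from [genes_expressed()]).
#' @param n_null size of the empirical null (the study used 100,000;
#'   tests use 10,000).
#' @param rho_threshold,alpha classification thresholds.
#' @param min_mean genes with mean log expression at or below this are
#'   excluded.
#' @param seed seed for the permutations.
#' @return tibble: gene, rho, p (empirical, (r+1)/(n+1) two-sided), q
#'   (BH), class in {"positive", "negative", "ns"}.
#' @export
correlation_screen <- function(logm, complexity, n_null = 100000L,
                               rho_threshold = 0.3, alpha = 0.1,
                               min_mean = 0.1, seed = 1L) {
  m <- as.matrix(logm)
  if (is.data.frame(complexity)) complexity <- complexity$n_genes
  stopifnot(length(complexity) == ncol(m))
  if (stats::var(complexity) == 0) stop("constant complexity vector")
  keep <- rowMeans(m) > min_mean
  if (!any(keep)) stop("no genes pass the expression filter")
  m <- m[keep, , drop = FALSE]
  n <- ncol(m)

  std_rank <- function(v) {
    r <- rank(v)
    r <- r - mean(r)
    s <- sqrt(sum(r^2))
    if (s == 0) r else r / s
  }
  G <- t(apply(m, 1, std_rank))             # genes x cells, unit rows
  cc <- std_rank(complexity)
  rho <- as.numeric(G %*% cc)

  null_rho <- withr::with_seed(seed, {
    out <- numeric(n_null)
    chunk <- 2000L
    done <- 0L
    while (done < n_null) {
      mchunk <- min(chunk, n_null - done)
      gi <- sample(nrow(G), mchunk, replace = TRUE)
      P <- vapply(seq_len(mchunk), function(i) cc[sample.int(n)], numeric(n))
      out[done + seq_len(mchunk)] <- colSums(t(G[gi, , drop = FALSE]) * P)
      done <- done + mchunk
    }
    out
  })
  null_abs <- sort(abs(null_rho))
  r_ge <- n_null - findInterval(abs(rho) - 1e-12, null_abs)
  p <- (r_ge + 1) / (n_null + 1)
  q <- stats::p.adjust(p, method = "BH")
  cls <- dplyr::case_when(
    rho < -rho_threshold & q < alpha ~ "negative",
    rho > rho_threshold & q < alpha ~ "positive",
    TRUE ~ "ns"
  )
  tibble::tibble(
    gene = rownames(m) %||% as.character(which(keep)),
    rho = rho, p = p, q = q, class = cls
  )
}

#' Stem cell and progenitor scores
#'
#' The fraction of a marker panel detected (count > 0) per cell, for a
#' spermatogonial stem cell panel and a progenitor panel.
#'
#' @param x [sperm_counts] or genes x cells count matrix.
#' @param ssc_panel,progenitor_panel gene identifiers or symbols; the
#'   defaults are the published panels.
#' @return tibble: barcode, frac_ssc, frac_prog.
#' @export
stemness_scores <- function(x,
                            ssc_panel = c("Id4", "Gfra1", "Lhx1", "Egr2",
                                          "Etv5", "Nanos2", "Ret", "Eomes"),
                            progenitor_panel = c("Neurog3", "Rarg", "Nanos3",
                                                 "Lin28a", "Upp1")) {
  m <- if (inherits(x, "sperm_counts")) x$counts else x
  symbols <- if (inherits(x, "sperm_counts")) x$genes$symbol else rownames(m)
  ids <- rownames(m) %||% symbols
  match_panel <- function(panel) {
    hit <- which(ids %in% panel | symbols %in% panel)
    missing <- setdiff(panel, union(ids[hit], symbols[hit]))
    if (length(missing)) {
      warning("panel genes not found, dropped: ", paste(missing, collapse = ", "))
    }
    if (!length(hit)) stop("empty panel after dropping missing genes")
    hit
  }
  s_idx <- match_panel(ssc_panel)
  p_idx <- match_panel(progenitor_panel)
  tibble::tibble(
    barcode = colnames(m) %||% as.character(seq_len(ncol(m))),
    frac_ssc = as.numeric(Matrix::colMeans(m[s_idx, , drop = FALSE] > 0)),
    frac_prog = as.numeric(Matrix::colMeans(m[p_idx, , drop = FALSE] > 0))
  )
}

#' Aggregate multi-copy gene families
#'
#' Sums normalised counts over the members of each family (the family
#' map — genes with high sequence similarity — is a consumed input; the
#' study restricted it to the X chromosome).
#'
#' @param norm genes x cells matrix of normalised counts.
#' @param family_map tibble with `gene_id` and `family`; a gene in two
#'   families errors.
#' @param annotation optional; when given, the map is restricted to
#'   genes of `restrict_class`.
#' @param restrict_class gene class restriction (default `"X"`).
#' @return families x cells matrix of summed normalised counts.
#' @export
aggregate_multicopy <- function(norm, family_map, annotation = NULL,
                                restrict_class = "X") {
  m <- as.matrix(norm)
  if (anyDuplicated(family_map$gene_id)) stop("gene assigned to two families")
  fm <- family_map
  if (!is.null(annotation)) {
    keep_ids <- annotation$gene_id[annotation$class == restrict_class]
    fm <- fm[fm$gene_id %in% keep_ids, , drop = FALSE]
  }
  fm <- fm[fm$gene_id %in% rownames(m), , drop = FALSE]
  fams <- unique(fm$family)
  out <- matrix(0, length(fams), ncol(m), dimnames = list(fams, colnames(m)))
  for (f in fams) {
    idx <- fm$gene_id[fm$family == f]
    out[f, ] <- colSums(m[idx, , drop = FALSE])
  }
  out
}

#' Group genes into correlation-ordered sets
#'
#' Genes are ranked by rho and cut into `n_sets` contiguous bins of
#' (near-)equal size; when the division is uneven the remainder goes to
#' the earliest bins.
#'
#' @param corr result of [correlation_screen()] (or any tibble with
#'   `gene` and `rho`).
#' @param n_sets number of sets (default 9).
#' @return tibble: gene, rho, set (1 = most negative rho).
#' @export
group_gene_sets <- function(corr, n_sets = 9L) {
  if (n_sets < 1) stop("n_sets must be at least 1")
  if (nrow(corr) < n_sets) stop("fewer genes than sets")
  ord <- order(corr$rho)
  n <- nrow(corr)
  sizes <- rep(floor(n / n_sets), n_sets) + (seq_len(n_sets) <= n %% n_sets)
  set <- integer(n)
  set[ord] <- rep(seq_len(n_sets), sizes)
  tibble::tibble(gene = corr$gene, rho = corr$rho, set = set)
}

#' Mean scaled expression of gene sets along pseudotime
#'
#' @param logm genes x cells log-normalised matrix.
#' @param sets output of [group_gene_sets()].
#' @param pseudotime per-cell pseudotime.
#' @param n_bins pseudotime bins.
#' @return tibble: set, bin, pseudotime (bin midpoint), mean_z.
#' @export
gene_set_profiles <- function(logm, sets, pseudotime, n_bins = 20L) {
  m <- as.matrix(logm)[sets$gene, , drop = FALSE]
  mu <- rowMeans(m)
  sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  sd[sd == 0] <- 1
  z <- (m - mu) / sd
  br <- seq(min(pseudotime), max(pseudotime), length.out = n_bins + 1)
  bin <- cut(pseudotime, br, include.lowest = TRUE, labels = FALSE)
  mids <- (br[-1] + br[-length(br)]) / 2
  ub <- sort(unique(bin))
  purrr::map_dfr(sort(unique(sets$set)), function(s) {
    zi <- z[sets$set == s, , drop = FALSE]
    # computed before the tibble call: a `bin` column would otherwise
    # shadow the per-cell bin vector inside tibble()'s tidy evaluation
    mz <- vapply(ub, function(b) mean(zi[, bin == b, drop = FALSE]), numeric(1))
    tibble::tibble(set = s, bin = ub, pseudotime = mids[ub], mean_z = mz)
  })
}
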