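#' Pseudo-bulk construction
#'
#' Sums single-cell counts within each (cluster, batch) combination,
#' giving replicate-aware count samples for negative binomial testing.
#'
#' @param x [sperm_counts] or genes x cells count matrix.
#' @param clusters,batches labels per cell.
#' @return list: `counts` (genes x columns), `samples` (tibble: sample,
#'   cluster, batch, n_cells, flagged — columns with fewer than 10 cells).
#' @export
pseudobulk <- function(x, clusters, batches) {
  m <- if (inherits(x, "sperm_counts")) x$counts else x
  stopifnot(length(clusters) == ncol(m), length(batches) == ncol(m))
  key <- paste(clusters, batches, sep = "|")
  levels <- unique(key)
  out <- vapply(levels, function(k) as.numeric(Matrix::rowSums(m[, key == k, drop = FALSE])),
                numeric(nrow(m)))
  rownames(out) <- rownames(m)
  n_cells <- vapply(levels, function(k) sum(key == k), integer(1))
  info <- tibble::tibble(
    sample = levels,
    cluster = sub("\\|.*", "", levels),
    batch = sub(".*\\|", "", levels),
    n_cells = n_cells,
    flagged = n_cells < 10
  )
  list(counts = out, samples = info)
}

# DESeq-style median-of-ratios size factors for bulk samples
median_ratio_sf <- function(counts) {
  if (any(colSums(counts) == 0)) stop("sample with all-zero library")
  lg <- log(counts)
  use <- rowSums(!is.finite(lg)) == 0
  if (!any(use)) {
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  ref <- rowMeans(lg[use, , drop = FALSE])
  apply(counts[use, , drop = FALSE], 2, function(v) exp(stats::median(log(v) - ref)))
}

#' Negative binomial test against a fold-change threshold
#'
#' A TREAT-style test of H0: |log2 fold-change| <= tau on a two-group
#' count table. Samples are normalised by median-of-ratios size factors;
#' per-gene dispersions come from a method-of-moments estimate shrunk
#' towards a fitted mean-dispersion trend (prior weight equivalent to
#' `prior_weight` observations); the log2 fold-change of group means
#' (pseudo-count 0.5) is tested with a Wald statistic re-centred at the
#' nearer threshold boundary:
#' `p = Phi(-(|lfc| - tau)/se) + Phi(-(|lfc| + tau)/se)`,
#' which reduces to the ordinary two-sided Wald test at tau = 0 and is
#' monotone non-decreasing in tau.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @param group two-level factor/vector, one entry per sample; the
#'   reported fold-change is level 2 over level 1.
#' @param lfc_threshold tau >= 0.
#' @param size_factors optional precomputed factors.
#' @param prior_weight dispersion shrinkage prior weight.
#' @param pseudo pseudo-count for the fold-change.
#' @return tibble: gene, base_mean, mean_1, mean_2, log2fc, se,
#'   dispersion, p, fdr.
#' @export
nb_threshold_test <- function(counts, group, lfc_threshold = 0,
                              size_factors = NULL, prior_weight = 10,
                              pseudo = 0.5) {
  counts <- as.matrix(counts)
  if (lfc_threshold < 0) stop("lfc_threshold must be non-negative")
  if (any(counts < 0)) stop("negative counts")
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  n1 <- sum(group == levels(group)[1])
  n2 <- sum(group == levels(group)[2])
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  if (is.null(size_factors)) size_factors <- median_ratio_sf(counts)
  norm <- t(t(counts) / size_factors)

  i1 <- group == levels(group)[1]
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, !i1, drop = FALSE])
  lfc <- log2((m2 + pseudo) / (m1 + pseudo))

  # method-of-moments dispersion, pooled within groups
  v1 <- rowSums((norm[, i1, drop = FALSE] - m1)^2)
  v2 <- rowSums((norm[, !i1, drop = FALSE] - m2)^2)
  s2 <- (v1 + v2) / (n1 + n2 - 2)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  raw_disp <- pmax((s2 - mu) / pmax(mu, 1e-8)^2, 0)

  # mean-dispersion trend (log-mean loess), shrink with prior weight
  use <- mu > 0
  trend <- rep(stats::median(raw_disp[use]), length(mu))
  if (sum(use) >= 100) {
    lf <- stats::loess(raw_disp[use] ~ log(mu[use]), span = 0.5,
                       family = "symmetric")
    trend[use] <- pmax(stats::predict(lf, log(mu[use])), 1e-6)
  }
  df <- n1 + n2 - 2
  disp <- (df * raw_disp + prior_weight * trend) / (df + prior_weight)

  # delta-method SE of the log2 fold-change under NB(m, disp)
  vlog <- function(m, n) ((m + disp * m^2) / n) / ((m + pseudo)^2 * log(2)^2)
  se <- sqrt(vlog(m1, n1) + vlog(m2, n2))
  se[se == 0] <- NA_real_

  al <- abs(lfc)
  p <- stats::pnorm(-(al - lfc_threshold) / se) +
       stats::pnorm(-(al + lfc_threshold) / se)
  p <- pmin(p, 1)
  p[is.na(se)] <- 1   # no variability and no counts: nothing to call

  tibble::tibble(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = unname(mu), mean_1 = unname(m1), mean_2 = unname(m2),
    log2fc = unname(lfc), se = unname(se), dispersion = unname(disp),
    p = unname(p), fdr = unname(stats::p.adjust(p, method = "BH"))
  )
}

#' Call de novo escape genes from the bulk time course
#'
#' Splits the bulk series into early (< `split_day`) and late
#' (>= `split_day`) samples, restricts to X-linked genes passing the
#' mean-count filter, runs the threshold test (late vs early, tau =
#' `lfc_test`), and calls a gene spermatid-specific when its log2
#' fold-change exceeds `lfc_call` at BH FDR below `fdr`. The remaining
#' filtered X genes are the non-specific set; the two sets partition the
#' filtered X genes.
#'
#' @param bulk a `bulk_series` (needs `samples$day`) or a count matrix
#'   plus `days`.
#' @param days per-sample postnatal day (taken from `bulk$samples$day`
#'   when omitted).
#' @param split_day early/late boundary; the boundary day counts as late.
#' @param lfc_test tau for the threshold test (default 2).
#' @param lfc_call call threshold on the observed fold-change (default 5,
#'   strict >).
#' @param fdr FDR threshold (default 0.1).
#' @param gene_class annotation class tested (default "X").
#' @param min_mean average-count expression filter (default 10).
#' @return `escape_calls`: list with `table` (per-gene tibble including
#'   `call`), `spermatid_specific`, `non_specific`.
#' @export
call_escape_genes <- function(bulk, days = NULL, split_day = 20L,
                              lfc_test = 2, lfc_call = 5, fdr = 0.1,
                              gene_class = "X", min_mean = 10) {
  if (inherits(bulk, "bulk_series")) {
    counts <- bulk$counts
    if (is.null(days)) days <- bulk$samples$day
    cls <- bulk$genes$class[match(rownames(counts), bulk$genes$gene_id)]
  } else {
    counts <- as.matrix(bulk)
    cls <- attr(bulk, "class_vector")
    if (is.null(cls)) stop("supply a bulk_series or a matrix with a class_vector attribute")
  }
  stopifnot(!is.null(days), length(days) == ncol(counts))
  late <- days >= split_day
  if (sum(late) < 2 || sum(!late) < 2) stop("need at least 2 samples per side of the split")
  keep <- cls == gene_class & rowMeans(counts) >= min_mean
  if (!any(keep)) stop("no genes pass the expression filter")
  sub <- counts[keep, , drop = FALSE]
  res <- nb_threshold_test(sub, factor(ifelse(late, "late", "early"),
                                       levels = c("early", "late")),
                           lfc_threshold = lfc_test,
                           size_factors = median_ratio_sf(counts))
  res$call <- ifelse(res$log2fc > lfc_call & res$fdr < fdr,
                     "spermatid_specific", "non_specific")
  structure(list(
    table = res,
    spermatid_specific = res$gene[res$call == "spermatid_specific"],
    non_specific = res$gene[res$call == "non_specific"]
  ), class = "escape_calls")
}

#' @method print escape_calls
#' @export
print.escape_calls <- function(x, ...) {
  cat(sprintf("<escape_calls> %d spermatid-specific, %d non-specific (of %d filtered X genes)\n",
              length(x$spermatid_specific), length(x$non_specific), nrow(x$table)))
  invisible(x)
}

#' Differential cell-type proportion test
#'
#' Per cell type, a quasi-binomial logistic regression of
#' (count, total - count) on the group label; the dispersion is
#' estimated from Pearson residuals, moderated across types by
#' empirical-Bayes shrinkage (limma's `squeezeVar`, mirroring the
#' quasi-likelihood moderation of the original analysis) and floored at
#' 1; the two-sided p-value uses a t reference whose degrees of freedom
#' are the residual df plus the prior df earned by the moderation. BH
#' correction across types; the study controlled the FDR to 10%.
#'
#' @param type_counts types x samples matrix of cell counts.
#' @param totals total cells per sample.
#' @param group two-level factor per sample.
#' @param fdr significance threshold.
#' @param moderate share dispersion information across types (default);
#'   `FALSE` gives the plain per-type estimate with n - 2 df.
#' @return tibble: type, log_odds_change, se, dispersion, df, p, fdr,
#'   significant.
#' @export
test_proportions <- function(type_counts, totals, group, fdr = 0.1,
                             moderate = TRUE) {
  type_counts <- as.matrix(type_counts)
  group <- factor(group)
  stopifnot(nlevels(group) == 2, length(totals) == ncol(type_counts),
            length(group) == ncol(type_counts))
  if (any(totals < apply(type_counts, 2, max))) stop("totals smaller than type counts")
  if (min(table(group)) < 2) stop("need at least 2 samples per group")
  if (any(rowSums(type_counts) == 0)) stop("cell type absent from all samples")
  nsamp <- ncol(type_counts)
  ntype <- nrow(type_counts)
  fits <- lapply(seq_len(ntype), function(i) {
    y <- type_counts[i, ]
    suppressWarnings(stats::glm(cbind(y, totals - y) ~ group,
                                family = stats::binomial()))
  })
  phi_raw <- vapply(fits, function(f) {
    sum(stats::residuals(f, type = "pearson")^2) / (nsamp - 2)
  }, numeric(1))
  if (moderate && ntype >= 2) {
    sq <- limma::squeezeVar(phi_raw, df = nsamp - 2)
    phi <- pmax(sq$var.post, 1)
    tdf <- (nsamp - 2) + sq$df.prior
  } else {
    phi <- pmax(phi_raw, 1)
    tdf <- nsamp - 2
  }
  est <- vapply(fits, function(f) summary(f)$coefficients[2, 1], numeric(1))
  se0 <- vapply(fits, function(f) summary(f)$coefficients[2, 2], numeric(1))
  se <- se0 * sqrt(phi)
  p <- 2 * stats::pt(-abs(est / se), df = tdf)
  res <- tibble::tibble(
    type = rownames(type_counts) %||% as.character(seq_len(ntype)),
    log_odds_change = est, se = se, dispersion = phi,
    df = if (length(tdf) == 1) rep(tdf, ntype) else tdf,
    p = p,
    fdr = stats::p.adjust(p, method = "BH")
  )
  res$significant <- res$fdr < fdr
  res
}

#' @export
tidy.escape_calls <- function(x, ...) x$table

#' @export
glance.escape_calls <- function(x, ...) {
  tibble::tibble(n_spermatid_specific = length(x$spermatid_specific),
                 n_non_specific = length(x$non_specific),
                 n_tested = nrow(x$table))
}
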