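#' Per-barcode quality control
#'
#' Retains barcodes that express at least `min_genes` genes and have a
#' mitochondrial fraction of at most `max_mito` (the rule is "more than
#' 10% excluded", so exactly 10% is kept).
#'
#' @param x a [sperm_counts]; mitochondrial genes are those with gene
#'   `class == "MT"` in the annotation.
#' @param min_genes minimum genes detected (>0 counts). 1000 in default
#'   mode; 500 after droplet recovery.
#' @param max_mito maximum mitochondrial fraction.
#' @return list with `counts` (filtered [sperm_counts]) and `report`
#'   (tibble: barcode, total, genes_detected, mito_frac, keep, fail_rule).
#' @export
qc_filter <- function(x, min_genes = 1000L, max_mito = 0.10) {
  stopifnot(inherits(x, "sperm_counts"))
  if (min_genes > nrow(x$counts)) stop("min_genes exceeds number of genes")
  m <- x$counts
  total <- Matrix::colSums(m)
  detected <- Matrix::colSums(m > 0)
  mt <- x$genes$class == "MT"
  mito <- if (any(mt)) Matrix::colSums(m[mt, , drop = FALSE]) / pmax(total, 1) else rep(0, ncol(m))
  pass_genes <- detected >= min_genes
  pass_mito <- mito <= max_mito
  keep <- pass_genes & pass_mito
  report <- tibble::tibble(
    barcode = colnames(m),
    total = as.numeric(total),
    genes_detected = as.integer(detected),
    mito_frac = as.numeric(mito),
    pass_genes = unname(pass_genes),
    pass_mito = unname(pass_mito),
    keep = unname(keep),
    fail_rule = dplyr::case_when(
      keep ~ NA_character_,
      !pass_genes & !pass_mito ~ "min_genes;max_mito",
      !pass_genes ~ "min_genes",
      TRUE ~ "max_mito"
    )
  )
  list(counts = x[, which(keep)], report = report)
}

#' Estimate the ambient RNA profile from low-count barcodes
#'
#' The ambient pool is every barcode whose total UMI count is at most
#' `total_max`; the profile is the pooled gene counts plus a pseudo-count,
#' renormalised. The pseudo-count keeps every gene's ambient proportion
#' positive, so observed genes never have likelihood zero under the null.
#'
#' @param x a [sperm_counts] of unfiltered barcodes.
#' @param total_max pool threshold T (default 100).
#' @param alpha pseudo-count (default 0.1).
#' @param min_pool minimum number of pooled barcodes required (default
#'   100; lower it only for toy inputs).
#' @return numeric vector of ambient proportions (sums to 1) with
#'   attributes `total_max`, `alpha`, `n_pool`.
#' @export
estimate_ambient <- function(x, total_max = 100L, alpha = 0.1,
                             min_pool = 100L) {
  stopifnot(inherits(x, "sperm_counts"))
  total <- Matrix::colSums(x$counts)
  pool <- which(total <= total_max)
  if (length(pool) < min_pool) {
    stop("too few low-count barcodes in the ambient pool (", length(pool),
         "); increase total_max")
  }
  g <- Matrix::rowSums(x$counts[, pool, drop = FALSE]) + alpha
  p <- as.numeric(g / sum(g))
  names(p) <- rownames(x$counts)
  attr(p, "total_max") <- total_max
  attr(p, "alpha") <- alpha
  attr(p, "n_pool") <- length(pool)
  p
}

#' Monte-Carlo empty-droplet test against the ambient profile
#'
#' For each barcode with a total above the ambient-pool threshold, the
#' multinomial log-likelihood of its counts under the ambient profile is
#' compared with `n_mc` simulated draws of the same total; the empirical
#' p-value uses the (r+1)/(n_mc+1) estimator, and Benjamini-Hochberg
#' correction across tested barcodes controls the FDR (1% by default).
#' Barcodes above the knee of the log-rank/log-total curve are always
#' retained. Barcodes at or below the pool threshold (including zero
#' totals) are called empty without testing.
#'
#' @param x a [sperm_counts] of unfiltered barcodes.
#' @param ambient ambient profile from [estimate_ambient()].
#' @param n_mc Monte-Carlo iterations (>= 1000).
#' @param fdr FDR threshold for the cell call.
#' @param retain_above_knee always keep barcodes above the knee.
#' @param seed seed for the Monte-Carlo draws.
#' @return tibble: barcode, total, log_lik, p_value, q_value, knee_retained,
#'   call in {"cell", "empty", "retained-by-knee"}.
#' @export
test_droplets <- function(x, ambient, n_mc = 2000L, fdr = 0.01,
                          retain_above_knee = TRUE, seed = 1L) {
  stopifnot(inherits(x, "sperm_counts"), n_mc >= 1000)
  m <- x$counts
  p <- as.numeric(ambient)
  stopifnot(length(p) == nrow(m), all(p > 0))
  total <- as.numeric(Matrix::colSums(m))
  t_max <- attr(ambient, "total_max")
  if (is.null(t_max)) t_max <- 0
  tested <- which(total > t_max)

  # observed multinomial log-likelihood per barcode (sparse-aware)
  lp <- log(p)
  obs_ll <- rep(NA_real_, ncol(m))
  if (length(tested)) {
    sub <- m[, tested, drop = FALSE]
    idx <- Matrix::summary(sub)
    ll_data <- tapply(idx$x * lp[idx$i] - lgamma(idx$x + 1), idx$j, sum)
    ll <- numeric(length(tested))
    ll[as.integer(names(ll_data))] <- ll_data
    obs_ll[tested] <- lgamma(total[tested] + 1) + ll
  }

  # Monte Carlo: incremental likelihood paths shared across totals
  pval <- rep(NA_real_, ncol(m))
  if (length(tested)) {
    tot_u <- sort(unique(total[tested]))
    t_big <- max(tot_u)
    sim_ll <- withr::with_seed(seed, {
      vapply(seq_len(n_mc), function(r) {
        draws <- sample.int(length(p), t_big, replace = TRUE, prob = p)
        occ <- data.table::rowid(draws)
        cum <- cumsum(lp[draws] - log(occ))
        cum[tot_u] + lgamma(tot_u + 1)
      }, numeric(length(tot_u)))
    })  # totals x n_mc
    for (j in seq_along(tot_u)) {
      here <- tested[total[tested] == tot_u[j]]
      sims <- sort(sim_ll[j, ])
      # deviation from ambient shows as LOW likelihood:
      # r = #{L_sim <= L_obs}, p = (r + 1) / (n_mc + 1)
      r <- findInterval(obs_ll[here], sims)
      pval[here] <- (r + 1) / (n_mc + 1)
    }
  }

  qval <- rep(NA_real_, ncol(m))
  qval[tested] <- stats::p.adjust(pval[tested], method = "BH")

  knee_keep <- rep(FALSE, ncol(m))
  if (retain_above_knee) {
    knee_total <- knee_point(total)
    knee_keep <- total > knee_total
  }

  call <- rep("empty", ncol(m))
  call[tested][qval[tested] <= fdr] <- "cell"
  call[knee_keep & call != "cell"] <- "retained-by-knee"

  tibble::tibble(
    barcode = colnames(m),
    total = total,
    log_lik = obs_ll,
    p_value = pval,
    q_value = qval,
    knee_retained = knee_keep,
    call = call
  )
}

# knee of the log-rank / log-total barcode curve: the point of minimum
# first derivative of a smoothing spline through the unique-total curve
# (rank = number of barcodes at or above the total); the search stays in
# the interior of the rank range so boundary wiggles cannot win
knee_point <- function(total) {
  tt <- sort(total[total > 0], decreasing = TRUE)
  if (length(tt) < 10) return(Inf)
  ut <- sort(unique(tt), decreasing = TRUE)
  rk <- findInterval(-ut, sort(-tt))          # barcodes with total >= ut
  lr <- log10(rk)
  lt <- log10(ut)
  if (length(ut) < 5) return(Inf)
  fit <- stats::smooth.spline(lr, lt, df = min(20, length(ut) - 1))
  grid <- seq(stats::quantile(lr, 0.01), stats::quantile(lr, 0.95),
              length.out = 500)
  d1 <- stats::predict(fit, grid, deriv = 1)$y
  10^stats::predict(fit, grid[which.min(d1)])$y
}

#' Pooled median-ratio size factors
#'
#' Cells are pre-clustered (a quick k-means on PCA of library-normalised
#' log counts, clusters capped at `max_cluster_size`), factors are
#' computed within each cluster as the median ratio of the cell to the
#' cluster pseudo-reference over genes detected in at least half the
#' cluster, clusters are rescaled to a common reference via their
#' pseudo-bulk median ratios, and the final factors are scaled to mean 1.
#'
#' @param x a [sperm_counts] or genes x cells matrix.
#' @param clusters optional precomputed cluster labels covering all cells.
#' @param max_cluster_size cap on pre-cluster size (default 2000).
#' @return numeric vector of positive size factors (mean 1), with the
#'   cluster labels as attribute `clusters`.
#' @export
size_factors <- function(x, clusters = NULL, max_cluster_size = 2000L) {
  m <- if (inherits(x, "sperm_counts")) x$counts else x
  n <- ncol(m)
  if (is.null(clusters)) clusters <- quick_cluster(m, max_cluster_size)
  stopifnot(length(clusters) == n)

  sf <- numeric(n)
  cl_scale <- numeric(length(unique(clusters)))
  names(cl_scale) <- unique(clusters)
  global_ref <- Matrix::rowMeans(m)
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    sub <- as.matrix(m[, idx, drop = FALSE])
    ref <- rowMeans(sub)
    use <- which(ref > 0 & rowMeans(sub > 0) >= 0.5)
    if (length(use) == 0) stop("cluster ", cl, " has no genes shared with its reference")
    for (k in seq_along(idx)) {
      ratios <- sub[use, k] / ref[use]
      f <- stats::median(ratios)
      # very shallow cells can be zero at over half the reference genes;
      # fall back to the mean ratio (equal under no-DE, never zero for a
      # cell with any counts on the reference genes)
      if (is.finite(f) && f == 0) f <- mean(ratios)
      if (!is.finite(f) || f <= 0) stop("non-positive size factor for cell ", colnames(m)[idx[k]])
      sf[idx[k]] <- f
    }
    # cross-cluster scaling via the pseudo-bulk (average cell) median ratio
    both <- which(ref > 0 & global_ref > 0 & rowMeans(sub > 0) >= 0.5)
    if (length(both) == 0) both <- which(ref > 0 & global_ref > 0)
    cl_scale[as.character(cl)] <- stats::median(ref[both] / global_ref[both])
  }
  sf <- sf * cl_scale[as.character(clusters)]
  sf <- sf / mean(sf)
  if (any(sf <= 0)) stop("non-positive size factor")
  names(sf) <- colnames(m)
  attr(sf, "clusters") <- clusters
  sf
}

# fast deterministic pre-clustering for size factor pooling
quick_cluster <- function(m, max_cluster_size = 2000L) {
  n <- ncol(m)
  k0 <- max(1L, ceiling(n / max_cluster_size))
  if (n < 50 || (k0 == 1L && n <= max_cluster_size)) {
    if (n <= max_cluster_size) return(rep(1L, n))
  }
  lib <- pmax(Matrix::colSums(m), 1)
  lm <- log1p(t(t(as.matrix(m)) / as.numeric(lib)) * mean(lib))
  v <- matrixStats_rowVars(lm)
  top <- order(v, decreasing = TRUE)[seq_len(min(500, nrow(lm)))]
  pc <- stats::prcomp(t(lm[top, , drop = FALSE]), rank. = min(10, length(top), n - 1))$x
  k <- max(k0, min(4L, floor(n / 100)))
  if (k <= 1) return(rep(1L, n))
  km <- withr::with_seed(42L, stats::kmeans(pc, centers = k, nstart = 5, iter.max = 50))
  cl <- km$cluster
  # split any oversized cluster by library size order
  repeat {
    sizes <- table(cl)
    big <- names(sizes)[sizes > max_cluster_size]
    if (!length(big)) break
    b <- big[1]
    idx <- which(cl == as.integer(b))
    half <- idx[order(lib[idx])][seq_len(ceiling(length(idx) / 2))]
    cl[half] <- max(cl) + 1L
  }
  cl
}

matrixStats_rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Log-normalise counts
#'
#' Returns `log2(count / size_factor + 1)`; zeros map to zero, so the
#' result stays sparse.
#'
#' @param x a [sperm_counts] or genes x cells matrix.
#' @param sf positive size factors, one per cell.
#' @return sparse genes x cells matrix of log2 normalised counts.
#' @export
lognormalise <- function(x, sf) {
  m <- if (inherits(x, "sperm_counts")) x$counts else x
  stopifnot(length(sf) == ncol(m), all(sf > 0))
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  idx <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log2(m@x / sf[idx] + 1)
  m
}

#' Highly variable gene selection by variance decomposition
#'
#' Fits a smooth mean-variance trend (loess; quadratic fallback below 200
#' genes) to the per-gene total variance of log-normalised counts and
#' takes the technical component to be the trend value at the gene's
#' mean. The biological variance is total minus trend; the top `n` genes
#' by biological variance are selected, ties broken by higher mean.
#'
#' @param logm genes x cells matrix of log-normalised counts.
#' @param n number of genes to select (default 1000).
#' @param span loess span.
#' @return tibble: gene_id, mean, total_var, trend_var, bio_var, rank,
#'   selected.
#' @export
select_hvg <- function(logm, n = 1000L, span = 0.3) {
  if (n > nrow(logm)) stop("n exceeds the number of genes")
  if (ncol(logm) < 2) stop("need at least 2 cells")
  mu <- as.numeric(Matrix::rowMeans(logm))
  v <- as.numeric(Matrix::rowMeans(logm^2)) - mu^2
  v <- v * ncol(logm) / (ncol(logm) - 1)
  fitted <- rep(0, length(mu))
  use <- v > 0
  if (sum(use) >= 200) {
    lf <- stats::loess(v[use] ~ mu[use], span = span, degree = 2,
                       family = "symmetric")
    fitted[use] <- pmax(stats::predict(lf, mu[use]), 0)
  } else if (sum(use) >= 3) {
    lf <- stats::lm(v[use] ~ stats::poly(mu[use], min(2, sum(use) - 1)))
    fitted[use] <- pmax(stats::fitted(lf), 0)
  }
  bio <- v - fitted
  ord <- order(-bio, -mu)
  rank <- integer(length(mu))
  rank[ord] <- seq_along(ord)
  tibble::tibble(
    gene_id = rownames(logm) %||% sprintf("g%04d", seq_along(mu)),
    mean = mu, total_var = v, trend_var = fitted, bio_var = bio,
    rank = rank, selected = rank <= n
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
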