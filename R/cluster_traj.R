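#' Principal component embedding
#'
#' Centred PCA of cells over a chosen gene set (typically the highly
#' variable genes), with a deterministic sign convention: each
#' component's largest-magnitude gene loading is made positive.
#'
#' @param logm genes x cells matrix of log-normalised counts (already
#'   restricted to the genes to use).
#' @param d number of components.
#' @return `sperm_pca`: list with `scores` (cells x d), `var` (component
#'   variances, non-increasing), `rotation` (gene loadings).
#' @export
pca_embed <- function(logm, d = 50L) {
  X <- t(as.matrix(logm))
  d <- min(d, nrow(X) - 1L, ncol(X))
  if (all(apply(X, 2, stats::var) == 0)) stop("constant matrix")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(scores = pc$x, var = pc$sdev[seq_len(d)]^2,
                 rotation = pc$rotation), class = "sperm_pca")
}

#' @method print sperm_pca
#' @export
print.sperm_pca <- function(x, ...) {
  cat(sprintf("<sperm_pca> %d cells x %d components; PC1 %.1f%% variance\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$var[1] / sum(x$var)))
  invisible(x)
}

# exact kNN by blocks of the squared-distance matrix; returns n x k index
# matrix ordered by increasing distance
knn_index <- function(X, k) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  block <- max(1L, floor(2e7 / n))
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1L, n)
    D <- outer(sq[s:e], sq, "+") - 2 * X[s:e, , drop = FALSE] %*% t(X)
    for (i in seq_len(e - s + 1L)) {
      d <- D[i, ]
      d[s + i - 1L] <- Inf
      out[s + i - 1L, ] <- order(d)[seq_len(k)]
    }
  }
  out
}

#' Shared nearest-neighbour graph clustering
#'
#' Builds a k-nearest-neighbour graph on the first `d_use` principal
#' components, weights each edge by shared-neighbour ranks (an edge
#' between i and j gets weight `k - r/2`, where r is the smallest rank
#' sum of any neighbour the two cells share, the cells themselves
#' counting at rank 0), and partitions the graph by multi-level
#' modularity optimisation (Louvain). Cluster labels are relabelled to
#' descending size.
#'
#' @param embedding a `sperm_pca` (or bare score matrix).
#' @param k shared nearest neighbours (the study uses 5, 10 or 15).
#' @param d_use number of leading components (default 50).
#' @param seed seed for the community search.
#' @return integer vector of cluster labels (1 = largest cluster), with
#'   the igraph graph as attribute `graph`.
#' @export
cluster_snn <- function(embedding, k = 5L, d_use = 50L, seed = 1L) {
  X <- if (inherits(embedding, "sperm_pca")) embedding$scores else as.matrix(embedding)
  if (k <= 0) stop("k must be positive")
  if (k >= nrow(X)) stop("k must be smaller than the number of cells")
  X <- X[, seq_len(min(d_use, ncol(X))), drop = FALSE]
  n <- nrow(X)
  nn <- knn_index(X, k)

  # two cells are connected when they share at least one neighbour (each
  # cell counting itself at rank 0); the edge weight is k - r/2 with r the
  # smallest rank sum over shared neighbours
  ii <- c(seq_len(n), rep(seq_len(n), k))         # cell owning the entry
  vv <- c(seq_len(n), as.vector(nn))              # the neighbour itself
  rr <- c(rep(0L, n), rep(seq_len(k), each = n))  # rank of vv in ii's list
  ord_v <- order(vv)
  ii <- ii[ord_v]; rr <- rr[ord_v]; vv <- vv[ord_v]
  bounds <- c(0L, cumsum(tabulate(vv, n)))
  pairs <- vector("list", n)
  for (v in seq_len(n)) {
    span_idx <- (bounds[v] + 1L):bounds[v + 1L]
    members <- ii[span_idx]
    ranks <- rr[span_idx]
    if (length(members) < 2) next
    cmb <- utils::combn(seq_along(members), 2)
    pairs[[v]] <- cbind(members[cmb[1, ]], members[cmb[2, ]],
                        k - (ranks[cmb[1, ]] + ranks[cmb[2, ]]) / 2)
  }
  em <- do.call(rbind, pairs)
  em <- em[em[, 3] > 0, , drop = FALSE]
  # undirected: one copy per pair, at the maximum weight
  lo <- pmin(em[, 1], em[, 2]); hi <- pmax(em[, 1], em[, 2])
  key <- lo * (n + 1) + hi
  ord_w <- order(key, -em[, 3])
  em <- cbind(lo, hi, em[, 3])[ord_w, , drop = FALSE]
  em <- em[!duplicated(key[ord_w]), , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(em[, 1], em[, 2]), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = em[, 3])
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comm <- withr::with_seed(seed, igraph::cluster_louvain(g))
  lab <- igraph::membership(comm)
  sizes <- sort(table(lab), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relab[as.character(lab)])
  attr(out, "graph") <- g
  out
}

#' Principal-curve pseudotime ordering
#'
#' Hastie-Stuetzle iteration on the leading principal components:
#' initialise with the first component, then alternately (i) smooth each
#' coordinate against the current ordering with a fixed-span running-mean
#' smoother and (ii) project cells onto the smoothed curve and re-order
#' by arc length, until the mean squared projection distance changes by
#' less than `tol` or `max_iter` is reached. Pseudotime is the arc-length
#' position along the curve. If `early` marks a set of cells known to be
#' developmentally early, the curve is oriented so those cells have the
#' lower mean pseudotime.
#'
#' @param embedding `sperm_pca` or score matrix.
#' @param d_use components to use (the study uses 3 or 10).
#' @param span smoother span as a fraction of cells.
#' @param tol convergence tolerance on the mean squared projection
#'   distance.
#' @param max_iter iteration cap.
#' @param early optional logical/index vector of early cells for
#'   orientation.
#' @param init `"mst"` (default) initialises the ordering by distances
#'   along the minimum spanning tree of k-means cluster centres (from
#'   one end of the tree diameter), which unfolds strongly curved
#'   trajectories that a plain first-component initialisation leaves
#'   folded; `"pc1"` uses the first component.
#' @return `principal_curve_fit`: list with `pseudotime` (arc-length
#'   position per cell), `curve` (ordered curve points), `length`,
#'   `reversed`, `mse`, `iterations`, `converged`.
#' @export
fit_principal_curve <- function(embedding, d_use = 3L, span = 0.1,
                                tol = 1e-4, max_iter = 50L, early = NULL,
                                init = c("mst", "pc1")) {
  init <- match.arg(init)
  X <- if (inherits(embedding, "sperm_pca")) embedding$scores else as.matrix(embedding)
  X <- X[, seq_len(min(d_use, ncol(X))), drop = FALSE]
  n <- nrow(X)
  if (n < 10) stop("need at least 10 cells")
  w <- max(3L, floor(span * n))
  if (w >= n) stop("smoother span too wide for the number of cells")

  lambda <- X[, 1]
  if (init == "mst") {
    gl <- mst_order(X)
    if (!is.null(gl)) lambda <- gl
  }
  mse_old <- Inf
  iter <- 0L
  converged <- FALSE
  curve <- NULL
  ord <- order(lambda)
  repeat {
    iter <- iter + 1L
    ord <- order(lambda)
    curve <- apply(X[ord, , drop = FALSE], 2, running_mean, w = w)
    # arc length along the smoothed curve
    seglen <- sqrt(rowSums((curve[-1, , drop = FALSE] - curve[-n, , drop = FALSE])^2))
    arclen <- c(0, cumsum(seglen))
    # project every cell onto the polyline (nearest vertex, refined on the
    # two adjacent segments), exact for cells lying on the curve
    pr <- project_to_polyline(X, curve, arclen)
    mse <- pr$mse
    lambda <- pr$lambda
    if (abs(mse_old - mse) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    mse_old <- mse
  }
  total <- max(lambda)
  reversed <- FALSE
  if (!is.null(early) && mean(lambda[early]) > mean(lambda)) {
    lambda <- total - lambda
    curve <- curve[rev(seq_len(nrow(curve))), , drop = FALSE]
    reversed <- TRUE
  }
  names(lambda) <- rownames(X)
  structure(list(pseudotime = lambda, curve = curve, length = total,
                 reversed = reversed, mse = mse, iterations = iter,
                 converged = converged), class = "principal_curve_fit")
}

# initial 1D ordering along the minimum spanning tree of k-means cluster
# centres, measured from one end of the tree diameter (deterministic seed);
# within a cluster, cells are offset along the local direction of travel so
# the fine ordering is resolved from the start
mst_order <- function(X, n_centers = 15L) {
  n <- nrow(X)
  k <- min(n_centers, max(2L, floor(n / 20)))
  if (k < 2) return(NULL)
  km <- withr::with_seed(7L, suppressWarnings(
    stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)))
  D <- as.matrix(stats::dist(km$centers))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
  tree <- igraph::mst(g)
  tip <- igraph::get_diameter(tree)[1]
  pos <- as.numeric(igraph::distances(tree, v = tip)[1, ])
  ordc <- order(pos)
  rankc <- match(seq_len(k), ordc)
  lambda <- pos[km$cluster]
  for (c in seq_len(k)) {
    idx <- which(km$cluster == c)
    prev <- if (rankc[c] > 1) ordc[rankc[c] - 1L] else c
    nxt <- if (rankc[c] < k) ordc[rankc[c] + 1L] else c
    u <- km$centers[nxt, ] - km$centers[prev, ]
    nu <- sqrt(sum(u^2))
    if (nu == 0) next
    u <- u / nu
    off <- as.numeric((X[idx, , drop = FALSE] -
                         matrix(km$centers[c, ], length(idx), ncol(X),
                                byrow = TRUE)) %*% u)
    lambda[idx] <- lambda[idx] + off
  }
  lambda
}

# orthogonal projection of points onto the piecewise-linear curve: find the
# nearest curve vertex, then refine on its two adjacent segments
project_to_polyline <- function(X, curve, arclen) {
  n <- nrow(X)
  m <- nrow(curve)
  d2 <- outer(rowSums(X^2), rowSums(curve^2), "+") - 2 * X %*% t(curve)
  nearest <- max.col(-d2, ties.method = "first")
  best <- pmax(d2[cbind(seq_len(n), nearest)], 0)
  lambda <- arclen[nearest]
  for (off in c(-1L, 0L)) {
    j <- nearest + off                     # segment j -> j + 1
    ok <- which(j >= 1L & j < m)
    if (!length(ok)) next
    a <- curve[j[ok], , drop = FALSE]
    ab <- curve[j[ok] + 1L, , drop = FALSE] - a
    len2 <- rowSums(ab^2)
    tt <- rowSums((X[ok, , drop = FALSE] - a) * ab) / pmax(len2, 1e-300)
    # terminal segments extend linearly beyond the curve ends, so cells
    # past the smoothed range keep an exact perpendicular projection
    lo <- ifelse(j[ok] == 1L, -Inf, 0)
    hi <- ifelse(j[ok] == m - 1L, Inf, 1)
    tt <- pmin(pmax(tt, lo), hi)
    dd <- rowSums((X[ok, , drop = FALSE] - (a + ab * tt))^2)
    upd <- dd < best[ok]
    best[ok[upd]] <- dd[upd]
    lambda[ok[upd]] <- (arclen[j[ok]] + tt * sqrt(len2))[upd]
  }
  lambda <- lambda - min(lambda)
  list(lambda = lambda, mse = mean(best))
}

# centred running mean with window w (edges use the available cells)
running_mean <- function(y, w) {
  n <- length(y)
  h <- floor(w / 2)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @method print principal_curve_fit
#' @export
print.principal_curve_fit <- function(x, ...) {
  cat(sprintf("<principal_curve_fit> %d cells, curve length %.3f, %d iterations (%s)\n",
              length(x$pseudotime), x$length, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Number of genes expressed per cell
#'
#' The transcriptional-complexity statistic: genes with a count above
#' zero, per barcode.
#'
#' @param x a [sperm_counts] or genes x cells matrix.
#' @return tibble with `barcode` and `n_genes`.
#' @export
genes_expressed <- function(x) {
  m <- if (inherits(x, "sperm_counts")) x$counts else x
  tibble::tibble(
    barcode = colnames(m) %||% as.character(seq_len(ncol(m))),
    n_genes = as.integer(Matrix::colSums(m > 0))
  )
}

#' Cluster marker detection with batch blocking
#'
#' For every gene and every target cluster, a Welch t-test is run against
#' each other cluster within each block (batch); per-block effects
#' (log2 fold-changes of mean log expression) are combined by cell-count
#' weighting and per-block p-values by Stouffer's method; per-pair
#' p-values are then combined across the other clusters with Simes'
#' method, and the minimum per-pair rank is recorded. A gene is a marker
#' for its cluster when its effect is positive against every other
#' cluster and its BH-adjusted Simes p is below `fdr`.
#'
#' @param logm genes x cells log-normalised matrix.
#' @param clusters cluster labels per cell.
#' @param blocks optional blocking labels (e.g. sample/batch) per cell.
#' @param fdr marker FDR threshold (default 0.1).
#' @return tibble: gene, cluster, summary_lfc (minimum effect over
#'   pairs), log_p and p (Simes-combined), fdr (BH within cluster), min_rank,
#'   marker.
#' @export
find_markers <- function(logm, clusters, blocks = NULL, fdr = 0.1) {
  m <- as.matrix(logm)
  n <- ncol(m)
  stopifnot(length(clusters) == n)
  if (is.null(blocks)) blocks <- rep("all", n)
  cl_levels <- sort(unique(clusters))
  bl_levels <- unique(blocks)
  genes <- rownames(m) %||% sprintf("g%04d", seq_len(nrow(m)))

  # per (cluster, block) moments
  stats_for <- function(idx) {
    sub <- m[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    s2 <- if (length(idx) > 1) rowSums((sub - mu)^2) / (length(idx) - 1) else rep(NA_real_, nrow(m))
    list(mu = mu, s2 = s2, n = length(idx))
  }
  grp <- list()
  for (cl in cl_levels) for (b in bl_levels) {
    idx <- which(clusters == cl & blocks == b)
    if (length(idx) >= 2) grp[[paste(cl, b)]] <- stats_for(idx)
  }

  out <- purrr::map_dfr(cl_levels, function(A) {
    others <- setdiff(cl_levels, A)
    # log-scale p-values throughout: marker effects can be so strong that
    # double-precision p underflows, and the top-N shortlist needs the
    # ordering to survive that
    pair_lp <- matrix(NA_real_, nrow(m), length(others))
    pair_lfc <- matrix(NA_real_, nrow(m), length(others))
    for (oi in seq_along(others)) {
      B <- others[oi]
      zs <- list(); ws <- c(); lfcs <- list(); lws <- c()
      for (b in bl_levels) {
        ga <- grp[[paste(A, b)]]; gb <- grp[[paste(B, b)]]
        if (is.null(ga) || is.null(gb)) next
        se2 <- ga$s2 / ga$n + gb$s2 / gb$n
        tt <- (ga$mu - gb$mu) / sqrt(pmax(se2, 1e-300))
        tt[se2 == 0] <- sign(ga$mu - gb$mu)[se2 == 0] * 1e6
        df <- pmax(se2^2 / (ga$s2^2 / (ga$n^2 * (ga$n - 1)) +
                            gb$s2^2 / (gb$n^2 * (gb$n - 1))), 1)
        df[!is.finite(df)] <- 1
        lp1 <- stats::pt(-abs(tt), df, log.p = TRUE)   # one-sided, log scale
        z <- -sign(tt) * stats::qnorm(lp1, log.p = TRUE)
        zs[[b]] <- z
        ws <- c(ws, sqrt(ga$n + gb$n))
        lfcs[[b]] <- ga$mu - gb$mu
        lws <- c(lws, ga$n + gb$n)
      }
      if (!length(zs)) next
      Z <- do.call(cbind, zs)
      zc <- as.numeric(Z %*% ws) / sqrt(sum(ws^2))
      pair_lp[, oi] <- log(2) + stats::pnorm(-abs(zc), log.p = TRUE)
      L <- do.call(cbind, lfcs)
      pair_lfc[, oi] <- as.numeric(L %*% lws) / sum(lws)
    }
    # ranks within each pairwise comparison (marker shortlist machinery)
    pr <- apply(pair_lp, 2, function(p) rank(p, ties.method = "min", na.last = "keep"))
    min_rank <- suppressWarnings(apply(pr, 1, min, na.rm = TRUE))
    min_rank[!is.finite(min_rank)] <- NA_integer_
    simes_lp <- apply(pair_lp, 1, function(lp) {
      lp <- lp[!is.na(lp)]
      if (!length(lp)) return(NA_real_)
      min(log(length(lp)) + sort(lp) - log(seq_along(lp)))
    })
    simes_lp <- pmin(simes_lp, 0)
    tibble::tibble(
      gene = genes, cluster = A,
      summary_lfc = suppressWarnings(apply(pair_lfc, 1, min, na.rm = TRUE)),
      log_p = simes_lp,
      p = exp(simes_lp),
      fdr = stats::p.adjust(exp(simes_lp), method = "BH"),
      min_rank = as.integer(min_rank)
    )
  })
  out$summary_lfc[!is.finite(out$summary_lfc)] <- NA_real_
  out$marker <- !is.na(out$fdr) & out$fdr < fdr &
    !is.na(out$summary_lfc) & out$summary_lfc > 0
  out
}

#' Top marker shortlist per cluster
#'
#' @param markers output of [find_markers()].
#' @param n list size (the staging panel uses 50).
#' @param positive_only keep only genes with positive summary effect.
#' @return tibble of at most `n` genes per cluster ordered by `min_rank`
#'   (ties broken by lower combined p).
#' @export
top_markers <- function(markers, n = 50L, positive_only = TRUE) {
  x <- markers
  if (positive_only) x <- dplyr::filter(x, !is.na(.data$summary_lfc), .data$summary_lfc > 0)
  x |>
    dplyr::arrange(.data$cluster, .data$min_rank, .data$log_p) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup()
}
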