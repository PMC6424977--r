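#' Gene-wise Z scores
#'
#' Standardises each gene (row) across the columns:
#' `z_ij = (x_ij - mu_i) / sigma_i` with the sample standard deviation.
#' Constant rows (sigma = 0) are dropped with a warning and listed in the
#' `dropped` attribute.
#'
#' @param m genes x samples (or genes x cells) numeric matrix.
#' @return matrix of the same orientation; attributes `mu`, `sigma`,
#'   `dropped`.
#' @export
zscore <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("Z score undefined for a single sample")
  mu <- rowMeans(m)
  sigma <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  drop <- sigma == 0
  if (any(drop)) {
    warning(sum(drop), " constant rows dropped from Z scoring")
  }
  z <- (m[!drop, , drop = FALSE] - mu[!drop]) / sigma[!drop]
  attr(z, "mu") <- mu[!drop]
  attr(z, "sigma") <- sigma[!drop]
  attr(z, "dropped") <- rownames(m)[drop]
  z
}

#' Train the bulk staging classifier on single cells
#'
#' Cells are split (seeded) into a training set of `n_train` and a
#' held-out test set (the study used 2000 training / 1215 test cells);
#' the panel is the top marker genes per cluster; expression is Z-scored
#' per gene across the standardisation population; a probabilistic
#' multiclass classifier is fitted. The classifier is an interchangeable
#' component behind the class-probability contract; the default is a
#' diagonal-covariance Gaussian classifier (diagonal LDA, the nearest
#' shrunken centroid family), which is deterministic and well behaved
#' when the panel is larger than the training set.
#'
#' @param logm genes x cells log-normalised matrix.
#' @param labels cluster label per cell.
#' @param panel character vector of panel genes (e.g. from
#'   [top_markers()]); all must be present in `logm`.
#' @param n_train number of training cells.
#' @param seed seed for the train/test split.
#' @param var_floor lower bound on the pooled per-gene variance of the
#'   Z scores.
#' @return `stage_classifier`: list with `fit` (class means, pooled
#'   variances, priors), `panel`, `mu`, `sigma` (training
#'   standardisation), `classes`, `accuracy` (held-out), `confusion`.
#' @export
train_stage_classifier <- function(logm, labels, panel, n_train = 2000L,
                                   seed = 1L, var_floor = 0.01) {
  missing <- setdiff(panel, rownames(logm))
  if (length(missing)) stop("panel gene absent from matrix: ", missing[1])
  n <- ncol(logm)
  stopifnot(length(labels) == n, n_train < n)
  labels <- as.character(labels)
  z <- zscore(as.matrix(logm[panel, , drop = FALSE]))
  panel <- rownames(z)
  idx <- withr::with_seed(seed, sample(n, n_train))
  if (!all(unique(labels) %in% labels[idx])) {
    stop("cluster absent from training split; increase n_train or reseed")
  }
  ztr <- z[, idx, drop = FALSE]
  ytr <- labels[idx]
  cls <- sort(unique(ytr))
  means <- vapply(cls, function(k) rowMeans(ztr[, ytr == k, drop = FALSE]),
                  numeric(nrow(ztr)))
  ss <- rowSums((ztr - means[, match(ytr, cls)])^2)
  pooled_var <- pmax(ss / max(1, length(idx) - length(cls)), var_floor)
  fit <- list(means = means, var = pooled_var,
              prior = as.numeric(table(factor(ytr, cls))) / length(idx))
  pred <- dlda_posterior(fit, z[, -idx, drop = FALSE])
  hard <- cls[max.col(pred, ties.method = "first")]
  acc <- mean(hard == labels[-idx])
  structure(list(
    fit = fit, panel = panel,
    mu = attr(z, "mu"), sigma = attr(z, "sigma"),
    classes = cls, accuracy = acc,
    confusion = table(truth = labels[-idx], predicted = factor(hard, levels = cls)),
    n_train = n_train, n_test = n - n_train
  ), class = "stage_classifier")
}

# posteriors of the diagonal-covariance Gaussian classifier; z is a
# genes x samples matrix on the classifier's panel
dlda_posterior <- function(fit, z) {
  K <- ncol(fit$means)
  lp <- vapply(seq_len(K), function(k) {
    -0.5 * colSums((z - fit$means[, k])^2 / fit$var) + log(fit$prior[k])
  }, numeric(ncol(z)))
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1)
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp)
  post <- post / rowSums(post)
  colnames(post) <- colnames(fit$means)
  rownames(post) <- colnames(z)
  post
}

#' @method print stage_classifier
#' @export
print.stage_classifier <- function(x, ...) {
  cat(sprintf("<stage_classifier> %d panel genes, %d classes, held-out accuracy %.3f (%d/%d split)\n",
              length(x$panel), length(x$classes), x$accuracy, x$n_train, x$n_test))
  invisible(x)
}

#' Probabilistic staging of bulk samples
#'
#' Bulk counts are normalised to counts-per-million, log2-transformed
#' with a pseudo-count of 1, Z-scored per gene, and pushed through the
#' trained classifier to yield one class-probability vector per sample
#' (rows sum to 1). By default the bulk Z score is computed across the
#' bulk series itself, mirroring the published procedure; set
#' `project = TRUE` to standardise with the training cells' mu and sigma
#' instead.
#'
#' @param classifier a [train_stage_classifier()] fit.
#' @param bulk `bulk_series` or genes x samples count matrix.
#' @param project use training-cell standardisation instead of the bulk
#'   series' own.
#' @return tibble: sample, dominant stage, one probability column per
#'   class; the bare probability matrix is attached as attribute
#'   `"posterior"`.
#' @export
stage_bulk <- function(classifier, bulk, project = FALSE) {
  counts <- if (inherits(bulk, "bulk_series")) bulk$counts else as.matrix(bulk)
  if (ncol(counts) < 2 && !project) stop("Z score undefined for fewer than 2 bulk samples")
  cpm <- t(t(counts) * 1e6 / colSums(counts))
  lg <- log2(cpm + 1)
  lg <- lg[classifier$panel, , drop = FALSE]
  if (project) {
    z <- (lg - classifier$mu) / classifier$sigma
  } else {
    mu <- rowMeans(lg)
    sigma <- sqrt(rowSums((lg - mu)^2) / (ncol(lg) - 1))
    sigma[sigma == 0] <- 1   # constant panel gene carries no information
    z <- (lg - mu) / sigma
  }
  post <- dlda_posterior(classifier$fit, z)
  post <- post / rowSums(post)
  out <- tibble::as_tibble(post)
  out <- dplyr::bind_cols(
    tibble::tibble(sample = colnames(counts),
                   dominant = colnames(post)[max.col(post, ties.method = "first")]),
    out
  )
  attr(out, "posterior") <- post
  out
}

#' @export
tidy.stage_classifier <- function(x, ...) {
  tibble::tibble(
    class = rownames(x$confusion)[row(x$confusion)],
    predicted = colnames(x$confusion)[col(x$confusion)],
    n = as.integer(x$confusion)
  )
}

#' @export
glance.stage_classifier <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_panel = length(x$panel),
                 n_classes = length(x$classes),
                 n_train = x$n_train, n_test = x$n_test)
}

#' @export
tidy.principal_curve_fit <- function(x, ...) {
  tibble::tibble(barcode = names(x$pseudotime) %||% as.character(seq_along(x$pseudotime)),
                 pseudotime = as.numeric(x$pseudotime))
}

#' @export
glance.principal_curve_fit <- function(x, ...) {
  tibble::tibble(length = x$length, mse = x$mse, iterations = x$iterations,
                 converged = x$converged, reversed = x$reversed)
}
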