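#' Cluster composition per sample
#'
#' The fraction of each sample's cells allocated to each cluster; rows
#' sum to 1.
#'
#' @param clusters cluster label per cell.
#' @param samples sample (or time-point) label per cell.
#' @return wide tibble: `sample` plus one fraction column per cluster;
#'   the long form is attached as attribute `"long"`.
#' @export
composition <- function(clusters, samples) {
  stopifnot(length(clusters) == length(samples))
  long <- tibble::tibble(sample = as.character(samples),
                         cluster = as.character(clusters)) |>
    dplyr::count(.data$sample, .data$cluster) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  wide <- long |>
    dplyr::select("sample", "cluster", "fraction") |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "fraction",
                       values_fill = 0)
  attr(wide, "long") <- long
  wide
}

#' Stage-by-gene table for the escape-gene heatmap
#'
#' Normalised expression is averaged per stage prior to scaling, each
#' gene is Z-scaled across stages, and genes are ordered by the stage of
#' their expression peak (ties broken by the gene's correlation with the
#' stage index), reproducing the temporal-activation layout.
#'
#' @param norm genes x cells matrix of normalised counts.
#' @param genes escape gene identifiers (e.g.
#'   `escape_calls$spermatid_specific`), all present in `norm`.
#' @param stages ordered factor (or character vector, taken in order of
#'   first appearance) of per-cell stage labels.
#' @return long tibble: gene (factor in heatmap order), stage (ordered
#'   factor), mean_expr, z; the stage x gene matrix is attached as
#'   attribute `"matrix"`.
#' @export
escape_heatmap_table <- function(norm, genes, stages) {
  if (!length(genes)) stop("escape set is empty")
  missing <- setdiff(genes, rownames(norm))
  if (length(missing)) stop("gene absent from matrix: ", missing[1])
  if (!is.factor(stages)) stages <- factor(stages, levels = unique(stages))
  m <- as.matrix(norm)[genes, , drop = FALSE]
  sm <- vapply(levels(stages), function(s) rowMeans(m[, stages == s, drop = FALSE]),
               numeric(length(genes)))
  if (length(genes) == 1) sm <- matrix(sm, nrow = 1, dimnames = list(genes, levels(stages)))
  mu <- rowMeans(sm)
  sd <- sqrt(rowSums((sm - mu)^2) / (ncol(sm) - 1))
  sd[sd == 0] <- 1
  z <- (sm - mu) / sd
  peak <- max.col(z, ties.method = "first")
  rho <- apply(sm, 1, function(v) stats::cor(v, seq_along(v), method = "spearman"))
  ord <- order(peak, rho)
  zo <- z[ord, , drop = FALSE]
  out <- tibble::tibble(
    gene = factor(rep(rownames(zo), ncol(zo)), levels = rownames(zo)),
    stage = factor(rep(colnames(zo), each = nrow(zo)), levels = levels(stages),
                   ordered = TRUE),
    mean_expr = as.numeric(sm[ord, ]),
    z = as.numeric(zo)
  )
  attr(out, "matrix") <- zo
  out
}
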