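#' Read a BED file of genomic intervals
#'
#' Intervals are kept in the native BED convention: 0-based, half-open
#' `[start, end)`. The same convention is used everywhere inside the
#' package; GTF input is converted at the boundary by
#' [read_gene_annotation()].
#'
#' @param path BED file (3-6 columns, tab separated, no header).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   supplied, intervals on unknown chromosomes or past the end error.
#' @return tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = cols[seq_len(max(utils::count.fields(path, sep = "\t")))],
                         fill = TRUE, stringsAsFactors = FALSE)
  x <- tibble::as_tibble(x)
  if (any(x$start >= x$end)) stop("malformed BED: start >= end")
  if (any(x$start < 0)) stop("malformed BED: negative start")
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_lengths))
    if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
    if (any(x$end > chrom_lengths[x$chrom])) stop("interval past chromosome end")
  }
  x
}

#' Write intervals as 6-column BED
#'
#' @param x tibble with at least `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotation from GTF or TSV
#'
#' GTF coordinates (1-based, closed) are converted to the internal 0-based
#' half-open convention. A TSV is expected to already use 0-based half-open
#' coordinates and carry a header with at least
#' `gene_id, chrom, start, end, strand`.
#'
#' @param path annotation file; format guessed from extension
#'   (`.gtf`/`.gff` vs anything else) unless `format` is given.
#' @param format `"gtf"` or `"tsv"`.
#' @param chrom_lengths optional named vector used to validate coordinates.
#' @return tibble with `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `class`.
#' @export
read_gene_annotation <- function(path, format = NULL, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.g[tf]f[0-9]?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "gtf") {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    bad <- vapply(f, length, 0L) < 9L
    if (any(bad)) stop("malformed GTF line")
    f <- f[vapply(f, function(v) v[3] == "gene", TRUE)]
    attr_field <- function(a, key) {
      out <- rep(NA_character_, length(a))
      hit <- regexpr(paste0(key, ' "[^"]*"'), a) > 0
      out[hit] <- sub(paste0('.*', key, ' "([^"]*)".*'), "\\1", a[hit])
      out
    }
    a9 <- vapply(f, `[`, "", 9)
    ann <- tibble::tibble(
      gene_id = attr_field(a9, "gene_id"),
      symbol = attr_field(a9, "gene_name"),
      chrom = vapply(f, `[`, "", 1),
      start = as.integer(vapply(f, `[`, "", 4)) - 1L,  # 1-based closed -> 0-based half-open
      end = as.integer(vapply(f, `[`, "", 5)),
      strand = vapply(f, `[`, "", 7)
    )
    ann$symbol[is.na(ann$symbol)] <- ann$gene_id[is.na(ann$symbol)]
  } else {
    ann <- readr::read_tsv(path, show_col_types = FALSE)
    if (!"symbol" %in% names(ann)) ann$symbol <- ann$gene_id
    if (!"strand" %in% names(ann)) ann$strand <- "+"
  }
  if (any(ann$start >= ann$end)) stop("annotation with start >= end")
  if (anyDuplicated(ann$gene_id)) stop("duplicate identifiers: gene_id")
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(ann$chrom), names(chrom_lengths))
    if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  ann$class <- chrom_class(ann$chrom)
  ann[, c("gene_id", "symbol", "chrom", "start", "end", "strand", "class")]
}

# map chromosome name to gene class used by the X:A machinery
chrom_class <- function(chrom) {
  cc <- sub("^chr", "", chrom)
  dplyr::case_when(
    cc %in% c("X", "x") ~ "X",
    cc %in% c("Y", "y") ~ "Y",
    cc %in% c("MT", "M", "mt") ~ "MT",
    TRUE ~ "autosome"
  )
}

#' Pipeline configuration with published defaults
#'
#' Every tunable threshold of the pipeline, defaulting to the values used
#' in the study it reimplements, so a zero-argument configuration is the
#' faithful run. See the methods vignette for the meaning of each.
#'
#' @param ... named overrides of any default.
#' @return A named list of class `sperm_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    min_genes = 1000L,          # default-threshold QC mode
    min_genes_recovered = 500L, # after droplet recovery
    max_mito = 0.10,
    droplet_fdr = 0.01,
    ambient_total_max = 100L,
    ambient_alpha = 0.1,
    n_mc = 2000L,
    n_hvg = 1000L,
    pca_d = 50L,
    snn_k = 5L,
    curve_pcs = 3L,
    marker_fdr = 0.1,
    rho_threshold = 0.3,
    null_size = 100000L,
    corr_alpha = 0.1,
    corr_min_mean = 0.1,
    xa_expressed_frac = 0.3,
    lfc_pseudobulk = 0.5,
    lfc_escape_test = 2,
    lfc_escape_call = 5,
    escape_fdr = 0.1,
    bulk_min_mean = 10,
    split_day = 20L,
    window_width = 1000L,
    top_n_windows = 1000L,
    merge_tolerance = 1500L,
    promoter_upstream = 2000L,
    promoter_downstream = 200L,
    fragment_max_len = 1000L,
    min_quality = 10,
    proportion_fdr = 0.1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "sperm_config")
}

validate_config <- function(cfg) {
  in01 <- c("max_mito", "droplet_fdr", "marker_fdr", "corr_alpha",
            "escape_fdr", "proportion_fdr", "xa_expressed_frac")
  for (f in in01) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " outside [0, 1]")
  }
  pos <- c("n_mc", "n_hvg", "window_width", "null_size", "top_n_windows")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  invisible(cfg)
}

#' Serialise / restore a pipeline configuration
#'
#' @param cfg a `sperm_config`; `path` a JSON file path.
#' @rdname pipeline_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

config_hash <- function(cfg) {
  # cheap content hash: stable across sessions, no external digest dependency
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}
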