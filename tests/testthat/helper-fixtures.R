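# fixtures are generated in code and cached for the duration of the run;
# everything is a deterministic function of the seeds fixed here

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# the default planted world: full stage trajectory, ambient droplets
fx_world <- function() get_fixture("world", function() {
  cfg <- sim_config(seed = 42L)
  simulate_droplets(cfg)
})

# real cells of the default world with size factors and log counts
fx_cells <- function() get_fixture("cells", function() {
  sim <- fx_world()
  keep <- which(sim$truth$cells$kind == "cell")
  cells <- sim$counts[, keep]
  sf <- size_factors(cells)
  logm <- lognormalise(cells, sf)
  list(
    counts = cells, sf = sf, logm = logm,
    truth = sim$truth,
    stage = sim$truth$cells$stage[keep],
    batch = sim$truth$cells$batch[keep],
    pseudotime = sim$truth$cells$pseudotime[keep]
  )
})

# two well-separated Gaussian blobs for clustering contracts
fx_blobs <- function(seed = 1, n = 100, d = 5, sep = 10, sigma = 0.1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n * d, 0, sigma), n, d),
      matrix(rnorm(n * d, sep / sqrt(d), sigma), n, d)
    )
    list(x = x, labels = rep(1:2, each = n))
  })
}

# tiny annotated count container
toy_counts <- function(m, chrom = NULL) {
  g <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(g))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  if (is.null(chrom)) chrom <- rep("chr1", g)
  ann <- tibble::tibble(
    gene_id = rownames(m), symbol = rownames(m), chrom = chrom,
    start = 1000L * seq_len(g), end = 1000L * seq_len(g) + 500L,
    strand = "+", class = spermdyn:::chrom_class(chrom)
  )
  sperm_counts(m, ann)
}
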