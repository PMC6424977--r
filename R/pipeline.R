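#' Run the full analysis pipeline on a synthetic fixture
#'
#' An in-R orchestrator covering every stage of the analysis —
#' simulate, qc, recover, normalise, cluster, trajectory, markers,
#' stage-bulk, dynamics, escape, proportions, chromatin, report — each
#' writing versioned TSV/JSON outputs into `outdir` together with a log
#' recording the configuration hash and seed. Deterministic stages are
#' byte-identical across reruns at a fixed seed.
#'
#' @param outdir output directory.
#' @param steps character vector of step names, or `"all"`.
#' @param config a [pipeline_config()].
#' @param sim a [sim_config()] for the synthetic fixture (its seed
#'   defaults to the pipeline seed).
#' @return invisibly, a list with the in-memory results of the executed
#'   steps.
#' @export
run_pipeline <- function(outdir, steps = "all", config = pipeline_config(),
                         sim = NULL) {
  all_steps <- c("simulate", "qc", "recover", "normalise", "cluster",
                 "trajectory", "markers", "stage-bulk", "dynamics",
                 "escape", "proportions", "chromatin", "report")
  if (identical(steps, "all")) steps <- all_steps
  unknown <- setdiff(steps, all_steps)
  if (length(unknown)) stop("unknown step: ", paste(unknown, collapse = ", "))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(sim)) sim <- sim_config(seed = config$seed)
  st <- new.env(parent = emptyenv())
  log <- list(config_hash = config_hash(config), seed = config$seed, steps = list())
  need <- function(what, file) {
    if (!is.null(st[[what]])) return(st[[what]])
    stop("missing prerequisite: ", what, " (expected from earlier step; ",
         file, " not loaded)")
  }
  out <- function(...) file.path(outdir, ...)

  for (step in all_steps[all_steps %in% steps]) {
    t0 <- Sys.time()
    switch(step,
      "simulate" = {
        simres <- simulate_droplets(sim)
        st$counts_raw <- simres$counts
        st$truth <- simres$truth
        write_counts(simres$counts, outdir)
        write_truth(simres$truth, out("truth.json"))
        comp <- first_wave_compositions(simres$truth)
        st$bulk <- simulate_bulk(simres$truth, comp, depth = 1e6,
                                 days = attr(comp, "days"))
        utils::write.table(st$bulk$counts, out("bulk_counts.tsv"),
                           sep = "\t", quote = FALSE)
        readr::write_tsv(st$bulk$samples, out("bulk_samples.tsv"))
        st$frag_sim <- simulate_fragments(simres$truth)
        write_bed(st$frag_sim$fragments, out("fragments.bed"))
        write_bed(st$frag_sim$repeats, out("repeats.bed"))
        write_bed(st$frag_sim$blacklist, out("blacklist.bed"))
      },
      "qc" = {
        x <- need("counts_raw", "matrix.mtx")
        qc <- qc_filter(x, min_genes = config$min_genes_recovered,
                        max_mito = config$max_mito)
        st$qc <- qc
        readr::write_tsv(qc$report, out("qc_report.tsv"))
      },
      "recover" = {
        x <- need("counts_raw", "matrix.mtx")
        amb <- estimate_ambient(x, total_max = config$ambient_total_max,
                                alpha = config$ambient_alpha)
        dr <- test_droplets(x, amb, n_mc = config$n_mc,
                            fdr = config$droplet_fdr, seed = config$seed)
        st$droplets <- dr
        readr::write_tsv(dr, out("droplets.tsv"))
        keep <- dr$barcode[dr$call != "empty"]
        x2 <- x[, match(keep, colnames(x$counts))]
        st$recovered <- qc_filter(x2, min_genes = config$min_genes_recovered,
                                  max_mito = config$max_mito)$counts
      },
      "normalise" = {
        x <- st$recovered %||% need("qc", "qc_report.tsv")$counts
        sf <- size_factors(x)
        st$sf <- sf
        st$logm <- lognormalise(x, sf)
        st$cells_use <- x
        readr::write_tsv(tibble::tibble(barcode = colnames(x$counts),
                                        size_factor = as.numeric(sf)),
                         out("size_factors.tsv"))
      },
      "cluster" = {
        logm <- need("logm", "size_factors.tsv")
        hvg <- select_hvg(logm, n = min(config$n_hvg, nrow(logm) - 1L))
        st$hvg <- hvg
        emb <- pca_embed(logm[hvg$selected, , drop = FALSE], d = config$pca_d)
        st$embedding <- emb
        cl <- cluster_snn(emb, k = config$snn_k, d_use = config$pca_d,
                          seed = config$seed)
        st$clusters <- cl
        readr::write_tsv(tibble::tibble(barcode = colnames(logm),
                                        cluster = as.integer(cl)),
                         out("clusters.tsv"))
      },
      "trajectory" = {
        emb <- need("embedding", "clusters.tsv")
        fit <- fit_principal_curve(emb, d_use = config$curve_pcs)
        st$trajectory <- fit
        readr::write_tsv(tidy(fit), out("pseudotime.tsv"))
      },
      "markers" = {
        logm <- need("logm", "size_factors.tsv")
        cl <- need("clusters", "clusters.tsv")
        batch <- st$cells_use$cells$batch %||% rep("all", ncol(logm))
        mk <- find_markers(logm, cl, blocks = batch, fdr = config$marker_fdr)
        st$markers <- mk
        readr::write_tsv(mk, out("markers.tsv"))
      },
      "stage-bulk" = {
        logm <- need("logm", "size_factors.tsv")
        cl <- need("clusters", "clusters.tsv")
        mk <- need("markers", "markers.tsv")
        panel <- unique(top_markers(mk, n = 50)$gene)
        # small clusters of unclear identity are excluded from the bridge
        big <- names(which(table(cl) >= 25))
        use <- cl %in% as.integer(big)
        logm_use <- logm[, use, drop = FALSE]
        cl_use <- cl[use]
        ntr <- min(2000L, floor(ncol(logm_use) * 0.6))
        clf <- train_stage_classifier(logm_use, cl_use, panel, n_train = ntr,
                                      seed = config$seed)
        st$classifier <- clf
        post <- stage_bulk(clf, need("bulk", "bulk_counts.tsv"))
        st$posterior <- post
        readr::write_tsv(post, out("stage_posterior.tsv"))
      },
      "dynamics" = {
        x <- st$cells_use %||% need("qc", "qc_report.tsv")$counts
        logm <- need("logm", "size_factors.tsv")
        sf <- need("sf", "size_factors.tsv")
        norm <- t(t(as.matrix(x$counts)) / as.numeric(sf))
        cx <- genes_expressed(x)
        st$complexity <- cx
        truth <- st$truth
        stage <- truth$cells$stage[match(colnames(x$counts), truth$cells$barcode)]
        g1 <- which(stage == truth$config$stages$name[1])
        g2 <- which(stage == truth$config$stages$name[nrow(truth$config$stages) - 1L])
        xa <- xa_ratio(norm, x$genes, g1, g2, frac = config$xa_expressed_frac)
        st$xa <- xa
        readr::write_tsv(xa, out("xa_ratio.tsv"))
        cs <- correlation_screen(logm, cx$n_genes,
                                 n_null = min(config$null_size, 10000L),
                                 rho_threshold = config$rho_threshold,
                                 alpha = config$corr_alpha,
                                 min_mean = config$corr_min_mean,
                                 seed = config$seed)
        st$correlation <- cs
        readr::write_tsv(cs, out("correlation_screen.tsv"))
        readr::write_tsv(stemness_scores(x), out("scores.tsv"))
        readr::write_tsv(group_gene_sets(cs), out("gene_sets.tsv"))
      },
      "escape" = {
        bulk <- need("bulk", "bulk_counts.tsv")
        esc <- call_escape_genes(bulk, split_day = config$split_day,
                                 lfc_test = config$lfc_escape_test,
                                 lfc_call = config$lfc_escape_call,
                                 fdr = config$escape_fdr,
                                 min_mean = config$bulk_min_mean)
        st$escape <- esc
        readr::write_tsv(esc$table, out("escape_calls.tsv"))
      },
      "proportions" = {
        x <- st$cells_use
        cl <- need("clusters", "clusters.tsv")
        batch <- x$cells$batch
        tab <- table(cl, batch)
        if (ncol(tab) >= 4) {
          grp <- rep(c("a", "b"), length.out = ncol(tab))
          pr <- test_proportions(unclass(tab), colSums(tab), grp,
                                 fdr = config$proportion_fdr)
          st$proportions <- pr
          readr::write_tsv(pr, out("proportions.tsv"))
        } else {
          # synthetic default has 2 batches: record the composition table
          readr::write_tsv(tibble::as_tibble(as.data.frame(tab)),
                           out("proportions.tsv"))
        }
      },
      "chromatin" = {
        fs <- need("frag_sim", "fragments.bed")
        fr <- filter_fragments(fs$fragments, fs$blacklist,
                               min_quality = config$min_quality,
                               max_len = config$fragment_max_len)
        prom <- fs$promoters
        sig <- count_fragments(fr, prom)
        st$promoter_signal <- sig
        readr::write_tsv(sig, out("promoter_signal.tsv"))
        k9 <- fr[fr$mark == "H3K9me3" & fr$population == "spermatocytes" &
                   fr$replicate == "r1", , drop = FALSE]
        win <- tile_windows(fs$chrom_lengths["X"], width = config$window_width)
        wsig <- count_fragments(k9, win)
        hs <- high_signal_regions(wsig, top_n = min(config$top_n_windows, nrow(wsig)),
                                  tolerance = config$merge_tolerance)
        st$high_regions <- hs
        readr::write_tsv(hs, out("h3k9me3_regions.tsv"))
        re <- repeat_enrichment(hs, fs$repeats, fs$chrom_lengths[["X"]])
        st$repeat_enrichment <- re
        readr::write_tsv(re, out("repeat_enrichment.tsv"))
      },
      "report" = {
        truth <- st$truth
        x <- st$cells_use
        cl <- need("clusters", "clusters.tsv")
        batch <- x$cells$batch
        comp <- composition(cl, batch)
        readr::write_tsv(comp, out("report_composition.tsv"))
        if (!is.null(st$escape) && length(st$escape$spermatid_specific) &&
            !is.null(st$sf)) {
          stage <- truth$cells$stage[match(colnames(x$counts), truth$cells$barcode)]
          ok <- !is.na(stage)
          norm <- t(t(as.matrix(x$counts[, ok])) / as.numeric(st$sf)[ok])
          heat <- escape_heatmap_table(
            norm, intersect(st$escape$spermatid_specific, rownames(norm)),
            factor(stage[ok], levels = truth$config$stages$name))
          readr::write_tsv(heat, out("report_escape_heatmap.tsv"))
        }
      }
    )
    log$steps[[step]] <- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  }
  jsonlite::write_json(log, out("log.json"), auto_unbox = TRUE, digits = NA)
  invisible(as.list(st))
}
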