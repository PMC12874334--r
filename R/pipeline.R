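#' Run configuration for the end-to-end pipeline
#'
#' Bundles the simulation configuration and every stage threshold. All
#' threshold defaults are the published values: caller consensus >= 2 of 4,
#' clustered window 10 bp / > 3 mutations, DEG |log2FC| >= 1 & FDR < 0.05,
#' DMS |delta-beta| >= 0.2 & p < 0.05, promoter -1500/+500 bp, quadrant
#' thresholds 1.0 (RNA) / 0.1 (methylation), inverse-correlation screen
#' r <= -0.6 & p < 0.1.
#'
#' @param seed Master seed (propagated to the simulation and GSEA).
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param min_callers,min_samples,window_bp,max_in_window Mutation filters.
#' @param deg_fdr,deg_lfc DEG thresholds.
#' @param dms_delta,dms_p DMS thresholds.
#' @param promoter_upstream,promoter_downstream Promoter window (bp).
#' @param quad_rna,quad_meth Quadrant effect thresholds.
#' @param corr_r,corr_p Inverse-correlation screen thresholds.
#' @param gsea_n_perm GSEA permutations used by the pipeline stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, sim = NULL, min_callers = 2L,
                       min_samples = 2L, window_bp = 10L, max_in_window = 3L,
                       deg_fdr = 0.05, deg_lfc = 1, dms_delta = 0.2,
                       dms_p = 0.05, promoter_upstream = 1500L,
                       promoter_downstream = 500L, quad_rna = 1,
                       quad_meth = 0.1, corr_r = -0.6, corr_p = 0.1,
                       gsea_n_perm = 1000L) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as JSON
#'
#' @param cfg A [run_config()].
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$sim <- unclass(x$sim)
  # a named atomic vector would serialize as a bare array; keep the names
  x$sim$chrom_lengths <- as.list(x$sim$chrom_lengths)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- x$sim
  sim$chrom_lengths <- unlist(sim$chrom_lengths)
  if (length(sim$sbs_spectrum) == 0L) sim$sbs_spectrum <- NULL
  else sim$sbs_spectrum <- unlist(sim$sbs_spectrum)
  x$sim <- do.call(sim_config, sim[names(sim) %in% names(formals(sim_config))])
  do.call(run_config, x[names(x) %in% names(formals(run_config))])
}

#' Run the full pipeline: simulate, mutations, spectra, expression,
#' methylation, integration
#'
#' Each stage writes its outputs under `outdir` and the run ends with a
#' machine-readable manifest (`manifest.json`) recording seeds, thresholds,
#' per-stage record counts and md5 digests of every output file. Re-running
#' with the same configuration reproduces byte-identical outputs; any stage
#' failure aborts with the failing stage named.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory.
#' @return The manifest, invisibly.
#' @export
run_all <- function(cfg = run_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "hdmomics", seed = cfg$seed,
                   thresholds = list(
                     min_callers = cfg$min_callers,
                     min_samples = cfg$min_samples,
                     window_bp = cfg$window_bp,
                     max_in_window = cfg$max_in_window,
                     deg_fdr = cfg$deg_fdr, deg_lfc = cfg$deg_lfc,
                     dms_delta = cfg$dms_delta, dms_p = cfg$dms_p,
                     promoter = c(-cfg$promoter_upstream,
                                  cfg$promoter_downstream),
                     quad_rna = cfg$quad_rna, quad_meth = cfg$quad_meth,
                     corr_r = cfg$corr_r, corr_p = cfg$corr_p),
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res
    res
  }

  ## 1: simulate ------------------------------------------------------------
  study <- NULL
  stage("simulate", {
    study <- simulate_study(cfg$sim)
    write_study(study, outdir)
    list(n_genes = nrow(study$annotation),
         n_cpg = nrow(study$methylation$sites),
         n_variants = nrow(study$vcfs$variants),
         n_samples = nrow(study$expression$design))
  })

  ## 2: mutation consolidation ----------------------------------------------
  records <- NULL
  stage("mutations", {
    vcf_dir <- file.path(outdir, "vcf")
    paths <- list.files(vcf_dir, pattern = "\\.vcf$", full.names = TRUE)
    paths <- paths[basename(paths) != "known_sites.vcf"]
    recs <- read_caller_vcfs(paths)
    known <- read_sites_vcf(file.path(vcf_dir, "known_sites.vcf"))
    recs <- filter_pipeline(recs, known, cfg$min_callers, cfg$min_samples,
                            cfg$window_bp, cfg$max_in_window)
    records <- recs
    write_tsv(recs[, c("sample", "chrom", "pos", "ref", "alt", "n_callers",
                       "filter_status")],
              file.path(outdir, "mutations.tsv"))
    burden <- mutational_burden(recs, cfg$sim$callable_mb)
    des <- study$expression$design
    burden$treatment <- des$treatment[match(burden$sample, des$sample)]
    wt <- welch_t_test(burden$burden[burden$treatment == "HDM"],
                       burden$burden[burden$treatment == "VEH"])
    burden_out <- burden[, c("sample", "treatment", "n_mutations",
                             "callable_mb", "burden")]
    write_tsv(burden_out, file.path(outdir, "burden.tsv"))
    c(as.list(attr(recs, "audit")), burden_welch_p = wt$p)
  })

  ## 3: spectra ---------------------------------------------------------------
  stage("spectra", {
    out <- list()
    for (schema in c("SBS96", "DBS78", "ID83")) {
      mat <- build_spectrum(records, study$genome, schema)
      write_spectrum(mat, file.path(outdir, paste0(tolower(schema), ".tsv")))
      out[[schema]] <- sum(mat)
    }
    sbs <- read_tsv_matrix(file.path(outdir, "sbs96.tsv"))
    write_tsv(cosine_table(sbs), file.path(outdir, "sbs96_cosine.tsv"))
    des <- study$expression$design
    grp <- des$treatment[match(colnames(sbs), des$sample)]
    avg <- cbind(HDM = rowMeans(sbs[, grp == "HDM", drop = FALSE]),
                 VEH = rowMeans(sbs[, grp == "VEH", drop = FALSE]))
    out$group_cosine <- cosine_similarity(avg[, "HDM"], avg[, "VEH"])
    write_tsv(round(avg, 4), file.path(outdir, "sbs96_group_mean.tsv"),
              "MutationType")
    out
  })

  ## 4: expression ------------------------------------------------------------
  de_normal <- NULL
  log_tpm <- NULL
  stage("expression", {
    counts <- filter_low_counts(study$expression$counts)
    des <- study$expression$design
    log_tpm <- log2(study$expression$tpm + 1)
    out <- list(n_genes_tested = nrow(counts))
    for (tis in c("normal", "tumor")) {
      de <- nb_wald_de(counts, des, tissue = tis, fdr_max = cfg$deg_fdr,
                       lfc_min = cfg$deg_lfc)
      write_tsv(de, file.path(outdir, paste0("de_", tis, ".tsv")))
      out[[paste0("n_deg_", tis)]] <- sum(de$is_deg)
      if (tis == "normal") de_normal <- de
    }
    scores <- do.call(rbind, lapply(names(study$expression$gene_sets),
      function(nm) {
        unlist(lapply(c("normal", "tumor"), function(tis) {
          sm <- des$sample[des$tissue == tis]
          module_score(log_tpm, study$expression$gene_sets[[nm]], sm)
        }))
      }))
    rownames(scores) <- names(study$expression$gene_sets)
    write_tsv(round(scores, 4), file.path(outdir, "module_scores.tsv"),
              "module")
    ranked <- stats::setNames(de_normal$wald_stat, de_normal$gene)
    gsea <- preranked_gsea(ranked, study$expression$gene_sets,
                           n_perm = cfg$gsea_n_perm, seed = cfg$seed)
    gsea$leading_edge <- vapply(gsea$leading_edge, paste, character(1),
                                collapse = ",")
    write_tsv(gsea, file.path(outdir, "gsea.tsv"))
    dec <- marker_deconvolution(log_tpm, study$expression$marker_sets)
    write_tsv(round(dec, 4), file.path(outdir, "deconvolution.tsv"),
              "population")
    nsm <- des$sample[des$tissue == "normal"]
    dtest <- deconvolution_test(dec[, nsm, drop = FALSE],
                                des$treatment[match(nsm, des$sample)])
    write_tsv(dtest, file.path(outdir, "deconvolution_test.tsv"))
    out$gsea_nes <- stats::setNames(gsea$nes, gsea$set)
    out
  })

  ## 5: methylation -----------------------------------------------------------
  meth_normal <- NULL
  stage("methylation", {
    beta <- study$methylation$beta
    sites <- study$methylation$sites
    des <- study$methylation$design
    pmap <- build_promoter_map(study$annotation, cfg$promoter_upstream,
                               cfg$promoter_downstream,
                               cfg$sim$chrom_lengths)
    gene_bodies <- data.frame(id = study$annotation$gene_id,
                              chrom = study$annotation$chrom,
                              start = study$annotation$start,
                              end = study$annotation$end,
                              stringsAsFactors = FALSE)
    regions <- list(
      promoters = data.frame(id = pmap$gene_id, chrom = pmap$chrom,
                             start = pmap$start, end = pmap$end,
                             stringsAsFactors = FALSE),
      genes = gene_bodies,
      cpg_islands = study$cpg_islands[, c("id", "chrom", "start", "end")],
      tiles = study$tiles[, c("id", "chrom", "start", "end")])
    out <- list()
    for (tis in c("normal", "tumor")) {
      res <- list(sites = site_differential(beta, des, tissue = tis,
                                            delta_min = cfg$dms_delta,
                                            p_max = cfg$dms_p))
      for (nm in names(regions)) {
        rb <- suppressMessages(aggregate_regions(beta, sites, regions[[nm]]))
        res[[nm]] <- region_differential(rb, des, tissue = tis,
                                         delta_min = cfg$dms_delta,
                                         p_max = cfg$dms_p)
      }
      write_tsv(res$sites, file.path(outdir, paste0("meth_sites_", tis,
                                                    ".tsv")))
      counts <- count_dms(res)
      counts$tissue <- tis
      write_tsv(counts, file.path(outdir, paste0("dms_counts_", tis,
                                                 ".tsv")))
      out[[tis]] <- stats::setNames(counts$n_hyper + counts$n_hypo,
                                    counts$feature_class)
      if (tis == "normal") meth_normal <- res$sites
    }
    out
  })

  ## 6: integration -----------------------------------------------------------
  stage("integration", {
    des <- study$expression$design
    pmap <- build_promoter_map(study$annotation, cfg$promoter_upstream,
                               cfg$promoter_downstream,
                               cfg$sim$chrom_lengths)
    dmgs <- derive_dmgs(meth_normal, study$methylation$sites, pmap,
                        p_max = cfg$dms_p)
    quad <- classify_quadrants(dmgs, de_normal, cfg$quad_rna, cfg$quad_meth)
    counts <- filter_low_counts(study$expression$counts)
    tmm <- tmm_factors(counts)
    lib <- colSums(counts)
    log_tmm <- log2(sweep(counts, 2, lib * tmm / mean(lib), "/") * mean(lib)
                    + 1)
    pbeta <- promoter_beta_matrix(study$methylation$beta,
                                  study$methylation$sites, pmap)
    hdm_normal <- des$sample[des$tissue == "normal" & des$treatment == "HDM"]
    res <- suppressMessages(
      inverse_correlation_filter(log_tmm, pbeta, quad, hdm_normal,
                                 cfg$corr_r, cfg$corr_p,
                                 deg_genes = de_normal$gene[de_normal$is_deg]))
    write_tsv(res, file.path(outdir, "integration.tsv"))
    rep <- integration_report(res, n_dmg = nrow(dmgs),
                              n_deg = sum(de_normal$is_deg))
    summary <- data.frame(quadrant = names(rep$quadrant_counts),
                          n = as.integer(rep$quadrant_counts))
    write_tsv(summary, file.path(outdir, "integration_summary.tsv"))
    list(quadrants = as.list(rep$quadrant_counts),
         epi_control = as.list(rep$epi_control_counts),
         venn = as.list(rep$venn))
  })

  files <- sort(list.files(outdir, recursive = TRUE))
  files <- files[files != "manifest.json"]
  digests <- tools::md5sum(file.path(outdir, files))
  manifest$files <- stats::setNames(as.list(unname(digests)), files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
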