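#' @title Promoter methylation-expression integration
#' @description The two-step integration: promoter-assigned differentially
#'   methylated genes are intersected with differentially expressed genes
#'   and classified into five effect-size quadrants (hyper-up, hyper-down,
#'   hypo-up, hypo-down, low-effect); candidates are then screened for
#'   strong inverse correlation between promoter methylation and expression
#'   (Pearson r <= -0.6, p < 0.1) to call "epigenetically controlled"
#'   genes.
#' @name integration
NULL

#' Build the promoter map (-1.5 kb / +0.5 kb around the TSS)
#'
#' Windows are laid out in transcription orientation: for a plus-strand TSS
#' `t` (0-based) the promoter is `[t - 1500, t + 500)`; for a minus-strand
#' TSS it is the strand mirror `[t - 499, t + 1501)`. Every unclipped
#' interval has width exactly 2,000 bp; intervals are clipped to chromosome
#' bounds with a warning when `chrom_lengths` is supplied.
#'
#' @param annotation Data frame with `gene_id`, `chrom`, `strand` (+/-),
#'   `tss` (0-based position of the first transcribed base).
#' @param upstream,downstream Window extents in bp (defaults 1500 and 500).
#' @param chrom_lengths Optional named vector for boundary clipping.
#' @return Data frame: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
build_promoter_map <- function(annotation, upstream = 1500L,
                               downstream = 500L, chrom_lengths = NULL) {
  if (!all(annotation$strand %in% c("+", "-")))
    stop("build_promoter_map: unknown strand value")
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream,
                  annotation$tss - (downstream - 1L))
  end <- ifelse(plus, annotation$tss + downstream,
                annotation$tss + upstream + 1L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[annotation$chrom]
    if (any(start < 0L | end > lim))
      warning("build_promoter_map: intervals clipped to chromosome bounds")
    start <- pmax(start, 0L)
    end <- pmin(end, lim)
  }
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = annotation$strand, stringsAsFactors = FALSE)
}

#' Derive promoter-assigned differentially methylated genes (DMGs)
#'
#' Significant CpG sites (p < `p_max`) falling inside a promoter are
#' assigned to that promoter's gene; a CpG overlapping two promoters is
#' assigned to both. The per-gene methylation effect is the mean (or the
#' most significant site's value, with `aggregate = "top"`) of the member
#' sites' mean-quotient log2 effects.
#'
#' @param site_diff Site-level table from [site_differential()].
#' @param sites Data frame with `site_id`, `chrom`, `pos` matching the
#'   features of `site_diff`.
#' @param pmap Promoter map from [build_promoter_map()].
#' @param p_max Site significance cutoff (default 0.05).
#' @param aggregate "mean" (default) or "top" (most significant CpG).
#' @return Data frame: `gene_id`, `meth_log2fc`, `n_sites`, `min_p`.
#' @export
derive_dmgs <- function(site_diff, sites, pmap, p_max = 0.05,
                        aggregate = c("mean", "top")) {
  aggregate <- match.arg(aggregate)
  sd <- merge(site_diff, sites, by.x = "feature", by.y = "site_id")
  sig <- sd[sd$p < p_max, ]
  if (nrow(sig) == 0L)
    return(data.frame(gene_id = character(), meth_log2fc = numeric(),
                      n_sites = integer(), min_p = numeric(),
                      stringsAsFactors = FALSE))
  site_gr <- GenomicRanges::GRanges(sig$chrom,
                                    IRanges::IRanges(sig$pos, width = 1))
  prom_gr <- GenomicRanges::GRanges(pmap$chrom,
                                    IRanges::IRanges(pmap$start + 1L,
                                                     pmap$end))
  hits <- GenomicRanges::findOverlaps(prom_gr, site_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  by_gene <- split(sh, pmap$gene_id[qh])
  do.call(rbind, lapply(names(by_gene), function(g) {
    rows <- by_gene[[g]]
    eff <- if (aggregate == "mean") mean(sig$mean_quot_log2[rows])
    else sig$mean_quot_log2[rows][which.min(sig$p[rows])]
    data.frame(gene_id = g, meth_log2fc = eff, n_sites = length(rows),
               min_p = min(sig$p[rows]), stringsAsFactors = FALSE)
  }))
}

#' Quadrant classification of DMG-by-DEG genes
#'
#' Genes present in both tables are classified by the signs of the paired
#' effects at |RNA log2FC| >= `rna_min` and |methylation log2FC| >=
#' `meth_min`; genes failing either threshold are `low_effect`.
#'
#' @param dmgs DMG table from [derive_dmgs()].
#' @param degs DE table from [nb_wald_de()].
#' @param rna_min,meth_min Effect thresholds (defaults 1 and 0.1).
#' @return Data frame: `gene`, `rna_log2fc`, `meth_log2fc`, `quadrant`.
#' @export
classify_quadrants <- function(dmgs, degs, rna_min = 1, meth_min = 0.1) {
  skipped <- setdiff(dmgs$gene_id, degs$gene)
  if (length(skipped))
    message("classify_quadrants: ", length(skipped),
            " DMG(s) missing from the expression table skipped")
  m <- merge(dmgs, degs, by.x = "gene_id", by.y = "gene")
  quadrant <- ifelse(abs(m$log2fc) < rna_min | abs(m$meth_log2fc) < meth_min,
                     "low_effect",
                     ifelse(m$meth_log2fc > 0,
                            ifelse(m$log2fc > 0, "hyper_up", "hyper_down"),
                            ifelse(m$log2fc > 0, "hypo_up", "hypo_down")))
  data.frame(gene = m$gene_id, rna_log2fc = m$log2fc,
             meth_log2fc = m$meth_log2fc, quadrant = quadrant,
             rna_fdr = m$fdr, stringsAsFactors = FALSE)
}

#' Per-gene promoter beta matrix
#'
#' Mean beta over the CpG sites inside each gene's promoter, per sample.
#'
#' @param beta Site-by-sample beta matrix.
#' @param sites Site coordinate table (`site_id`, `chrom`, `pos`).
#' @param pmap Promoter map from [build_promoter_map()].
#' @return Gene-by-sample beta matrix (genes with no promoter CpG dropped).
#' @export
promoter_beta_matrix <- function(beta, sites, pmap) {
  regions <- data.frame(id = pmap$gene_id, chrom = pmap$chrom,
                        start = pmap$start, end = pmap$end,
                        stringsAsFactors = FALSE)
  suppressMessages(aggregate_regions(beta, sites, regions))
}

#' Inverse-correlation screen for epigenetically controlled genes
#'
#' For each candidate gene, the Pearson correlation between promoter beta
#' and expression across the shared samples (the treated group, n >= 3) is
#' computed; genes are retained iff `r <= r_max` and `p < p_max` (boundary
#' semantics: r at the threshold passes, p at the threshold fails).
#' Retained hyper-down genes are labelled `repressed`, hypo-up genes
#' `activated`; retained genes in other quadrants get no label. Genes with
#' a constant methylation or expression vector are excluded with a message.
#'
#' @param expr Gene-by-sample expression matrix (log2 TMM-normalized
#'   values by default; scale is the caller's choice and documented).
#' @param promoter_beta Gene-by-sample promoter beta matrix.
#' @param candidates Quadrant table from [classify_quadrants()].
#' @param samples Sample ids to correlate over (>= 3, present in both
#'   matrices).
#' @param r_max,p_max Screen thresholds (defaults -0.6 and 0.1).
#' @param deg_genes Optional character vector of DEG ids; when supplied,
#'   `epi_control` labels are restricted to the DMG-and-DEG intersection
#'   (correlations are still computed and reported for every candidate).
#' @return `candidates` with added `pearson_r`, `pearson_p`, `pearson_fdr`,
#'   `epi_control` columns.
#' @export
inverse_correlation_filter <- function(expr, promoter_beta, candidates,
                                       samples, r_max = -0.6, p_max = 0.1,
                                       deg_genes = NULL) {
  if (length(samples) < 3L)
    stop("inverse_correlation_filter: need >= 3 shared samples")
  if (!all(samples %in% colnames(expr)) ||
      !all(samples %in% colnames(promoter_beta)))
    stop("inverse_correlation_filter: samples missing from a matrix")
  r <- p <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    g <- candidates$gene[i]
    if (!g %in% rownames(expr) || !g %in% rownames(promoter_beta)) next
    e <- expr[g, samples]; b <- promoter_beta[g, samples]
    if (anyNA(e) || anyNA(b)) next            # complete cases only
    if (stats::sd(e) == 0 || stats::sd(b) == 0) {
      message("inverse_correlation_filter: constant vector for ", g,
              "; excluded")
      next
    }
    ct <- pearson_corr_test(b, e)
    r[i] <- ct$r; p[i] <- ct$p
  }
  retained <- !is.na(r) & r <= r_max & p < p_max
  if (!is.null(deg_genes)) retained <- retained & candidates$gene %in% deg_genes
  epi <- rep("none", nrow(candidates))
  epi[retained & candidates$quadrant == "hyper_down"] <- "repressed"
  epi[retained & candidates$quadrant == "hypo_up"] <- "activated"
  out <- candidates
  out$pearson_r <- r
  out$pearson_p <- p
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) fdr[ok] <- bh_adjust(p[ok])$adjusted_p
  out$pearson_fdr <- fdr                       # reported, not used for calls
  out$epi_control <- epi
  out
}

#' Integration summary tables
#'
#' @param records Table from [inverse_correlation_filter()] (or
#'   [classify_quadrants()]).
#' @param n_dmg,n_deg Optional totals for the Venn-style overlap summary.
#' @return List with `quadrant_counts`, `epi_control_counts`, `venn`
#'   (when totals given) and the per-gene `table` for plotting.
#' @export
integration_report <- function(records, n_dmg = NULL, n_deg = NULL) {
  lev <- c("hyper_up", "hyper_down", "hypo_up", "hypo_down", "low_effect")
  qc <- table(factor(records$quadrant, levels = lev))
  ec <- if (!is.null(records$epi_control))
    table(factor(records$epi_control,
                 levels = c("activated", "repressed", "none")))
  else NULL
  venn <- if (!is.null(n_dmg) && !is.null(n_deg))
    c(n_dmg = n_dmg, n_deg = n_deg, n_intersection = nrow(records))
  else NULL
  list(quadrant_counts = qc, epi_control_counts = ec, venn = venn,
       table = records)
}
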