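#' Simulation configuration for the synthetic toy study
#'
#' Bundles every tunable of the synthetic-data generator. Defaults mirror the
#' emulated study design: two treatment groups (HDM allergen vs VEH vehicle),
#' two tissues (normal lung vs tumor), n = 3 biological replicates per group,
#' a 2-Mb toy genome over two chromosomes, ~1,000 somatic mutations per tumor
#' sample drawn from a planted trinucleotide spectrum, 5% planted
#' differentially expressed genes, and 12 epigenetically activated plus 8
#' epigenetically repressed genes whose promoter methylation is wired
#' inversely to their expression.
#'
#' @param seed Integer seed; the single source of randomness. Each generator
#'   stage derives its own stream as `seed + stage offset`.
#' @param n_per_group Replicates per treatment-by-tissue cell.
#' @param n_genes,n_cpg Number of genes / CpG sites.
#' @param chrom_lengths Named integer vector of toy chromosome lengths (bp).
#' @param n_mutations_per_sample True somatic SNVs planted per tumor sample.
#' @param planted_deg_frac Fraction of genes planted as DEGs.
#' @param planted_dms_frac Fraction of CpG sites planted as (non-promoter)
#'   differentially methylated sites.
#' @param n_epi_up,n_epi_down Planted epigenetically activated
#'   (hypomethylated/upregulated) and repressed (hypermethylated/
#'   downregulated) gene counts.
#' @param expr_log2fc_mean Mean |log2 fold change| of planted DEGs (all
#'   planted DEGs have |log2FC| >= this value, i.e. fold change >= 2 when 1).
#' @param delta_beta_mean Planted promoter |delta-beta| for epi genes.
#' @param dispersion Negative-binomial dispersion of the count generator.
#' @param beta_precision Precision of the beta distribution used for
#'   methylation noise (mean/precision parameterisation).
#' @param epi_coupling Amplitude (M-value units per expression z-score unit)
#'   of the inverse methylation-expression coupling of epi genes; applied on
#'   the logit2 scale so the coupling-induced variance is uniform on the
#'   scale the differential test uses.
#' @param epi_gradient_log2 Per-sample expression gradient (log2 units) of
#'   epi genes across exposed normal samples; gives the correlation screen
#'   within-group spread to work with.
#' @param tile_bp Width of genome tiling regions.
#' @param indel_frac,dbs_frac Fractions of planted true mutations that are
#'   small indels / doublet substitutions (the rest are SNVs).
#' @param n_decoys_per_sample Single-caller decoy variants per sample.
#' @param n_germline Planted germline sites (all samples + known-sites VCF).
#' @param n_clusters_per_sample Planted clustered-artifact groups per sample
#'   (4 variants within a 10-bp span each).
#' @param n_shared_artifacts Variants planted in >= 2 samples.
#' @param callable_mb Callable megabases used for burden normalisation.
#' @param sbs_spectrum Optional length-96 probability vector over SBS96
#'   categories; defaults to [default_sbs_spectrum()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = 3L,
                       n_genes = 2000L,
                       n_cpg = 20000L,
                       chrom_lengths = c(chr1 = 1000000L, chr2 = 1000000L),
                       n_mutations_per_sample = 1000L,
                       planted_deg_frac = 0.05,
                       planted_dms_frac = 0.01,
                       n_epi_up = 12L,
                       n_epi_down = 8L,
                       expr_log2fc_mean = 3,
                       delta_beta_mean = 0.4,
                       dispersion = 0.02,
                       beta_precision = 2000,
                       epi_coupling = 0.45,
                       epi_gradient_log2 = 0.25,
                       tile_bp = 5000L,
                       indel_frac = 0.04,
                       dbs_frac = 0.02,
                       n_decoys_per_sample = 150L,
                       n_germline = 30L,
                       n_clusters_per_sample = 4L,
                       n_shared_artifacts = 20L,
                       callable_mb = 30,
                       sbs_spectrum = NULL) {
  cfg <- list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
              n_genes = as.integer(n_genes), n_cpg = as.integer(n_cpg),
              chrom_lengths = chrom_lengths,
              n_mutations_per_sample = as.integer(n_mutations_per_sample),
              planted_deg_frac = planted_deg_frac,
              planted_dms_frac = planted_dms_frac,
              n_epi_up = as.integer(n_epi_up),
              n_epi_down = as.integer(n_epi_down),
              expr_log2fc_mean = expr_log2fc_mean,
              delta_beta_mean = delta_beta_mean,
              dispersion = dispersion, beta_precision = beta_precision,
              epi_coupling = epi_coupling,
              epi_gradient_log2 = epi_gradient_log2,
              tile_bp = as.integer(tile_bp),
              indel_frac = indel_frac, dbs_frac = dbs_frac,
              n_decoys_per_sample = as.integer(n_decoys_per_sample),
              n_germline = as.integer(n_germline),
              n_clusters_per_sample = as.integer(n_clusters_per_sample),
              n_shared_artifacts = as.integer(n_shared_artifacts),
              callable_mb = callable_mb,
              sbs_spectrum = sbs_spectrum)
  counts <- c(cfg$n_per_group, cfg$n_genes, cfg$n_cpg, cfg$chrom_lengths,
              cfg$n_mutations_per_sample, cfg$tile_bp)
  if (any(counts <= 0)) stop("sim_config: all counts must be positive")
  if (is.null(names(cfg$chrom_lengths)))
    stop("sim_config: chrom_lengths must be named")
  for (f in c("planted_deg_frac", "planted_dms_frac"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("sim_config: ", f, " must lie in (0, 1)")
  n_deg <- round(cfg$planted_deg_frac * cfg$n_genes)
  if (cfg$n_epi_up + cfg$n_epi_down > n_deg)
    stop("sim_config: n_epi_up + n_epi_down exceeds the planted DEG count")
  if (!is.null(sbs_spectrum) && length(sbs_spectrum) != 96L)
    stop("sim_config: sbs_spectrum must have length 96")
  class(cfg) <- "sim_config"
  cfg
}

# Stage seed offsets keep the four generator stages on independent,
# reproducible streams derived from the one user-facing seed.
.stage_seed <- function(cfg, stage) {
  off <- c(genome = 0L, vcf = 1L, expression = 2L, methylation = 3L)
  cfg$seed + off[[stage]]
}

#' Simulate the toy reference genome, gene annotation and region sets
#'
#' Generates random chromosome sequences, non-overlapping gene bodies laid
#' out on an even grid (~50% per strand, every TSS with >= 1.5 kb clearance
#' from the chromosome ends), CpG islands centred on a subset of promoters,
#' and a tiling of each chromosome into fixed-width windows.
#'
#' Coordinates are 0-based half-open throughout the in-memory tables; VCF
#' output is 1-based.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome` (named character vector of chromosome
#'   sequences), `annotation` (gene_id, chrom, strand, tss, start, end,
#'   length), `cpg_islands` and `tiles` (BED-like data frames).
#' @export
simulate_genome_and_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.stage_seed(cfg, "genome"))
  chroms <- names(cfg$chrom_lengths)
  genome <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_lengths[[ch]],
                 replace = TRUE), collapse = "")
  }, character(1))

  margin <- 2000L
  gpc <- rep(cfg$n_genes %/% length(chroms), length(chroms))
  rem <- cfg$n_genes - sum(gpc)
  if (rem > 0) gpc[seq_len(rem)] <- gpc[seq_len(rem)] + 1L
  ann <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    len <- cfg$chrom_lengths[[ci]]
    k <- gpc[ci]
    slot <- (len - 2L * margin) %/% k
    if (slot < 100L)
      stop("simulate_genome_and_annotation: genome too small for ",
           cfg$n_genes, " genes")
    body <- max(60L, as.integer(slot * 0.6))
    start <- margin + (seq_len(k) - 1L) * slot
    strand <- sample(c("+", "-"), k, replace = TRUE)
    data.frame(chrom = chroms[ci], strand = strand,
               start = start, end = start + body,
               stringsAsFactors = FALSE)
  }))
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  ann$length <- ann$end - ann$start
  ann$gene_id <- sprintf("g%05d", seq_len(nrow(ann)))
  ann <- ann[, c("gene_id", "chrom", "strand", "tss", "start", "end", "length")]

  isl_idx <- seq(1L, nrow(ann), by = 5L)
  islands <- data.frame(
    id = sprintf("isl%04d", seq_along(isl_idx)),
    chrom = ann$chrom[isl_idx],
    start = pmax(0L, ann$tss[isl_idx] - 300L),
    end = pmin(cfg$chrom_lengths[ann$chrom[isl_idx]], ann$tss[isl_idx] + 300L),
    stringsAsFactors = FALSE)

  tiles <- do.call(rbind, lapply(chroms, function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    start <- seq(0L, len - 1L, by = cfg$tile_bp)
    data.frame(id = sprintf("%s_tile%05d", ch, seq_along(start)),
               chrom = ch, start = start,
               end = pmin(start + cfg$tile_bp, len),
               stringsAsFactors = FALSE)
  }))
  rownames(ann) <- rownames(islands) <- rownames(tiles) <- NULL
  list(genome = genome, annotation = ann, cpg_islands = islands, tiles = tiles)
}

#' Sample design table for the emulated study
#'
#' @param cfg A [sim_config()].
#' @return Data frame with `sample`, `tissue` (normal/tumor) and `treatment`
#'   (HDM/VEH), n_per_group rows per cell.
#' @export
sim_design <- function(cfg) {
  grid <- expand.grid(rep = seq_len(cfg$n_per_group),
                      treatment = c("HDM", "VEH"),
                      tissue = c("normal", "tumor"),
                      stringsAsFactors = FALSE)
  data.frame(sample = sprintf("%s_%s_%d",
                              ifelse(grid$tissue == "normal", "N", "T"),
                              grid$treatment, grid$rep),
             tissue = grid$tissue, treatment = grid$treatment,
             stringsAsFactors = FALSE)
}

#' Default planted SBS96 spectrum
#'
#' A fixed synthetic single-base-substitution signature: a flat background
#' over all 96 trinucleotide categories with strong enrichment of C>T at CpG
#' contexts and moderate enrichment of C>A, loosely shaped like the clock-like
#' and oxidative-damage signatures seen in mouse tissue. Sums to 1.
#'
#' @return Named numeric vector of length 96 in canonical SBS96 order.
#' @export
default_sbs_spectrum <- function() {
  cats <- sbs96_categories()
  w <- rep(1, 96)
  w[grepl("\\[C>T\\]G", cats)] <- 12
  w[grepl("\\[C>A\\]", cats)] <- 3
  names(w) <- cats
  w / sum(w)
}

# trinucleotide position index for one chromosome: list raw-trinuc -> 1-based
# centre positions (positions 2..L-1)
.trinuc_index <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  tri <- paste0(v[1:(L - 2)], v[2:(L - 1)], v[3:L])
  split(2:(L - 1), tri)
}

.revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(v)
    paste(rev(v), collapse = ""), character(1)))
}

#' Simulate per-sample caller VCF quartets with planted ground truth
#'
#' Emulates an ensemble of four somatic variant callers run on each tumor
#' sample. True somatic variants (SNVs drawn so their trinucleotide spectrum
#' matches the planted SBS96 signature, plus a small fraction of indels and
#' doublet substitutions) are reported by at least two callers; decoy calls
#' appear in exactly one caller; planted germline sites appear in every
#' sample and in the known-sites VCF; clustered artifacts place 4 variants
#' within a 10-bp span; shared artifacts recur across samples. Every planted
#' variant occupies its own 10-bp genomic bin (clusters get a one-bin
#' buffer), so true somatic variants can never accidentally trip the shared-
#' or clustered-mutation filters: the designed consensus set is exactly
#' recoverable.
#'
#' @param cfg A [sim_config()].
#' @param genome Genome from [simulate_genome_and_annotation()] (the
#'   `genome` element, or the full list).
#' @return List of class `sim_vcfs` with `variants` (sample, chrom, pos
#'   1-based, ref, alt, callers comma-string, class), `known_sites`,
#'   `spectrum` (the planted SBS96 probabilities), `samples`, `callers`.
#' @export
simulate_caller_vcfs <- function(cfg, genome) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  set.seed(.stage_seed(cfg, "vcf"))
  callers <- c("mutect2", "varscan2", "strelka2", "muse")
  des <- sim_design(cfg)
  samples <- des$sample[des$tissue == "tumor"]
  spectrum <- if (is.null(cfg$sbs_spectrum)) default_sbs_spectrum() else {
    s <- cfg$sbs_spectrum
    if (is.null(names(s))) names(s) <- sbs96_categories()
    s / sum(s)
  }

  chroms <- names(genome)
  tri_idx <- lapply(genome, .trinuc_index)
  nbins <- vapply(genome, function(s) nchar(s) %/% 10L + 1L, integer(1))
  used <- lapply(nbins, function(n) logical(n))

  claim_bin <- function(chrom, pos, buffer = 0L) {
    b <- (pos - 1L) %/% 10L + 1L
    rng <- max(1L, b - buffer):min(nbins[[chrom]], b + buffer)
    if (any(used[[chrom]][rng])) return(FALSE)
    used[[chrom]][rng] <<- TRUE
    TRUE
  }
  rand_free_pos <- function(buffer = 0L, margin = 20L) {
    repeat {
      ch <- sample(chroms, 1)
      pos <- sample.int(nchar(genome[[ch]]) - 2L * margin, 1) + margin
      if (claim_bin(ch, pos, buffer)) return(list(chrom = ch, pos = pos))
    }
  }
  base_at <- function(ch, pos) substr(genome[[ch]], pos, pos)

  cat96 <- sbs96_categories()
  # per-category candidate positions: pyrimidine-context positions plus
  # reverse-complement (purine) positions, per chromosome
  cat_ctx <- function(cat) {
    ref <- substr(cat, 3, 3); alt <- substr(cat, 5, 5)
    up <- substr(cat, 1, 1); dn <- substr(cat, 7, 7)
    fwd <- paste0(up, ref, dn)
    list(fwd = fwd, rev = .revcomp_chr(fwd), alt_fwd = alt,
         alt_rev = .revcomp_chr(alt))
  }
  ctxs <- lapply(cat96, cat_ctx)
  names(ctxs) <- cat96

  draw_snv <- function(cat) {
    cx <- ctxs[[cat]]
    repeat {
      ch <- sample(chroms, 1)
      fwd_pos <- tri_idx[[ch]][[cx$fwd]]
      rev_pos <- tri_idx[[ch]][[cx$rev]]
      nf <- length(fwd_pos); nr <- length(rev_pos)
      if (nf + nr == 0L) next
      i <- sample.int(nf + nr, 1)
      if (i <= nf) { pos <- fwd_pos[i]; alt <- cx$alt_fwd }
      else { pos <- rev_pos[i - nf]; alt <- cx$alt_rev }
      if (claim_bin(ch, pos)) {
        return(list(chrom = ch, pos = pos, ref = base_at(ch, pos), alt = alt))
      }
    }
  }

  pick_callers <- function(min_n = 2L) {
    n <- sample(min_n:4L, 1)
    paste(sort(sample(callers, n)), collapse = ",")
  }

  rows <- list()
  add <- function(sample, chrom, pos, ref, alt, callers_str, class) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample = sample, chrom = chrom, pos = as.integer(pos), ref = ref,
      alt = alt, callers = callers_str, class = class,
      stringsAsFactors = FALSE)
  }

  n_mut <- cfg$n_mutations_per_sample
  n_indel <- round(cfg$indel_frac * n_mut)
  n_dbs <- round(cfg$dbs_frac * n_mut)
  n_snv <- n_mut - n_indel - n_dbs
  for (sm in samples) {
    cats <- sample(cat96, n_snv, replace = TRUE, prob = spectrum)
    for (cat in cats) {
      v <- draw_snv(cat)
      add(sm, v$chrom, v$pos, v$ref, v$alt, pick_callers(), "true_somatic")
    }
    for (i in seq_len(n_indel)) {
      p <- rand_free_pos()
      ref1 <- base_at(p$chrom, p$pos)
      if (stats::runif(1) < 0.5) {               # deletion of 1-3 bp
        w <- sample(1:3, 1)
        ref <- substr(genome[[p$chrom]], p$pos, p$pos + w)
        add(sm, p$chrom, p$pos, ref, ref1, pick_callers(), "true_somatic")
      } else {                                   # insertion of 1-2 bp
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:2, 1),
                            replace = TRUE), collapse = "")
        add(sm, p$chrom, p$pos, ref1, paste0(ref1, ins), pick_callers(),
            "true_somatic")
      }
    }
    for (i in seq_len(n_dbs)) {
      p <- rand_free_pos()
      ref <- substr(genome[[p$chrom]], p$pos, p$pos + 1L)
      alt <- paste0(sample(setdiff(c("A", "C", "G", "T"),
                                   substr(ref, 1, 1)), 1),
                    sample(setdiff(c("A", "C", "G", "T"),
                                   substr(ref, 2, 2)), 1))
      add(sm, p$chrom, p$pos, ref, alt, pick_callers(), "true_somatic")
    }
    for (i in seq_len(cfg$n_decoys_per_sample)) {
      p <- rand_free_pos()
      ref <- base_at(p$chrom, p$pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      add(sm, p$chrom, p$pos, ref, alt, sample(callers, 1), "decoy")
    }
    for (i in seq_len(cfg$n_clusters_per_sample)) {
      p <- rand_free_pos(buffer = 1L)
      offs <- c(0L, 2L, 5L, 8L)                  # span 9 bp -> 4 within 10 bp
      sup <- pick_callers()
      for (o in offs) {
        ref <- base_at(p$chrom, p$pos + o)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        add(sm, p$chrom, p$pos + o, ref, alt, sup, "clustered")
      }
    }
  }
  # germline: same allele in every sample and in the known-sites file
  germ <- vector("list", cfg$n_germline)
  for (i in seq_len(cfg$n_germline)) {
    p <- rand_free_pos()
    ref <- base_at(p$chrom, p$pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    germ[[i]] <- data.frame(chrom = p$chrom, pos = p$pos, ref = ref,
                            alt = alt, stringsAsFactors = FALSE)
    for (sm in samples)
      add(sm, p$chrom, p$pos, ref, alt, paste(callers, collapse = ","),
          "germline")
  }
  known_sites <- do.call(rbind, germ)
  # shared artifacts: same allele in >= 2 samples
  for (i in seq_len(cfg$n_shared_artifacts)) {
    p <- rand_free_pos()
    ref <- base_at(p$chrom, p$pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    for (sm in sample(samples, sample(2:length(samples), 1)))
      add(sm, p$chrom, p$pos, ref, alt, pick_callers(), "shared")
  }

  variants <- do.call(rbind, rows)
  variants <- variants[order(variants$sample, variants$chrom, variants$pos,
                             variants$alt), ]
  rownames(variants) <- NULL
  structure(list(variants = variants, known_sites = known_sites,
                 spectrum = spectrum, samples = samples, callers = callers),
            class = "sim_vcfs")
}

#' Simulate gene-by-sample expression matrices
#'
#' Counts are drawn from a negative-binomial model with per-gene baselines,
#' shared dispersion, and per-sample library-size factors. Planted DEGs have
#' |log2 fold change| >= `expr_log2fc_mean` for the HDM-vs-VEH contrast in
#' normal tissue (group mean ratio >= 2 at the default of 1 or more); the
#' tumor-tissue contrast carries no planted effects. Epi-class genes
#' additionally carry a per-sample expression gradient across the exposed
#' normal samples, the within-group spread the downstream correlation screen
#' relies on. Synthetic gene-set stand-ins for the IL-1/inflammasome and
#' IL-17 modules (drawn from the upregulated DEGs) and marker sets for a
#' "myeloid-up" deconvolution design are returned alongside.
#'
#' @param cfg A [sim_config()].
#' @param annotation Gene table from [simulate_genome_and_annotation()].
#' @return List with `counts` (integer matrix), `tpm`, `design`,
#'   `truth_genes`, `gene_sets` and `marker_sets` (lists of gene-id vectors),
#'   and `size_factors` (the true planted factors).
#' @export
simulate_expression <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.list(annotation) && !is.null(annotation$annotation))
    annotation <- annotation$annotation
  set.seed(.stage_seed(cfg, "expression"))
  des <- sim_design(cfg)
  ng <- nrow(annotation); ns <- nrow(des)
  genes <- annotation$gene_id

  q <- exp(stats::rnorm(ng, log(200), 1.2))
  n_deg <- round(cfg$planted_deg_frac * ng)
  # planted DEGs are drawn from genes with detectable baseline expression
  # (mean count >= 50): effects planted below the detection floor of an
  # n = 3 design would be unrecoverable by construction
  eligible <- which(q >= 50)
  if (length(eligible) < n_deg) eligible <- order(q, decreasing = TRUE)[1:n_deg]
  deg_idx <- sort(sample(eligible, n_deg))
  n_up <- cfg$n_epi_up + ceiling((n_deg - cfg$n_epi_up - cfg$n_epi_down) / 2)
  up_idx <- deg_idx[seq_len(n_up)]
  down_idx <- setdiff(deg_idx, up_idx)
  epi_up <- up_idx[seq_len(cfg$n_epi_up)]
  epi_down <- down_idx[seq_len(cfg$n_epi_down)]

  lfc <- numeric(ng)
  lfc[up_idx] <- cfg$expr_log2fc_mean + abs(stats::rnorm(length(up_idx), 0, 0.5))
  lfc[down_idx] <- -(cfg$expr_log2fc_mean +
                       abs(stats::rnorm(length(down_idx), 0, 0.5)))

  sf <- stats::runif(ns, 0.7, 1.3)
  names(sf) <- des$sample
  hdm_normal <- which(des$tissue == "normal" & des$treatment == "HDM")
  # fixed regulatory gradient across the exposed normal replicates
  grad <- cfg$epi_gradient_log2 * seq(-1, 1, length.out = length(hdm_normal))

  log2mu <- matrix(rep(log2(q), ns), nrow = ng)
  log2mu[, hdm_normal] <- log2mu[, hdm_normal] + lfc
  epi_idx <- c(epi_up, epi_down)
  if (length(epi_idx))
    log2mu[epi_idx, hdm_normal] <- log2mu[epi_idx, hdm_normal] +
      matrix(rep(grad, each = length(epi_idx)), nrow = length(epi_idx))

  mu <- sweep(2^log2mu, 2, sf, "*")
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu, size = 1 / cfg$dispersion),
                   nrow = ng, dimnames = list(genes, des$sample))
  tpm <- tpm_from_counts(counts, annotation$length)

  direction <- rep("none", ng)
  direction[up_idx] <- "up"; direction[down_idx] <- "down"
  epi_class <- rep("none", ng)
  epi_class[epi_up] <- "hypo_up"; epi_class[epi_down] <- "hyper_down"
  truth_genes <- data.frame(gene_id = genes,
                            is_deg = seq_len(ng) %in% deg_idx,
                            direction = direction, log2fc = lfc,
                            epi_class = epi_class,
                            is_dmg = epi_class != "none",
                            stringsAsFactors = FALSE)

  non_epi_up <- setdiff(up_idx, epi_up)
  gene_sets <- list(
    IL1_inflammasome_synthetic = genes[non_epi_up[seq_len(min(17, length(non_epi_up)))]],
    IL17_targets_synthetic = genes[rev(non_epi_up)[seq_len(min(12, length(non_epi_up)))]])
  null_genes <- genes[setdiff(seq_len(ng), deg_idx)]
  marker_sets <- list(
    myeloid_synthetic = genes[non_epi_up[seq_len(min(10, length(non_epi_up)))]],
    lymphoid_synthetic = null_genes[seq_len(10)])

  list(counts = counts, tpm = tpm, design = des, truth_genes = truth_genes,
       gene_sets = gene_sets, marker_sets = marker_sets, size_factors = sf)
}

#' TPM from counts and gene lengths
#'
#' @param counts Gene-by-sample count matrix.
#' @param lengths Gene lengths in bp (recycled along rows).
#' @return Matrix of transcripts-per-million values.
#' @export
tpm_from_counts <- function(counts, lengths) {
  rpk <- counts / (lengths / 1000)
  sweep(rpk, 2, colSums(rpk), "/") * 1e6
}

#' Simulate the CpG-by-sample methylation beta matrix
#'
#' CpG sites are placed both inside gene promoters (so promoter-level
#' aggregation and integration have realistic input) and uniformly across the
#' toy genome. Beta values are drawn from a beta distribution around per-site
#' baselines (mean/precision parameterisation, so values stay strictly inside
#' (0,1)). Planted effects, all in normal tissue: promoters of epi-class
#' genes shift by +/- `delta_beta_mean` in the exposed group and are coupled
#' inversely to the gene's realized expression across the exposed samples;
#' an additional `planted_dms_frac` of background sites shift by +/-0.35.
#'
#' @param cfg A [sim_config()].
#' @param annotation Gene table from [simulate_genome_and_annotation()].
#' @param expression Result of [simulate_expression()] (needed for the
#'   expression-methylation coupling and the shared design).
#' @return List with `beta` (site-by-sample matrix), `sites` (site_id, chrom,
#'   pos 1-based), `design`, and `truth_cpgs` (per-site planted flags).
#' @export
simulate_methylation <- function(cfg, annotation, expression) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.list(annotation) && !is.null(annotation$annotation))
    annotation <- annotation$annotation
  set.seed(.stage_seed(cfg, "methylation"))
  des <- expression$design
  truth <- expression$truth_genes
  ns <- nrow(des)

  pmap <- build_promoter_map(annotation)
  epi_genes <- truth$gene_id[truth$epi_class != "none"]

  # promoter sites: 6 per epi gene, ~40% of the remainder over random genes
  site_list <- list()
  for (g in epi_genes) {
    pr <- pmap[pmap$gene_id == g, ]
    pos <- sort(sample(pr$start:(pr$end - 1L), 6L)) + 1L   # 1-based
    site_list[[length(site_list) + 1L]] <- data.frame(
      chrom = pr$chrom, pos = pos, gene_id = g, planted = "epi",
      stringsAsFactors = FALSE)
  }
  n_prom_extra <- max(0L, round(0.4 * cfg$n_cpg) - 6L * length(epi_genes))
  # filler promoter sites avoid epi genes: every CpG in an epi promoter is
  # part of the coupled, shifted set
  non_epi_rows <- which(!pmap$gene_id %in% epi_genes)
  gidx <- non_epi_rows[sample.int(length(non_epi_rows), n_prom_extra,
                                  replace = TRUE)]
  off <- sample.int(2000L, n_prom_extra, replace = TRUE) - 1L
  site_list[[length(site_list) + 1L]] <- data.frame(
    chrom = pmap$chrom[gidx], pos = pmap$start[gidx] + off + 1L,
    gene_id = pmap$gene_id[gidx], planted = "none", stringsAsFactors = FALSE)
  n_bg <- cfg$n_cpg - n_prom_extra - 6L * length(epi_genes)
  bg_ch <- sample(names(cfg$chrom_lengths), n_bg, replace = TRUE)
  bg_pos <- vapply(bg_ch, function(ch)
    sample.int(cfg$chrom_lengths[[ch]] - 2L, 1) + 1L, integer(1))
  site_list[[length(site_list) + 1L]] <- data.frame(
    chrom = bg_ch, pos = bg_pos, gene_id = NA_character_, planted = "none",
    stringsAsFactors = FALSE)
  sites <- do.call(rbind, site_list)
  # epi-gene promoters contain exactly their coupled site set: filler and
  # background sites falling inside an epi promoter window are removed, so
  # promoter-level aggregates carry the full planted delta-beta
  epi_prom <- pmap[pmap$gene_id %in% epi_genes, ]
  if (nrow(epi_prom)) {
    in_epi <- rep(FALSE, nrow(sites))
    for (i in seq_len(nrow(epi_prom)))
      in_epi <- in_epi | (sites$chrom == epi_prom$chrom[i] &
                            sites$pos - 1L >= epi_prom$start[i] &
                            sites$pos - 1L < epi_prom$end[i])
    sites <- sites[!(in_epi & sites$planted != "epi"), ]
  }
  sites <- sites[!duplicated(sites[, c("chrom", "pos")]), ]
  sites <- sites[order(sites$chrom, sites$pos), ]
  sites$site_id <- sprintf("cg%06d", seq_len(nrow(sites)))
  rownames(sites) <- NULL
  nsite <- nrow(sites)

  # planted non-promoter DMS among background sites
  bg_idx <- which(sites$planted == "none" & is.na(sites$gene_id))
  n_dms_extra <- min(length(bg_idx), round(cfg$planted_dms_frac * cfg$n_cpg))
  dms_idx <- sort(sample(bg_idx, n_dms_extra))
  dms_dir <- sample(c(1, -1), n_dms_extra, replace = TRUE)

  # baselines: bimodal background, mid-range for planted sites
  base <- ifelse(stats::runif(nsite) < 0.5,
                 stats::runif(nsite, 0.08, 0.25),
                 stats::runif(nsite, 0.65, 0.9))
  epi_rows <- which(sites$planted == "epi")
  gene_class <- truth$epi_class[match(sites$gene_id, truth$gene_id)]
  # hyper_down genes start low and gain methylation; hypo_up the reverse
  base[epi_rows] <- ifelse(gene_class[epi_rows] == "hyper_down", 0.25, 0.72)
  base[dms_idx] <- ifelse(dms_dir > 0, 0.3, 0.7)

  mu <- matrix(rep(base, ns), nrow = nsite,
               dimnames = list(sites$site_id, des$sample))
  hdm_normal <- which(des$tissue == "normal" & des$treatment == "HDM")
  dirsite <- numeric(nsite)
  dirsite[epi_rows] <- ifelse(gene_class[epi_rows] == "hyper_down", 1, -1)
  dirsite[dms_idx] <- dms_dir
  delta <- numeric(nsite)
  delta[epi_rows] <- cfg$delta_beta_mean
  delta[dms_idx] <- 0.35
  mu[, hdm_normal] <- mu[, hdm_normal] + dirsite * delta

  # inverse coupling to the realized expression of the parent epi gene, on
  # the same scale the downstream correlation screen uses (log2 of
  # TMM-normalized counts + 1): promoter methylation tracks expression as
  # analyzed, limited only by beta noise
  cnt_f <- filter_low_counts(expression$counts)
  tmmf <- tmm_factors(cnt_f)
  lib <- colSums(cnt_f)
  log_expr <- log2(sweep(cnt_f, 2, lib * tmmf / mean(lib), "/") *
                     mean(lib) + 1)
  fallback <- log2(expression$tpm + 1)   # for genes below the count filter
  veh_normal <- which(des$tissue == "normal" & des$treatment == "VEH")
  mu <- pmin(pmax(mu, 0.03), 0.97)
  for (g in epi_genes) {
    rws <- which(sites$gene_id %in% g & sites$planted == "epi")
    # methylation tracks expression in every normal sample; the coupling is
    # applied on the logit2 (M-value) scale and z-scored within treatment
    # group, so the planted group delta-beta stays intact and the two group
    # variances are comparable on the scale the tests use
    for (grp in list(hdm_normal, veh_normal)) {
      e <- if (g %in% rownames(log_expr)) log_expr[g, grp]
      else fallback[g, grp]
      z <- if (stats::sd(e) > 0) (e - mean(e)) / stats::sd(e)
      else rep(0, length(e))
      m <- beta_to_m(mu[rws, grp, drop = FALSE]) -
        matrix(rep(cfg$epi_coupling * z, each = length(rws)),
               nrow = length(rws))
      mu[rws, grp] <- m_to_beta(m)
    }
  }
  mu <- pmin(pmax(mu, 0.02), 0.98)
  phi <- cfg$beta_precision
  beta <- matrix(stats::rbeta(nsite * ns, mu * phi, (1 - mu) * phi),
                 nrow = nsite, dimnames = dimnames(mu))
  beta <- clamp_beta(beta)

  truth_cpgs <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                           pos = sites$pos,
                           is_dms = dirsite != 0,
                           direction = ifelse(dirsite > 0, "hyper",
                                              ifelse(dirsite < 0, "hypo", "none")),
                           gene_id = sites$gene_id,
                           stringsAsFactors = FALSE)
  list(beta = beta, sites = sites[, c("site_id", "chrom", "pos")],
       design = des, truth_cpgs = truth_cpgs)
}

#' Generate the complete synthetic study
#'
#' Runs all four generator stages under one seed and assembles the combined
#' TruthTable. Every planted epi-class gene is by construction both a DEG and
#' a promoter DMG with opposite effect signs.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_study` with elements `config`, `genome`,
#'   `annotation`, `cpg_islands`, `tiles`, `vcfs`, `expression`,
#'   `methylation`, and `truth` (genes, cpgs, variants, spectrum).
#' @export
simulate_study <- function(cfg) {
  gen <- simulate_genome_and_annotation(cfg)
  vcfs <- simulate_caller_vcfs(cfg, gen$genome)
  expr <- simulate_expression(cfg, gen$annotation)
  meth <- simulate_methylation(cfg, gen$annotation, expr)
  truth <- list(genes = expr$truth_genes, cpgs = meth$truth_cpgs,
                variants = vcfs$variants, spectrum = vcfs$spectrum)
  structure(list(config = cfg, genome = gen$genome,
                 annotation = gen$annotation, cpg_islands = gen$cpg_islands,
                 tiles = gen$tiles, vcfs = vcfs, expression = expr,
                 methylation = meth, truth = truth),
            class = "sim_study")
}
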