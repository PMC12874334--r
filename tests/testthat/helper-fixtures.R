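# Shared fixtures: everything is generated in code at test time.

# a desk-scale simulation configuration (small genome, few mutations)
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 500, n_cpg = 3000,
             chrom_lengths = c(chr1 = 200000L, chr2 = 200000L),
             n_mutations_per_sample = 200, n_decoys_per_sample = 30,
             n_germline = 8, n_clusters_per_sample = 2,
             n_shared_artifacts = 4, ...)
}

# the scaled default used for recovery runs: the emulated study's planted
# design (12 + 8 epi genes, n = 3/group) at reduced matrix sizes for runtime
recovery_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_genes = 1000, n_cpg = 10000,
             chrom_lengths = c(chr1 = 600000L, chr2 = 600000L),
             n_mutations_per_sample = 50, n_decoys_per_sample = 5,
             n_germline = 3, n_clusters_per_sample = 1,
             n_shared_artifacts = 2, ...)
}

# build mutation_records directly from vectors
make_records <- function(pos, sample = "s1", chrom = "chr1", ref = "A",
                         alt = "T", callers = "m2,strelka2") {
  n <- length(pos)
  df <- data.frame(sample = rep_len(sample, n), chrom = rep_len(chrom, n),
                   pos = as.integer(pos), ref = rep_len(ref, n),
                   alt = rep_len(alt, n), callers = rep_len(callers, n),
                   stringsAsFactors = FALSE)
  hdmomics:::.new_records(df)
}

# tiny deterministic genome for classifier tests
toy_genome <- function(chr1 = "ACGTACGTACGTACGTACGT") c(chr1 = chr1)

# run the integration chain on a simulated study (no VCF stages)
run_integration_chain <- function(cfg) {
  gen <- simulate_genome_and_annotation(cfg)
  expr <- simulate_expression(cfg, gen$annotation)
  meth <- simulate_methylation(cfg, gen$annotation, expr)
  des <- expr$design
  counts <- filter_low_counts(expr$counts)
  de <- nb_wald_de(counts, des, tissue = "normal")
  pmap <- build_promoter_map(gen$annotation, chrom_lengths = cfg$chrom_lengths)
  md <- site_differential(meth$beta, des, tissue = "normal")
  dmgs <- derive_dmgs(md, meth$sites, pmap)
  quad <- classify_quadrants(dmgs, de)
  tmm <- tmm_factors(counts)
  lib <- colSums(counts)
  log_tmm <- log2(sweep(counts, 2, lib * tmm / mean(lib), "/") * mean(lib) + 1)
  pbeta <- promoter_beta_matrix(meth$beta, meth$sites, pmap)
  hdm <- des$sample[des$tissue == "normal" & des$treatment == "HDM"]
  res <- suppressMessages(
    inverse_correlation_filter(log_tmm, pbeta, quad, hdm,
                               deg_genes = de$gene[de$is_deg]))
  list(truth = expr$truth_genes, de = de, dmgs = dmgs, quad = quad,
       result = res)
}

# memoized default-configuration study for the acceptance suite (indel and
# doublet fractions zeroed so the planted catalog is exactly 1,000 signature
# SNVs per sample; every other parameter is the package default)
.acc_env <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.acc_env$study))
    .acc_env$study <- simulate_study(sim_config(seed = 1, indel_frac = 0,
                                                dbs_frac = 0))
  .acc_env$study
}

# build a (genome, variant) pair designed to land in a given ID83 category
id83_case <- function(cat) {
  f <- strsplit(cat, ":")[[1]]
  L <- as.integer(f[1]); type <- f[2]; sub <- f[3]; n <- as.integer(f[4])
  if (sub %in% c("C", "T")) {                 # 1-bp events
    b <- sub
    if (type == "Del") {
      genome <- paste0("AG", strrep(b, n + 1L), "GA")
      list(genome = genome, pos = 2L, ref = paste0("G", b), alt = "G")
    } else {
      genome <- paste0("AG", strrep(b, n), "GA")
      list(genome = genome, pos = 2L, ref = "G", alt = paste0("G", b))
    }
  } else if (sub == "R") {
    motif <- substr("CAGCA", 1, L)
    if (type == "Del") {
      genome <- paste0("TT", strrep(motif, n + 1L), "TT")
      list(genome = genome, pos = 2L, ref = paste0("T", motif), alt = "T")
    } else {
      genome <- paste0("TT", strrep(motif, n), "TT")
      list(genome = genome, pos = 2L, ref = "T", alt = paste0("T", motif))
    }
  } else {                                     # microhomology deletions
    real_L <- if (L == 5L && n == 5L) 6L else L   # 5:Del:M:5 needs length 6
    motif <- substr("CAGCAC", 1, real_L)
    genome <- paste0("TT", motif, substr(motif, 1, n), "TT")
    list(genome = genome, pos = 2L, ref = paste0("T", motif), alt = "T")
  }
}

# brute-force BH step-up oracle (literal definition)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m))
    adj_sorted[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# literal running-sum GSEA ES oracle (step-by-step loop)
gsea_es_oracle <- function(stat, members) {
  o <- order(stat, decreasing = TRUE)
  s <- stat[o]
  genes <- names(stat)[o]
  nr <- sum(abs(s[genes %in% members]))
  n_miss <- sum(!genes %in% members)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    if (genes[i] %in% members) {
      run <- run + if (nr == 0) 1 / sum(genes %in% members) else abs(s[i]) / nr
    } else {
      run <- run - 1 / n_miss
    }
    if (abs(run) > abs(best) + 1e-10) best <- run   # earliest peak on ties
  }
  unname(best)
}

# brute-force clustered-mutation oracle: enumerate every subset of size
# > max_in and test its inclusive span
clustered_oracle <- function(pos, window_bp = 10, max_in = 3) {
  n <- length(pos)
  dropped <- logical(n)
  if (n <= max_in) return(dropped)
  idx <- seq_len(n)
  for (size in (max_in + 1):n) {
    cmb <- utils::combn(idx, size)
    for (j in seq_len(ncol(cmb))) {
      sub <- cmb[, j]
      if (max(pos[sub]) - min(pos[sub]) + 1 <= window_bp) dropped[sub] <- TRUE
    }
  }
  dropped
}
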