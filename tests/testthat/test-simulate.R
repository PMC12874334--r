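test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(planted_deg_frac = 0), "\\(0, 1\\)")
  expect_error(sim_config(n_epi_up = 900, n_epi_down = 200), "exceeds")
  expect_error(
    simulate_genome_and_annotation(
      sim_config(n_genes = 5000, chrom_lengths = c(chr1 = 30000L))),
    "too small")
})

test_that("genome/annotation generation meets its contract", {
  cfg <- small_cfg()
  gen <- simulate_genome_and_annotation(cfg)
  expect_equal(nchar(gen$genome), c(chr1 = 200000L, chr2 = 200000L),
               ignore_attr = FALSE)
  ann <- gen$annotation
  expect_equal(nrow(ann), cfg$n_genes)
  # non-overlapping bodies per chromosome
  for (ch in names(gen$genome)) {
    a <- ann[ann$chrom == ch, ]
    a <- a[order(a$start), ]
    expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  }
  # TSS clearance and strand balance
  expect_true(all(ann$tss >= 1500 &
                    ann$tss <= cfg$chrom_lengths[ann$chrom] - 1500))
  expect_gt(mean(ann$strand == "+"), 0.35)
  expect_lt(mean(ann$strand == "+"), 0.65)
  # tiles partition each chromosome: 2 x 200 kb / 5 kb = 80 tiles
  expect_equal(nrow(gen$tiles), 80L)
  expect_equal(sum(gen$tiles$end - gen$tiles$start), 400000L)
  # determinism
  gen2 <- simulate_genome_and_annotation(cfg)
  expect_identical(gen, gen2)
  # all promoters have width exactly 2000
  pmap <- build_promoter_map(ann)
  expect_true(all(pmap$end - pmap$start == 2000L))
})

test_that("caller VCF simulation plants its designed structure", {
  cfg <- small_cfg(seed = 5)
  gen <- simulate_genome_and_annotation(cfg)
  sv <- simulate_caller_vcfs(cfg, gen$genome)
  v <- sv$variants
  n_callers <- lengths(strsplit(v$callers, ","))
  # caller support by construction
  expect_true(all(n_callers[v$class == "true_somatic"] >= 2))
  expect_true(all(n_callers[v$class == "decoy"] == 1))
  expect_true(all(n_callers[v$class == "germline"] == 4))
  # germline sites appear in every sample and in known_sites
  germ <- v[v$class == "germline", ]
  key <- paste(germ$chrom, germ$pos, germ$ref, germ$alt)
  expect_equal(unname(table(key)), rep(length(sv$samples), cfg$n_germline),
               ignore_attr = TRUE)
  expect_setequal(unique(key), paste(sv$known_sites$chrom, sv$known_sites$pos,
                                     sv$known_sites$ref, sv$known_sites$alt))
  # clusters: 4 variants within a 10-bp span, per sample
  cl <- v[v$class == "clustered", ]
  expect_equal(nrow(cl), 4L * cfg$n_clusters_per_sample * length(sv$samples))
  # shared artifacts appear in >= 2 samples
  sh <- v[v$class == "shared", ]
  n_samp <- tapply(sh$sample, paste(sh$chrom, sh$pos, sh$alt),
                   function(s) length(unique(s)))
  expect_true(all(n_samp >= 2))
  # determinism
  expect_identical(sv, simulate_caller_vcfs(cfg, gen$genome))
})

test_that("planted true-variant spectrum matches the target", {
  cfg <- sim_config(seed = 2, n_genes = 100, n_cpg = 500,
                    chrom_lengths = c(chr1 = 400000L, chr2 = 400000L),
                    n_mutations_per_sample = 1000, indel_frac = 0,
                    dbs_frac = 0, n_decoys_per_sample = 1, n_germline = 1,
                    n_clusters_per_sample = 1, n_shared_artifacts = 1,
                    n_epi_up = 2L, n_epi_down = 2L)
  gen <- simulate_genome_and_annotation(cfg)
  sv <- simulate_caller_vcfs(cfg, gen$genome)
  tr <- sv$variants[sv$variants$class == "true_somatic" &
                      sv$variants$sample == sv$samples[1], ]
  spec <- build_spectrum(tr, gen$genome, "SBS96")
  expect_gte(cosine_similarity(spec[, 1], sv$spectrum), 0.95)
})

test_that("expression simulation plants DEGs and stays deterministic", {
  cfg <- small_cfg(seed = 3)
  gen <- simulate_genome_and_annotation(cfg)
  expr <- simulate_expression(cfg, gen$annotation)
  tg <- expr$truth_genes
  expect_equal(sum(tg$is_deg), round(cfg$planted_deg_frac * cfg$n_genes))
  expect_true(all(abs(tg$log2fc[tg$is_deg]) >= cfg$expr_log2fc_mean))
  # empirical group ratio of planted DEGs respects the >= 2-fold contract
  des <- expr$design
  hdm <- des$sample[des$tissue == "normal" & des$treatment == "HDM"]
  veh <- des$sample[des$tissue == "normal" & des$treatment == "VEH"]
  up <- tg$gene_id[tg$direction == "up"]
  ratio <- rowMeans(expr$counts[up, hdm]) / (rowMeans(expr$counts[up, veh]) + 1)
  expect_gt(median(ratio), 2)
  # null genes centre near ratio 1 (log2 scale)
  null <- tg$gene_id[!tg$is_deg]
  lr <- log2((rowMeans(expr$counts[null, hdm]) + 1) /
               (rowMeans(expr$counts[null, veh]) + 1))
  expect_lt(abs(median(lr)), 0.15)
  expect_identical(expr, simulate_expression(cfg, gen$annotation))
})

test_that("methylation simulation respects support, nulls and truth wiring", {
  cfg <- small_cfg(seed = 4)
  gen <- simulate_genome_and_annotation(cfg)
  expr <- simulate_expression(cfg, gen$annotation)
  meth <- simulate_methylation(cfg, gen$annotation, expr)
  expect_true(all(meth$beta > 0 & meth$beta < 1))
  # non-planted sites have group delta-beta centred at 0
  des <- expr$design
  hdm <- des$sample[des$tissue == "normal" & des$treatment == "HDM"]
  veh <- des$sample[des$tissue == "normal" & des$treatment == "VEH"]
  null_sites <- meth$truth_cpgs$site_id[!meth$truth_cpgs$is_dms]
  d <- rowMeans(meth$beta[null_sites, hdm]) - rowMeans(meth$beta[null_sites, veh])
  expect_lt(abs(mean(d)), 0.01)
  # planted epi promoters: hyper_down genes gain promoter methylation under
  # exposure while their expression drops (and vice versa)
  tg <- expr$truth_genes
  pmap <- build_promoter_map(gen$annotation)
  pbeta <- promoter_beta_matrix(meth$beta, meth$sites, pmap)
  log_tpm <- log2(expr$tpm + 1)
  for (cls in c("hyper_down", "hypo_up")) {
    g <- tg$gene_id[tg$epi_class == cls]
    dbeta <- rowMeans(pbeta[g, hdm]) - rowMeans(pbeta[g, veh])
    dexpr <- rowMeans(log_tpm[g, hdm]) - rowMeans(log_tpm[g, veh])
    if (cls == "hyper_down") {
      expect_true(all(dbeta > 0.2) && all(dexpr < 0))
    } else {
      expect_true(all(dbeta < -0.2) && all(dexpr > 0))
    }
  }
})

test_that("simulate_study truth table is internally consistent", {
  cfg <- small_cfg(seed = 6)
  st <- simulate_study(cfg)
  tg <- st$truth$genes
  epi <- tg[tg$epi_class != "none", ]
  expect_equal(nrow(epi), cfg$n_epi_up + cfg$n_epi_down)
  # every epi gene is a DEG and a DMG with opposite directions
  expect_true(all(epi$is_deg & epi$is_dmg))
  expect_true(all(epi$direction[epi$epi_class == "hypo_up"] == "up"))
  expect_true(all(epi$direction[epi$epi_class == "hyper_down"] == "down"))
  # written study is byte-identical under the same seed
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  write_study(st, d1)
  write_study(simulate_study(cfg), d2)
  f <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
  unlink(c(d1, d2), recursive = TRUE)
})
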