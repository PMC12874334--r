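test_that("promoter map follows the strand-mirrored window", {
  ann <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(10000L, 10000L))
  pmap <- build_promoter_map(ann)
  expect_equal(pmap$start, c(8500L, 9501L))
  expect_equal(pmap$end, c(10500L, 11501L))
  expect_true(all(pmap$end - pmap$start == 2000L))
  expect_error(build_promoter_map(transform(ann, strand = "?")), "strand")
  # clipping warns
  ann2 <- data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 100L)
  expect_warning(p2 <- build_promoter_map(ann2,
                                          chrom_lengths = c(chr1 = 5000L)),
                 "clipped")
  expect_equal(p2$start, 0L)
})

test_that("derive_dmgs assigns significant CpGs by promoter overlap", {
  pmap <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     start = c(8500L, 10000L), end = c(10500L, 12000L),
                     strand = "+")
  sites <- data.frame(site_id = paste0("cg", 1:4), chrom = "chr1",
                      pos = c(9000L, 10250L, 11000L, 20000L))
  sd <- data.frame(feature = paste0("cg", 1:4),
                   mean_quot_log2 = c(0.5, 0.3, -0.2, 1),
                   p = c(0.01, 0.02, 0.04, 0.5))
  dmgs <- derive_dmgs(sd, sites, pmap)
  # cg1 -> g1; cg2 overlaps both promoters -> both genes; cg3 -> g2;
  # cg4 not significant
  expect_setequal(dmgs$gene_id, c("g1", "g2"))
  expect_equal(dmgs$n_sites[dmgs$gene_id == "g1"], 2L)
  expect_equal(dmgs$meth_log2fc[dmgs$gene_id == "g1"], mean(c(0.5, 0.3)))
  expect_equal(dmgs$meth_log2fc[dmgs$gene_id == "g2"], mean(c(0.3, -0.2)))
  # "top" aggregation takes the most significant CpG
  top <- derive_dmgs(sd, sites, pmap, aggregate = "top")
  expect_equal(top$meth_log2fc[top$gene_id == "g2"], 0.3)
  # no significant CpGs -> empty set
  expect_equal(nrow(derive_dmgs(transform(sd, p = 0.9), sites, pmap)), 0L)
})

test_that("quadrant classification applies both effect thresholds", {
  dmgs <- data.frame(gene_id = paste0("g", 1:5),
                     meth_log2fc = c(-0.5, -0.5, 0.15, 0.05, 0.3),
                     n_sites = 1L, min_p = 0.01)
  degs <- data.frame(gene = paste0("g", 1:5),
                     log2fc = c(2, 0.5, -1.2, -3, 2),
                     fdr = 0.01, is_deg = TRUE)
  quad <- classify_quadrants(dmgs, degs)
  expect_equal(quad$quadrant,
               c("hypo_up", "low_effect", "hyper_down", "low_effect",
                 "hyper_up"))
  # missing expression entries are skipped with a message
  dmgs2 <- rbind(dmgs, data.frame(gene_id = "gX", meth_log2fc = 1,
                                  n_sites = 1L, min_p = 0.01))
  expect_message(q2 <- classify_quadrants(dmgs2, degs), "skipped")
  expect_false("gX" %in% q2$gene)
})

test_that("quadrant labels swap correctly under treatment relabeling", {
  set.seed(3)
  n <- 40
  dmgs <- data.frame(gene_id = paste0("g", 1:n),
                     meth_log2fc = runif(n, -1, 1), n_sites = 1L,
                     min_p = 0.01)
  degs <- data.frame(gene = paste0("g", 1:n), log2fc = runif(n, -3, 3),
                     fdr = 0.01, is_deg = TRUE)
  fwd <- classify_quadrants(dmgs, degs)
  rev <- classify_quadrants(transform(dmgs, meth_log2fc = -meth_log2fc),
                            transform(degs, log2fc = -log2fc))
  map <- c(hyper_up = "hypo_down", hypo_down = "hyper_up",
           hyper_down = "hypo_up", hypo_up = "hyper_down",
           low_effect = "low_effect")
  expect_identical(unname(map[fwd$quadrant]), rev$quadrant)
})

test_that("inverse correlation screen applies boundary semantics", {
  samples <- paste0("s", 1:3)
  expr <- rbind(gA = c(9, 5, 1), gB = c(1, 5, 9), gC = c(4, 4.5, 5))
  beta <- rbind(gA = c(0.1, 0.5, 0.9), gB = c(0.1, 0.5, 0.9),
                gC = c(0.5, 0.5, 0.5))
  colnames(expr) <- colnames(beta) <- samples
  cand <- data.frame(gene = c("gA", "gB", "gC"),
                     rna_log2fc = c(2, 2, -2), meth_log2fc = c(-0.5, -0.5, 0.5),
                     quadrant = c("hypo_up", "hypo_up", "hyper_down"))
  res <- suppressMessages(
    inverse_correlation_filter(expr, beta, cand, samples))
  expect_equal(res$pearson_r[1], -1)
  expect_equal(res$epi_control, c("activated", "none", "none"))
  # constant vector excluded with a message
  expect_message(inverse_correlation_filter(expr, beta, cand[3, ], samples),
                 "constant")
  expect_error(inverse_correlation_filter(expr, beta, cand, samples[1:2]),
               ">= 3")
  # deg_genes restriction keeps the epi list inside DMG-and-DEG
  res2 <- suppressMessages(
    inverse_correlation_filter(expr, beta, cand, samples, deg_genes = "gB"))
  expect_true(all(res2$epi_control == "none"))
})

test_that("integration_report partitions the classified set", {
  rec <- data.frame(gene = paste0("g", 1:6),
                    quadrant = c("hyper_up", "hyper_down", "hypo_up",
                                 "hypo_up", "low_effect", "hypo_down"),
                    epi_control = c("none", "repressed", "activated",
                                    "none", "none", "none"))
  rep <- integration_report(rec, n_dmg = 10, n_deg = 4)
  expect_equal(sum(rep$quadrant_counts), nrow(rec))
  expect_equal(unname(rep$venn["n_intersection"]), nrow(rec))
  expect_equal(unname(rep$epi_control_counts[c("activated", "repressed")]),
               c(1L, 1L), ignore_attr = TRUE)
  empty <- integration_report(rec[0, ])
  expect_equal(sum(empty$quadrant_counts), 0L)
})

test_that("planted epi genes are recovered end to end (single seed)", {
  chain <- run_integration_chain(recovery_cfg(seed = 2))
  called <- chain$result$gene[chain$result$epi_control != "none"]
  planted <- chain$truth$gene_id[chain$truth$epi_class != "none"]
  sens <- length(intersect(called, planted)) / length(planted)
  prec <- length(intersect(called, planted)) / max(1, length(called))
  expect_gte(sens, 0.6)
  expect_gte(prec, 0.8)
  # epi genes are a subset of DMG and DEG
  expect_true(all(called %in% chain$dmgs$gene_id))
  expect_true(all(called %in% chain$de$gene[chain$de$is_deg]))
  # activated genes sit in the hypo_up quadrant, repressed in hyper_down
  act <- chain$result$gene[chain$result$epi_control == "activated"]
  repg <- chain$result$gene[chain$result$epi_control == "repressed"]
  expect_true(all(chain$result$quadrant[match(act, chain$result$gene)] ==
                    "hypo_up"))
  expect_true(all(chain$result$quadrant[match(repg, chain$result$gene)] ==
                    "hyper_down"))
})
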