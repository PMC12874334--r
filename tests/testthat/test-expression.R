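test_that("filter_low_counts applies the row-sum boundary", {
  m <- rbind(a = c(5, 4), b = c(5, 5), c = c(0, 0))
  out <- filter_low_counts(m)
  expect_identical(rownames(out), "b")   # row sum 9 removed, 10 kept
  expect_warning(filter_low_counts(matrix(0, 2, 2)), "no gene")
})

test_that("median-of-ratios size factors match the formula oracle", {
  cnt <- cbind(s1 = c(10, 20, 40, 80, 100), s2 = 2 * c(10, 20, 40, 80, 100))
  sf <- size_factors_median_of_ratios(cnt)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples -> all ones
  same <- cbind(a = c(3, 9, 27), b = c(3, 9, 27))
  expect_equal(unname(size_factors_median_of_ratios(same)), c(1, 1))
  # permutation equivariance
  cnt3 <- cbind(s1 = c(5, 50, 500), s2 = c(9, 90, 900), s3 = c(2, 22, 222))
  sf3 <- size_factors_median_of_ratios(cnt3)
  expect_equal(unname(size_factors_median_of_ratios(cnt3[, c(3, 1, 2)])),
               unname(sf3[c(3, 1, 2)]))
  expect_error(size_factors_median_of_ratios(cbind(c(1, 0), c(0, 1))),
               "no gene")
})

test_that("tmm_factors: contracts and edgeR oracle agreement", {
  set.seed(21)
  cnt <- matrix(rnbinom(600, mu = 60, size = 5), ncol = 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  f <- tmm_factors(cnt)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)  # geometric mean 1
  # identical samples -> all ones
  expect_equal(unname(tmm_factors(cbind(a = c(10, 20, 30, 40),
                                        b = c(10, 20, 30, 40)))), c(1, 1))
  # pure library-size difference -> factors 1 after library-size division
  expect_equal(unname(tmm_factors(cbind(cnt[, 1], 3 * cnt[, 1]))), c(1, 1),
               tolerance = 1e-9)
  skip_if_not_installed("edgeR")
  ref <- edgeR::calcNormFactors(cnt, method = "TMM")
  expect_equal(unname(f), unname(ref), tolerance = 1e-6)
})

test_that("nb_wald_de flags planted effects and nothing under the null", {
  # identical groups with equal counts -> log2fc exactly 0
  des <- data.frame(sample = paste0("s", 1:6),
                    tissue = "normal",
                    treatment = rep(c("HDM", "VEH"), each = 3))
  cnt <- matrix(50, nrow = 3, ncol = 6,
                dimnames = list(paste0("g", 1:3), des$sample))
  de <- nb_wald_de(cnt, des)
  expect_equal(de$log2fc, rep(0, 3))
  expect_error(nb_wald_de(cnt[, 1:4], des[c(1, 2, 3, 4), ]), ">= 2 samples")
  # power: planted log2FC = 3, low dispersion, n = 3 -> > 90% called
  set.seed(31)
  ng <- 600; n_sig <- 60
  q <- exp(rnorm(ng, log(300), 0.8))
  mu <- matrix(rep(q, 6), ncol = 6)
  mu[seq_len(n_sig), 1:3] <- mu[seq_len(n_sig), 1:3] * 8
  cnt <- matrix(rnbinom(ng * 6, mu = mu, size = 1 / 0.01), ncol = 6,
                dimnames = list(sprintf("g%03d", seq_len(ng)), des$sample))
  de <- nb_wald_de(cnt, des)
  expect_gt(mean(de$is_deg[seq_len(n_sig)]), 0.9)
  expect_lt(sum(de$is_deg[-seq_len(n_sig)]), 4)
  # DEG flag invariant: is_deg <=> fdr < 0.05 & |lfc| >= 1
  expect_identical(de$is_deg, de$fdr < 0.05 & abs(de$log2fc) >= 1)
  # gene/sample order invariance
  perm_g <- sample(ng); perm_s <- sample(6)
  de2 <- nb_wald_de(cnt[perm_g, perm_s], des[perm_s, ])
  expect_equal(de2$p[match(de$gene, de2$gene)], de$p, tolerance = 1e-12)
})

test_that("module_score centres, handles constants and ignores non-members", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(4, 6, 8), g3 = c(7, 7, 7))
  colnames(m) <- paste0("s", 1:3)
  sc <- module_score(m, c("g1", "g2"))
  expect_equal(sum(sc), 0, tolerance = 1e-12)   # z-scores centre
  # constant gene contributes z = 0
  expect_equal(unname(module_score(m, "g3")), c(0, 0, 0))
  # adding non-member genes does not change the score
  m2 <- rbind(m, g4 = c(100, 1, 50))
  expect_equal(module_score(m2, c("g1", "g2")), sc)
  expect_message(module_score(m, c("g1", "gX")), "missing")
  expect_error(module_score(m, "gZ"), "no gene-set member")
})

test_that("preranked_gsea matches the exhaustive running-sum oracle", {
  # top-ranked singleton with equal |stat| -> ES = 1
  s <- setNames(rep(2, 5), paste0("g", 1:5))
  r <- preranked_gsea(s, list(top = "g1"), n_perm = 200, seed = 1)
  expect_equal(r$es, 1)
  # reversing the ranking negates the ES
  s2 <- setNames(c(5, 4, 1, -2, -6), paste0("g", 1:5))
  es_fwd <- preranked_gsea(s2, list(a = c("g1", "g2")), n_perm = 50, seed = 1)$es
  es_rev <- preranked_gsea(-s2, list(a = c("g1", "g2")), n_perm = 50, seed = 1)$es
  expect_equal(es_rev, -es_fwd)
  expect_error(preranked_gsea(s2, list(all = paste0("g", 1:5)), 10, 1),
               "covers all")
  # oracle equivalence over all subsets for n = 2..8, several stat shapes
  set.seed(17)
  for (n in 2:8) {
    stats_list <- list(sort(rnorm(n), decreasing = TRUE),
                       seq(n, 1) - n / 2,      # signed, evenly spaced
                       rep(1, n))              # fully tied weights
    for (st in stats_list) {
      names(st) <- paste0("g", seq_len(n))
      sorted <- st[order(st, decreasing = TRUE)]   # stable, like the oracle
      for (mask in seq_len(2^n - 2)) {
        members <- names(st)[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
        if (length(members) %in% c(0, n)) next
        got <- hdmomics:::.gsea_es(sorted, names(sorted) %in% members)
        expect_equal(got, gsea_es_oracle(st, members), tolerance = 1e-12)
      }
    }
  }
})

test_that("gsea NES/p behave sensibly on a planted enrichment", {
  set.seed(23)
  st <- setNames(c(rnorm(20, 3), rnorm(180)), paste0("g", 1:200))
  r <- preranked_gsea(st, list(sig = paste0("g", 1:20),
                               rand = paste0("g", sample(21:200, 20))),
                      n_perm = 500, seed = 9)
  expect_equal(sign(r$nes), sign(r$es))
  expect_lt(r$p[r$set == "sig"], 0.01)
  expect_gt(r$p[r$set == "rand"], 0.05)
  expect_true(all(r$fdr >= r$p))
})

test_that("marker deconvolution scores and tests work end to end", {
  m <- rbind(a = c(5, 5, 5, 5), b = c(5, 5, 5, 5), c = c(1, 2, 3, 4))
  colnames(m) <- paste0("s", 1:4)
  sc <- marker_deconvolution(m, list(pop1 = c("a", "b"), pop2 = "c"))
  expect_equal(unname(sc["pop1", ]), rep(5, 4))
  # doubling TPM raises a log2 score by exactly 1 (pseudocount negligible
  # at high expression)
  tpm <- matrix(2^(m + 10), nrow = 3, dimnames = dimnames(m))
  s1 <- marker_deconvolution(log2(tpm + 1), list(p = "c"))
  s2 <- marker_deconvolution(log2(2 * tpm + 1), list(p = "c"))
  expect_equal(unname(s2 - s1), matrix(rep(1, 4), 1), tolerance = 1e-3)
  expect_warning(marker_deconvolution(m, list(p1 = "a", px = "zz")),
                 "omitted")
  # planted myeloid-up design recovered with Welch p < 0.05
  set.seed(41)
  expr <- matrix(rnorm(10 * 6, 5), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expr[1:4, 1:3] <- expr[1:4, 1:3] + 3
  sc <- marker_deconvolution(expr, list(myeloid = paste0("g", 1:4),
                                        lymphoid = paste0("g", 5:8)))
  tst <- deconvolution_test(sc, rep(c("HDM", "VEH"), each = 3))
  expect_lt(tst$p[tst$population == "myeloid"], 0.05)
  expect_gt(tst$p[tst$population == "lymphoid"], 0.05)
})

test_that("GMT round-trip and packaged modules", {
  sets <- list(A = c("x", "y"), B = c("z"))
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, p)
  expect_equal(read_gmt(p), sets)
  il <- il_module_gene_sets()
  expect_length(il$IL1_inflammasome, 17L)
  expect_length(il$IL17_targets, 12L)
  expect_true(all(c("Il1b", "Nlrp3", "Casp1") %in% il$IL1_inflammasome))
  expect_true(all(c("Cxcl1", "Lcn2", "S100a8") %in% il$IL17_targets))
})
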