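#' @title Bulk expression analysis
#' @description Count filtering, median-of-ratios and TMM normalization, a
#'   simplified per-gene negative-binomial Wald test for two-group contrasts,
#'   curated-module mean z-scores, preranked gene-set enrichment, and
#'   marker-set deconvolution scores.
#' @name expression
NULL

#' Remove genes with very low counts
#'
#' @param counts Gene-by-sample integer count matrix.
#' @param min_row_sum Minimum total count for a gene to be kept (default 10;
#'   rows with total below it are removed).
#' @return The filtered matrix, gene order preserved.
#' @export
filter_low_counts <- function(counts, min_row_sum = 10L) {
  keep <- rowSums(counts) >= min_row_sum
  if (!any(keep)) warning("filter_low_counts: no gene passes the filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-positive genes of the ratio between
#' the sample's count and the gene's geometric mean across samples.
#'
#' @param counts Gene-by-sample count matrix; at least one gene must be
#'   non-zero in every sample.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  loggm <- rowMeans(log(counts))
  use <- is.finite(loggm)
  if (!any(use))
    stop("size_factors_median_of_ratios: no gene expressed in all samples")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - loggm[use])))
  sf
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Per-sample scaling factors computed against a reference sample from the
#' weighted trimmed mean of per-gene log2 expression ratios (M-values),
#' double-trimmed on M (default 30%) and on average log intensity A (default
#' 5%), with inverse-variance weights. Factors are normalized to geometric
#' mean 1.
#'
#' @param counts Gene-by-sample count matrix (>= 2 samples).
#' @param ref_sample Optional reference column name/index; by default the
#'   sample whose upper quartile of scaled counts is closest to the mean.
#' @param logratio_trim,sum_trim Trim fractions for M and A.
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05) {
  if (ncol(counts) < 2L) stop("tmm_factors: need >= 2 samples")
  if (any(colSums(counts > 0) < 2L))
    stop("tmm_factors: degenerate sample with < 2 non-zero genes")
  lib <- colSums(counts)
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  refc <- counts[, ref_sample]
  nref <- lib[ref_sample]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; nobs <- lib[j]
    use <- obs > 0 & refc > 0
    o <- obs[use] / nobs; r <- refc[use] / nref
    M <- log2(o / r)
    A <- (log2(o) + log2(r)) / 2
    w <- (nobs - obs[use]) / (nobs * obs[use]) +
      (nref - refc[use]) / (nref * refc[use])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Simplified per-gene negative-binomial Wald differential expression
#'
#' Two-group contrast (treatment within one tissue). Counts are normalized
#' by size-factor offsets (median-of-ratios by default); the per-gene
#' dispersion is a method-of-moments estimate pooled across the two groups
#' with floor 1e-8 (no shrinkage, no outlier replacement, no independent
#' filtering); the Wald statistic log2FC/SE is referenced to a t
#' distribution with nA+nB-2 degrees of freedom (small-sample correction;
#' see the methods vignette); p-values are BH-adjusted. A gene is flagged a
#' DEG iff FDR < `fdr_max` and |log2FC| >= `lfc_min`.
#'
#' @param counts Filtered gene-by-sample count matrix.
#' @param design Data frame with `sample`, `tissue`, `treatment`.
#' @param tissue Tissue in which to contrast treatments.
#' @param treatment_levels Length-2 character vector `(A, B)`; log2FC is
#'   A over B (default HDM over VEH).
#' @param size_factors Optional precomputed factors (all samples of the
#'   contrast); defaults to median-of-ratios on the contrast submatrix.
#' @param fdr_max,lfc_min DEG thresholds (defaults 0.05 and 1).
#' @return Data frame (one row per gene): `gene`, `baseMean`, `log2fc`,
#'   `wald_stat`, `p`, `fdr`, `is_deg`, `direction`.
#' @export
nb_wald_de <- function(counts, design, tissue = "normal",
                       treatment_levels = c("HDM", "VEH"),
                       size_factors = NULL, fdr_max = 0.05, lfc_min = 1) {
  des <- design[match(colnames(counts), design$sample), ]
  sel <- which(des$tissue == tissue &
                 des$treatment %in% treatment_levels)
  cnt <- counts[, sel, drop = FALSE]
  grp <- des$treatment[sel]
  nA <- sum(grp == treatment_levels[1]); nB <- sum(grp == treatment_levels[2])
  if (nA < 2L || nB < 2L)
    stop("nb_wald_de: each contrast level needs >= 2 samples")
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(cnt)
  norm <- sweep(cnt, 2, size_factors, "/")
  A <- norm[, grp == treatment_levels[1], drop = FALSE]
  B <- norm[, grp == treatment_levels[2], drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  mu <- (mA + mB) / 2
  disp <- pmax(((vA + vB) / 2 - mu) / mu^2, 1e-8)
  l2 <- log(2)
  lfc <- log2(mA + 0.5) - log2(mB + 0.5)
  se <- sqrt((1 / l2^2) * ((1 / (mA + 0.5) + disp) / nA +
                             (1 / (mB + 0.5) + disp) / nB))
  stat <- lfc / se
  p <- 2 * stats::pt(-abs(stat), df = nA + nB - 2)
  fdr <- bh_adjust(p)$adjusted_p
  is_deg <- fdr < fdr_max & abs(lfc) >= lfc_min
  data.frame(gene = rownames(cnt), baseMean = rowMeans(norm),
             log2fc = lfc, wald_stat = stat, p = p, fdr = fdr,
             is_deg = is_deg,
             direction = ifelse(!is_deg, "none",
                                ifelse(lfc > 0, "up", "down")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean z-score module score
#'
#' Each member gene is z-scored across the samples in scope; the module
#' score of a sample is the mean z over the members present in the matrix.
#' Constant genes (sd = 0) contribute z = 0.
#'
#' @param log_expr Gene-by-sample log-scale expression matrix
#'   (log2(TPM+1)).
#' @param gene_set Character vector of member gene ids.
#' @param samples Optional subset of columns to score (z-scoring is computed
#'   within this scope); default all columns.
#' @return Named numeric vector, one score per sample in scope.
#' @export
module_score <- function(log_expr, gene_set, samples = NULL) {
  if (is.null(samples)) samples <- colnames(log_expr)
  present <- intersect(gene_set, rownames(log_expr))
  if (length(present) == 0L)
    stop("module_score: no gene-set member present in the matrix")
  if (length(present) < length(gene_set))
    message("module_score: ", length(gene_set) - length(present),
            " member(s) missing from the matrix")
  x <- log_expr[present, samples, drop = FALSE]
  mu <- rowMeans(x); sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd == 0, Inf, sd)
  colMeans(z)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score; returns the
# signed extremum and its rank position
.gsea_run <- function(stat_sorted, in_set) {
  nr <- sum(abs(stat_sorted[in_set]))
  n_miss <- sum(!in_set)
  if (nr == 0) {  # all member stats zero: equal hit weights
    step_hit <- in_set / sum(in_set)
  } else {
    step_hit <- ifelse(in_set, abs(stat_sorted) / nr, 0)
  }
  step_miss <- ifelse(in_set, 0, 1 / n_miss)
  run <- cumsum(step_hit - step_miss)
  # exact +/- ties of the extremum (possible with symmetric weights) are
  # broken toward the earliest rank position, robust to last-bit rounding
  peak <- which(abs(run) >= max(abs(run)) - 1e-10)[1]
  list(es = run[peak], peak = peak)
}

.gsea_es <- function(stat_sorted, in_set) .gsea_run(stat_sorted, in_set)$es

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score (weight =
#' |statistic|) on the ranking induced by `stats`, with gene-label
#' permutations for normalization: NES = ES divided by the mean |ES| of
#' same-sign permutation scores, permutation p-value, and BH-FDR across
#' sets.
#'
#' @param stats Named numeric vector (gene -> ranking statistic), no
#'   duplicated names.
#' @param gene_sets A list of gene-id vectors (or one vector).
#' @param n_perm Number of gene-label permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @return Data frame per set: `set`, `size`, `es`, `nes`, `p`, `fdr`, and
#'   a list-column `leading_edge`.
#' @export
preranked_gsea <- function(stats, gene_sets, n_perm = 10000L, seed = 1L) {
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (anyDuplicated(names(stats)))
    stop("preranked_gsea: duplicated gene names in ranking")
  o <- order(stats, decreasing = TRUE)
  s <- stats[o]
  genes <- names(s)
  n <- length(s)
  set.seed(seed)
  res <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], genes)
    k <- length(members)
    if (k == 0L) stop("preranked_gsea: set '", nm, "' has no ranked member")
    if (k == n) stop("preranked_gsea: set '", nm, "' covers all ranked genes")
    in_set <- genes %in% members
    run <- .gsea_run(s, in_set)
    es <- run$es
    perm_es <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, k)
      flag <- logical(n); flag[idx] <- TRUE
      .gsea_es(s, flag)
    }, numeric(1))
    same <- perm_es[sign(perm_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else sign(es) * Inf
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    le <- if (es >= 0) genes[seq_len(run$peak)][in_set[seq_len(run$peak)]]
    else genes[run$peak:n][in_set[run$peak:n]]
    data.frame(set = nm, size = k, es = es, nes = nes, p = p,
               stringsAsFactors = FALSE,
               leading_edge = I(list(le)))
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)$adjusted_p
  out[, c("set", "size", "es", "nes", "p", "fdr", "leading_edge")]
}

#' Marker-set deconvolution scores
#'
#' Population score = mean log2(TPM+1) over the population's marker genes,
#' per sample. Populations with no marker present are omitted with a
#' warning.
#'
#' @param log_expr Gene-by-sample log-scale expression matrix.
#' @param marker_sets Named list of marker gene-id vectors.
#' @return Population-by-sample numeric matrix.
#' @export
marker_deconvolution <- function(log_expr, marker_sets) {
  if (length(marker_sets) == 0L) stop("marker_deconvolution: no marker set")
  rows <- lapply(names(marker_sets), function(nm) {
    present <- intersect(marker_sets[[nm]], rownames(log_expr))
    if (length(present) == 0L) {
      warning("marker_deconvolution: population '", nm,
              "' has no marker present; omitted", call. = FALSE)
      return(NULL)
    }
    colMeans(log_expr[present, , drop = FALSE])
  })
  names(rows) <- names(marker_sets)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("marker_deconvolution: no population scored")
  do.call(rbind, rows)
}

#' Group comparison of deconvolution (or module) scores
#'
#' Two-sided Welch's t-test per population between two sample groups, with
#' BH-FDR across populations.
#'
#' @param scores Population-by-sample score matrix.
#' @param groups Character/factor vector aligned with columns of `scores`.
#' @param level_a,level_b The two group labels to compare (A vs B).
#' @return Data frame with `population`, `mean_a`, `mean_b`, `t`, `p`,
#'   `fdr`.
#' @export
deconvolution_test <- function(scores, groups, level_a = "HDM",
                               level_b = "VEH") {
  a <- groups == level_a; b <- groups == level_b
  res <- t(apply(scores, 1, function(x) {
    w <- welch_t_test(x[a], x[b])
    c(mean_a = mean(x[a]), mean_b = mean(x[b]), t = w$t, p = w$p)
  }))
  out <- data.frame(population = rownames(scores), res,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fdr <- bh_adjust(out$p)$adjusted_p
  out
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, members;
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1L))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1)), path)
}
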