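#' @title Differential DNA methylation
#' @description Site- and region-level differential methylation of CpG
#'   beta-value matrices: beta/M conversions, two-group differential calls
#'   at |delta-beta| >= 0.2 and p < 0.05 (significance tested on M-values,
#'   effect size reported on the beta scale), region aggregation over
#'   promoters, gene bodies, CpG islands and fixed-width tiles, and
#'   hyper/hypo counting.
#' @name methylation
NULL

#' Clamp beta values into the open unit interval
#'
#' @param beta Numeric vector/matrix of methylation fractions.
#' @param eps Clamp bound (default 1e-6): values are forced into
#'   `[eps, 1 - eps]`.
#' @return Clamped object of the same shape.
#' @export
clamp_beta <- function(beta, eps = 1e-6) pmin(pmax(beta, eps), 1 - eps)

#' Beta to M-value (logit2) conversion
#'
#' `M = log2(beta / (1 - beta))`; strictly increasing, inverted by
#' [m_to_beta()].
#'
#' @param beta Values strictly inside (0, 1) (inputs are expected to be
#'   pre-clamped with [clamp_beta()]).
#' @return M-values.
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) stop("beta_to_m: beta must lie in (0, 1)")
  log2(beta / (1 - beta))
}

#' M-value to beta conversion (inverse of [beta_to_m()])
#'
#' @param m M-values.
#' @return Beta values in (0, 1).
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

# vectorised two-group Welch test over matrix rows, run on M-values
.row_welch <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: both groups constant
  zero <- se2 == 0
  t[zero] <- ifelse(mA[zero] == mB[zero], 0, sign(mA - mB)[zero] * Inf)
  p[zero] <- ifelse(mA[zero] == mB[zero], 1, 0)
  df[zero] <- nA + nB - 2
  list(t = t, df = df, p = p)
}

#' Site-level differential methylation
#'
#' Per feature: delta-beta (group A minus group B, on the beta scale), the
#' mean-quotient log2 effect `log2((meanA + eps) / (meanB + eps))`, and a
#' two-sided Welch p-value computed on M-values. A feature is called
#' `hyper` iff delta-beta >= `delta_min` and p < `p_max`, `hypo` iff
#' delta-beta <= -`delta_min` and p < `p_max` (thresholds inclusive at the
#' delta bound).
#'
#' @param beta Feature-by-sample beta matrix (values in (0, 1)).
#' @param design Data frame with `sample`, `tissue`, `treatment` covering
#'   the columns.
#' @param tissue Tissue whose samples enter the contrast.
#' @param treatment_levels Length-2 vector `(A, B)` (default HDM vs VEH).
#' @param delta_min,p_max Call thresholds (defaults 0.2 and 0.05).
#' @param quot_eps Stabilizing offset of the mean-quotient (default 0.01).
#' @return Data frame: `feature`, `mean_beta_a`, `mean_beta_b`,
#'   `delta_beta`, `mean_quot_log2`, `p`, `call`.
#' @export
site_differential <- function(beta, design, tissue = "normal",
                              treatment_levels = c("HDM", "VEH"),
                              delta_min = 0.2, p_max = 0.05,
                              quot_eps = 0.01) {
  des <- design[match(colnames(beta), design$sample), ]
  a <- which(des$tissue == tissue & des$treatment == treatment_levels[1])
  b <- which(des$tissue == tissue & des$treatment == treatment_levels[2])
  if (length(a) < 2L || length(b) < 2L)
    stop("site_differential: each group needs >= 2 samples")
  A <- beta[, a, drop = FALSE]; B <- beta[, b, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  delta <- mA - mB
  w <- .row_welch(beta_to_m(clamp_beta(A)), beta_to_m(clamp_beta(B)))
  call <- rep("none", nrow(beta))
  # inclusive delta threshold, with a tiny slack so that group means landing
  # exactly on the boundary are not lost to floating-point representation
  eps <- 1e-12
  call[delta >= delta_min - eps & w$p < p_max] <- "hyper"
  call[delta <= -(delta_min - eps) & w$p < p_max] <- "hypo"
  data.frame(feature = rownames(beta), mean_beta_a = mA, mean_beta_b = mB,
             delta_beta = delta,
             mean_quot_log2 = log2((mA + quot_eps) / (mB + quot_eps)),
             p = w$p, call = call, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Aggregate CpG sites into region-level beta values
#'
#' Region beta = unweighted mean of member-site beta per sample. Intervals
#' are 0-based half-open: a site with 1-based position `p` belongs to a
#' region iff `start <= p - 1 < end`. Regions with no site are dropped (a
#' message reports the count).
#'
#' @param beta Site-by-sample beta matrix, rows named by site id.
#' @param sites Data frame with `site_id`, `chrom`, `pos` (1-based).
#' @param regions Data frame with `id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Region-by-sample beta matrix.
#' @export
aggregate_regions <- function(beta, sites, regions) {
  if (any(regions$end <= regions$start))
    stop("aggregate_regions: malformed region (end <= start)")
  sites <- sites[match(rownames(beta), sites$site_id), ]
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, width = 1))
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, site_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  by_region <- split(sh, qh)
  if (length(by_region) < nrow(regions))
    message("aggregate_regions: ", nrow(regions) - length(by_region),
            " region(s) without sites dropped")
  out <- do.call(rbind, lapply(by_region, function(rows)
    colMeans(beta[rows, , drop = FALSE])))
  rownames(out) <- regions$id[as.integer(names(by_region))]
  out
}

#' Region-level differential methylation
#'
#' [site_differential()] applied to a region-aggregated beta matrix.
#'
#' @inheritParams site_differential
#' @param region_beta Region-by-sample beta matrix from
#'   [aggregate_regions()].
#' @param ... Passed to [site_differential()].
#' @return As [site_differential()].
#' @export
region_differential <- function(region_beta, design, ...) {
  site_differential(region_beta, design, ...)
}

#' Hyper/hypo counts across feature classes
#'
#' @param results Named list of differential tables (one per feature class,
#'   e.g. sites, promoters, genes, cpg_islands, tiles), or a single table.
#' @return Data frame with `feature_class`, `n_hyper`, `n_hypo`, `n_tested`.
#' @export
count_dms <- function(results) {
  if (is.data.frame(results)) results <- list(features = results)
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(feature_class = nm,
               n_hyper = sum(r$call == "hyper"),
               n_hypo = sum(r$call == "hypo"),
               n_tested = nrow(r), stringsAsFactors = FALSE)
  }))
}
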