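#' @title Mutational spectrum classification
#' @description COSMIC-style classification of somatic mutations into the
#'   SBS96 (single-base substitutions by trinucleotide context), DBS78
#'   (doublet substitutions) and ID83 (small insertions/deletions by length,
#'   repeat context and microhomology) schemas, plus spectrum matrices and
#'   cosine similarity.
#' @name spectra
NULL

.as_genome <- function(genome) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  if (inherits(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome
}

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.rc <- function(x) {
  vapply(strsplit(x, ""), function(v)
    paste(rev(unname(.comp[v])), collapse = ""), character(1))
}

#' Canonical SBS96 category labels
#'
#' Ninety-six labels `X[R>A]Y` ordered by substitution class (C>A, C>G, C>T,
#' T>A, T>C, T>G), then 5' base, then 3' base.
#'
#' @return Character vector of length 96.
#' @export
sbs96_categories <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(u)
      paste0(u, "[", s, "]", bases)))))
}

# canonical DBS78 reference doublets and their alternate doublets
.dbs78_table <- list(
  AC = c("CA", "CG", "CT", "GA", "GG", "GT", "TA", "TG", "TT"),
  AT = c("CA", "CC", "CG", "GA", "GC", "TA"),
  CC = c("AA", "AG", "AT", "GA", "GG", "GT", "TA", "TG", "TT"),
  CG = c("AT", "GC", "GT", "TA", "TC", "TT"),
  CT = c("AA", "AC", "AG", "GA", "GC", "GG", "TA", "TC", "TG"),
  GC = c("AA", "AG", "AT", "CA", "CG", "TA"),
  TA = c("AT", "CG", "CT", "GC", "GG", "GT"),
  TC = c("AA", "AG", "AT", "CA", "CG", "CT", "GA", "GG", "GT"),
  TG = c("AA", "AC", "AT", "CA", "CC", "CT", "GA", "GC", "GT"),
  TT = c("AA", "AC", "AG", "CA", "CC", "CG", "GA", "GC", "GG"))

#' Canonical DBS78 category labels
#'
#' @return Character vector of length 78 (`REF>ALT` doublet labels in
#'   canonical COSMIC orientation and order).
#' @export
dbs78_categories <- function() {
  unlist(lapply(names(.dbs78_table), function(r)
    paste0(r, ">", .dbs78_table[[r]])))
}

#' Canonical ID83 category labels
#'
#' Eighty-three labels `L:Del|Ins:C|T|R|M:n`: 1-bp deletions/insertions
#' subtyped by the pyrimidine of the affected base with homopolymer-run bins
#' 0..5 (n = number of additional identical bases, 5 meaning 5 or more);
#' longer events binned by length (2, 3, 4, 5+) and repeat-unit count 0..5;
#' deletions not in a repeat additionally classified by microhomology length.
#'
#' @return Character vector of length 83.
#' @export
id83_categories <- function() {
  c(paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5),
    unlist(lapply(2:5, function(L) paste0(L, ":Del:R:", 0:5))),
    unlist(lapply(2:5, function(L) paste0(L, ":Ins:R:", 0:5))),
    "2:Del:M:1", "3:Del:M:1", "3:Del:M:2",
    paste0("4:Del:M:", 1:3), paste0("5:Del:M:", 1:5))
}

.ref_base <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " not in reference")
  L <- nchar(genome[[chrom]])
  if (start < 1L || end > L) stop("locus outside reference: ", chrom, ":", start)
  substr(genome[[chrom]], start, end)
}

#' Classify a single-base substitution into SBS96
#'
#' Pyrimidine-centric: purine-reference mutations are reverse-complemented
#' (together with their flanking context) before labelling.
#'
#' @param chrom,pos,ref,alt Variant (1-based position, single bases).
#' @param genome Named character vector (or DNAStringSet) of chromosome
#'   sequences.
#' @return The category label, or `NA_character_` if the context contains N.
#' @export
classify_sbs <- function(chrom, pos, ref, alt, genome) {
  genome <- .as_genome(genome)
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L, ref != alt)
  gref <- .ref_base(genome, chrom, pos, pos)
  if (gref != ref) stop("reference mismatch at ", chrom, ":", pos)
  ctx <- .ref_base(genome, chrom, pos - 1L, pos + 1L)
  if (grepl("N", ctx) || ref == "N" || alt == "N") return(NA_character_)
  up <- substr(ctx, 1, 1); dn <- substr(ctx, 3, 3)
  if (ref %in% c("G", "A")) {
    new_up <- .comp[[dn]]; new_dn <- .comp[[up]]
    ref <- .comp[[ref]]; alt <- .comp[[alt]]
    up <- new_up; dn <- new_dn
  }
  paste0(up, "[", ref, ">", alt, "]", dn)
}

#' Classify a doublet-base substitution into DBS78
#'
#' The doublet is mapped to the canonical COSMIC orientation
#' (reverse-complementing both reference and alternate when needed).
#' Doublets whose alternate shares a base with the reference at the same
#' position have no canonical category and are excluded (`NA`).
#'
#' @inheritParams classify_sbs
#' @return The category label, or `NA_character_` if unclassifiable.
#' @export
classify_dbs <- function(chrom, pos, ref, alt, genome) {
  genome <- .as_genome(genome)
  stopifnot(nchar(ref) == 2L, nchar(alt) == 2L)
  gref <- .ref_base(genome, chrom, pos, pos + 1L)
  if (gref != ref) stop("reference mismatch at ", chrom, ":", pos)
  if (grepl("N", paste0(ref, alt))) return(NA_character_)
  if (!is.null(.dbs78_table[[ref]]) && alt %in% .dbs78_table[[ref]])
    return(paste0(ref, ">", alt))
  rr <- .rc(ref); ra <- .rc(alt)
  if (!is.null(.dbs78_table[[rr]]) && ra %in% .dbs78_table[[rr]])
    return(paste0(rr, ">", ra))
  NA_character_
}

# strip the shared VCF anchor/affixes; returns the pure event or NULL
.normalize_indel <- function(pos, ref, alt) {
  # longest common prefix
  np <- 0L
  while (np < min(nchar(ref), nchar(alt)) &&
         substr(ref, np + 1L, np + 1L) == substr(alt, np + 1L, np + 1L))
    np <- np + 1L
  ref2 <- substr(ref, np + 1L, nchar(ref))
  alt2 <- substr(alt, np + 1L, nchar(alt))
  # longest common suffix of the remainder
  ns <- 0L
  while (ns < min(nchar(ref2), nchar(alt2)) &&
         substr(ref2, nchar(ref2) - ns, nchar(ref2) - ns) ==
         substr(alt2, nchar(alt2) - ns, nchar(alt2) - ns))
    ns <- ns + 1L
  ref2 <- substr(ref2, 1L, nchar(ref2) - ns)
  alt2 <- substr(alt2, 1L, nchar(alt2) - ns)
  if (nchar(ref2) > 0L && nchar(alt2) > 0L) return(NULL)  # complex
  if (nchar(ref2) == 0L && nchar(alt2) == 0L) return(NULL)
  list(start = pos + np,          # first affected ref base (del) or first
       motif = if (nchar(ref2)) ref2 else alt2,   # base after ins point
       type = if (nchar(ref2)) "Del" else "Ins")
}

#' Classify a small insertion or deletion into ID83
#'
#' The event is normalized (shared VCF anchor bases stripped) and
#' left-aligned against the reference before classification. One-bp events
#' are subtyped by the pyrimidine of the affected base with
#' homopolymer-run bins; longer events are binned by length and repeat-unit
#' count; deletions with no additional repeat copy are classified by
#' microhomology length when present.
#'
#' @inheritParams classify_sbs
#' @param ref,alt VCF-style reference and alternate alleles (anchored or
#'   pure); complex substitutions return `NA`.
#' @return The category label, or `NA_character_` if unclassifiable.
#' @export
classify_indel <- function(chrom, pos, ref, alt, genome) {
  genome <- .as_genome(genome)
  gref <- .ref_base(genome, chrom, pos, pos + nchar(ref) - 1L)
  if (gref != ref) stop("reference mismatch at ", chrom, ":", pos)
  ev <- .normalize_indel(pos, ref, alt)
  if (is.null(ev)) return(NA_character_)
  if (grepl("N", ev$motif)) return(NA_character_)
  seqc <- genome[[chrom]]
  L <- nchar(ev$motif)
  s <- ev$start
  # left-align: slide while the base before the event equals the motif tail
  while (s > 1L && substr(seqc, s - 1L, s - 1L) == substr(ev$motif, L, L)) {
    ev$motif <- paste0(substr(seqc, s - 1L, s - 1L),
                       substr(ev$motif, 1L, L - 1L))
    s <- s - 1L
  }
  # count tandem copies of the motif in the reference starting at s
  k <- 0L
  while (s + (k + 1L) * L - 1L <= nchar(seqc) &&
         substr(seqc, s + k * L, s + (k + 1L) * L - 1L) == ev$motif)
    k <- k + 1L
  if (L == 1L) {
    base <- ev$motif
    if (base %in% c("G", "A")) base <- .comp[[base]]
    n_extra <- if (ev$type == "Del") k - 1L else k
    return(paste0("1:", ev$type, ":", base, ":", min(n_extra, 5L)))
  }
  len_bin <- min(L, 5L)
  if (ev$type == "Ins")
    return(paste0(len_bin, ":Ins:R:", min(k, 5L)))
  # deletion: k includes the deleted copy itself
  if (k >= 2L) return(paste0(len_bin, ":Del:R:", min(k - 1L, 5L)))
  # no full additional copy: check microhomology on both flanks
  right <- 0L
  while (right < L - 1L &&
         s + L + right <= nchar(seqc) &&
         substr(seqc, s + L + right, s + L + right) ==
         substr(ev$motif, right + 1L, right + 1L))
    right <- right + 1L
  left <- 0L
  while (left < L - 1L && s - 1L - left >= 1L &&
         substr(seqc, s - 1L - left, s - 1L - left) ==
         substr(ev$motif, L - left, L - left))
    left <- left + 1L
  mh <- max(left, right)
  if (mh == 0L) return(paste0(len_bin, ":Del:R:0"))
  mh_cap <- if (len_bin == 5L) 5L else len_bin - 1L
  paste0(len_bin, ":Del:M:", min(mh, mh_cap))
}

.mutation_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) return("SBS")
  if (nr == 2L && na == 2L) return("DBS")
  if (nr != na) return("ID")
  "other"
}

#' Build a category-by-sample spectrum matrix
#'
#' Classifies every pass-status record of the matching mutation type under
#' the requested schema. Column sums equal the number of classified
#' mutations per sample; mutations excluded (ambiguous context, complex
#' events) are reported in the `excluded` attribute.
#'
#' @param records A `mutation_records` data frame (or any data frame with
#'   `sample`, `chrom`, `pos`, `ref`, `alt`; a `filter_status` column, if
#'   present, restricts to "pass").
#' @param genome Reference genome (named character vector or DNAStringSet).
#' @param schema One of "SBS96", "DBS78", "ID83".
#' @return Integer matrix (category x sample) with canonical category order;
#'   attribute `excluded` counts unclassifiable mutations per sample.
#' @export
build_spectrum <- function(records, genome, schema = c("SBS96", "DBS78", "ID83")) {
  schema <- match.arg(schema)
  genome <- .as_genome(genome)
  if (!is.null(records$filter_status))
    records <- records[records$filter_status == "pass", ]
  cats <- switch(schema, SBS96 = sbs96_categories(),
                 DBS78 = dbs78_categories(), ID83 = id83_categories())
  type <- switch(schema, SBS96 = "SBS", DBS78 = "DBS", ID83 = "ID")
  samples <- unique(records$sample)
  if (length(samples) == 0L) samples <- "sample"
  mat <- matrix(0L, nrow = length(cats), ncol = length(samples),
                dimnames = list(cats, samples))
  excluded <- stats::setNames(integer(length(samples)), samples)
  classify <- switch(schema, SBS96 = classify_sbs, DBS78 = classify_dbs,
                     ID83 = classify_indel)
  keep <- vapply(seq_len(nrow(records)), function(i)
    .mutation_type(records$ref[i], records$alt[i]) == type, logical(1))
  rec <- records[keep, , drop = FALSE]
  for (i in seq_len(nrow(rec))) {
    lab <- classify(rec$chrom[i], rec$pos[i], rec$ref[i], rec$alt[i], genome)
    if (is.na(lab)) excluded[rec$sample[i]] <- excluded[rec$sample[i]] + 1L
    else mat[lab, rec$sample[i]] <- mat[lab, rec$sample[i]] + 1L
  }
  attr(mat, "excluded") <- excluded
  attr(mat, "schema") <- schema
  mat
}

#' Cosine similarity between two spectra
#'
#' `dot(a, b) / (||a|| ||b||)`; scale-invariant, in `[0, 1]` for
#' non-negative spectra.
#'
#' @param a,b Non-negative numeric vectors of equal length, each with at
#'   least one non-zero entry.
#' @return A number in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("cosine_similarity: unequal lengths")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity: zero vector")
  sum(a * b) / (na * nb)
}

#' Pairwise cosine similarity table for spectrum columns
#'
#' @param mat Category-by-sample spectrum matrix.
#' @return Data frame with `sample_a`, `sample_b`, `cosine` for all unordered
#'   pairs.
#' @export
cosine_table <- function(mat) {
  sm <- colnames(mat)
  pairs <- utils::combn(seq_along(sm), 2)
  data.frame(sample_a = sm[pairs[1, ]], sample_b = sm[pairs[2, ]],
             cosine = apply(pairs, 2, function(ij)
               cosine_similarity(mat[, ij[1]], mat[, ij[2]])),
             stringsAsFactors = FALSE)
}
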