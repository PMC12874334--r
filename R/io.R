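#' @title Plain-text writers for the study artifacts
#' @name io
NULL

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rownames_as),
                    as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write the toy reference genome as FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output FASTA path.
#' @export
write_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

#' Read a reference genome FASTA into the internal representation
#'
#' @param path FASTA path.
#' @return Named character vector of chromosome sequences.
#' @export
read_fasta_genome <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  stats::setNames(as.character(dna), names(dna))
}

.vcf_header <- function(reference = "toy") {
  c("##fileformat=VCFv4.2",
    paste0("##reference=", reference),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

.write_vcf_body <- function(df, path, reference = "toy") {
  df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                   df$chrom, df$pos, df$ref, df$alt)
  writeLines(c(.vcf_header(reference), lines), path)
  invisible(path)
}

#' Write the simulated caller VCF quartets and the known-sites VCF
#'
#' Files are named `<sample>.<caller>.vcf` plus `known_sites.vcf`.
#'
#' @param sim A `sim_vcfs` object from [simulate_caller_vcfs()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_sim_vcfs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sm in sim$samples) {
    for (cl in sim$callers) {
      sel <- sim$variants$sample == sm &
        vapply(strsplit(sim$variants$callers, ","), function(cs) cl %in% cs,
               logical(1))
      p <- file.path(dir, paste0(sm, ".", cl, ".vcf"))
      .write_vcf_body(sim$variants[sel, ], p)
      paths <- c(paths, p)
    }
  }
  ks <- file.path(dir, "known_sites.vcf")
  .write_vcf_body(sim$known_sites, ks)
  invisible(c(paths, ks))
}

#' Write a complete simulated study to disk
#'
#' Emits the reference FASTA, per-sample per-caller VCFs plus the
#' known-sites VCF, count/TPM/beta matrices and coordinate tables (TSV),
#' BED region files, gene-set and marker GMT files, and the TruthTable
#' (JSON).
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$genome, file.path(dir, "reference.fa"))
  write_sim_vcfs(study$vcfs, file.path(dir, "vcf"))
  write_tsv(study$annotation, file.path(dir, "annotation.tsv"))
  bed <- function(df, path)
    write_tsv(df[, c("chrom", "start", "end", "id")], path)
  bed(study$cpg_islands, file.path(dir, "cpg_islands.bed"))
  bed(study$tiles, file.path(dir, "tiles.bed"))
  write_tsv(study$expression$counts, file.path(dir, "counts.tsv"), "gene")
  write_tsv(round(study$expression$tpm, 4), file.path(dir, "tpm.tsv"), "gene")
  write_tsv(study$expression$design, file.path(dir, "design.tsv"))
  write_gmt(study$expression$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_gmt(study$expression$marker_sets, file.path(dir, "marker_sets.gmt"))
  write_tsv(round(study$methylation$beta, 6), file.path(dir, "beta.tsv"),
            "site_id")
  write_tsv(study$methylation$sites, file.path(dir, "cpg_sites.tsv"))
  truth <- study$truth
  truth$spectrum <- as.list(truth$spectrum)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a spectrum matrix in SigProfiler-style layout
#'
#' First column `MutationType`, one column per sample.
#'
#' @param mat Category-by-sample spectrum matrix.
#' @param path Output TSV path.
#' @export
write_spectrum <- function(mat, path) {
  write_tsv(mat, path, rownames_as = "MutationType")
}
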