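#' @title Somatic mutation consolidation
#' @description Consolidates per-caller somatic VCFs into high-confidence
#'   catalogs: caller-consensus filtering, known-germline-site removal,
#'   cross-sample shared-mutation removal, clustered-mutation removal, and
#'   mutational burden. Records are plain data frames with columns `sample`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `callers` (comma-joined ids),
#'   `n_callers`, `filter_status`.
#' @name somatic-mutations
NULL

.new_records <- function(df) {
  df$n_callers <- vapply(strsplit(df$callers, ","), length, integer(1))
  if (is.null(df$filter_status)) df$filter_status <- rep("pass", nrow(df))
  class(df) <- c("mutation_records", "data.frame")
  df
}

.parse_vcf_body <- function(path) {
  lines <- readLines(path)
  body_ln <- which(!startsWith(lines, "#"))
  body_ln <- body_ln[nzchar(lines[body_ln])]
  if (length(body_ln) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines[body_ln], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 8L)
  if (length(bad))
    stop("malformed VCF row in ", basename(path), " at line ", body_ln[bad[1]],
         ": fewer than 8 tab-separated fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  ref <- vapply(fields, `[[`, character(1), 4L)
  alt <- vapply(fields, `[[`, character(1), 5L)
  bad <- which(is.na(pos) | pos < 1L | !grepl("^[ACGTN]+$", ref) |
                 !grepl("^[ACGTN,*.]+$", alt))
  if (length(bad))
    stop("malformed VCF row in ", basename(path), " at line ", body_ln[bad[1]],
         ": invalid POS/REF/ALT")
  # split multiallelic ALT into one record per alternate allele
  alts <- strsplit(alt, ",", fixed = TRUE)
  n <- lengths(alts)
  data.frame(chrom = rep(chrom, n), pos = rep(pos, n),
             ref = rep(ref, n), alt = unlist(alts),
             stringsAsFactors = FALSE)
}

#' Read per-sample, per-caller somatic VCF files
#'
#' Accumulates caller support per variant key `(chrom, pos, ref, alt)` within
#' each sample. Multiallelic rows are split into one record per alternate
#' allele; duplicate records within one caller file are deduplicated with a
#' warning; malformed rows raise an error naming the file and line.
#'
#' @param paths Character vector of VCF paths.
#' @param samples,callers Character vectors aligned with `paths` giving the
#'   sample and caller id of each file. If omitted, they are parsed from
#'   file names of the form `<sample>.<caller>.vcf`.
#' @return A `mutation_records` data frame, all records `filter_status`
#'   "pass".
#' @export
read_caller_vcfs <- function(paths, samples = NULL, callers = NULL) {
  if (is.null(samples) || is.null(callers)) {
    bn <- sub("\\.vcf$", "", basename(paths))
    parts <- strsplit(bn, ".", fixed = TRUE)
    if (any(lengths(parts) < 2L))
      stop("cannot parse sample/caller from file names; pass them explicitly")
    samples <- vapply(parts, function(p)
      paste(p[-length(p)], collapse = "."), character(1))
    callers <- vapply(parts, function(p) p[[length(p)]], character(1))
  }
  per_file <- lapply(seq_along(paths), function(i) {
    df <- .parse_vcf_body(paths[i])
    if (nrow(df) == 0L) return(NULL)
    key <- paste(df$chrom, df$pos, df$ref, df$alt)
    if (anyDuplicated(key)) {
      warning("duplicate records in ", basename(paths[i]),
              "; deduplicated", call. = FALSE)
      df <- df[!duplicated(key), ]
    }
    df$sample <- samples[i]
    df$caller <- callers[i]
    df
  })
  all <- do.call(rbind, per_file)
  if (is.null(all))
    return(.new_records(data.frame(sample = character(), chrom = character(),
                                   pos = integer(), ref = character(),
                                   alt = character(), callers = character(),
                                   stringsAsFactors = FALSE)))
  key <- paste(all$sample, all$chrom, all$pos, all$ref, all$alt, sep = "\r")
  first <- !duplicated(key)
  callers_by_key <- vapply(split(all$caller, key), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  rec <- all[first, c("sample", "chrom", "pos", "ref", "alt")]
  rec$callers <- callers_by_key[key[first]]
  rec <- rec[order(rec$sample, rec$chrom, rec$pos, rec$alt), ]
  rownames(rec) <- NULL
  .new_records(rec)
}

#' Read a sites-only VCF of known germline variants
#'
#' @param path Path to a VCF file.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @export
read_sites_vcf <- function(path) .parse_vcf_body(path)

#' Caller-consensus filter
#'
#' Retains variants reported by at least `min_callers` of the callers;
#' records below the threshold are marked `dropped_consensus`. Monotone:
#' raising `min_callers` never adds a passing record.
#'
#' @param records A `mutation_records` data frame.
#' @param min_callers Minimum caller support (default 2, "at least two of
#'   the four callers").
#' @return The records with updated `filter_status`.
#' @export
consensus_filter <- function(records, min_callers = 2L) {
  stopifnot(min_callers >= 1L)
  drop <- records$filter_status == "pass" & records$n_callers < min_callers
  records$filter_status[drop] <- "dropped_consensus"
  records
}

#' Known germline site filter
#'
#' Removes passing records whose `(chrom, pos, ref, alt)` exactly matches a
#' known germline site. Allele identity is required: a different alternate
#' allele at a known position is kept.
#'
#' @param records A `mutation_records` data frame.
#' @param known_sites Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @return The records with matches marked `dropped_known_site`.
#' @export
known_site_filter <- function(records, known_sites) {
  if (nrow(known_sites) == 0L) return(records)
  key <- paste(records$chrom, records$pos, records$ref, records$alt)
  kkey <- paste(known_sites$chrom, known_sites$pos, known_sites$ref,
                known_sites$alt)
  drop <- records$filter_status == "pass" & key %in% kkey
  records$filter_status[drop] <- "dropped_known_site"
  records
}

#' Cross-sample shared-mutation filter
#'
#' Any variant key passing in at least `min_samples` distinct samples is
#' marked `dropped_shared` in every sample (germline contamination /
#' recurrent artifact removal).
#'
#' @param records A `mutation_records` data frame covering all samples.
#' @param min_samples Minimum number of samples for a variant to count as
#'   shared (default 2; the upstream description says "multiple samples").
#' @return The records with shared variants marked.
#' @export
shared_mutation_filter <- function(records, min_samples = 2L) {
  pass <- records$filter_status == "pass"
  key <- paste(records$chrom, records$pos, records$ref, records$alt)
  n_samp <- tapply(records$sample[pass], key[pass],
                   function(s) length(unique(s)))
  shared <- names(n_samp)[n_samp >= min_samples]
  drop <- pass & key %in% shared
  records$filter_status[drop] <- "dropped_shared"
  records
}

# core scan: which sorted-order positions belong to a >max_in group whose
# inclusive span (max - min + 1) is <= window_bp
.clustered_positions <- function(pos, window_bp = 10L, max_in_window = 3L) {
  n <- length(pos)
  dropped <- logical(n)
  if (n <= max_in_window) return(dropped)
  o <- order(pos)
  p <- pos[o]
  hi <- findInterval(p + (window_bp - 1L), p)   # last index within span
  viol <- which(hi - seq_len(n) + 1L > max_in_window)
  for (i in viol) dropped[o[i:hi[i]]] <- TRUE
  dropped
}

#' Clustered-mutation filter
#'
#' Marks every passing variant that belongs to a group of more than
#' `max_in_window` variants whose positions span at most `window_bp` bases
#' (inclusive span, `max(pos) - min(pos) + 1 <= window_bp`), scanning each
#' sample and chromosome independently. Idempotent, and order-free: the
#' result does not depend on input row order.
#'
#' @param records A `mutation_records` data frame.
#' @param window_bp Window width in bp (default 10).
#' @param max_in_window Maximum allowed variants within a window (default 3;
#'   the rule is "> 3 mutations within a 10 bp window").
#' @return The records with clustered variants marked `dropped_clustered`.
#' @export
clustered_mutation_filter <- function(records, window_bp = 10L,
                                      max_in_window = 3L) {
  pass_idx <- which(records$filter_status == "pass")
  if (length(pass_idx) == 0L) return(records)
  grp <- paste(records$sample[pass_idx], records$chrom[pass_idx], sep = "\r")
  for (idx in split(pass_idx, grp)) {
    dr <- .clustered_positions(records$pos[idx], window_bp, max_in_window)
    records$filter_status[idx[dr]] <- "dropped_clustered"
  }
  records
}

#' Apply the full post-calling filter chain
#'
#' Fixed order: consensus, known-site, shared-mutation, clustered-mutation.
#' Re-running the chain on its own output is a no-op. An audit log of
#' per-filter drop counts is attached as attribute `audit`.
#'
#' @param records A `mutation_records` data frame (all samples).
#' @param known_sites Data frame of known germline sites (may be empty).
#' @param min_callers,min_samples,window_bp,max_in_window Filter parameters;
#'   defaults are the published values.
#' @return Filtered records with attribute `audit`.
#' @export
filter_pipeline <- function(records, known_sites = NULL, min_callers = 2L,
                            min_samples = 2L, window_bp = 10L,
                            max_in_window = 3L) {
  n_pass <- function(r) sum(r$filter_status == "pass")
  audit <- c(input = n_pass(records))
  records <- consensus_filter(records, min_callers)
  audit["after_consensus"] <- n_pass(records)
  if (!is.null(known_sites)) records <- known_site_filter(records, known_sites)
  audit["after_known_site"] <- n_pass(records)
  records <- shared_mutation_filter(records, min_samples)
  audit["after_shared"] <- n_pass(records)
  records <- clustered_mutation_filter(records, window_bp, max_in_window)
  audit["after_clustered"] <- n_pass(records)
  attr(records, "audit") <- audit
  records
}

#' Mutational burden per sample
#'
#' @param records A `mutation_records` data frame; only `filter_status ==
#'   "pass"` records are counted.
#' @param callable_mb Callable sequence in megabases (must be positive).
#' @return Data frame with `sample`, `n_mutations`, `callable_mb`, `burden`
#'   (mutations per Mb).
#' @export
mutational_burden <- function(records, callable_mb) {
  if (!is.numeric(callable_mb) || callable_mb <= 0)
    stop("mutational_burden: callable_mb must be positive")
  pass <- records[records$filter_status == "pass", ]
  n <- table(factor(pass$sample, levels = unique(records$sample)))
  data.frame(sample = names(n), n_mutations = as.integer(n),
             callable_mb = callable_mb,
             burden = as.numeric(n) / callable_mb,
             stringsAsFactors = FALSE)
}
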