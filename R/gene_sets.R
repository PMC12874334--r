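#' Packaged curated gene-set modules
#'
#' Returns the curated IL-1/inflammasome and IL-17 downstream-target gene
#' modules (mouse gene symbols) that ship with the package as a GMT file
#' under `extdata/gene_sets/il_modules.gmt`. These are the module
#' definitions used for module scoring and preranked enrichment on real
#' data; the synthetic generator plants its own stand-in sets.
#'
#' @return Named list with elements `IL1_inflammasome` (17 genes) and
#'   `IL17_targets` (12 genes).
#' @export
il_module_gene_sets <- function() {
  read_gmt(system.file("extdata", "gene_sets", "il_modules.gmt",
                       package = "hdmomics", mustWork = TRUE))
}
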