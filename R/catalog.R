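# Bundled catalog of the six ADAR-edited sites reported in hippocampal
# exosome-enriched fractions, with their miRBase v21 mature sequences.
# Each mature sequence is carried as its own reference record (mature
# window = whole sequence) since hairpin context is not needed for seed or
# motif annotation.

#' The bundled edited-site catalog
#'
#' Six A>G edited sites on mouse miRNAs (miR-411-5p position 5, miR-376b-3p
#' position 6, miR-3099-3p position 7, miR-381-3p position 7, miR-421-3p
#' position 14, miR-378a-3p position 16) together with their miRBase v21
#' mature sequences, for seed classification and motif-context analysis.
#'
#' @param seed_start,seed_end seed window applied to the catalog reference.
#' @return list: `sites` (tibble mature_id, position, substitution, extent)
#'   and `reference` (a `mirna_reference` over the mature sequences).
#' @export
edited_site_catalog <- function(seed_start = 2L, seed_end = 8L) {
  fa <- system.file("extdata", "edited_matures_mirbase_v21.fa",
                    package = "exomir", mustWork = TRUE)
  tsv <- system.file("extdata", "edited_sites_catalog.tsv",
                     package = "exomir", mustWork = TRUE)
  seqs <- Biostrings::readBStringSet(fa)
  sites <- as_tibble(read.delim(tsv, sep = "\t", stringsAsFactors = FALSE))
  ref <- mirna_reference(
    gene_id = names(seqs),
    hairpin_seq = as.character(seqs),
    mature_id = names(seqs),
    mature_start = 1L,
    mature_end = nchar(as.character(seqs)),
    seed_start = seed_start, seed_end = seed_end)
  list(sites = sites, reference = ref)
}
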