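# Shared in-code fixtures: tiny references and design tables built fresh in
# each test run.

# Two-gene toy reference with 20-nt matures inside 32-nt hairpins.
toy_reference <- function() {
  mirna_reference(
    gene_id = c("toy-mir-1", "toy-mir-2"),
    hairpin_seq = c(
      paste0("GGGGGG", "UAGCUAGCAAUGGCAUCGAU", "CCCCCC"),
      paste0("AAAAAA", "CGAUCGGAUUCAGGCAUUAC", "UUUUUU")),
    mature_id = c("toy-miR-1-5p", "toy-miR-2-3p"),
    mature_start = c(7L, 7L),
    mature_end = c(26L, 26L))
}

# Minimal single-method design: n replicates x {control, KA} x {24h, 2wk}.
toy_design <- function(n_replicates = 3L, methods = "UC") {
  simulate_design(n_replicates, methods = methods)
}

# Config with equal expected abundance for every reference miRNA and a
# near-constant library size.
flat_config <- function(design, seed = 1L, lib = 2e4, ...) {
  simulation_config(design, seed = seed, library_size_mean = lib,
                    library_size_dispersion = 1e6, abundance_logsd = 0,
                    sample_logsd = 0, ...)
}
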