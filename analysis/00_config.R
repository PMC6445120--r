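# Shared study configuration for the analysis drivers.
# A pair of 5-Mb genomes diverged from a common ancestor, with a realistic
# mix of shared and genotype-specific LTR-RT events, masked gaps in
# genome B, and genome-wide divergence near the observed cultivar SNP
# density (~2 differences per kb).

library(genomepair)

ANALYSIS_SEED <- 20190402L

analysis_config <- function() {
  sim_config(seed = ANALYSIS_SEED,
             n_chromosomes = 2L,
             chrom_length = 2.5e6,
             gc_fraction = 0.38,
             snp_rate = 0.002,
             n_shared = 60L,
             n_insertions_A = 30L,
             n_insertions_B = 15L,
             n_eliminations = 10L,
             n_gaps = 20L)
}

results_dir <- function(stage) {
  d <- file.path("results", stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

analysis_sim <- function() {
  # deterministic: every driver reconstructs the identical pair
  simulate_pair(analysis_config())
}
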