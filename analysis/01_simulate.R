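#!/usr/bin/env Rscript
# Simulate the genome pair and write the FASTA files plus the truth ledger.

source("analysis/00_config.R")

sim <- analysis_sim()
dir <- results_dir("sim")
write_simulation(sim, dir)

cat("Simulated pair written to", dir, "\n")
cat("  genome A:", sum(Biostrings::width(sim$genome_A)), "bp,",
    "genome B:", sum(Biostrings::width(sim$genome_B)), "bp\n")
cat("  SNPs:", nrow(sim$truth$snps),
    "| indels:", nrow(sim$truth$indels),
    "| TE events:", nrow(sim$truth$te_events),
    "| masked gaps:", nrow(sim$truth$gaps), "\n")
print(table(sim$truth$te_events$class))
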