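#!/usr/bin/env Rscript
# Assembly QC: telomere arrays, heterochromatin-like windows, per-chromosome
# statistics for both simulated genomes, and the tabulation of the published
# two-cultivar chromosome table shipped with the package.

source("analysis/00_config.R")

sim <- analysis_sim()
dir <- results_dir("qc")

for (g in c("A", "B")) {
  genome <- if (g == "A") sim$genome_A else sim$genome_B
  tel <- detect_telomeres(genome, min_copies = 100L)
  st <- assembly_stats(genome, tel)
  write.table(tel, file.path(dir, paste0("telomeres_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(st$per_chrom, file.path(dir, paste0("chrom_stats_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "genome %s: %d bp, contig N50 %d, %d gaps, telomeres %d (Both %d / Single %d)\n",
    g, st$summary$total_length, st$summary$contig_n50, st$summary$n_gaps,
    st$summary$telomeres_total, st$summary$telomere_both,
    st$summary$telomere_single))
}

# repeat annotation from the truth ledger drives the heterochromatin scan;
# the simulated genomes are too repeat-poor to carry dense blocks, so this
# records the (empty) scan alongside the window parameters used
te <- sim$truth$te_events
reps <- te[!is.na(te$a_elem_start),
           c("chrom", "a_elem_start", "a_elem_end")]
names(reps) <- c("chrom", "start", "end")
lens <- setNames(Biostrings::width(sim$genome_A), names(sim$genome_A))
het <- scan_heterochromatin(reps, lens)
write.table(het, file.path(dir, "heterochromatin_blocks_A.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("heterochromatin-like blocks in A:", nrow(het), "\n")

# tabulation of the published chromosome table
tab <- read_chrom_table(system.file("extdata",
                                    "hfth1_gddh13_chrom_stats.tsv",
                                    package = "genomepair"))
s <- chrom_table_summary(tab[tab$genome == "HFTH1", ])
cat(sprintf(
  "published table: %d telomeres (%d both-end chromosomes), max chromosome %d bp\n",
  s$telomeres_total, s$n_both, s$max_length))
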