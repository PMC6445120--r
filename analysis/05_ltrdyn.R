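#!/usr/bin/env Rscript
# LTR retrotransposon dynamics: detect intact elements, classify them
# across the pair, date insertions from LTR-LTR divergence, profile
# cumulative nucleotide substitutions (CNS) around elements, relate flank
# CNS to element age, and summarise insertion sites relative to genes.

source("analysis/00_config.R")

sim <- analysis_sim()
dir <- results_dir("ltrdyn")

det <- detect_intact_ltr(sim$genome_A)
cat("intact elements detected in A:", nrow(det), "\n")

cls <- classify_cross_genome(det, sim$genome_A, sim$genome_B)
print(ltr_class_counts(cls))

cls$t_ltr <- insertion_time(cls$K, rate = 1.3e-8)
cat(sprintf("mean insertion time %.2f MY (raw clock at 1.3e-8/site/yr)\n",
            mean(cls$t_ltr, na.rm = TRUE) / 1e6))

cls <- flank_substitutions(cls, sim$genome_A, sim$genome_B)
cfg <- analysis_config()
cls$v_rate <- ifelse(
  !is.na(cls$s_f) & !is.na(cls$s_c) & cls$t_ltr > 0,
  cns_rate(cls$s_f, cls$s_c, pmax(cls$t_ltr, 1),
           cfg$divergence_time_years),
  NA_real_)
write.table(cls, file.path(dir, "classified_elements.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

prof <- cns_profile(cls, sim$genome_A, sim$genome_B, flank_len = 2000L,
                    n_control = 50L, control_len = 10000L,
                    seed = ANALYSIS_SEED, interior = TRUE)
write.table(prof$flank, file.path(dir, "cns_flank_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(prof$interior, file.path(dir, "cns_interior_bins.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(prof$control, file.path(dir, "cns_control_blocks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("flank CNS %.4f near elements vs control %.4f\n",
            mean(prof$flank$mean_s[prof$flank$offset == 0], na.rm = TRUE),
            mean(prof$control$s)))

curve <- cns_vs_time(cls[!is.na(cls$s_f) & !is.na(cls$t_ltr), ])
write.table(curve$curve, file.path(dir, "cns_vs_time.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# insertion sites of A-specific elements relative to a simulated gene set
lens <- setNames(Biostrings::width(sim$genome_B), names(sim$genome_B))
genes <- simulate_genes(lens, fraction = 0.2222, seed = ANALYSIS_SEED)
te <- sim$truth$te_events
sites <- te[te$class == "insertion_A", c("chrom", "b_repl_start")]
names(sites) <- c("chrom", "pos")
gd <- gene_distance_distribution(sites, genes, lens, seed = ANALYSIS_SEED)
write.table(gd$histogram, file.path(dir, "gene_distance_hist.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("genic genome fraction %.4f; insertions inside genes %.4f\n",
            gd$genic_fraction, gd$inside_fraction))
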