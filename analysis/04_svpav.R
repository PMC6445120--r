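#!/usr/bin/env Rscript
# Structural and presence/absence variation: whole-genome anchoring chain,
# PAV detection with the cross-genotype depth filter, flank-realignment
# validation of truth-derived indel candidates, sharing classification
# against a parity panel and repeat-class breakpoint annotation.

source("analysis/00_config.R")

sim <- analysis_sim()
dir <- results_dir("svpav")

blocks <- align_block_chain(sim$genome_A, sim$genome_B)
cat("aligned blocks:", nrow(blocks), "\n")

pav <- detect_pav(blocks, sim$genome_A, sim$genome_B,
                  simulate_depth(sim, "A", 30),
                  simulate_depth(sim, "B", 30))
write.table(pav, file.path(dir, "pav_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
expected <- expected_pavs(sim$truth, min_len = 500L)
cat(sprintf("PAV calls: %d (%d deletions / %d insertions); expected >=500 bp events: %d\n",
            nrow(pav), sum(pav$kind == "deletion"),
            sum(pav$kind == "insertion"), nrow(expected)))

# validate indel candidates derived from the truth ledger
te <- sim$truth$te_events
cands <- list()
for (i in seq_len(nrow(te))) {
  if (te$class[i] == "insertion_A")
    cands[[length(cands) + 1L]] <- list(
      kind = "insertion", chrom = te$chrom[i], start = te$b_repl_start[i],
      end = te$b_repl_end[i],
      length = te$a_elem_end[i] - te$a_elem_start[i])
  if (te$class[i] == "insertion_B")
    cands[[length(cands) + 1L]] <- list(
      kind = "deletion", chrom = te$chrom[i], start = te$b_elem_start[i],
      end = te$b_elem_end[i],
      length = te$b_elem_end[i] - te$b_elem_start[i])
}
val <- do.call(rbind, lapply(cands, validate_indel,
                             genome_b = sim$genome_B,
                             genome_a = sim$genome_A))
write.table(val, file.path(dir, "validated_indels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("indel candidates validated: %d/%d\n", sum(val$validated),
            nrow(val)))

# sharing classification of PAVs against a parity panel of genome B and a
# donor-exclusion check (here: the same genotype, so shared == consistent)
ctx <- function(v) {
  genome <- if (v$genome == "A") sim$genome_A else sim$genome_B
  lo <- max(0, v$start - 500L)
  hi <- min(Biostrings::width(genome)[match(v$chrom, names(genome))],
            v$end + 500L)
  as.character(Biostrings::subseq(genome[[v$chrom]], lo + 1, hi))
}
pav$shared <- vapply(seq_len(nrow(pav)), function(j) {
  present <- variant_present(ctx(pav[j, ]), sim$genome_B)
  classify_shared(rep(present, 3), donor_present = FALSE)
}, logical(1))

# breakpoint annotation against the truth-derived repeat track
reps <- te[!is.na(te$a_elem_start), c("chrom", "a_elem_start", "a_elem_end")]
names(reps) <- c("chrom", "start", "end")
reps$class <- "LTR"
ann <- annotate_breakpoints(pav[pav$genome == "A", ], reps)
write.table(ann, file.path(dir, "pav_annotated_A.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("A-side PAVs overlapping LTR annotation:",
    sum(ann$repeat_class == "LTR"), "of", nrow(ann), "\n")
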