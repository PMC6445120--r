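# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a 1-Mb pair carrying every event type, small telomeres for speed
sim_small <- function() {
  fixture("sim_small", function() {
    cfg <- sim_config(seed = 101L, n_chromosomes = 1L, chrom_length = 1e6,
                      n_shared = 5L, n_insertions_A = 4L, n_insertions_B = 3L,
                      n_eliminations = 2L, n_gaps = 3L, snp_rate = 0.002,
                      telomere_copies_range = c(30L, 40L))
    simulate_pair(cfg)
  })
}

# detection + classification on sim_small, reused by several tests
cls_small <- function() {
  fixture("cls_small", function() {
    sim <- sim_small()
    det <- detect_intact_ltr(sim$genome_A)
    classify_cross_genome(det, sim$genome_A, sim$genome_B)
  })
}

random_dna_str <- function(n, seed = 1) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# truth class (4-way) matching the classifier's labels
truth_class4 <- function(cls) {
  c(shared = "Shared", insertion_A = "Insertion",
    elimination_B = "Elimination", insertion_B = NA_character_)[cls]
}

pred_class4 <- function(cls) sub("High|Low", "", cls)

# reciprocal-overlap matching of PAV calls against expected events
pav_match_stats <- function(pav, expected) {
  ovl <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  recall <- vapply(seq_len(nrow(expected)), function(i) {
    any(vapply(seq_len(nrow(pav)), function(j) {
      pav$genome[j] == expected$genome[i] &&
        pav$chrom[j] == expected$chrom[i] &&
        ovl(expected$start[i], expected$end[i], pav$start[j], pav$end[j]) >=
          0.5 * (expected$end[i] - expected$start[i])
    }, logical(1)))
  }, logical(1))
  precision <- vapply(seq_len(nrow(pav)), function(j) {
    any(vapply(seq_len(nrow(expected)), function(i) {
      pav$genome[j] == expected$genome[i] &&
        pav$chrom[j] == expected$chrom[i] &&
        ovl(expected$start[i], expected$end[i], pav$start[j], pav$end[j]) >=
          0.5 * (pav$end[j] - pav$start[j])
    }, logical(1)))
  }, logical(1))
  list(recall = mean(recall), precision = mean(precision))
}
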