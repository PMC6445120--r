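test_that("ancestor generation respects length, alphabet, GC and seed", {
  cfg <- sim_config(seed = 1L, n_chromosomes = 1L, chrom_length = 1e5,
                    gc_fraction = 0.5, n_shared = 0L, n_insertions_A = 0L,
                    n_insertions_B = 0L, n_eliminations = 0L, n_gaps = 0L)
  anc <- generate_ancestor(cfg)
  expect_equal(Biostrings::width(anc), 100000L)
  freq <- Biostrings::alphabetFrequency(anc[[1]])
  expect_equal(freq[["N"]], 0L)
  expect_identical(as.character(anc), as.character(generate_ancestor(cfg)))

  cfg38 <- sim_config(seed = 2L, n_chromosomes = 1L, chrom_length = 1e6,
                      gc_fraction = 0.38, n_gaps = 0L)
  a38 <- generate_ancestor(cfg38)
  f <- Biostrings::alphabetFrequency(a38[[1]])
  gc <- (f[["G"]] + f[["C"]]) / 1e6
  expect_lt(abs(gc - 0.38), 0.01)
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(gc_fraction = 1.2), "gc_fraction")
  expect_error(sim_config(chrom_length = -5), "positive")
  expect_error(sim_config(tsd_length_range = c(3, 6)), "4, 6")
  expect_error(sim_config(chrom_length = 10000), "10x")
})

test_that("a configuration with no events yields identical descendants", {
  cfg <- sim_config(seed = 3L, n_chromosomes = 1L, chrom_length = 1e5,
                    snp_rate = 0, small_indel_rate = 0, n_shared = 0L,
                    n_insertions_A = 0L, n_insertions_B = 0L,
                    n_eliminations = 0L, n_gaps = 0L,
                    telomere_copies_range = c(10L, 12L))
  sim <- simulate_pair(cfg)
  expect_identical(as.character(sim$genome_A), as.character(sim$genome_B))
  # descendants are the ancestor plus terminal telomere arrays
  telo <- sim$truth$telomeres
  pre <- 7L * telo$copies[telo$end == "5prime"]
  post <- 7L * telo$copies[telo$end == "3prime"]
  expect_equal(Biostrings::width(sim$genome_A), 1e5 + pre + post)
  expect_equal(substr(as.character(sim$genome_A[[1]]), pre + 1, pre + 1e5),
               as.character(sim$ancestor[[1]]))
  expect_equal(nrow(sim$truth$snps), 0L)
  expect_equal(nrow(sim$truth$te_events), 0L)
})

test_that("the requested SNP count appears exactly and nowhere else", {
  cfg <- sim_config(seed = 4L, n_chromosomes = 1L, chrom_length = 1e5,
                    n_snps = 10L, small_indel_rate = 0, n_shared = 0L,
                    n_insertions_A = 0L, n_insertions_B = 0L,
                    n_eliminations = 0L, n_gaps = 0L,
                    telomere_copies_range = c(10L, 12L))
  sim <- simulate_pair(cfg)
  expect_equal(nrow(sim$truth$snps), 10L)
  # direct diff oracle: with no other events both genomes have equal length
  a <- strsplit(as.character(sim$genome_A[[1]]), "")[[1]]
  b <- strsplit(as.character(sim$genome_B[[1]]), "")[[1]]
  expect_equal(sort(which(a != b) - 1L), sort(sim$truth$snps$pos_A))
})

test_that("TE insertions carry the TSD structure the classifier relies on", {
  sim <- sim_small()
  te <- sim$truth$te_events
  expect_gt(nrow(te), 0L)
  getA <- function(ch, s, e)
    as.character(Biostrings::subseq(sim$genome_A[[ch]], s + 1, e))
  getB <- function(ch, s, e)
    as.character(Biostrings::subseq(sim$genome_B[[ch]], s + 1, e))
  for (i in seq_len(nrow(te))) {
    tl <- te$tsd_len[i]
    expect_true(tl >= 4 && tl <= 6)
    if (!is.na(te$a_elem_start[i])) {
      # two TSD copies flank the element in the carrier
      expect_equal(getA(te$chrom[i], te$a_elem_start[i] - tl,
                        te$a_elem_start[i]), te$tsd[i])
      expect_equal(getA(te$chrom[i], te$a_elem_end[i],
                        te$a_elem_end[i] + tl), te$tsd[i])
      expect_equal(getA(te$chrom[i], te$a_elem_start[i], te$a_elem_end[i]),
                   te$elem_A[i])
    }
    if (te$class[i] == "insertion_A") {
      # exactly one TSD copy, no intervening sequence, at the B site
      expect_equal(getB(te$chrom[i], te$b_repl_start[i], te$b_repl_end[i]),
                   te$tsd[i])
    }
    if (te$class[i] == "elimination_B") {
      # element replaced between the two TSD copies in B
      bseq <- getB(te$chrom[i], te$b_repl_start[i], te$b_repl_end[i])
      expect_true(startsWith(bseq, te$tsd[i]) && endsWith(bseq, te$tsd[i]))
      expect_false(grepl(te$elem_A[i], bseq, fixed = TRUE))
    }
  }
})

test_that("masked gaps record their pre-mask truth and the donor carries it", {
  sim <- sim_small()
  g <- sim$truth$gaps
  expect_gt(nrow(g), 0L)
  for (i in seq_len(nrow(g))) {
    masked <- as.character(Biostrings::subseq(sim$genome_B[[g$chrom[i]]],
                                              g$start[i] + 1, g$end[i]))
    expect_equal(masked, strrep("N", g$end[i] - g$start[i]))
    donor <- as.character(Biostrings::subseq(sim$genome_A[[g$chrom[i]]],
                                             g$a_start[i] + 1, g$a_end[i]))
    expect_equal(donor, g$truth_seq[i])
  }
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- sim_config(seed = 6L, n_chromosomes = 1L, chrom_length = 2e5,
                    n_shared = 1L, n_insertions_A = 1L, n_insertions_B = 1L,
                    n_eliminations = 1L, n_gaps = 1L,
                    telomere_copies_range = c(10L, 12L))
  s1 <- simulate_pair(cfg); s2 <- simulate_pair(cfg)
  expect_identical(as.character(s1$genome_A), as.character(s2$genome_A))
  expect_identical(as.character(s1$genome_B), as.character(s2$genome_B))
  expect_identical(s1$truth, s2$truth)
})

test_that("LTR aging follows the molecular clock", {
  ltr <- paste0("TG", random_dna_str(996, 7), "CA")
  elem <- paste0(ltr, random_dna_str(3000, 8), ltr)
  # age 0: LTRs stay identical
  aged0 <- age_ltr(elem, 1000L, 0)
  expect_identical(aged0, elem)
  # 1 MY at 1.3e-8/site/yr over 1-kb LTRs: ~26 pairwise differences expected
  diffs <- vapply(1:10, function(s) {
    aged <- age_ltr(elem, 1000L, 1e6, rate = 1.3e-8, seed = s)
    1000 * ltr_divergence(aged, 1000L)
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 26), 6)
  # terminal motif survives aging
  aged <- age_ltr(elem, 1000L, 2e6, seed = 99)
  expect_equal(substr(aged, 1, 2), "TG")
  expect_equal(substr(aged, nchar(aged) - 1, nchar(aged)), "CA")
  expect_error(age_ltr(elem, 1000L, -1), "non-negative")
})

test_that("simulation round-trips through disk", {
  sim <- sim_small()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  ga <- read_genome(file.path(dir, "genome_A.fa"))
  expect_identical(as.character(ga), as.character(sim$genome_A))
  te <- read.delim(file.path(dir, "te_events.tsv"))
  expect_equal(nrow(te), nrow(sim$truth$te_events))
  expect_true(file.exists(file.path(dir, "config.txt")))
})
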