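test_that("truth indels validate with recalculated borders; decoys do not", {
  sim <- sim_small()
  te <- sim$truth$te_events
  # A-specific element = insertion candidate at the B breakpoint
  i <- which(te$class == "insertion_A")[1]
  truth_len <- te$a_elem_end[i] - te$a_elem_start[i]
  ins <- validate_indel(list(kind = "insertion", chrom = te$chrom[i],
                             start = te$b_repl_start[i],
                             end = te$b_repl_end[i], length = truth_len),
                        sim$genome_B, sim$genome_A)
  expect_true(ins$validated)
  expect_lte(abs(ins$recalc_length - truth_len), te$tsd_len[i] + 1)

  # B-specific element = deletion candidate spanning the B interval
  j <- which(te$class == "insertion_B")[1]
  dlen <- te$b_elem_end[j] - te$b_elem_start[j]
  del <- validate_indel(list(kind = "deletion", chrom = te$chrom[j],
                             start = te$b_elem_start[j],
                             end = te$b_elem_end[j], length = dlen),
                        sim$genome_B, sim$genome_A)
  expect_true(del$validated)
  expect_lte(abs(del$recalc_length - dlen), te$tsd_len[j] + 1)

  # shuffled-coordinate decoy: anchors fine but size-incompatible
  decoy <- validate_indel(list(kind = "deletion", chrom = te$chrom[j],
                               start = te$b_elem_start[j] + 50000L,
                               end = te$b_elem_start[j] + 50600L,
                               length = 600L),
                          sim$genome_B, sim$genome_A)
  expect_false(decoy$validated)

  # the strict >100 bp rule rejects before any alignment
  short <- validate_indel(list(kind = "deletion", chrom = te$chrom[j],
                               start = 100000L, end = 100100L, length = 100L),
                          sim$genome_B, sim$genome_A)
  expect_false(short$validated)
  expect_equal(short$reason, "min_length")
})

test_that("validation is symmetric under swapping the genome roles", {
  sim <- sim_small()
  te <- sim$truth$te_events
  i <- which(te$class == "insertion_A")[1]
  truth_len <- te$a_elem_end[i] - te$a_elem_start[i]
  ins <- validate_indel(list(kind = "insertion", chrom = te$chrom[i],
                             start = te$b_repl_start[i],
                             end = te$b_repl_end[i], length = truth_len),
                        sim$genome_B, sim$genome_A)
  # seen from A, the same element is a deletion candidate over its A span
  del <- validate_indel(list(kind = "deletion", chrom = te$chrom[i],
                             start = te$a_elem_start[i],
                             end = te$a_elem_end[i], length = truth_len),
                        sim$genome_A, sim$genome_B)
  expect_true(ins$validated && del$validated)
  expect_equal(ins$recalc_length, del$recalc_length)
})

test_that("PAV detection honours the strict length rule and N handling", {
  # synthetic block table: identical genomes leave nothing unaligned
  g <- Biostrings::DNAStringSet(c(c1 = random_dna_str(5000, 31)))
  full <- data.frame(a_chrom = "c1", a_start = 0L, a_end = 5000L,
                     b_chrom = "c1", b_start = 0L, b_end = 5000L,
                     strand = "+")
  expect_equal(nrow(suppressWarnings(detect_pav(full, g, g))), 0L)

  # an 80-bp hole is excluded (strict > 100), a 150-bp hole is kept
  hole <- function(w) data.frame(
    a_chrom = "c1", a_start = c(0L, 2000L + w), a_end = c(2000L, 5000L),
    b_chrom = "c1", b_start = c(0L, 2000L + w), b_end = c(2000L, 5000L),
    strand = "+")
  expect_equal(nrow(suppressWarnings(detect_pav(hole(80L), g, g))), 0L)
  pav150 <- suppressWarnings(detect_pav(hole(150L), g, g))
  expect_equal(sort(pav150$length), c(150L, 150L))
  expect_true(all(pav150$depth_checked == FALSE))

  # unaligned regions made of N are removed
  gn <- Biostrings::DNAStringSet(c(c1 = paste0(
    random_dna_str(2000, 32), strrep("N", 150), random_dna_str(2850, 33))))
  expect_equal(nrow(suppressWarnings(detect_pav(hole(150L), gn, gn))), 0L)

  # the depth filter removes covered regions and keeps uncovered ones
  d_cov <- list(c1 = S4Vectors::Rle(30, 5000))
  expect_equal(nrow(detect_pav(hole(150L), g, g, d_cov, d_cov)), 0L)
  d_low <- list(c1 = S4Vectors::Rle(c(30, 0, 30), c(2000, 150, 2850)))
  low <- detect_pav(hole(150L), g, g, d_low, d_low)
  expect_equal(nrow(low), 2L)
  expect_true(all(low$mean_depth == 0))
})

test_that("implanted elements are recovered from the anchoring chain", {
  cfg <- sim_config(seed = 55L, n_chromosomes = 1L, chrom_length = 5e5,
                    n_shared = 2L, n_insertions_A = 2L, n_insertions_B = 1L,
                    n_eliminations = 1L, n_gaps = 0L, snp_rate = 0.002,
                    telomere_copies_range = c(20L, 30L))
  sim <- simulate_pair(cfg)
  blocks <- align_block_chain(sim$genome_A, sim$genome_B)
  pav <- detect_pav(blocks, sim$genome_A, sim$genome_B,
                    simulate_depth(sim, "A"), simulate_depth(sim, "B"))
  expected <- expected_pavs(sim$truth, min_len = 500L)
  stats <- pav_match_stats(pav, expected)
  expect_equal(stats$recall, 1)
  expect_equal(stats$precision, 1)
  # recovered insertion length within merge tolerance of the implant
  ins <- pav[pav$kind == "insertion", ][1, ]
  tr <- expected[expected$genome == "A", ]
  best <- tr[which.min(abs(tr$start - ins$start)), ]
  expect_lte(abs(ins$length - (best$end - best$start)), 100L)
})

test_that("shared-variant classification follows the panel definition", {
  expect_true(classify_shared(c(TRUE, TRUE, TRUE), donor_present = FALSE))
  expect_false(classify_shared(c(TRUE, TRUE, FALSE), donor_present = FALSE))
  expect_false(classify_shared(c(TRUE, TRUE, TRUE), donor_present = TRUE))
  expect_false(classify_shared(logical(0)))
})

test_that("synthetic parity panels reproduce the ledger's sharing labels", {
  sim <- sim_small()
  te <- sim$truth$te_events
  flank <- 500L
  ctx <- function(i) as.character(Biostrings::subseq(
    sim$genome_A[[te$chrom[i]]], te$a_elem_start[i] - flank + 1,
    te$a_elem_end[i] + flank))
  # parity panel: three copies of genome B; donor-exclusion: genome B too
  idx <- which(te$class %in% c("shared", "insertion_A"))
  for (i in idx[1:3]) {
    present <- vapply(1:3, function(k)
      variant_present(ctx(i), sim$genome_B), logical(1))
    shared <- classify_shared(present, donor_present = FALSE)
    expect_equal(shared, te$class[i] == "shared")
  }
})

test_that("breakpoint repeat annotation follows the class precedence", {
  reps <- data.frame(chrom = "c1",
                     start = c(100L, 400L, 450L, 2000L),
                     end = c(300L, 500L, 520L, 2500L),
                     class = c("LTR", "SINE", "LINE", "DNA"))
  v <- data.frame(kind = c("deletion", "deletion", "deletion", "inversion"),
                  chrom = "c1",
                  start = c(150L, 460L, 1000L, 150L),
                  end = c(200L, 480L, 1100L, 2100L))
  out <- annotate_breakpoints(v, reps)
  expect_equal(out$repeat_class, c("LTR", "SINE", "Non", "LTR"))
  # inversion breakpoints annotated separately
  expect_equal(out$bp_start_class[4], "LTR")
  expect_equal(out$bp_end_class[4], "DNA")
})
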