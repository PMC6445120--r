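test_that("gap merging follows the 500-bp rule", {
  expect_equal(nrow(extract_and_merge_gaps(
    Biostrings::DNAStringSet(c(c1 = random_dna_str(2000, 1))))), 0L)
  # runs (100,200) and (650,700): separation 450 <= 500 -> one merged gap
  g1 <- extract_and_merge_gaps(Biostrings::DNAStringSet(c(c1 = {
    s <- strsplit(random_dna_str(3000, 2), "")[[1]]
    s[101:200] <- "N"; s[651:700] <- "N"
    paste(s, collapse = "")
  })))
  expect_equal(nrow(g1), 1L)
  expect_equal(c(g1$start, g1$end), c(100L, 700L))
  g2 <- extract_and_merge_gaps(Biostrings::DNAStringSet(c(c1 = {
    s <- strsplit(random_dna_str(3000, 2), "")[[1]]
    s[101:200] <- "N"; s[801:850] <- "N"   # separation 600 > 500
    paste(s, collapse = "")
  })))
  expect_equal(nrow(g2), 2L)
})

# recipient with one gap whose flanks are f5/f3; donor built per scenario
.gap_scenario <- function(donor_parts, seed = 3) {
  f5 <- random_dna_str(500, seed)
  f3 <- random_dna_str(500, seed + 1)
  m <- random_dna_str(800, seed + 2)
  recipient <- Biostrings::DNAStringSet(c(r1 = paste0(
    random_dna_str(1000, seed + 3), f5, strrep("N", 300), f3,
    random_dna_str(1000, seed + 4))))
  donor_seq <- paste(vapply(donor_parts, function(p) switch(
    p, f5 = f5, f3 = f3, m = m,
    mN = paste0(substr(m, 1, 400), "N", substr(m, 402, 800)),
    random_dna_str(2000, seed + 5 + nchar(p))), character(1)),
    collapse = "")
  donor <- Biostrings::DNAStringSet(c(d1 = paste0(
    random_dna_str(500, seed + 6), donor_seq, random_dna_str(500, seed + 7))))
  list(recipient = recipient, donor = donor,
       gap = extract_and_merge_gaps(recipient)[1, ])
}

test_that("closure criteria fail in order with distinct reasons", {
  # clean scenario closes and recovers the intervening sequence
  sc <- .gap_scenario(c("f5", "m", "f3"))
  cl <- close_gap(sc$gap, sc$recipient, sc$donor)
  expect_equal(cl$status, "closed")
  expect_equal(nchar(cl$patched_sequence), 800L)

  # flanks placed 6 times in total -> criterion ii (strict < 5)
  sc2 <- .gap_scenario(c("f5", "m", "f3", "x1", "f5", "x2", "f5",
                         "x3", "f3", "x4", "f3"))
  cl2 <- close_gap(sc2$gap, sc2$recipient, sc2$donor)
  expect_equal(cl2$status, "failed")
  expect_equal(cl2$failed_criterion, "ii")
  expect_equal(cl2$n_hits, 6L)

  # intervening sequence contains one N -> criterion iii
  sc3 <- .gap_scenario(c("f5", "mN", "f3"))
  cl3 <- close_gap(sc3$gap, sc3$recipient, sc3$donor)
  expect_equal(cl3$failed_criterion, "iii")

  # failing both ii and iii still reports ii (ordering observable)
  sc4 <- .gap_scenario(c("f5", "mN", "f3", "x1", "f5", "x2", "f5",
                         "x3", "f3", "x4", "f3"))
  expect_equal(close_gap(sc4$gap, sc4$recipient, sc4$donor)$failed_criterion,
               "ii")

  # missing downstream flank -> criterion i
  sc5 <- .gap_scenario(c("f5", "m"))
  expect_equal(close_gap(sc5$gap, sc5$recipient, sc5$donor)$failed_criterion,
               "i")

  # depth route of criterion iv: zero coverage fails, adequate passes
  sc6 <- .gap_scenario(c("f5", "m", "f3"))
  zero <- list(d1 = S4Vectors::Rle(0, Biostrings::width(sc6$donor)[1]))
  cl6 <- close_gap(sc6$gap, sc6$recipient, sc6$donor, donor_depth = zero)
  expect_equal(cl6$failed_criterion, "iv")
  ok <- list(d1 = S4Vectors::Rle(30, Biostrings::width(sc6$donor)[1]))
  expect_equal(close_gap(sc6$gap, sc6$recipient, sc6$donor,
                         donor_depth = ok)$status, "closed")

  # parity route of criterion iv: corroboration by another assembly
  cl7 <- close_gap(sc6$gap, sc6$recipient, sc6$donor,
                   parity_assemblies = list(sc6$donor))
  expect_equal(cl7$status, "closed")
  expect_equal(cl7$iv_route, "parity")
  decoy <- Biostrings::DNAStringSet(c(p1 = random_dna_str(5000, 99)))
  expect_equal(close_gap(sc6$gap, sc6$recipient, sc6$donor,
                         parity_assemblies = list(decoy))$failed_criterion,
               "iv")

  # gaps at a sequence edge fail outside the i-iv ladder
  edge <- Biostrings::DNAStringSet(c(r1 = paste0(strrep("N", 200),
                                                 random_dna_str(2000, 8))))
  egap <- extract_and_merge_gaps(edge)[1, ]
  expect_equal(close_gap(egap, edge, sc6$donor)$failed_criterion,
               "flank_extraction")
})

test_that("synthetic gaps are recovered exactly and patching is idempotent", {
  sim <- sim_small()
  depth <- simulate_depth(sim, "A")
  res <- close_gaps(sim$genome_B, sim$genome_A, donor_depth = depth)
  expect_true(all(res$report$status == "closed"))
  tg <- sim$truth$gaps
  for (cl in res$closures) {
    j <- which(tg$start == cl$gap$start & tg$chrom == cl$gap$chrom)
    expect_length(j, 1L)
    expect_identical(cl$patched_sequence, tg$truth_seq[j])
  }
  patched <- apply_closures(sim$genome_B, res$closures)
  expect_equal(patched$report$n_closed, nrow(tg))
  # no closable gaps remain
  expect_equal(nrow(extract_and_merge_gaps(patched$genome)), 0L)
})

test_that("applying closures shifts coordinates consistently", {
  sim <- sim_small()
  # zero closures leave the genome byte-identical
  none <- apply_closures(sim$genome_B, list())
  expect_identical(as.character(none$genome), as.character(sim$genome_B))
  # replacing a 300-base N-run with a 534-base patch grows the chromosome
  rec <- Biostrings::DNAStringSet(c(r1 = paste0(
    random_dna_str(1000, 21), strrep("N", 300), random_dna_str(1000, 22))))
  fake <- list(list(gap = list(chrom = "r1", start = 1000L, end = 1300L),
                    status = "closed",
                    patched_sequence = random_dna_str(534, 23)))
  out <- apply_closures(rec, fake)
  expect_equal(Biostrings::width(out$genome), 2300L + 234L)
  expect_equal(out$report$mean_patch, 534)
})
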