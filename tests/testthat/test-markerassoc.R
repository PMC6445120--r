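junction26 <- "GGATTTTTATATATGTGTTGACCCTA"

test_that("junction search distinguishes carriers from split halves", {
  carrier <- Biostrings::DNAStringSet(c(s = paste0(
    random_dna_str(300, 1), junction26, random_dna_str(300, 2))))
  split_sample <- Biostrings::DNAStringSet(c(s = paste0(
    random_dna_str(300, 1), substr(junction26, 1, 13),
    random_dna_str(4000, 3), substr(junction26, 14, 26),
    random_dna_str(300, 2))))
  res <- junction_search(list(carrier = carrier, split = split_sample),
                         junction26)
  expect_true(res$present[res$sample == "carrier"])
  expect_false(res$present[res$sample == "split"])
  expect_error(junction_search(list(a = carrier), "ACGTACGTACGT"),
               "unspecific")
})

test_that("junction search is strand-symmetric and mismatch-aware", {
  carrier <- Biostrings::DNAStringSet(c(s = paste0(
    random_dna_str(200, 4), junction26, random_dna_str(200, 5))))
  rc <- Biostrings::reverseComplement(carrier)
  names(rc) <- names(carrier)
  r1 <- junction_search(list(x = carrier), junction26)
  r2 <- junction_search(list(x = rc), junction26)
  expect_equal(r1$present, r2$present)
  # one mismatch: missed at 0 tolerance, found at 1
  mut <- chartr("G", "T", substr(junction26, 1, 1))
  jm <- paste0(mut, substr(junction26, 2, 26))
  noisy <- Biostrings::DNAStringSet(c(s = paste0(
    random_dna_str(200, 6), jm, random_dna_str(200, 7))))
  expect_false(junction_search(list(x = noisy), junction26,
                               max_mismatch = 0)$present)
  expect_true(junction_search(list(x = noisy), junction26,
                              max_mismatch = 1)$present)
})

test_that("simulated carriers and non-carriers are called without error", {
  sim <- sim_small()
  te <- sim$truth$te_events
  ins <- te[te$class == "insertion_A", ][1, ]
  # junction spans the boundary between upstream flank and the element
  s <- ins$a_elem_start
  junction <- as.character(Biostrings::subseq(sim$genome_A[[ins$chrom]],
                                              s - 12, s + 13))
  res <- junction_search(list(A = sim$genome_A, B = sim$genome_B), junction)
  expect_true(res$present[res$sample == "A"])
  expect_false(res$present[res$sample == "B"])
})

test_that("in-silico PCR reports amplicons with the inclusive span", {
  fwd <- "GGTCACCCAACCCACACTGGGCCTTG"
  rev <- "CGGCCGCAATCGCAAGACGCAGA"
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  amplicon <- paste0(fwd, random_dna_str(750 - nchar(fwd) - nchar(rev), 8),
                     rc(rev))
  tmpl <- Biostrings::DNAStringSet(c(t = paste0(
    random_dna_str(400, 9), amplicon, random_dna_str(300, 10))))
  hits <- insilico_pcr(tmpl, fwd, rev, max_product = 2000)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_length, 750L)
  # template on the other strand still amplifies
  tmpl_rc <- Biostrings::DNAStringSet(c(t = rc(as.character(tmpl[[1]]))))
  hits_rc <- insilico_pcr(tmpl_rc, fwd, rev, max_product = 2000)
  expect_equal(hits_rc$product_length, 750L)
  # no binding sites, or the reverse site beyond max_product: no product
  none <- Biostrings::DNAStringSet(c(t = random_dna_str(2000, 11)))
  expect_equal(nrow(insilico_pcr(none, fwd, rev)), 0L)
  expect_equal(nrow(insilico_pcr(tmpl, fwd, rev, max_product = 700)), 0L)
  expect_error(insilico_pcr(tmpl, "ACGTACGT", rev), "18")
})

test_that("primer 3' clamps must match exactly", {
  fwd <- "GGTCACCCAACCCACACTGGGCCTTG"
  rev <- "CGGCCGCAATCGCAAGACGCAGA"
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  # mutate the last base of the forward primer's site in the template
  site <- paste0(substr(fwd, 1, 25), "A")
  tmpl <- Biostrings::DNAStringSet(c(t = paste0(
    random_dna_str(200, 12), site, random_dna_str(500, 13), rc(rev),
    random_dna_str(200, 14))))
  expect_equal(nrow(insilico_pcr(tmpl, fwd, rev, max_mismatch = 1)), 0L)
  # the same single mismatch away from the 3' end is tolerated
  site2 <- paste0("A", substr(fwd, 2, 26))
  tmpl2 <- Biostrings::DNAStringSet(c(t = paste0(
    random_dna_str(200, 12), site2, random_dna_str(500, 13), rc(rev),
    random_dna_str(200, 14))))
  expect_equal(nrow(insilico_pcr(tmpl2, fwd, rev, max_mismatch = 1)), 1L)
})

test_that("co-segregation tabulates concordance and the perfect flag", {
  acc <- data.frame(sample = paste0("a", 1:145),
                    phenotype = c(rep("red", 112), rep("non_red", 33)),
                    marker = c(rep("present", 112), rep("absent", 33)))
  s <- cosegregation(acc)
  expect_equal(s$concordance, 1.0)
  expect_true(s$perfect)
  expect_equal(s$n_known, 145L)
  expect_equal(sum(s$table), 145L)

  prog <- data.frame(sample = paste0("p", 1:75),
                     phenotype = c(rep("red", 41), rep("non_red", 34)),
                     marker = c(rep("present", 41), rep("absent", 34)))
  expect_equal(cosegregation(prog)$concordance, 1.0)

  ten <- data.frame(sample = paste0("s", 1:10),
                    phenotype = c(rep("red", 5), rep("non_red", 5)),
                    marker = c(rep("present", 4), "absent", rep("absent", 5)))
  s10 <- cosegregation(ten)
  expect_equal(s10$concordance, 0.9)
  expect_false(s10$perfect)

  # unknown phenotypes and failed assays are excluded from the denominator
  mixed <- rbind(ten, data.frame(sample = "s11", phenotype = "unknown",
                                 marker = "present"))
  expect_equal(cosegregation(mixed)$n_known, 10L)
  expect_error(cosegregation(data.frame(sample = "x", phenotype = "unknown",
                                        marker = "failed")), "usable")
  expect_error(cosegregation(ten[c(1, 1), ]), "unique")
})
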