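test_that("telomere arrays at chromosome ends are counted exactly", {
  unit <- "TTTAGGG"
  rc <- "CCCTAAA"
  body <- random_dna_str(60000, 11)
  chr300 <- paste0(strrep(rc, 120), body, strrep(unit, 300))
  g <- Biostrings::DNAStringSet(c(c1 = chr300))
  tel <- detect_telomeres(g)
  expect_equal(nrow(tel), 2L)
  expect_equal(tel$copies[tel$end == "3prime"], 300L)
  expect_equal(tel$copies[tel$end == "5prime"], 120L)
  # the smallest chromosome-end array observed in real assemblies
  g294 <- Biostrings::DNAStringSet(c(c1 = paste0(body, strrep(unit, 294))))
  tel294 <- detect_telomeres(g294)
  expect_equal(tel294$copies, 294L)
  expect_equal(tel294$end, "3prime")
  # no unit within the end window: no call
  expect_equal(nrow(detect_telomeres(Biostrings::DNAStringSet(c(c1 = body)))),
               0L)
  # arrays below min_copies are not reported
  g50 <- Biostrings::DNAStringSet(c(c1 = paste0(body, strrep(unit, 50))))
  expect_equal(nrow(detect_telomeres(g50, min_copies = 100)), 0L)
  expect_equal(detect_telomeres(g50, min_copies = 40)$copies, 50L)
})

test_that("interrupted arrays are tolerated up to the interruption budget", {
  unit <- "TTTAGGG"
  body <- random_dna_str(30000, 12)
  arr <- paste0(strrep(unit, 100), "ACGT", strrep(unit, 100))
  g <- Biostrings::DNAStringSet(c(c1 = paste0(body, arr)))
  tol <- detect_telomeres(g, min_copies = 150)
  expect_equal(tol$copies, 200L)
  strict <- detect_telomeres(g, min_copies = 150, strict = TRUE)
  expect_equal(nrow(strict), 0L)
})

test_that("heterochromatin windows obey the strict >90% rule and merge", {
  # one 1.2-Mb region at 95% repeat coverage inside a 10-Mb chromosome
  lens <- c(c1 = 1e7)
  dense <- do.call(rbind, lapply(seq(4e6, 5.2e6 - 2e4, by = 2e4), function(s)
    data.frame(chrom = "c1", start = s, end = s + 19000)))
  sparse <- do.call(rbind, lapply(seq(0, 1e7 - 1e5, by = 1e5), function(s)
    data.frame(chrom = "c1", start = s, end = s + 50000)))
  blocks <- scan_heterochromatin(rbind(dense, sparse), lens)
  expect_equal(nrow(blocks), 1L)
  expect_lte(blocks$start, 4e6)
  expect_gte(blocks$end, 5.2e6 - 25e4)
  # sliding-window oracle agreement on qualifying window count
  starts <- seq(0, 1e7 - 1e6, by = 2.5e5)
  rep_ir <- IRanges::reduce(IRanges::IRanges(
    c(dense$start, sparse$start) + 1L, c(dense$end, sparse$end)))
  frac <- vapply(starts, function(s) {
    w <- IRanges::IRanges(s + 1, s + 1e6)
    sum(IRanges::width(IRanges::intersect(rep_ir, w))) / 1e6
  }, numeric(1))
  expect_equal(blocks$n_windows, sum(frac > 0.9))

  # uniform 50% density qualifies nowhere
  expect_equal(nrow(scan_heterochromatin(sparse, lens)), 0L)

  # a window at exactly the threshold is excluded (strict inequality)
  exact <- data.frame(chrom = "c2", start = 0, end = 9e5)
  expect_equal(nrow(scan_heterochromatin(exact, c(c2 = 1e6))), 0L)
  above <- data.frame(chrom = "c2", start = 0, end = 9e5 + 1)
  expect_equal(nrow(scan_heterochromatin(above, c(c2 = 1e6))), 1L)
})

test_that("assembly statistics: N50 on gap-split segments, telomere tally", {
  g <- Biostrings::DNAStringSet(c(c1 = random_dna_str(5e4, 13)))
  st <- assembly_stats(g)
  expect_equal(st$summary$contig_n50, 5e4)
  expect_equal(st$per_chrom$telomere_status, "None")

  # segments 30k/19k (split by an N-run) plus a gapless 25k chromosome:
  # cumulative halves at the 25k segment
  g2 <- Biostrings::DNAStringSet(c(
    c1 = paste0(random_dna_str(30000, 14), strrep("N", 10),
                random_dna_str(19000, 15)),
    c2 = random_dna_str(25000, 16)))
  st2 <- assembly_stats(g2)
  expect_equal(st2$summary$contig_n50, 25000L)
  expect_equal(st2$per_chrom$n_gaps, c(1L, 0L))

  tel <- data.frame(chrom = c("c1", "c1", "c2"),
                    end = c("5prime", "3prime", "3prime"),
                    copies = c(100L, 100L, 100L),
                    start = 0L, end_pos = 700L)
  st3 <- assembly_stats(g2, telomere_calls = tel)
  expect_equal(st3$summary$telomeres_total,
               2L * st3$summary$telomere_both + st3$summary$telomere_single)
  expect_equal(st3$summary$telomeres_total, 3L)
})

test_that("printed chromosome tables tabulate consistently", {
  tab <- read_chrom_table(system.file("extdata",
                                      "hfth1_gddh13_chrom_stats.tsv",
                                      package = "genomepair"))
  h <- chrom_table_summary(tab[tab$genome == "HFTH1", ])
  expect_equal(h$telomeres_total, 2L * h$n_both + h$n_single)
  g <- chrom_table_summary(tab[tab$genome == "GDDH13", ])
  expect_equal(g$n_both, 0L)
  expect_equal(g$telomeres_total, g$n_single)
})
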