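test_that("the detector recovers simulated elements at exact coordinates", {
  sim <- sim_small()
  det <- detect_intact_ltr(sim$genome_A)
  te <- sim$truth$te_events
  carriers <- te[te$class %in% c("shared", "insertion_A", "elimination_B"), ]
  expect_equal(nrow(det), nrow(carriers))
  m <- merge(det, carriers, by.x = c("chrom", "start"),
             by.y = c("chrom", "a_elem_start"))
  expect_equal(nrow(m), nrow(carriers))
  expect_true(all(m$end == m$a_elem_end))
  expect_true(all(m$tsd.x == m$tsd.y))
  expect_true(all(m$ltr_len.x == m$ltr_len.y))
  expect_true(all(m$motif_ok))
  # measured LTR-LTR divergence tracks the simulated age
  expect_gt(stats::cor(m$K, m$age_years), 0.9)
})

test_that("elements with mutated TSD copies are not reported", {
  sim <- sim_small()
  te <- sim$truth$te_events
  i <- which(!is.na(te$a_elem_start))[1]
  ch <- te$chrom[i]
  lo <- te$a_elem_start[i] - 2000L; hi <- te$a_elem_end[i] + 2000L
  region <- as.character(Biostrings::subseq(sim$genome_A[[ch]], lo + 1, hi))
  expect_equal(nrow(detect_intact_ltr(
    Biostrings::DNAStringSet(c(r = region)))), 1L)
  # break one base of the right TSD copy
  v <- strsplit(region, "")[[1]]
  p <- te$a_elem_end[i] - lo + 1L
  v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  broken <- paste(v, collapse = "")
  expect_equal(nrow(detect_intact_ltr(
    Biostrings::DNAStringSet(c(r = broken)))), 0L)
})

test_that("a repeat-free genome yields no elements", {
  g <- Biostrings::DNAStringSet(c(c1 = random_dna_str(2e5, 77)))
  expect_equal(nrow(detect_intact_ltr(g)), 0L)
})

test_that("cross-genome classification reproduces the simulated classes", {
  sim <- sim_small()
  cls <- cls_small()
  te <- sim$truth$te_events
  m <- merge(cls, te, by.x = c("chrom", "start"),
             by.y = c("chrom", "a_elem_start"))
  expect_equal(nrow(m), sum(!is.na(te$a_elem_start)))
  expect_true(all(pred_class4(m$cls) == truth_class4(m$class)))
  # shared elements at this genome-wide divergence are the high-identity kind
  sh <- m[m$class == "shared", ]
  expect_true(all(sh$cls == "SharedHigh"))
  expect_true(all(sh$identity_cross >= 0.99))
  # the class partition plus discards accounts for every detected element
  expect_equal(sum(ltr_class_counts(cls)), nrow(cls))
})

test_that("insertion time follows the clock and its correction", {
  expect_equal(insertion_time(0), 0)
  expect_equal(insertion_time(0.0026), 1e5)
  expect_equal(insertion_time(0.0208), 8e5)
  K <- seq(0, 0.5, by = 0.01)
  t_raw <- insertion_time(K)
  expect_true(all(diff(t_raw) > 0))
  t_jc <- insertion_time(K, jc_correct = TRUE)
  expect_true(all(diff(t_jc) > 0))
  expect_true(all(t_jc[-1] >= t_raw[-1]))
  expect_error(insertion_time(0.8, jc_correct = TRUE), "0.75")
  expect_error(insertion_time(-0.1), "non-negative")
  expect_error(insertion_time(0.1, rate = 0), "positive")
})

test_that("ages are recovered from aged elements within the Poisson noise", {
  ltr <- paste0("TG", random_dna_str(996, 13), "CA")
  elem <- paste0(ltr, random_dna_str(2000, 14), ltr)
  ages <- rep(5e5, 20)
  k_hat <- vapply(seq_along(ages), function(s)
    ltr_divergence(age_ltr(elem, 1000L, ages[s], seed = 1000 + s), 1000L),
    numeric(1))
  # E[K] = 2 * r * t = 0.013; 20 replicates x 1 kb
  expect_lt(abs(mean(k_hat) - 0.013), 0.0025)
})

test_that("the CNS rate formula matches independent arithmetic", {
  # algebraic reductions
  expect_equal(cns_rate(0.01, 0.01, 1e6, 4e6), 0.01 / (2 * 4e6))
  expect_equal(cns_rate(0.02, 0, 1e6, 4e6), 0.02 / 1e6)
  expect_equal(cns_rate(0.02, 0.01, 1e6, 4e6), 1.125e-8)
  # 1000 random tuples against the rearranged identity
  # V * t_ltr + s_c * (1 - t_ltr / (2 t_div)) = s_f
  withr::with_seed(17, {
    s_f <- stats::runif(1000); s_c <- stats::runif(1000)
    t_ltr <- stats::runif(1000, 1e4, 5e6)
    t_div <- stats::runif(1000, 1e4, 1e7)
    v <- cns_rate(s_f, s_c, t_ltr, t_div)
    lhs <- v * t_ltr + s_c * (1 - t_ltr / (2 * t_div))
    expect_equal(lhs, s_f, tolerance = 1e-12)
  })
  expect_error(cns_rate(0.1, 0.1, 0, 1e6), "positive")
  expect_error(cns_rate(1.5, 0.1, 1e6, 1e6), "\\[0, 1\\]")
})

test_that("flank substitutions reflect the genome-wide divergence", {
  sim <- sim_small()
  cls <- cls_small()
  fs <- flank_substitutions(cls, sim$genome_A, sim$genome_B)
  ok <- !is.na(fs$s_f)
  expect_gt(sum(ok), 5)
  # flanks diverge at about the configured SNP rate (no elevation here)
  expect_lt(abs(mean(fs$s_f[ok]) - 0.002), 0.0015)
  expect_lt(abs(mean(fs$s_c, na.rm = TRUE) - 0.002), 0.002)
})

test_that("CNS-versus-age summarises sliding windows and rates", {
  el <- data.frame(t_ltr = seq(1e5, 2e6, length.out = 50))
  el$s_f <- 2 * 1.3e-8 * el$t_ltr
  out <- cns_vs_time(el)
  expect_true(all(diff(out$curve$mean_cns) >= 0))
  fit <- stats::lm(mean_cns ~ window_mid, data = out$curve)
  expect_lt(abs(coef(fit)[2] / (2 * 1.3e-8) - 1), 0.2)
  # degenerate cases
  one <- cns_vs_time(data.frame(t_ltr = c(0, 0), s_f = c(0, 0)))
  expect_equal(nrow(one$curve), 1L)
  expect_error(cns_vs_time(data.frame(t_ltr = numeric(), s_f = numeric())),
               "no elements")
})

test_that("insertion sites near genes are binned against a uniform control", {
  lens <- c(c1 = 1e6)
  genes <- simulate_genes(lens, fraction = 0.25, seed = 5)
  # uniform sites: inside fraction ~ genic fraction
  sites <- withr::with_seed(6, data.frame(
    chrom = "c1", pos = floor(stats::runif(400, 0, 1e6))))
  gd <- gene_distance_distribution(sites, genes, lens, seed = 7)
  expect_lt(abs(gd$inside_fraction - gd$genic_fraction), 0.07)
  expect_equal(sum(gd$histogram$count), 400)
  # avoidance sampling: inside fraction clearly below the genic fraction
  gr <- IRanges::IRanges(genes$start + 1L, genes$end)
  avoid <- withr::with_seed(8, {
    pos <- integer(0)
    while (length(pos) < 400) {
      p <- floor(stats::runif(1, 0, 1e6))
      inside <- IRanges::countOverlaps(IRanges::IRanges(p + 1, p + 1), gr) > 0
      if (!inside || stats::runif(1) < 0.3) pos <- c(pos, p)
    }
    data.frame(chrom = "c1", pos = pos)
  })
  gda <- gene_distance_distribution(avoid, genes, lens, seed = 9)
  expect_lt(gda$inside_fraction, gda$genic_fraction - 0.05)
})
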