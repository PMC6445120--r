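# Cumulative nucleotide substitution (CNS) analyses around LTR-RT
# insertions: per-element flank substitution frequencies, control regions,
# the CNS rate formula, flank profiles by distance, gene-distance
# distributions and the CNS-versus-age curve.

#' Cumulative nucleotide substitution rate of a flanking sequence
#'
#' `V = (S_f - S_c) / T_ltr + S_c / (2 * T_div)`, where `S_f` is the
#' substitution frequency of the element's flanking sequence, `S_c` that of
#' a control region far from the element, `T_ltr` the element's insertion
#' time and `T_div` the divergence time of the two genotypes. The first
#' term attributes flank excess over background to the element's residence
#' time; the second is the background per-lineage rate. May be negative
#' when `S_f < S_c` (reported as-is). Vectorised.
#'
#' @param s_f,s_c Substitution frequencies in \[0, 1\].
#' @param t_ltr,t_div Times in years, > 0.
#' @return Substitutions per site per year.
#' @export
cns_rate <- function(s_f, s_c, t_ltr, t_div) {
  if (any(t_ltr <= 0, na.rm = TRUE) || any(t_div <= 0, na.rm = TRUE))
    stop("t_ltr and t_div must be positive")
  if (any(s_f < 0 | s_f > 1 | s_c < 0 | s_c > 1, na.rm = TRUE))
    stop("substitution frequencies must be in [0, 1]")
  (s_f - s_c) / t_ltr + s_c / (2 * t_div)
}

# per-position mismatch vector along `a` (NA where a aligns to a gap or an
# N column); falls back to global alignment when a direct comparison looks
# frame-shifted
.column_mismatch <- function(a, b, max_direct_frac = 0.1) {
  a <- as.character(.as_dna(a)); b <- as.character(.as_dna(b))
  if (nchar(a) == nchar(b)) {
    av <- charToRaw(a); bv <- charToRaw(b)
    mm <- av != bv
    mm[av == charToRaw("N") | bv == charToRaw("N")] <- NA
    if (mean(mm, na.rm = TRUE) <= max_direct_frac || nchar(a) < 50)
      return(as.vector(mm))
  }
  aln <- Biostrings::pairwiseAlignment(
    .as_dna(a), .as_dna(b), type = "global",
    substitutionMatrix = .gp_submat(),
    gapOpening = .gp_align_defaults$gap_opening,
    gapExtension = .gp_align_defaults$gap_extension)
  pa <- charToRaw(as.character(Biostrings::alignedPattern(aln)))
  sa <- charToRaw(as.character(Biostrings::alignedSubject(aln)))
  in_a <- pa != charToRaw("-")
  mm <- (pa != sa)[in_a]
  bad <- (pa == charToRaw("N") | sa == charToRaw("N") |
            sa == charToRaw("-"))[in_a]
  mm[bad] <- NA
  as.vector(mm)
}

#' Flank and control substitution frequencies per element
#'
#' For every classified element with anchored flanks in genome B, compares
#' the A and B copies of both 500-bp flanks (`S_f`) and of a 500-bp window
#' inside a control region placed `control_offset` bases away from the
#' element (`S_c`); the control emulates a non-functional region unaffected
#' by the insertion.
#'
#' @param elements From [classify_cross_genome()].
#' @param genome_a,genome_b DNAStringSet pair.
#' @param flank Flank length, bases.
#' @param control_offset Distance of the control region from the element
#'   (default 9 kb).
#' @param control_len Control window length (500 bp).
#' @param min_coverage,min_identity Anchoring thresholds for the control.
#' @return `elements` with added `s_f`, `s_f_sites`, `s_c`, `s_c_sites`.
#' @export
flank_substitutions <- function(elements, genome_a, genome_b, flank = 500L,
                                control_offset = 9000L, control_len = 500L,
                                min_coverage = 0.8, min_identity = 0.8) {
  elements$s_f <- NA_real_; elements$s_f_sites <- NA_integer_
  elements$s_c <- NA_real_; elements$s_c_sites <- NA_integer_
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    if (is.na(el$b_chrom)) next
    sub_tot <- 0L; site_tot <- 0L
    for (side in c("up", "dn")) {
      aseq <- .element_flank_a(el, genome_a, side, flank)
      bseq <- .element_flank_b(el, genome_b, side, flank)
      if (is.null(aseq) || is.null(bseq)) next
      sc <- substitution_count(aseq, bseq)
      sub_tot <- sub_tot + sc$substitutions
      site_tot <- site_tot + sc$compared_sites
    }
    if (site_tot > 0) {
      elements$s_f[i] <- sub_tot / site_tot
      elements$s_f_sites[i] <- site_tot
    }
    ctrl <- .control_substitutions(el, genome_a, genome_b, control_offset,
                                   control_len, min_coverage, min_identity)
    if (!is.null(ctrl)) {
      elements$s_c[i] <- ctrl$s
      elements$s_c_sites[i] <- ctrl$sites
    }
  }
  elements
}

.element_flank_a <- function(el, genome_a, side, flank) {
  s <- el$start - el$tsd_len; e <- el$end + el$tsd_len
  L <- Biostrings::width(genome_a)[match(el$chrom, names(genome_a))]
  if (side == "up") {
    if (s - flank < 0) return(NULL)
    .gp_subseq(genome_a, el$chrom, s - flank, s)
  } else {
    if (e + flank > L) return(NULL)
    .gp_subseq(genome_a, el$chrom, e, e + flank)
  }
}

# B flank adjacent to the anchored placement, oriented to A
.element_flank_b <- function(el, genome_b, side, flank) {
  if (is.na(el$b_chrom)) return(NULL)
  L <- Biostrings::width(genome_b)[match(el$b_chrom, names(genome_b))]
  plus <- el$b_strand == "+"
  if (side == "up") {
    if (plus) { s <- el$b_up_end - flank; e <- el$b_up_end }
    else { s <- el$b_up_start; e <- el$b_up_start + flank }
  } else {
    if (plus) { s <- el$b_dn_start; e <- el$b_dn_start + flank }
    else { s <- el$b_dn_end - flank; e <- el$b_dn_end }
  }
  if (s < 0 || e > L) return(NULL)
  seq <- .gp_subseq(genome_b, el$b_chrom, s, e)
  if (!plus) seq <- Biostrings::reverseComplement(seq)
  seq
}

.control_substitutions <- function(el, genome_a, genome_b, control_offset,
                                   control_len, min_coverage, min_identity) {
  L <- Biostrings::width(genome_a)[match(el$chrom, names(genome_a))]
  starts <- c(el$start - el$tsd_len - control_offset - control_len,
              el$end + el$tsd_len + control_offset)
  for (s in starts) {
    if (s < 0 || s + control_len > L) next
    aseq <- .gp_subseq(genome_a, el$chrom, s, s + control_len)
    pl <- anchor_fragment(aseq, genome_b, min_coverage = min_coverage,
                          min_identity = min_identity, max_hits = 2L)
    if (nrow(pl) != 1 || pl$n_hits[1] != 1) next
    bseq <- .gp_subseq(genome_b, pl$chrom[1], pl$start[1], pl$end[1])
    if (pl$strand[1] == "-") bseq <- Biostrings::reverseComplement(bseq)
    sc <- substitution_count(aseq, bseq)
    if (sc$compared_sites == 0) next
    return(list(s = sc$substitutions / sc$compared_sites,
                sites = sc$compared_sites))
  }
  NULL
}

#' CNS profile around elements, interior bins and genome-wide control
#'
#' Computes, per flank offset, the mean substitution frequency between the
#' A and B copies of element flanks in sliding windows; the substitution
#' frequency across ten equal bins of the element interior (Shared
#' elements only); and a control distribution from randomly placed blocks
#' compared tile-by-tile between the genomes. Deterministic under `seed`.
#'
#' @param elements Classified elements with B anchors.
#' @param genome_a,genome_b DNAStringSet pair.
#' @param flank_len Flank region length profiled, bases.
#' @param window,step Sliding window for flank profiles.
#' @param inner_bins Number of equal interior bins.
#' @param n_control,control_len Control blocks: count and length.
#' @param seed RNG seed for control placement.
#' @param interior Also profile element interiors (costlier).
#' @return list: `flank` (side, offset, mean_s, n_sites), `interior`
#'   (bin, mean_s, n_sites), `control` (block values), `skipped` count.
#' @export
cns_profile <- function(elements, genome_a, genome_b, flank_len = 2000L,
                        window = 400L, step = 100L, inner_bins = 10L,
                        n_control = 3000L, control_len = 20000L, seed = 1L,
                        interior = TRUE) {
  usable <- elements[!is.na(elements$b_chrom), , drop = FALSE]
  skipped <- nrow(elements) - nrow(usable)
  # per-offset mismatch accumulation (offset 1 = base nearest the element)
  acc <- list(up = list(mm = numeric(flank_len), n = numeric(flank_len)),
              dn = list(mm = numeric(flank_len), n = numeric(flank_len)))
  for (i in seq_len(nrow(usable))) {
    el <- usable[i, ]
    for (side in c("up", "dn")) {
      aseq <- .element_flank_a(el, genome_a, side, flank_len)
      bseq <- .element_flank_b(el, genome_b, side, flank_len)
      if (is.null(aseq) || is.null(bseq)) next
      mm <- .column_mismatch(aseq, bseq)
      if (side == "up") mm <- rev(mm)  # index 1 = adjacent to element
      ok <- !is.na(mm)
      acc[[side]]$mm[ok] <- acc[[side]]$mm[ok] + mm[ok]
      acc[[side]]$n[ok] <- acc[[side]]$n[ok] + 1
    }
  }
  offs <- seq(0L, flank_len - window, by = step)
  flank_df <- do.call(rbind, lapply(c("up", "dn"), function(side) {
    a <- acc[[side]]
    data.frame(side = side, offset = offs,
               mean_s = vapply(offs, function(o) {
                 idx <- (o + 1L):(o + window)
                 n <- sum(a$n[idx])
                 if (n == 0) NA_real_ else sum(a$mm[idx]) / n
               }, numeric(1)),
               n_sites = vapply(offs, function(o)
                 sum(a$n[(o + 1L):(o + window)]), numeric(1)),
               stringsAsFactors = FALSE)
  }))

  interior_df <- .empty_df(bin = integer(), mean_s = numeric(),
                           n_sites = numeric())
  if (interior) {
    shared <- usable[grepl("^Shared", usable$cls), , drop = FALSE]
    bins_mm <- numeric(inner_bins); bins_n <- numeric(inner_bins)
    for (i in seq_len(nrow(shared))) {
      el <- shared[i, ]
      aseq <- .gp_subseq(genome_a, el$chrom, el$start - el$tsd_len,
                         el$end + el$tsd_len)
      bseq <- .gp_subseq(genome_b, el$b_chrom, el$b_start, el$b_end)
      if (el$b_strand == "-") bseq <- Biostrings::reverseComplement(bseq)
      mm <- .column_mismatch(aseq, bseq)
      bin <- ceiling(seq_along(mm) / (length(mm) / inner_bins))
      bin[bin > inner_bins] <- inner_bins
      ok <- !is.na(mm)
      for (b in unique(bin[ok])) {
        sel <- ok & bin == b
        bins_mm[b] <- bins_mm[b] + sum(mm[sel])
        bins_n[b] <- bins_n[b] + sum(sel)
      }
    }
    interior_df <- data.frame(bin = seq_len(inner_bins),
                              mean_s = ifelse(bins_n > 0, bins_mm / bins_n,
                                              NA_real_),
                              n_sites = bins_n)
  }

  control <- .with_seed(.stream_seed(seed, "control"),
                        .cns_control_blocks(genome_a, genome_b, n_control,
                                            control_len))
  list(flank = flank_df, interior = interior_df, control = control,
       skipped = skipped)
}

# random A blocks compared to B in 1-kb anchored tiles
.cns_control_blocks <- function(genome_a, genome_b, n_control, control_len,
                                tile = 1000L) {
  lens <- Biostrings::width(genome_a)
  names(lens) <- names(genome_a)
  vals <- numeric(0)
  tries <- 0L
  while (length(vals) < n_control && tries < 5L * n_control + 20L) {
    tries <- tries + 1L
    ch <- sample(names(lens), 1L, prob = lens / sum(lens))
    if (lens[[ch]] < control_len + 2L) next
    s <- floor(runif(1, 0, lens[[ch]] - control_len))
    sub_tot <- 0L; site_tot <- 0L
    for (ts in seq(s, s + control_len - tile, by = tile)) {
      aseq <- .gp_subseq(genome_a, ch, ts, ts + tile)
      if (Biostrings::countPattern("N", aseq, fixed = TRUE) > 0) next
      pl <- anchor_fragment(aseq, genome_b, min_coverage = 0.9,
                            min_identity = 0.8, max_hits = 2L)
      if (nrow(pl) != 1 || pl$n_hits[1] != 1) next
      bseq <- .gp_subseq(genome_b, pl$chrom[1], pl$start[1], pl$end[1])
      if (pl$strand[1] == "-") bseq <- Biostrings::reverseComplement(bseq)
      # background substitutions are scattered; a dense mismatch cluster
      # marks a structural edge (element boundary), not substitutions
      mm <- .column_mismatch(aseq, bseq)
      mm[is.na(mm)] <- FALSE
      dens <- diff(c(0, cumsum(mm)), lag = min(100L, length(mm)))
      if (max(dens) > 30) next
      sc <- substitution_count(aseq, bseq)
      sub_tot <- sub_tot + sc$substitutions
      site_tot <- site_tot + sc$compared_sites
    }
    if (site_tot >= tile) vals <- c(vals, sub_tot / site_tot)
  }
  data.frame(block = seq_along(vals), s = vals)
}

#' Distance of insertion sites to the nearest gene
#'
#' Bins each insertion site's distance to the nearest gene boundary (0 if
#' inside a gene) at `bin`-base resolution, together with a uniform random
#' control, the genic fraction of the genome and the inside-gene fraction
#' of insertions.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based insertion points).
#' @param genes data.frame with `chrom`, `start`, `end`.
#' @param chrom_lengths Named lengths of the genome the sites live on.
#' @param bin Bin width, bases.
#' @param n_control Control positions drawn uniformly.
#' @param seed RNG seed for the control.
#' @return list: `histogram` (bin_lo, count, control_count),
#'   `inside_fraction`, `genic_fraction`, `n`.
#' @export
gene_distance_distribution <- function(sites, genes, chrom_lengths,
                                       bin = 100L, n_control = 10000L,
                                       seed = 1L) {
  ggr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start + 1L, genes$end)))
  dist_of <- function(chrom, pos) {
    sgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
    d <- rep(NA_real_, length(sgr))
    hit <- GenomicRanges::distanceToNearest(sgr, ggr)
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    d
  }
  d_obs <- dist_of(sites$chrom, sites$pos)
  ctrl <- .with_seed(.stream_seed(seed, "control"), {
    ch <- sample(names(chrom_lengths), n_control, replace = TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    pos <- floor(runif(n_control, 0, chrom_lengths[ch]))
    data.frame(chrom = ch, pos = pos)
  })
  d_ctrl <- dist_of(ctrl$chrom, ctrl$pos)
  max_d <- max(c(d_obs, d_ctrl), na.rm = TRUE)
  breaks <- seq(0, max_d + bin, by = bin)
  hist_df <- data.frame(
    bin_lo = head(breaks, -1),
    count = as.vector(table(cut(d_obs, breaks, right = FALSE))),
    control_count = as.vector(table(cut(d_ctrl, breaks, right = FALSE))))
  genic_fraction <- sum(as.numeric(GenomicRanges::width(ggr))) /
    sum(as.numeric(chrom_lengths))
  list(histogram = hist_df,
       inside_fraction = mean(d_obs == 0, na.rm = TRUE),
       genic_fraction = genic_fraction,
       n = sum(!is.na(d_obs)))
}

#' CNS of flanking sequences over element age
#'
#' Mean flank substitution frequency in a sliding window over insertion
#' time, plus per-element CNS rates (`s_f / t_ltr`).
#'
#' @param elements data.frame with `t_ltr` (years) and `s_f` columns.
#' @param window Sliding window width, years.
#' @param step Window step (default `window / 4`).
#' @return list: `curve` (window_mid, mean_cns, n), `rates` (per element).
#' @export
cns_vs_time <- function(elements, window = 1e5, step = window / 4) {
  el <- elements[!is.na(elements$t_ltr) & !is.na(elements$s_f), , drop = FALSE]
  if (!nrow(el)) stop("no elements with both age and flank CNS")
  t <- el$t_ltr
  lo <- min(t)
  starts <- if (max(t) - lo < window) lo else seq(lo, max(t) - window, by = step)
  curve <- do.call(rbind, lapply(starts, function(s) {
    sel <- t >= s & t < s + window
    data.frame(window_mid = s + window / 2, mean_cns = mean(el$s_f[sel]),
               n = sum(sel))
  }))
  curve <- curve[curve$n > 0, , drop = FALSE]
  list(curve = curve,
       rates = data.frame(t_ltr = t, rate = el$s_f / pmax(t, 1)))
}
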