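# Structural-variant validation and presence/absence variation (PAV)
# detection. Candidate indels (from a truth ledger or an external caller)
# are validated by re-anchoring their +/-500 bp context onto the other
# genome and recomputing borders and length from the flank placements; PAVs
# are unaligned regions of a whole-genome anchoring chain, N-split, length
# filtered and corroborated by cross-genotype read depth.

#' Validate a candidate indel by flank re-anchoring
#'
#' The 500-bp flanks of the candidate's context window on genome B are
#' anchored onto genome A; the size difference between the inner flank
#' spans on the two genomes is compared to the candidate length. Variants
#' are oriented with B as the reference: a deletion is sequence present in
#' B but absent from A (confirmed when the A span is compatibly shorter),
#' an insertion is A-specific sequence (confirmed when the A span is
#' compatibly longer); compatible means within
#' `max(tol_frac * length, tol_bp)`. On confirmation the borders and
#' length are recalculated from the alignment.
#'
#' @param candidate list or single-row data.frame: `kind`
#'   (`deletion`/`insertion`), `chrom`, `start`, `end` (0-based half-open
#'   on B; an insertion candidate is the breakpoint with `start == end`),
#'   `length` (SV length, bases).
#' @param genome_b,genome_a DNAStringSet pair (candidate coordinates on B).
#' @param flank Context flank, bases.
#' @param min_sv_len Candidates at or below this length are rejected
#'   before alignment (strict `> 100 bp` rule).
#' @param tol_frac,tol_bp Size-compatibility tolerance.
#' @param min_coverage,min_identity Anchoring thresholds.
#' @return The candidate as a one-row data.frame with `validated`,
#'   `recalc_chrom`, `recalc_start`, `recalc_end` (on A), `recalc_length`
#'   and `reason`.
#' @export
validate_indel <- function(candidate, genome_b, genome_a, flank = 500L,
                           min_sv_len = 100L, tol_frac = 0.2, tol_bp = 50L,
                           min_coverage = 0.8, min_identity = 0.8) {
  cand <- as.list(candidate)
  out <- data.frame(kind = cand$kind, chrom = cand$chrom,
                    start = cand$start, end = cand$end,
                    length = cand$length, validated = FALSE,
                    recalc_chrom = NA_character_, recalc_start = NA_integer_,
                    recalc_end = NA_integer_, recalc_length = NA_integer_,
                    reason = "", stringsAsFactors = FALSE)
  if (cand$length <= min_sv_len) {
    out$reason <- "min_length"
    return(out)
  }
  L <- Biostrings::width(genome_b)[match(cand$chrom, names(genome_b))]
  if (is.na(L) || cand$start < flank || cand$end + flank > L) {
    out$reason <- "window_out_of_bounds"
    return(out)
  }
  f5 <- .gp_subseq(genome_b, cand$chrom, cand$start - flank, cand$start)
  f3 <- .gp_subseq(genome_b, cand$chrom, cand$end, cand$end + flank)
  pl <- anchor_fragments(Biostrings::DNAStringSet(list(f5 = f5, f3 = f3)),
                         genome_a, min_coverage = min_coverage,
                         min_identity = min_identity)
  p5 <- pl[pl$query == "f5", , drop = FALSE]
  p3 <- pl[pl$query == "f3", , drop = FALSE]
  gap_b <- cand$end - cand$start
  expected <- if (cand$kind == "deletion") -cand$length else cand$length
  tol <- max(tol_frac * cand$length, tol_bp)
  best <- NULL
  if (nrow(p5) && nrow(p3)) {
    for (i in seq_len(nrow(p5))) for (j in seq_len(nrow(p3))) {
      if (p5$chrom[i] != p3$chrom[j] || p5$strand[i] != p3$strand[j]) next
      if (p5$strand[i] == "+") {
        lo <- p5$end[i]; hi <- p3$start[j]
      } else {
        lo <- p3$end[j]; hi <- p5$start[i]
      }
      gap_a <- hi - lo
      # flanks sharing a duplicated target site may overlap slightly in A
      if (gap_a < -100 || gap_a > gap_b + abs(expected) + 1e5) next
      err <- abs((gap_a - gap_b) - expected)
      if (is.null(best) || err < best$err)
        best <- list(err = err, chrom = p5$chrom[i], lo = lo, hi = hi,
                     gap_a = gap_a)
    }
  }
  if (is.null(best)) {
    out$reason <- "flanks_not_anchored"
    return(out)
  }
  if (best$err > tol) {
    out$reason <- "size_incompatible"
    return(out)
  }
  out$validated <- TRUE
  out$recalc_chrom <- best$chrom
  out$recalc_start <- best$lo
  out$recalc_end <- best$hi
  out$recalc_length <- abs(best$gap_a - gap_b)
  out$reason <- "confirmed"
  out
}

#' Whole-genome anchoring chain between two assemblies
#'
#' Tiles genome A, anchors every tile onto genome B, keeps uniquely placed
#' tiles and chains them by longest collinear subsequence per chromosome
#' and strand. The chained tiles are the aligned blocks; everything else is
#' unaligned on the respective genome. Repetitive tiles (multiple
#' placements) are deliberately left unaligned - the depth filter of
#' [detect_pav()] decides their fate, as in read-based practice.
#'
#' @param genome_a,genome_b DNAStringSet pair.
#' @param tile Tile width, bases.
#' @param min_coverage,min_identity Anchoring thresholds for a tile.
#' @return data.frame of blocks: `a_chrom`, `a_start`, `a_end`, `b_chrom`,
#'   `b_start`, `b_end`, `strand`.
#' @export
align_block_chain <- function(genome_a, genome_b, tile = 1000L,
                              min_coverage = 0.9, min_identity = 0.9) {
  blocks <- list()
  for (ch in names(genome_a)) {
    L <- Biostrings::width(genome_a)[match(ch, names(genome_a))]
    starts <- seq(0L, L - tile, by = tile)
    tiles <- Biostrings::DNAStringSet(
      lapply(starts, function(s) .gp_subseq(genome_a, ch, s, s + tile)))
    names(tiles) <- sprintf("t%06d", starts)
    pl <- anchor_fragments(tiles, genome_b, min_coverage = min_coverage,
                           min_identity = min_identity, max_hits = 3L)
    pl <- pl[pl$n_hits == 1L, , drop = FALSE]
    if (!nrow(pl)) next
    pl$a_start <- as.integer(sub("^t", "", pl$query))
    for (bch in unique(pl$chrom)) for (strand in c("+", "-")) {
      p <- pl[pl$chrom == bch & pl$strand == strand, , drop = FALSE]
      if (!nrow(p)) next
      p <- p[order(p$a_start), , drop = FALSE]
      y <- if (strand == "+") p$start else -p$start
      keep <- .lis_index(y)
      p <- p[keep, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- data.frame(
        a_chrom = ch, a_start = p$a_start, a_end = p$a_start + tile,
        b_chrom = bch, b_start = p$start, b_end = p$end,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks))
    return(.empty_df(a_chrom = character(), a_start = integer(),
                     a_end = integer(), b_chrom = character(),
                     b_start = integer(), b_end = integer(),
                     strand = character()))
  do.call(rbind, blocks)
}

# longest strictly increasing subsequence, O(n log n), returns indices
.lis_index <- function(y) {
  n <- length(y)
  if (n <= 1) return(seq_len(n))
  tails <- integer(0)   # index of smallest tail of LIS of each length
  prev <- integer(n)
  for (i in seq_len(n)) {
    vals <- y[tails]
    pos <- findInterval(y[i] - 1e-9, vals) + 1L
    prev[i] <- if (pos > 1L) tails[pos - 1L] else 0L
    if (pos > length(tails)) tails <- c(tails, i) else tails[pos] <- i
  }
  out <- integer(0)
  k <- tails[length(tails)]
  while (k > 0L) { out <- c(k, out); k <- prev[k] }
  out
}

#' Detect presence/absence variation from an alignment block chain
#'
#' Per genome, merges aligned blocks separated by at most `merge_distance`
#' bases, extracts unaligned regions strictly longer than `min_len`,
#' removes or splits them at N bases, and retains a region as a PAV iff its
#' mean cross-genotype depth is below `depth_fraction` of the genome-wide
#' mean (N positions excluded from the mean). PAVs on genome B are labelled
#' deletions and PAVs on genome A insertions, so they are consistent with
#' indel calls against B as the reference.
#'
#' @param blocks From [align_block_chain()] (or imported coordinates).
#' @param genome_a,genome_b DNAStringSet pair.
#' @param depth_a,depth_b Per-chromosome depth lists (cross-genotype reads);
#'   `NULL` skips the filter and flags every emitted PAV.
#' @param merge_distance,min_len,depth_fraction Filter parameters.
#' @return data.frame: `kind`, `genome`, `chrom`, `start`, `end`, `length`,
#'   `mean_depth`, `depth_checked`.
#' @export
detect_pav <- function(blocks, genome_a, genome_b, depth_a = NULL,
                       depth_b = NULL, merge_distance = 50L, min_len = 100L,
                       depth_fraction = 0.1) {
  out <- list()
  for (side in c("A", "B")) {
    genome <- if (side == "A") genome_a else genome_b
    depth <- if (side == "A") depth_a else depth_b
    kind <- if (side == "A") "insertion" else "deletion"
    pre <- if (side == "A") "a_" else "b_"
    depth_mean <- if (!is.null(depth)) .depth_genome_mean(depth, genome) else NA
    if (is.null(depth))
      warning("no depth track for genome ", side,
              ": PAV depth filter skipped", call. = FALSE)
    for (ch in names(genome)) {
      L <- Biostrings::width(genome)[match(ch, names(genome))]
      b <- blocks[blocks[[paste0(pre, "chrom")]] == ch, , drop = FALSE]
      aligned <- IRanges::reduce(
        IRanges::IRanges(b[[paste0(pre, "start")]] + 1L,
                         b[[paste0(pre, "end")]]),
        min.gapwidth = merge_distance + 1L)
      un <- IRanges::gaps(aligned, start = 1L, end = L)
      if (!length(un)) next
      # split/remove at N positions
      nr <- find_n_runs(genome[ch], min_len = 1L)
      if (nrow(nr)) {
        nir <- IRanges::IRanges(nr$start + 1L, nr$end)
        un <- IRanges::setdiff(un, nir)
      }
      un <- un[IRanges::width(un) > min_len]
      for (i in seq_along(un)) {
        s0 <- IRanges::start(un)[i] - 1L; e0 <- IRanges::end(un)[i]
        md <- NA_real_; keep <- TRUE; checked <- FALSE
        if (!is.null(depth) && !is.null(depth[[ch]])) {
          checked <- TRUE
          cutoff <- depth_fraction * depth_mean
          v <- as.numeric(depth[[ch]][(s0 + 1L):e0])
          # block boundaries are block-resolution coarse: shrink the region
          # to its longest run of sub-cutoff positions before testing
          r <- rle(v < cutoff)
          if (any(r$values)) {
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            bi <- which(r$values)[which.max(r$lengths[r$values])]
            e0 <- s0 + ends[bi]
            s0 <- s0 + starts[bi] - 1L
            v <- v[starts[bi]:ends[bi]]
          }
          md <- mean(v)
          keep <- md < cutoff && (e0 - s0) > min_len
        }
        if (keep)
          out[[length(out) + 1L]] <- data.frame(
            kind = kind, genome = side, chrom = ch, start = s0, end = e0,
            length = e0 - s0, mean_depth = md, depth_checked = checked,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(.empty_df(kind = character(), genome = character(),
                     chrom = character(), start = integer(), end = integer(),
                     length = integer(), mean_depth = numeric(),
                     depth_checked = logical()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

.depth_genome_mean <- function(depth, genome) {
  tot <- 0; n <- 0
  for (ch in names(depth)) {
    v <- as.numeric(depth[[ch]])
    nr <- find_n_runs(genome[ch], min_len = 1L)
    if (nrow(nr)) {
      mask <- rep(TRUE, length(v))
      for (i in seq_len(nrow(nr))) mask[(nr$start[i] + 1L):nr$end[i]] <- FALSE
      v <- v[mask]
    }
    tot <- tot + sum(v); n <- n + length(v)
  }
  tot / n
}

#' Is a variant context present in an assembly?
#'
#' Anchors the +/-500 bp context sequence of a variant onto an assembly and
#' reports presence (at least one placement at the thresholds).
#'
#' @param context_seq The variant's context sequence (allele plus flanks).
#' @param assembly DNAStringSet.
#' @param min_coverage,min_identity Anchoring thresholds.
#' @return logical.
#' @export
variant_present <- function(context_seq, assembly, min_coverage = 0.8,
                            min_identity = 0.9) {
  nrow(anchor_fragment(context_seq, assembly, min_coverage = min_coverage,
                       min_identity = min_identity, max_hits = 1L)) > 0
}

#' Shared-variant classification against a parity panel
#'
#' A variant is shared iff it is present in every parity assembly and
#' absent from the donor-exclusion assembly (the panel definition used for
#' shared SNPs and shared SVs between cultivar assemblies).
#'
#' @param parity_present Logical vector, presence per parity assembly.
#' @param donor_present Logical, presence in the exclusion genome.
#' @return logical.
#' @export
classify_shared <- function(parity_present, donor_present = FALSE) {
  length(parity_present) > 0 && all(parity_present) && !donor_present
}

#' Annotate variants with the repeat class at their breakpoints
#'
#' Assigns each variant the class of the repeat it overlaps, by fixed
#' precedence LTR > DNA > SINE > LINE > Other; `Non` when no repeat
#' overlaps. For inversions both breakpoints are annotated separately as
#' well.
#'
#' @param variants data.frame with `chrom`, `start`, `end` and optionally
#'   `kind`.
#' @param repeats data.frame with `chrom`, `start`, `end`, `class`.
#' @return `variants` with `repeat_class` (and `bp_start_class`,
#'   `bp_end_class` for inversions).
#' @export
annotate_breakpoints <- function(variants, repeats) {
  precedence <- c("LTR", "DNA", "SINE", "LINE", "Other")
  rcl <- ifelse(repeats$class %in% precedence, repeats$class, "Other")
  rgr <- GenomicRanges::GRanges(repeats$chrom,
                                IRanges::IRanges(repeats$start + 1L,
                                                 repeats$end), class = rcl)
  pick <- function(gr) {
    ov <- GenomicRanges::findOverlaps(gr, rgr)
    cls <- rep("Non", length(gr))
    if (length(ov)) {
      for (i in unique(S4Vectors::queryHits(ov))) {
        hits <- rcl[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
        cls[i] <- precedence[min(match(hits, precedence))]
      }
    }
    cls
  }
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$start + 1L,
                                                 pmax(variants$end,
                                                      variants$start + 1L)))
  variants$repeat_class <- pick(vgr)
  if ("kind" %in% names(variants) && any(variants$kind == "inversion")) {
    inv <- variants$kind == "inversion"
    bp1 <- GenomicRanges::GRanges(variants$chrom[inv],
             IRanges::IRanges(variants$start[inv] + 1L, variants$start[inv] + 1L))
    bp2 <- GenomicRanges::GRanges(variants$chrom[inv],
             IRanges::IRanges(variants$end[inv], variants$end[inv]))
    variants$bp_start_class <- NA_character_
    variants$bp_end_class <- NA_character_
    variants$bp_start_class[inv] <- pick(bp1)
    variants$bp_end_class[inv] <- pick(bp2)
  }
  variants
}
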