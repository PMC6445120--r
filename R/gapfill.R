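# Reciprocal gap closure: extract and merge N-gaps on the recipient, anchor
# the 500-bp flanks of each gap in the donor, apply the four closure
# criteria in order, and patch the closed gaps with the donor intervening
# sequence.
#
# Criteria (evaluated in order, first failure recorded):
#   i   both flanks anchored (coverage >= 0.8) within `max_span` on the same
#       chromosome with the same orientation;
#   ii  the combined placement count of the two flanks is < 5;
#   iii the donor intervening sequence contains no ambiguous (N) bases;
#   iv  the intervening sequence is corroborated: it anchors (coverage >=
#       0.8) in at least one parity assembly, OR more than 90% of its
#       positions have depth > 3 in the donor depth track. With neither
#       source supplied the criterion is skipped and flagged.

#' Extract N-gaps and merge nearby ones
#'
#' Maximal N-runs merged when separated by at most `merge_distance` bases;
#' a merged gap spans from the first run's start to the last run's end.
#'
#' @param genome DNAStringSet (the gap-bearing recipient).
#' @param merge_distance Maximum separation for merging, bases (default 500).
#' @param min_len Minimum N-run length to consider.
#' @return data.frame `chrom`, `start`, `end`, `width` (0-based half-open).
#' @export
extract_and_merge_gaps <- function(genome, merge_distance = 500L,
                                   min_len = 1L) {
  runs <- find_n_runs(genome, min_len = min_len)
  if (!nrow(runs)) return(runs)
  out <- lapply(split(runs, runs$chrom), function(r) {
    ir <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end),
                          min.gapwidth = merge_distance + 1L)
    data.frame(chrom = r$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), width = IRanges::width(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attempt to close one gap from the donor genome
#'
#' @param gap One row of [extract_and_merge_gaps()] output (list or
#'   single-row data.frame with `chrom`, `start`, `end`).
#' @param recipient,donor DNAStringSet genomes.
#' @param parity_assemblies Optional list of DNAStringSet assemblies for
#'   criterion iv corroboration.
#' @param donor_depth Optional per-chromosome depth (list of numeric/Rle)
#'   over the donor genome for the depth route of criterion iv.
#' @param flank Flank length, bases (default 500).
#' @param max_span Maximum donor span between flank placements (500 kb).
#' @param max_total_hits Criterion ii bound: combined flank placements must
#'   be strictly below this (default 5).
#' @param hits_per_flank Apply the placement bound per flank instead of to
#'   the sum.
#' @param min_coverage,min_identity Anchoring thresholds.
#' @return list of class `gap_closure`: `gap`, `status`
#'   (`closed`/`failed`), `failed_criterion` (`i`..`iv`, `none`, or
#'   `flank_extraction`), `patched_sequence`, `donor_chrom`,
#'   `donor_start`, `donor_end`, `strand`, `n_hits`, `iv_route`.
#' @export
close_gap <- function(gap, recipient, donor, parity_assemblies = NULL,
                      donor_depth = NULL, flank = 500L, max_span = 5e5,
                      max_total_hits = 5L, hits_per_flank = FALSE,
                      min_coverage = 0.8, min_identity = 0.8) {
  gap <- as.list(gap)
  res <- list(gap = gap, status = "failed", failed_criterion = "none",
              patched_sequence = "", donor_chrom = NA_character_,
              donor_start = NA_integer_, donor_end = NA_integer_,
              strand = NA_character_, n_hits = NA_integer_,
              iv_route = NA_character_)
  class(res) <- "gap_closure"
  L <- Biostrings::width(recipient)[match(gap$chrom, names(recipient))]
  if (gap$start < flank || gap$end + flank > L) {
    res$failed_criterion <- "flank_extraction"
    return(res)
  }
  f5 <- .gp_subseq(recipient, gap$chrom, gap$start - flank, gap$start)
  f3 <- .gp_subseq(recipient, gap$chrom, gap$end, gap$end + flank)
  qs <- Biostrings::DNAStringSet(list(f5 = f5, f3 = f3))
  pl <- anchor_fragments(qs, donor, min_coverage = min_coverage,
                         min_identity = min_identity)
  p5 <- pl[pl$query == "f5", , drop = FALSE]
  p3 <- pl[pl$query == "f3", , drop = FALSE]
  n5 <- if (nrow(p5)) p5$n_hits[1] else 0L
  n3 <- if (nrow(p3)) p3$n_hits[1] else 0L
  res$n_hits <- n5 + n3

  pair <- .pick_flank_pair(p5, p3, max_span)
  if (is.null(pair)) {
    res$failed_criterion <- "i"
    return(res)
  }
  ii_fail <- if (hits_per_flank) (n5 >= max_total_hits || n3 >= max_total_hits)
             else (n5 + n3 >= max_total_hits)
  if (ii_fail) {
    res$failed_criterion <- "ii"
    return(res)
  }
  intv <- .donor_intervening(pair, donor)
  if (Biostrings::countPattern("N", intv$seq, fixed = TRUE) > 0) {
    res$failed_criterion <- "iii"
    return(res)
  }
  iv <- .criterion_iv(intv, parity_assemblies, donor_depth,
                      min_coverage, min_identity)
  res$iv_route <- iv$route
  if (!iv$pass) {
    res$failed_criterion <- "iv"
    return(res)
  }
  res$status <- "closed"
  res$patched_sequence <- as.character(intv$seq)
  res$donor_chrom <- intv$chrom
  res$donor_start <- intv$start
  res$donor_end <- intv$end
  res$strand <- intv$strand
  res
}

# Criterion i: same chrom, same strand, correct order, span bound; among
# admissible pairs choose the one minimising the intervening span, failing
# as ambiguous on an exact tie between distinct pairs.
.pick_flank_pair <- function(p5, p3, max_span) {
  if (!nrow(p5) || !nrow(p3)) return(NULL)
  cand <- list()
  for (i in seq_len(nrow(p5))) for (j in seq_len(nrow(p3))) {
    if (p5$chrom[i] != p3$chrom[j] || p5$strand[i] != p3$strand[j]) next
    if (p5$strand[i] == "+") {
      inner_lo <- p5$end[i]; inner_hi <- p3$start[j]
    } else {
      inner_lo <- p3$end[j]; inner_hi <- p5$start[i]
    }
    span <- inner_hi - inner_lo
    if (span < 0 || span > max_span) next
    cand[[length(cand) + 1L]] <- list(p5 = p5[i, ], p3 = p3[j, ], span = span)
  }
  if (!length(cand)) return(NULL)
  spans <- vapply(cand, `[[`, numeric(1), "span")
  best <- which(spans == min(spans))
  if (length(best) > 1) return(NULL)  # ambiguous
  cand[[best]]
}

.donor_intervening <- function(pair, donor) {
  ch <- pair$p5$chrom
  if (pair$p5$strand == "+") {
    s <- pair$p5$end; e <- pair$p3$start
  } else {
    s <- pair$p3$end; e <- pair$p5$start
  }
  seq <- .gp_subseq(donor, ch, s, e)
  if (pair$p5$strand == "-") seq <- Biostrings::reverseComplement(seq)
  list(seq = seq, chrom = ch, start = s, end = e, strand = pair$p5$strand)
}

.criterion_iv <- function(intv, parity_assemblies, donor_depth,
                          min_coverage, min_identity) {
  if (is.null(parity_assemblies) && is.null(donor_depth))
    return(list(pass = TRUE, route = "unchecked"))
  if (!is.null(parity_assemblies)) {
    for (asm in parity_assemblies) {
      if (length(intv$seq) >= 50) {
        hit <- anchor_fragment(intv$seq, asm, min_coverage = min_coverage,
                               min_identity = min_identity, max_hits = 1L)
        if (nrow(hit)) return(list(pass = TRUE, route = "parity"))
      }
    }
  }
  if (!is.null(donor_depth)) {
    d <- donor_depth[[intv$chrom]]
    if (!is.null(d) && intv$end > intv$start) {
      v <- as.numeric(d[(intv$start + 1L):intv$end])
      if (mean(v > 3) > 0.9) return(list(pass = TRUE, route = "depth"))
    }
    if (intv$end == intv$start) return(list(pass = TRUE, route = "depth"))
  }
  list(pass = FALSE, route = "none")
}

#' Close all gaps of a recipient genome
#'
#' @inheritParams close_gap
#' @param gaps From [extract_and_merge_gaps()]; computed if omitted.
#' @param ... Passed to [close_gap()].
#' @return list with `closures` (list of `gap_closure`) and `report`
#'   (one data.frame row per gap).
#' @export
close_gaps <- function(recipient, donor, gaps = NULL, ...) {
  if (is.null(gaps)) gaps <- extract_and_merge_gaps(recipient)
  closures <- lapply(seq_len(nrow(gaps)), function(i)
    close_gap(gaps[i, ], recipient, donor, ...))
  report <- do.call(rbind, lapply(closures, function(cl) data.frame(
    chrom = cl$gap$chrom, start = cl$gap$start, end = cl$gap$end,
    gap_width = cl$gap$end - cl$gap$start, status = cl$status,
    failed_criterion = cl$failed_criterion,
    patch_length = nchar(cl$patched_sequence), n_hits = cl$n_hits,
    iv_route = cl$iv_route, stringsAsFactors = FALSE)))
  list(closures = closures, report = report)
}

#' Apply gap closures to the recipient genome
#'
#' Replaces each closed gap's merged N-span with its patched sequence,
#' shifting downstream coordinates consistently.
#'
#' @param recipient DNAStringSet.
#' @param closures List of `gap_closure` objects (from [close_gaps()]).
#' @return list with `genome` (patched DNAStringSet) and `report` (closed
#'   count, mean/median patch length, per-gap rows with old and new
#'   coordinates).
#' @export
apply_closures <- function(recipient, closures) {
  closed <- Filter(function(cl) cl$status == "closed", closures)
  seqs <- as.character(recipient)
  rows <- list()
  for (ch in names(seqs)) {
    cls <- Filter(function(cl) cl$gap$chrom == ch, closed)
    if (!length(cls)) next
    starts <- vapply(cls, function(cl) cl$gap$start, numeric(1))
    ends <- vapply(cls, function(cl) cl$gap$end, numeric(1))
    o <- order(starts)
    if (any(starts[o][-1] < ends[o][-length(o)]))
      stop("overlapping closures on ", ch)
    cls <- cls[o]
    shift <- 0L
    s <- seqs[[ch]]
    for (cl in cls) {
      ns <- cl$gap$start + shift; ne <- cl$gap$end + shift
      patch <- cl$patched_sequence
      s <- paste0(substr(s, 1L, ns), patch, substr(s, ne + 1L, nchar(s)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, old_start = cl$gap$start, old_end = cl$gap$end,
        new_start = ns, new_end = ns + nchar(patch),
        patch_length = nchar(patch), stringsAsFactors = FALSE)
      shift <- shift + nchar(patch) - (cl$gap$end - cl$gap$start)
    }
    seqs[[ch]] <- s
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(recipient)
  patched <- if (length(rows)) do.call(rbind, rows) else
    .empty_df(chrom = character(), old_start = integer(),
              old_end = integer(), new_start = integer(),
              new_end = integer(), patch_length = integer())
  lens <- patched$patch_length
  list(genome = genome,
       report = list(n_closed = length(closed),
                     mean_patch = if (length(lens)) mean(lens) else NA_real_,
                     median_patch = if (length(lens)) median(lens) else NA_real_,
                     patched = patched))
}
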