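# Fragment anchoring: k-mer seeding (matchPDict) followed by verification,
# either a fast gap-free mismatch count at the seeded diagonal or a local
# Smith-Waterman in a candidate window. This is the placement engine shared
# by gap filling, SV validation, PAV chaining and LTR flank classification.

#' Anchor a set of query fragments onto a target genome
#'
#' Finds all placements of each query on either strand that meet both the
#' coverage threshold (aligned fraction of the query) and the identity
#' threshold (matches per alignment column). Placements are ranked by
#' identity, then coverage, with ties broken by (chrom, start) so the
#' ordering is deterministic. `n_hits` on every row is the total number of
#' reported placements for that query.
#'
#' @param queries Named DNAStringSet (or character vector) of fragments.
#' @param target Named DNAStringSet genome.
#' @param min_coverage Minimum aligned query fraction (default 0.8, the
#'   conventional flank-anchoring threshold).
#' @param min_identity Minimum identity per alignment column.
#' @param k Seed length.
#' @param stride Offset between successive seeds taken from the query.
#' @param band Window padding around the seeded diagonal for verification.
#' @param max_hits Stop reporting beyond this many placements per query.
#' @return data.frame with columns `query`, `chrom`, `start`, `end`
#'   (0-based half-open on the target), `strand`, `coverage`, `identity`,
#'   `score`, `n_hits`.
#' @export
anchor_fragments <- function(queries, target, min_coverage = 0.8,
                             min_identity = 0.8, k = 15L, stride = 25L,
                             band = 60L, max_hits = 100L) {
  queries <- .as_dnaset(queries)
  target <- .as_dnaset(target)
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(target))) names(target) <- paste0("t", seq_along(target))
  if (any(Biostrings::width(queries) < k))
    stop("fragment shorter than the seed size (", k, " bp) is unusable as an anchor")

  hits <- list()
  for (ori in c("+", "-")) {
    qset <- if (ori == "+") queries else Biostrings::reverseComplement(queries)
    seeds <- .seed_table(qset, k, stride)
    if (!nrow(seeds$tab)) next
    pd <- Biostrings::PDict(seeds$set)
    for (ci in seq_along(target)) {
      m <- Biostrings::matchPDict(pd, target[[ci]])
      st <- Biostrings::startIndex(m)
      nh <- lengths(st)
      if (!sum(nh)) next
      idx <- rep.int(seq_along(nh), nh)
      df <- data.frame(qi = seeds$tab$qi[idx], qoff = seeds$tab$off[idx],
                       tstart = unlist(st, use.names = FALSE))
      df$diag <- df$tstart - df$qoff + 1L
      hits[[length(hits) + 1L]] <-
        .verify_candidates(df, qset, target, ci, ori, min_coverage,
                           min_identity, band, max_hits)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out) || !nrow(out)) {
    return(.empty_df(query = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     coverage = numeric(), identity = numeric(),
                     score = numeric(), n_hits = integer()))
  }
  out <- .dedup_placements(out)
  # deterministic ranking within query
  out <- out[order(out$query, -out$identity, -out$coverage,
                   out$chrom, out$start), , drop = FALSE]
  nh <- table(out$query)
  out$n_hits <- as.integer(nh[out$query])
  keep <- unlist(lapply(split(seq_len(nrow(out)), out$query),
                        function(i) head(i, max_hits)), use.names = FALSE)
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor a single fragment
#'
#' Convenience wrapper around [anchor_fragments()] for one query.
#' @inheritParams anchor_fragments
#' @param fragment A single sequence (character or DNAString), length >= 50.
#' @return See [anchor_fragments()].
#' @export
anchor_fragment <- function(fragment, target, min_coverage = 0.8,
                            min_identity = 0.8, ...) {
  fragment <- .as_dnaset(fragment)
  if (Biostrings::width(fragment)[1] < 50)
    stop("fragment shorter than 50 bp is unusable as an anchor")
  names(fragment) <- "query"
  anchor_fragments(fragment, target, min_coverage = min_coverage,
                   min_identity = min_identity, ...)
}

# seeds per query at fixed offsets; seeds containing N are dropped
.seed_table <- function(qset, k, stride) {
  qi <- integer(); off <- integer()
  for (i in seq_along(qset)) {
    w <- Biostrings::width(qset)[i]
    o <- unique(c(seq(1L, w - k + 1L, by = stride), w - k + 1L))
    qi <- c(qi, rep.int(i, length(o))); off <- c(off, o)
  }
  set <- Biostrings::DNAStringSet(qset[qi], start = off, width = k)
  names(set) <- NULL
  has_n <- Biostrings::vcountPattern("N", set, fixed = TRUE) > 0
  tab <- data.frame(qi = qi, off = off)[!has_n, , drop = FALSE]
  list(set = set[!has_n], tab = tab)
}

# Cluster seed hits on the diagonal and verify each candidate window.
# Verification stops once `stop_cap` placements pass for a query (callers
# that cap reported hits need no more than that many).
.verify_candidates <- function(df, qset, target, ci, ori, min_coverage,
                               min_identity, band, stop_cap = Inf) {
  subj <- target[[ci]]
  tlen <- length(subj)
  chrom <- names(target)[ci]
  res <- list()
  o <- order(df$qi, df$diag)
  df <- df[o, , drop = FALSE]
  qi_runs <- rle(df$qi)
  row_end <- cumsum(qi_runs$lengths)
  row_start <- row_end - qi_runs$lengths + 1L
  widths <- Biostrings::width(qset)
  for (r in seq_along(qi_runs$values)) {
    qi <- qi_runs$values[r]
    dg <- df$diag[row_start[r]:row_end[r]]
    grp <- cumsum(c(1L, diff(dg) > 2L * band))
    qlen <- widths[qi]
    q <- qset[[qi]]
    ws_v <- integer(); we_v <- integer(); diag_v <- integer()
    for (g in unique(grp)) {
      dd <- dg[grp == g]
      ws_v <- c(ws_v, max(1L, dd[1] - band))
      we_v <- c(we_v, min(tlen, dd[length(dd)] + qlen - 1L + band))
      # modal diagonal = best gap-free placement guess
      tb <- tabulate(match(dd, unique(dd)))
      diag_v <- c(diag_v, unique(dd)[which.max(tb)])
    }
    # merge overlapping windows
    keep_w <- rep(TRUE, length(ws_v))
    if (length(ws_v) > 1) {
      oo <- order(ws_v)
      ws_v <- ws_v[oo]; we_v <- we_v[oo]; diag_v <- diag_v[oo]
      merged_ws <- ws_v[1]; merged_we <- we_v[1]
      mw <- list(); md <- list(); cur_d <- diag_v[1]
      for (j in seq_along(ws_v)[-1]) {
        if (ws_v[j] <= merged_we) {
          merged_we <- max(merged_we, we_v[j]); cur_d <- c(cur_d, diag_v[j])
        } else {
          mw[[length(mw) + 1L]] <- c(merged_ws, merged_we)
          md[[length(md) + 1L]] <- cur_d
          merged_ws <- ws_v[j]; merged_we <- we_v[j]; cur_d <- diag_v[j]
        }
      }
      mw[[length(mw) + 1L]] <- c(merged_ws, merged_we)
      md[[length(md) + 1L]] <- cur_d
    } else {
      mw <- list(c(ws_v, we_v)); md <- list(diag_v)
    }
    # widest seed support first, so early termination keeps the best hits
    ord <- order(-vapply(md, length, integer(1)))
    found <- 0L
    for (wi in ord) {
      if (found >= stop_cap) break
      pl <- .verify_one(q, subj, mw[[wi]][1], mw[[wi]][2], unique(md[[wi]]),
                        qlen, tlen, min_coverage, min_identity)
      if (is.null(pl)) next
      found <- found + 1L
      res[[length(res) + 1L]] <- data.frame(
        query = names(qset)[qi], chrom = chrom, start = pl$start,
        end = pl$end, strand = ori, coverage = pl$coverage,
        identity = pl$identity, score = pl$score, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

.verify_one <- function(q, subj, ws, we, cand_diags, qlen, tlen,
                        min_coverage, min_identity) {
  # fast path: gap-free placement at a seeded diagonal
  best <- NULL
  for (dg in cand_diags) {
    if (dg >= 1L && dg + qlen - 1L <= tlen) {
      mm <- Biostrings::neditStartingAt(q, subj, starting.at = dg,
                                        with.indels = FALSE)
      ident <- 1 - mm / qlen
      if (ident >= min_identity &&
          (is.null(best) || ident > best$identity)) {
        best <- list(start = dg - 1L, end = dg - 1L + qlen, coverage = 1,
                     identity = ident, score = 2 * (qlen - mm) - 3 * mm)
      }
    }
  }
  if (!is.null(best)) return(best)
  # slow path: local DP inside the window
  win <- Biostrings::subseq(subj, ws, we)
  aln <- Biostrings::pairwiseAlignment(
    q, win, type = "local", substitutionMatrix = .gp_submat(),
    gapOpening = .gp_align_defaults$gap_opening,
    gapExtension = .gp_align_defaults$gap_extension)
  if (Biostrings::score(aln) <= 0) return(NULL)
  p <- Biostrings::pattern(aln)
  covg <- (IRanges::end(p) - IRanges::start(p) + 1) / qlen
  if (covg < min_coverage) return(NULL)
  has_n <- Biostrings::countPattern("N", win, fixed = TRUE) > 0 ||
    Biostrings::countPattern("N", q, fixed = TRUE) > 0
  if (!has_n) {
    # C-level counters; equivalent to the column count when no N involved
    ni <- Biostrings::nindel(aln)
    cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
      sum(Biostrings::insertion(ni)[, "WidthSum"]) +
      sum(Biostrings::deletion(ni)[, "WidthSum"])
    ident <- Biostrings::nmatch(aln) / cols
  } else {
    ident <- .aln_identity(aln)$identity
  }
  if (ident < min_identity) return(NULL)
  s <- Biostrings::subject(aln)
  list(start = ws - 1L + IRanges::start(s) - 1L,
       end = ws - 1L + IRanges::end(s),
       coverage = covg, identity = ident,
       score = Biostrings::score(aln))
}

# collapse overlapping placements of the same query/chrom/strand, keeping the
# best-scoring representative
.dedup_placements <- function(out) {
  key <- paste(out$query, out$chrom, out$strand, sep = "\r")
  dup <- key %in% key[duplicated(key)]
  if (!any(dup)) return(out)
  keep <- !dup
  for (kk in unique(key[dup])) {
    i <- which(key == kk)
    ir <- IRanges::IRanges(out$start[i] + 1L, out$end[i])
    ov <- IRanges::findOverlaps(ir, IRanges::reduce(ir))
    for (g in unique(S4Vectors::subjectHits(ov))) {
      members <- i[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == g]]
      keep[members[which.max(out$score[members])]] <- TRUE
    }
  }
  out[keep, , drop = FALSE]
}
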