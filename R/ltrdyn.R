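# Intact LTR retrotransposon detection, cross-genome classification and
# molecular dating.
#
# The detector is a direct-repeat scanner sufficient for assemblies whose
# intact elements carry near-identical LTR pairs, TG...CA termini and exact
# TSD copies (the structure the simulator produces); it is not a
# general-purpose replacement for repeat-dense real genomes. Candidate LTR
# pairs are seeded from k-mers occurring at a conserved separation, then
# boundaries are refined so that the terminal motif and a 4-6 bp TSD frame
# the element.

#' Detect intact LTR retrotransposons
#'
#' @param genome DNAStringSet.
#' @param min_ltr,max_ltr LTR length bounds, bases.
#' @param min_similarity Minimum LTR-LTR global identity.
#' @param tsd_range TSD length bounds (within 4-6).
#' @param motif Terminal motif; `"TGCA"` means each LTR starts `TG` and
#'   ends `CA`.
#' @param max_element Maximum element length, bases.
#' @param k Seed k-mer length.
#' @param min_seeds Minimum k-mer pairs supporting a candidate.
#' @param max_code_count Ignore k-mers occurring more often than this
#'   (tandem-repeat guard).
#' @return data.frame: `chrom`, `start`, `end` (element body, 0-based
#'   half-open, TSDs excluded), `ltr_len`, `tsd`, `tsd_len`,
#'   `motif_ok`, `ltr_identity`, `K` (raw LTR-LTR divergence),
#'   `n_seeds`.
#' @export
detect_intact_ltr <- function(genome, min_ltr = 100L, max_ltr = 7000L,
                              min_similarity = 0.9, tsd_range = c(4L, 6L),
                              motif = "TGCA", max_element = 20000L,
                              k = 16L, min_seeds = 5L,
                              max_code_count = 100L) {
  genome <- .as_dnaset(genome)
  out <- list()
  for (ci in seq_along(genome)) {
    ch <- names(genome)[ci]
    s_chr <- as.character(genome[[ci]])
    cands <- .ltr_candidates(s_chr, min_ltr, max_ltr, max_element, k,
                             min_seeds, max_code_count)
    for (cand in cands) {
      el <- .refine_ltr_boundaries(s_chr, cand, min_ltr, max_ltr,
                                   max_element, tsd_range, motif,
                                   min_similarity)
      if (is.null(el)) next
      out[[length(out) + 1L]] <- cbind(data.frame(chrom = ch,
                                                  stringsAsFactors = FALSE),
                                       el)
    }
  }
  if (!length(out))
    return(.empty_df(chrom = character(), start = integer(), end = integer(),
                     ltr_len = integer(), tsd = character(),
                     tsd_len = integer(), motif_ok = logical(),
                     ltr_identity = numeric(), K = numeric(),
                     n_seeds = integer()))
  df <- do.call(rbind, out)
  # two nearby copies of one family can masquerade as a single huge element
  # whose "LTRs" are the full copies; such a candidate has a complete
  # element nested inside one of its LTRs (padded for boundary jitter) and
  # is dropped
  if (nrow(df) > 1) {
    pad <- 500L
    drop <- rep(FALSE, nrow(df))
    for (i in seq_len(nrow(df))) {
      inside <- function(lo, hi) any(
        df$chrom == df$chrom[i] & seq_len(nrow(df)) != i &
          df$start >= lo - pad & df$end <= hi + pad)
      if (inside(df$start[i], df$start[i] + df$ltr_len[i]) ||
          inside(df$end[i] - df$ltr_len[i], df$end[i]))
        drop[i] <- TRUE
    }
    df <- df[!drop, , drop = FALSE]
  }
  # resolve remaining overlaps by weighted interval scheduling on the
  # alignment score: two genuine elements jointly outscore any chimeric
  # candidate spanning parts of both
  df <- do.call(rbind, lapply(split(df, df$chrom), .wis_select))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# maximum-total-score set of non-overlapping candidates (classic DP)
.wis_select <- function(d) {
  n <- nrow(d)
  if (n <= 1) return(d)
  d <- d[order(d$end), , drop = FALSE]
  pred <- vapply(seq_len(n), function(i) {
    j <- which(d$end <= d$start[i])
    if (length(j)) max(j) else 0L
  }, integer(1))
  opt <- numeric(n + 1L)
  take <- logical(n)
  for (i in seq_len(n)) {
    with_i <- d$score[i] + opt[pred[i] + 1L]
    opt[i + 1L] <- max(opt[i], with_i)
    take[i] <- with_i >= opt[i]
  }
  keep <- logical(n)
  i <- n
  while (i >= 1L) {
    if (take[i]) { keep[i] <- TRUE; i <- pred[i] } else i <- i - 1L
  }
  d[keep, , drop = FALSE]
}

# k-mer pairs at conserved separation -> candidate (p1_min, p1_max, d)
.ltr_candidates <- function(s_chr, min_ltr, max_ltr, max_element, k,
                            min_seeds, max_code_count) {
  L <- nchar(s_chr)
  if (L < 2L * min_ltr + k) return(list())
  v <- match(strsplit(s_chr, "", fixed = TRUE)[[1]], DNA_BASES4) - 1L
  n <- L - k + 1L
  code <- numeric(n)
  for (j in 0:(k - 1L))
    code <- code + v[(1L + j):(n + j)] * 4^(k - 1L - j)
  ok <- !is.na(code)
  pos <- which(ok)
  cd <- code[ok]
  o <- order(cd, pos)
  cd <- cd[o]; pos <- pos[o]
  grp_start <- c(TRUE, cd[-1] != cd[-length(cd)])
  gs <- which(grp_start)
  ge <- c(gs[-1] - 1L, length(cd))
  cnt <- ge - gs + 1L
  # pair occurrences of the same k-mer within the element-length window
  p1 <- integer(0); p2 <- integer(0)
  min_sep <- min_ltr + 20L
  max_sep <- max_element - min_ltr
  for (g in which(cnt >= 2L & cnt <= max_code_count)) {
    p <- pos[gs[g]:ge[g]]
    for (i in seq_len(length(p) - 1L)) {
      jj <- which(p > p[i] + min_sep & p <= p[i] + max_sep)
      if (length(jj)) { p1 <- c(p1, rep.int(p[i], length(jj))); p2 <- c(p2, p[jj]) }
    }
  }
  if (!length(p1)) return(list())
  d <- p2 - p1
  o <- order(d, p1)
  p1 <- p1[o]; d <- d[o]
  grp <- cumsum(c(1L, diff(d) > 20L | abs(diff(p1)) > 2000L))
  cands <- list()
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (length(i) < min_seeds) next
    cands[[length(cands) + 1L]] <- list(p1_min = min(p1[i]),
                                        p1_max = max(p1[i]) + k - 1L,
                                        d = as.integer(round(median(d[i]))),
                                        n_seeds = length(i))
  }
  cands
}

# exact boundary search: TG start, CA end, identical TSD copies. The
# aged-LTR seed cluster can start well inside the LTR (no intact k-mer near
# the boundary), so motif positions are enumerated over a generous window.
.refine_ltr_boundaries <- function(s_chr, cand, min_ltr, max_ltr,
                                   max_element, tsd_range, motif,
                                   min_similarity, slack_out = 400L,
                                   slack_in = 80L) {
  m5 <- substr(motif, 1, 2); m3 <- substr(motif, 3, 4)
  L <- nchar(s_chr)
  motif_pos <- function(pat, lo, hi) {
    lo <- max(1L, lo); hi <- min(L - 1L, hi)
    if (hi < lo) return(integer())
    win <- substr(s_chr, lo, hi + 1L)
    hits <- gregexpr(pat, win, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer() else as.integer(hits) + lo - 1L
  }
  s_cands <- motif_pos(m5, max(tsd_range[2] + 1L, cand$p1_min - slack_out),
                       cand$p1_min + slack_in)
  e_cands <- motif_pos(m3, cand$p1_max + cand$d - slack_in,
                       cand$p1_max + cand$d + slack_out) + 1L
  best <- NULL
  for (s1 in s_cands) {             # 1-based LTR5 start (TG at s1)
    for (e1 in e_cands) {           # 1-based element end (CA ends at e1)
      ltr_len <- e1 - cand$d - s1 + 1L
      if (ltr_len < min_ltr || ltr_len > max_ltr) next
      if (e1 + tsd_range[2] > L) next
      if (cand$d + ltr_len > max_element) next
      e5 <- s1 + ltr_len - 1L
      tsd_len <- 0L
      for (tl in rev(seq(tsd_range[1], tsd_range[2]))) {
        left <- substr(s_chr, s1 - tl, s1 - 1L)
        right <- substr(s_chr, e1 + 1L, e1 + tl)
        if (left == right && !grepl("N", left, fixed = TRUE)) {
          tsd_len <- tl
          break
        }
      }
      if (!tsd_len) next
      ltr5 <- substr(s_chr, s1, e5)
      ltr3 <- substr(s_chr, s1 + cand$d, e5 + cand$d)
      sc <- substitution_count(ltr5, ltr3)
      ident <- 1 - sc$substitutions / max(sc$compared_sites, 1L)
      if (ident < min_similarity) next
      cand_el <- data.frame(
        start = s1 - 1L, end = e1, ltr_len = ltr_len,
        tsd = substr(s_chr, s1 - tsd_len, s1 - 1L), tsd_len = tsd_len,
        motif_ok = TRUE, ltr_identity = ident,
        K = sc$substitutions / max(sc$compared_sites, 1L),
        n_seeds = cand$n_seeds,
        # alignment-like score: trimmed framings of the true pair lose the
        # matched columns they drop, over-extended framings pay for the
        # random flank-vs-internal columns they add
        score = (sc$compared_sites - 4L * sc$substitutions) + tsd_len,
        stringsAsFactors = FALSE)
      score <- cand_el$score
      if (is.null(best) || score > best$score)
        best <- list(el = cand_el, score = score)
    }
  }
  if (is.null(best)) NULL else best$el
}

#' Classify detected elements across the genome pair
#'
#' For each element of genome A, the 500-bp flanks immediately outside the
#' TSD copies are anchored in both genomes. Elements whose flanks do not
#' anchor uniquely in A are discarded (`discarded_A`); likewise for B
#' (`discarded_B`, counted separately). The B sequence intervening between
#' the flank anchors then decides the class:
#' \itemize{
#'   \item intervening > 100 bp with a local alignment hit to the A element
#'     -> `Shared` (split `SharedHigh`/`SharedLow` at 0.99 global identity
#'     of the counterpart sequence);
#'   \item a single TSD copy with no intervening sequence (at most 10 bp of
#'     jitter beyond one TSD) -> `Insertion`;
#'   \item no local hit and two or zero TSD copies -> `Elimination`;
#'   \item anything else -> `Unknown`.
#' }
#'
#' @param elements From [detect_intact_ltr()] (columns `chrom`, `start`,
#'   `end`, `tsd`, `tsd_len`).
#' @param genome_a,genome_b DNAStringSet pair (elements on A).
#' @param flank Flank length, bases.
#' @param max_span Maximum B span between flank anchors (20 kb, the longest
#'   element length).
#' @param high_identity Shared high/low similarity split.
#' @param hit_score_floor Minimum local alignment score counting as a hit.
#' @param insertion_jitter Tolerated intervening bases beyond one TSD copy
#'   for an Insertion call.
#' @param min_coverage,min_identity Flank anchoring thresholds.
#' @return `elements` with added columns `cls`, `identity_cross`,
#'   `b_chrom`, `b_start`, `b_end`, `b_strand` (intervening span on B) and
#'   flank anchor coordinates; discarded elements keep `cls`
#'   `discarded_A`/`discarded_B`.
#' @export
classify_cross_genome <- function(elements, genome_a, genome_b, flank = 500L,
                                  max_span = 20000L, high_identity = 0.99,
                                  hit_score_floor = 100,
                                  insertion_jitter = 10L,
                                  min_coverage = 0.8, min_identity = 0.8) {
  n <- nrow(elements)
  elements$cls <- NA_character_
  elements$identity_cross <- NA_real_
  elements$b_chrom <- NA_character_
  elements$b_start <- NA_integer_
  elements$b_end <- NA_integer_
  elements$b_strand <- NA_character_
  elements$b_up_start <- NA_integer_; elements$b_up_end <- NA_integer_
  elements$b_dn_start <- NA_integer_; elements$b_dn_end <- NA_integer_
  if (!n) return(elements)

  # batch-extract all flanks, then anchor them in one pass per genome
  qs <- list()
  for (i in seq_len(n)) {
    ch <- elements$chrom[i]
    s <- elements$start[i] - elements$tsd_len[i]
    e <- elements$end[i] + elements$tsd_len[i]
    L <- Biostrings::width(genome_a)[match(ch, names(genome_a))]
    if (s - flank < 0 || e + flank > L) next
    qs[[paste0("e", i, "_up")]] <- .gp_subseq(genome_a, ch, s - flank, s)
    qs[[paste0("e", i, "_dn")]] <- .gp_subseq(genome_a, ch, e, e + flank)
  }
  if (!length(qs)) {
    elements$cls <- "discarded_A"
    return(elements)
  }
  qset <- Biostrings::DNAStringSet(qs)
  plA <- anchor_fragments(qset, genome_a, min_coverage = min_coverage,
                          min_identity = min_identity, max_hits = 3L)
  plB <- anchor_fragments(qset, genome_b, min_coverage = min_coverage,
                          min_identity = min_identity, max_hits = 3L)

  one <- function(pl, q) {
    p <- pl[pl$query == q, , drop = FALSE]
    if (nrow(p) == 1 && p$n_hits[1] == 1) p else NULL
  }
  for (i in seq_len(n)) {
    qup <- paste0("e", i, "_up"); qdn <- paste0("e", i, "_dn")
    if (!qup %in% names(qs)) { elements$cls[i] <- "discarded_A"; next }
    if (is.null(one(plA, qup)) || is.null(one(plA, qdn))) {
      elements$cls[i] <- "discarded_A"; next
    }
    up <- one(plB, qup); dn <- one(plB, qdn)
    ok <- !is.null(up) && !is.null(dn) && up$chrom == dn$chrom &&
      up$strand == dn$strand
    if (ok) {
      if (up$strand == "+") { lo <- up$end; hi <- dn$start }
      else { lo <- dn$end; hi <- up$start }
      ok <- hi >= lo && (hi - lo) <= max_span
    }
    if (!ok) { elements$cls[i] <- "discarded_B"; next }
    intv <- .gp_subseq(genome_b, up$chrom, lo, hi)
    if (up$strand == "-") intv <- Biostrings::reverseComplement(intv)
    elements$b_chrom[i] <- up$chrom
    elements$b_start[i] <- lo; elements$b_end[i] <- hi
    elements$b_strand[i] <- up$strand
    elements$b_up_start[i] <- up$start; elements$b_up_end[i] <- up$end
    elements$b_dn_start[i] <- dn$start; elements$b_dn_end[i] <- dn$end
    elements[i, c("cls", "identity_cross")] <-
      .classify_intervening(intv, elements[i, ], genome_a, high_identity,
                            hit_score_floor, insertion_jitter)
  }
  elements
}

.classify_intervening <- function(intv, el, genome_a, high_identity,
                                  hit_score_floor, insertion_jitter) {
  len <- length(intv)
  tsd <- el$tsd; tl <- el$tsd_len
  intv_chr <- as.character(intv)
  if (len <= tl + insertion_jitter) {
    if (Biostrings::countPattern(tsd, intv, max.mismatch = 0) >= 1)
      return(list("Insertion", NA_real_))
    if (len <= insertion_jitter) return(list("Elimination", NA_real_))
    return(list("Unknown", NA_real_))
  }
  elem_a <- .gp_subseq(genome_a, el$chrom, el$start, el$end)
  hit <- Biostrings::pairwiseAlignment(
    intv, elem_a, type = "local", substitutionMatrix = .gp_submat(),
    gapOpening = .gp_align_defaults$gap_opening,
    gapExtension = .gp_align_defaults$gap_extension, scoreOnly = TRUE)
  if (len > 100 && hit >= hit_score_floor) {
    counterpart_a <- .gp_subseq(genome_a, el$chrom, el$start - tl,
                                el$end + tl)
    ident <- global_identity(counterpart_a, intv)
    cls <- if (ident >= high_identity) "SharedHigh" else "SharedLow"
    return(list(cls, ident))
  }
  if (hit < hit_score_floor) {
    starts_tsd <- startsWith(intv_chr, tsd)
    ends_tsd <- endsWith(intv_chr, tsd)
    if ((starts_tsd && ends_tsd) || (!starts_tsd && !ends_tsd))
      return(list("Elimination", NA_real_))
  }
  list("Unknown", NA_real_)
}

#' Insertion time from LTR-LTR divergence
#'
#' Under a constant clock, an element's two LTRs are identical at insertion
#' and diverge at `2 * rate` per site per year, so `T = K / (2 * rate)`
#' (raw) or with a Jukes-Cantor correction
#' `T = -(3/4) * log(1 - 4K/3) / (2 * rate)`.
#'
#' @param K Raw LTR-LTR divergence, substitutions per site (vectorised).
#' @param rate Substitutions per site per year (default 1.3e-8).
#' @param jc_correct Apply the Jukes-Cantor distance correction
#'   (requires `K < 0.75`).
#' @return Years.
#' @export
insertion_time <- function(K, rate = 1.3e-8, jc_correct = FALSE) {
  if (any(K < 0)) stop("K must be non-negative")
  if (rate <= 0) stop("rate must be positive")
  d <- if (jc_correct) {
    if (any(K >= 0.75)) stop("Jukes-Cantor correction undefined for K >= 0.75")
    -0.75 * log(1 - 4 * K / 3)
  } else K
  d / (2 * rate)
}

#' Raw LTR-LTR divergence of an element
#'
#' Compares an element's two LTRs (equal-length direct comparison, global
#' alignment when lengths differ; gap and N columns excluded).
#'
#' @param element Element sequence structured LTR + internal + LTR.
#' @param ltr_len LTR length, bases.
#' @return `K`, substitutions per compared site.
#' @export
ltr_divergence <- function(element, ltr_len) {
  element <- as.character(.as_dna(element))
  n <- nchar(element)
  stopifnot(n >= 2 * ltr_len)
  sc <- substitution_count(substr(element, 1L, ltr_len),
                           substr(element, n - ltr_len + 1L, n))
  sc$substitutions / max(sc$compared_sites, 1L)
}

#' Class tally of a classified element table
#'
#' @param elements From [classify_cross_genome()].
#' @return Named integer vector over the five classes plus discards.
#' @export
ltr_class_counts <- function(elements) {
  lv <- c("SharedHigh", "SharedLow", "Insertion", "Elimination", "Unknown",
          "discarded_A", "discarded_B")
  table(factor(elements$cls, levels = lv))
}
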