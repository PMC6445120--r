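#' Detect telomere arrays at chromosome ends
#'
#' Searches a window at each end of every chromosome for the maximal tandem
#' array of the telomere unit (the 5' end is searched with the unit's
#' reverse complement, so the G-rich strand reads 5'-unit-3' towards each
#' terminus). Occurrences are chained into an array while interrupting bases
#' stay within `max_interrupt_frac` of the array span (real telomere arrays
#' are imperfect); `strict = TRUE` demands perfect tandem repetition. A call
#' is reported iff the array holds at least `min_copies` units and lies
#' within `terminus_slack` bases of the terminus.
#'
#' @param genome DNAStringSet.
#' @param unit Telomere repeat unit (default plant-type `TTTAGGG`), length
#'   >= 4.
#' @param end_window Bases searched at each terminus.
#' @param min_copies Minimum unit copies to report a call.
#' @param max_interrupt_frac Tolerated non-unit fraction within the array.
#' @param terminus_slack Maximum distance of the array edge from the
#'   terminus.
#' @param strict Disallow any interrupting bases.
#' @return data.frame `chrom`, `end` (`5prime`/`3prime`), `copies`, `start`,
#'   `end_pos` (0-based half-open span of the array).
#' @export
detect_telomeres <- function(genome, unit = "TTTAGGG", end_window = 50000L,
                             min_copies = 100L, max_interrupt_frac = 0.1,
                             terminus_slack = 1000L, strict = FALSE) {
  if (nchar(unit) < 4) stop("telomere unit must be at least 4 bases")
  genome <- .as_dnaset(genome)
  if (strict) max_interrupt_frac <- 0
  out <- list()
  for (i in seq_along(genome)) {
    L <- Biostrings::width(genome)[i]
    win <- min(end_window, L)
    for (side in c("5prime", "3prime")) {
      u <- if (side == "5prime") .gp_revcomp(unit) else unit
      ws <- if (side == "5prime") 1L else L - win + 1L
      seq_win <- Biostrings::subseq(genome[[i]], ws, ws + win - 1L)
      m <- Biostrings::matchPattern(u, seq_win)
      if (!length(m)) next
      arr <- .best_unit_array(IRanges::start(m), nchar(u), win, side,
                              max_interrupt_frac, terminus_slack)
      if (is.null(arr) || arr$copies < min_copies) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = names(genome)[i], end = side, copies = arr$copies,
        start = ws - 1L + arr$from - 1L, end_pos = ws - 1L + arr$to,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(.empty_df(chrom = character(), end = character(),
                     copies = integer(), start = integer(),
                     end_pos = integer()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# chain unit occurrences into candidate arrays and pick the one nearest the
# terminus that satisfies the interruption tolerance
.best_unit_array <- function(starts, ulen, win, side, max_frac, slack) {
  starts <- sort(starts)
  # drop overlapping occurrences (tandem units are non-overlapping)
  keep <- logical(length(starts)); last_end <- -1L
  for (j in seq_along(starts)) {
    if (starts[j] > last_end) { keep[j] <- TRUE; last_end <- starts[j] + ulen - 1L }
  }
  starts <- starts[keep]
  gaps <- diff(starts) - ulen
  grp <- cumsum(c(1L, gaps > max(2L * ulen, 20L)))
  best <- NULL
  for (g in unique(grp)) {
    s <- starts[grp == g]
    from <- s[1]; to <- s[length(s)] + ulen - 1L
    span <- to - from + 1L
    interrupt <- span - length(s) * ulen
    if (interrupt > max_frac * span) {
      # trim to the longest clean sub-chain
      runs <- cumsum(c(1L, (diff(s) != ulen)))
      tab <- tapply(s, runs, function(x) x)
      lens <- lengths(tab)
      s <- tab[[which.max(lens)]]
      from <- s[1]; to <- s[length(s)] + ulen - 1L
    }
    dist_term <- if (side == "5prime") from - 1L else win - to
    if (dist_term > slack) next
    cand <- list(copies = length(s), from = from, to = to)
    if (is.null(best) || cand$copies > best$copies) best <- cand
  }
  best
}

#' Scan for heterochromatin-like windows of high repeat density
#'
#' Slides fixed windows across each chromosome and reports those whose
#' repeat-covered fraction strictly exceeds the threshold; qualifying
#' windows that overlap or touch are merged into blocks (the conventional
#' pericentromeric proxy: 1 Mb windows, 250 kb step, >90% repeat coverage).
#'
#' @param repeats data.frame of repeat intervals (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window,step Window size and step, bases.
#' @param threshold Repeat-fraction threshold (strict `>`).
#' @return data.frame of merged blocks `chrom`, `start`, `end`,
#'   `n_windows`, `max_fraction`.
#' @export
scan_heterochromatin <- function(repeats, chrom_lengths, window = 1e6,
                                 step = 2.5e5, threshold = 0.9) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    if (L < window) next
    r <- repeats[repeats$chrom == ch, , drop = FALSE]
    rr <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
    if (any(r$end > L) || any(r$start < 0))
      stop("repeat interval outside chromosome bounds on ", ch)
    starts <- seq(0, L - window, by = step)
    ws <- IRanges::IRanges(starts + 1L, starts + window)
    cov <- IRanges::coverage(rr, width = L)
    frac <- IRanges::viewSums(IRanges::Views(cov, ws)) / window
    ok <- frac > threshold
    if (!any(ok)) next
    merged <- IRanges::reduce(ws[ok], min.gapwidth = 1L, with.revmap = TRUE)
    for (b in seq_along(merged)) {
      members <- S4Vectors::mcols(merged)$revmap[[b]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = IRanges::start(merged)[b] - 1L,
        end = IRanges::end(merged)[b], n_windows = length(members),
        max_fraction = max(frac[ok][members]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(.empty_df(chrom = character(), start = numeric(), end = numeric(),
                     n_windows = integer(), max_fraction = numeric()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Per-chromosome assembly statistics and summary
#'
#' Tabulates chromosome length, gap count and telomere status, plus a
#' summary with total length, gap-aware contig N50 (contigs are the
#' N-run-delimited segments) and the telomere tally (Both counts two,
#' Single counts one).
#'
#' @param genome DNAStringSet.
#' @param telomere_calls From [detect_telomeres()]; optional.
#' @param gap_runs From [find_n_runs()]; computed from `genome` if omitted.
#' @return list with `per_chrom` (data.frame sorted by chromosome id) and
#'   `summary`.
#' @export
assembly_stats <- function(genome, telomere_calls = NULL, gap_runs = NULL) {
  genome <- .as_dnaset(genome)
  if (is.null(gap_runs)) gap_runs <- find_n_runs(genome, min_len = 1L)
  if (is.null(telomere_calls))
    telomere_calls <- .empty_df(chrom = character(), end = character(),
                                copies = integer(), start = integer(),
                                end_pos = integer())
  chroms <- sort(names(genome))
  per <- do.call(rbind, lapply(chroms, function(ch) {
    tc <- telomere_calls[telomere_calls$chrom == ch, , drop = FALSE]
    status <- if (nrow(tc) >= 2) "Both" else if (nrow(tc) == 1) "Single" else "None"
    data.frame(chrom = ch,
               length = Biostrings::width(genome)[match(ch, names(genome))],
               n_gaps = sum(gap_runs$chrom == ch),
               telomere_status = status, stringsAsFactors = FALSE)
  }))
  segs <- unlist(lapply(chroms, function(ch) {
    L <- per$length[per$chrom == ch]
    g <- gap_runs[gap_runs$chrom == ch, , drop = FALSE]
    if (!nrow(g)) return(L)
    ir <- IRanges::gaps(IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end)),
                        start = 1L, end = L)
    IRanges::width(ir)
  }))
  n_both <- sum(per$telomere_status == "Both")
  n_single <- sum(per$telomere_status == "Single")
  list(per_chrom = per,
       summary = list(total_length = sum(as.numeric(per$length)),
                      n_chromosomes = nrow(per),
                      n_gaps = nrow(gap_runs),
                      contig_n50 = .n50(segs),
                      telomeres_total = 2L * n_both + n_single,
                      telomere_both = n_both,
                      telomere_single = n_single,
                      telomere_none = sum(per$telomere_status == "None")))
}

#' Tabulate a printed per-chromosome assembly table
#'
#' Recomputes the headline telomere and length tabulations from a
#' chromosome-statistics table as printed in an assembly report: total
#' telomere count (Both counts two ends, Single one), the number of
#' chromosomes with telomeres at both ends, and the maximum pseudo-chromosome
#' length. Organelle and unanchored rows (telomere status `NA`/`-` handled
#' as no telomere) are excluded from the length maximum via the
#' `chrom_prefix` filter.
#'
#' @param tab data.frame with columns `chrom`, `length`, `telomere`
#'   (values `Both`, `Single`, `-` or `NA`).
#' @param chrom_prefix Rows whose `chrom` starts with this prefix are
#'   treated as pseudo-chromosomes (default `"Chr"`).
#' @return list `telomeres_total`, `n_both`, `n_single`, `max_length`.
#' @export
chrom_table_summary <- function(tab, chrom_prefix = "Chr") {
  is_chr <- startsWith(tab$chrom, chrom_prefix)
  tel <- tab$telomere[is_chr]
  tel[is.na(tel)] <- "-"
  n_both <- sum(tel == "Both")
  n_single <- sum(tel == "Single")
  list(telomeres_total = 2L * n_both + n_single,
       n_both = n_both, n_single = n_single,
       max_length = max(tab$length[is_chr]))
}

#' Read a per-chromosome assembly statistics table (TSV)
#'
#' @param path TSV with columns `chrom`, `length`, `n_gaps`, `telomere`.
#' @return data.frame.
#' @export
read_chrom_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
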