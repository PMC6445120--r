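# Presence/absence marker analysis for an element insertion: junction
# sequence search across samples, in-silico PCR, and co-segregation of the
# marker with a binary phenotype.

#' Search samples for an insertion junction sequence
#'
#' A sample is called `present` iff the junction sequence (or its reverse
#' complement) occurs with at most `max_mismatch` mismatches. The junction
#' spans the insertion boundary, so a sample carrying only the two
#' separated halves is called `absent`.
#'
#' @param samples Named list of DNAStringSet (one per sample), or a single
#'   DNAStringSet treated as one sample per sequence.
#' @param junction Junction sequence, length >= 20 (shorter is refused as
#'   unspecific).
#' @param max_mismatch Tolerated mismatches (0 for assemblies, small values
#'   for noisy reads).
#' @return data.frame `sample`, `present`, `n_hits`, `positions`
#'   (semicolon-joined "seq:pos:strand").
#' @export
junction_search <- function(samples, junction, max_mismatch = 0L) {
  junction <- as.character(.as_dna(junction))
  if (nchar(junction) < 20)
    stop("junction shorter than 20 bases is refused (unspecific)")
  if (is(samples, "DNAStringSet") || is.character(samples)) {
    s <- .as_dnaset(samples)
    if (is.null(names(s))) names(s) <- paste0("sample", seq_along(s))
    samples <- lapply(seq_along(s), function(i) s[i])
    names(samples) <- names(s)
  }
  jf <- .as_dna(junction)
  jr <- Biostrings::reverseComplement(jf)
  out <- lapply(names(samples), function(nm) {
    sset <- .as_dnaset(samples[[nm]])
    pos <- character(0)
    for (i in seq_along(sset)) {
      sid <- names(sset)[i] %||% as.character(i)
      for (ori in c("+", "-")) {
        pat <- if (ori == "+") jf else jr
        m <- Biostrings::matchPattern(pat, sset[[i]],
                                      max.mismatch = max_mismatch)
        if (length(m))
          pos <- c(pos, paste0(sid, ":", IRanges::start(m) - 1L, ":", ori))
      }
    }
    data.frame(sample = nm, present = length(pos) > 0, n_hits = length(pos),
               positions = paste(pos, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' In-silico PCR
#'
#' Reports every amplicon where the forward primer matches one strand and
#' the reverse primer's reverse complement matches downstream within
#' `max_product` bases. Product length is the inclusive span of both
#' primers. The 3' terminal bases of each primer must match exactly
#' (standard PCR specificity); mismatches elsewhere up to `max_mismatch`
#' are tolerated.
#'
#' @param template DNAStringSet.
#' @param fwd,rev Primer sequences (5'->3'), length >= 18.
#' @param max_product Maximum product length, bases.
#' @param max_mismatch Tolerated mismatches outside the 3' clamp.
#' @param clamp Number of exact 3'-end bases required.
#' @return data.frame `chrom`, `start` (0-based), `product_length`,
#'   `strand`.
#' @export
insilico_pcr <- function(template, fwd, rev, max_product = 5000L,
                         max_mismatch = 0L, clamp = 3L) {
  fwd <- as.character(.as_dna(fwd)); rev <- as.character(.as_dna(rev))
  if (nchar(fwd) < 18 || nchar(rev) < 18)
    stop("primers must be at least 18 bases")
  template <- .as_dnaset(template)
  if (is.null(names(template)))
    names(template) <- paste0("seq", seq_along(template))
  out <- list()
  scan <- function(p_left, p_right, strand) {
    # p_left binds the plus strand 5'->3'; p_right's reverse complement
    # binds the plus strand downstream
    right_rc <- .gp_revcomp(p_right)
    for (i in seq_along(template)) {
      subj <- template[[i]]
      ml <- .primer_sites(p_left, subj, max_mismatch, clamp, end3 = "right")
      mr <- .primer_sites(right_rc, subj, max_mismatch, clamp, end3 = "left")
      if (!length(ml) || !length(mr)) next
      for (ls in ml) {
        ends <- mr[mr > ls] + nchar(p_right) - 1L
        ends <- ends[ends - ls + 1L <= max_product & ends - ls + 1L >=
                       nchar(p_left) + nchar(p_right)]
        for (e in ends)
          out[[length(out) + 1L]] <<- data.frame(
            chrom = names(template)[i], start = ls - 1L,
            product_length = e - ls + 1L, strand = strand,
            stringsAsFactors = FALSE)
      }
    }
  }
  scan(fwd, rev, "+")
  scan(rev, fwd, "-")
  if (!length(out))
    return(.empty_df(chrom = character(), start = integer(),
                     product_length = integer(), strand = character()))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# match a primer on the plus strand; its 3' end is on the `end3` side of
# the match and must be mismatch-free over the clamp
.primer_sites <- function(primer, subj, max_mismatch, clamp, end3) {
  m <- Biostrings::matchPattern(primer, subj, max.mismatch = max_mismatch,
                                fixed = TRUE)
  if (!length(m) || max_mismatch == 0 || clamp == 0)
    return(IRanges::start(m))
  keep <- vapply(seq_along(m), function(j) {
    s <- as.character(m[[j]])
    if (end3 == "right")
      substr(s, nchar(s) - clamp + 1L, nchar(s)) ==
        substr(primer, nchar(primer) - clamp + 1L, nchar(primer))
    else substr(s, 1L, clamp) == substr(primer, 1L, clamp)
  }, logical(1))
  IRanges::start(m)[keep]
}

#' Marker-phenotype co-segregation summary
#'
#' Tabulates marker presence against a binary phenotype, computes the
#' concordance fraction over samples with known phenotype and a usable
#' marker assay, and flags perfect association.
#'
#' @param panel data.frame with columns `sample`, `phenotype` (`red`,
#'   `non_red` or `unknown`) and `marker` (`present`, `absent` or
#'   `failed`).
#' @return list: `table` (2x2 over known phenotypes), `concordance`,
#'   `perfect`, `n_known`, `n_total`.
#' @export
cosegregation <- function(panel) {
  stopifnot(nrow(panel) > 0)
  if (anyDuplicated(panel$sample)) stop("sample ids must be unique")
  known <- panel$phenotype %in% c("red", "non_red") &
    panel$marker %in% c("present", "absent")
  if (!any(known)) stop("panel contains no usable phenotype/marker pairs")
  k <- panel[known, , drop = FALSE]
  tab <- table(factor(k$phenotype, levels = c("red", "non_red")),
               factor(k$marker, levels = c("present", "absent")))
  conc <- (tab["red", "present"] + tab["non_red", "absent"]) / nrow(k)
  list(table = tab, concordance = as.numeric(conc), perfect = conc == 1,
       n_known = nrow(k), n_total = nrow(panel))
}
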