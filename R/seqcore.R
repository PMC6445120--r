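#' Read a genome FASTA into a normalised DNAStringSet
#'
#' Sequence names are truncated at the first whitespace and any IUPAC
#' ambiguity code other than A/C/G/T/N is normalised to N (the number of
#' normalised bases is reported via a message so silent data loss is visible).
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate sequence ids in ", path)
  if (any(Biostrings::width(x) == 0)) stop("empty sequence in ", path)
  freq <- Biostrings::alphabetFrequency(x)
  other <- sum(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"), drop = FALSE])
  if (other > 0) {
    x <- Biostrings::DNAStringSet(Biostrings::replaceAmbiguities(x, new = "N"))
    message("normalised ", other, " ambiguous bases to N")
  }
  x
}

#' Write a genome FASTA (80-column wrap)
#'
#' @param genome A named DNAStringSet (or coercible).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(.as_dnaset(genome), path, width = 80L)
  invisible(path)
}

#' Locate runs of ambiguous (N) bases
#'
#' Maximal runs of N of at least `min_len` bases, per chromosome, sorted and
#' non-overlapping.
#'
#' @param genome DNAStringSet (or a single sequence).
#' @param min_len Minimum run length in bases.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `width`.
#' @export
find_n_runs <- function(genome, min_len = 1L) {
  genome <- .as_dnaset(genome)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  out <- lapply(seq_along(genome), function(i) {
    # fixed = TRUE so the N pattern matches literal N only
    m <- Biostrings::matchPattern("N", genome[[i]], fixed = TRUE)
    ir <- IRanges::reduce(methods::as(m, "IRanges"))
    ir <- ir[IRanges::width(ir) >= min_len]
    if (!length(ir)) return(NULL)
    data.frame(chrom = names(genome)[i], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), width = IRanges::width(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- .empty_df(chrom = character(), start = integer(),
                                     end = integer(), width = integer())
  out
}

#' Global identity between two sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties; identity is
#' the number of matching columns divided by the total number of alignment
#' columns (gap columns count; N never counts as a match). Symmetric in its
#' arguments.
#'
#' @param a,b Sequences (character or DNAString), both non-empty.
#' @param match,mismatch,gap_opening,gap_extension Alignment scoring.
#' @return Fraction in \[0, 1\].
#' @export
global_identity <- function(a, b, match = 2, mismatch = -3,
                            gap_opening = 5, gap_extension = 2) {
  a <- .as_dna(a); b <- .as_dna(b)
  if (length(a) == 0 || length(b) == 0) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = .gp_submat(match, mismatch),
    gapOpening = gap_opening, gapExtension = gap_extension)
  .aln_identity(aln)$identity
}

# matches / columns and query coverage from a PairwiseAlignments object
.aln_identity <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- length(p)
  matches <- sum(p == s & p != "-" & p != "N")
  list(identity = if (cols) matches / cols else 0,
       matches = matches, columns = cols)
}

#' Count nucleotide substitutions between orthologous sequences
#'
#' Counts mismatched columns, excluding gap columns and columns containing N;
#' `compared_sites` is the number of columns actually compared. Equal-length
#' inputs are compared column-wise; unequal lengths are globally aligned
#' first.
#'
#' @param a,b Orthologous sequences (caller's responsibility).
#' @param align Force global alignment even for equal lengths.
#' @return list with `substitutions` and `compared_sites`.
#' @export
substitution_count <- function(a, b, align = NULL) {
  a_chr <- as.character(.as_dna(a)); b_chr <- as.character(.as_dna(b))
  if (is.null(align)) align <- nchar(a_chr) != nchar(b_chr)
  if (align) {
    aln <- Biostrings::pairwiseAlignment(
      .as_dna(a_chr), .as_dna(b_chr), type = "global",
      substitutionMatrix = .gp_submat(),
      gapOpening = .gp_align_defaults$gap_opening,
      gapExtension = .gp_align_defaults$gap_extension)
    a_chr <- as.character(Biostrings::alignedPattern(aln))
    b_chr <- as.character(Biostrings::alignedSubject(aln))
  }
  av <- charToRaw(a_chr); bv <- charToRaw(b_chr)
  skip <- av == charToRaw("-") | bv == charToRaw("-") |
    av == charToRaw("N") | bv == charToRaw("N")
  compared <- sum(!skip)
  subs <- sum(av[!skip] != bv[!skip])
  list(substitutions = as.integer(subs), compared_sites = as.integer(compared))
}
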