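# Internal helpers shared across modules.
#
# Coordinate convention: every interval in a data.frame returned or consumed
# by this package is 0-based half-open [start, end); conversion to R's 1-based
# string indexing happens only at the point of sequence extraction.

#' @import methods
#' @importFrom stats rbinom rpois runif median setNames quantile lm coef
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

# Substitution matrix over the simulator alphabet. N never scores as a match.
.gp_submat <- function(match = 2L, mismatch = -3L, n_score = -1L) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- n_score
  m[, "N"] <- n_score
  m
}

.gp_align_defaults <- list(gap_opening = 5, gap_extension = 2)

.as_dna <- function(x) {
  if (is(x, "DNAString")) x else Biostrings::DNAString(as.character(x))
}

.as_dnaset <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  Biostrings::DNAStringSet(as.character(x))
}

# Extract [start0, end0) from chromosome `chrom` of a DNAStringSet genome.
.gp_subseq <- function(genome, chrom, start0, end0) {
  stopifnot(start0 >= 0, end0 >= start0)
  Biostrings::subseq(genome[[chrom]], start = start0 + 1L, width = end0 - start0)
}

.gp_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(.as_dna(x)))
}

# Run expr under a private RNG stream without disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derived category seeds; fixed offsets keep streams independent so that e.g.
# changing the SNP count does not reshuffle TE placements.
.stream_seed <- function(seed, category) {
  offsets <- c(ancestor = 11L, te = 23L, snp = 37L, indel = 51L, gap = 67L,
               telomere = 83L, age = 97L, elim = 113L, depth = 131L,
               genes = 149L, control = 167L)
  stopifnot(category %in% names(offsets))
  # double arithmetic: exact well past 2^31, avoids integer overflow
  (as.numeric(seed) * 2654435 + as.numeric(offsets[[category]])) %% 2147483629
}

# Random DNA string at a given GC fraction.
.random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES4, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute `n_sub` random positions of a character sequence (1-based
# positions drawn from `eligible`), always to a different base.
.mutate_positions <- function(seq_chr, n_sub, eligible = NULL) {
  if (n_sub <= 0) return(seq_chr)
  v <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  if (is.null(eligible)) eligible <- seq_along(v)
  eligible <- eligible[v[eligible] %in% DNA_BASES4]
  if (!length(eligible)) return(seq_chr)
  n_sub <- min(n_sub, length(eligible))
  pos <- sample(eligible, n_sub)
  for (p in pos) {
    v[p] <- sample(setdiff(DNA_BASES4, v[p]), 1L)
  }
  paste(v, collapse = "")
}

# N50 of a vector of segment lengths.
.n50 <- function(widths) {
  if (!length(widths)) return(0)
  w <- sort(widths, decreasing = TRUE)
  total <- sum(as.numeric(w))
  w[which(cumsum(as.numeric(w)) >= total / 2)[1]]
}

.empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(x) x[0]), stringsAsFactors = FALSE)
}
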