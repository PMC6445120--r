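#' Simulated cross-genotype depth tracks
#'
#' Emulates mapping short reads of one genotype onto the other genotype's
#' assembly: uniform depth everywhere except zero over segments the read
#' genotype does not possess (genome-specific TE insertions, elimination
#' fillers) and over masked N-gaps. `which = "A"` gives the depth of
#' B-derived reads on genome A, and vice versa.
#'
#' @param sim A simulation from [simulate_pair()] (or a list with `genome_A`,
#'   `genome_B`, `truth`).
#' @param which Which assembly the reads are layered on.
#' @param mean_depth Depth outside absent segments.
#' @return Named list of numeric [S4Vectors::Rle] vectors, one per
#'   chromosome.
#' @export
simulate_depth <- function(sim, which = c("A", "B"), mean_depth = 30) {
  which <- match.arg(which)
  genome <- if (which == "A") sim$genome_A else sim$genome_B
  te <- sim$truth$te_events
  zero <- list()
  addz <- function(chrom, s, e) {
    if (length(s) && !is.na(s) && e > s)
      zero[[length(zero) + 1L]] <<- data.frame(chrom = chrom, start = s, end = e)
  }
  if (nrow(te)) for (i in seq_len(nrow(te))) {
    cls <- te$class[i]
    if (which == "A" && cls %in% c("insertion_A", "elimination_B"))
      addz(te$chrom[i], te$a_elem_start[i], te$a_elem_end[i])
    if (which == "B" && cls %in% c("insertion_B", "elimination_B"))
      addz(te$chrom[i], te$b_elem_start[i], te$b_elem_end[i])
  }
  if (which == "B" && nrow(sim$truth$gaps)) {
    g <- sim$truth$gaps
    for (i in seq_len(nrow(g))) addz(g$chrom[i], g$start[i], g$end[i])
  }
  zero <- if (length(zero)) do.call(rbind, zero) else NULL
  out <- lapply(names(genome), function(ch) {
    d <- S4Vectors::Rle(mean_depth, Biostrings::width(genome)[match(ch, names(genome))])
    if (!is.null(zero)) {
      z <- zero[zero$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(z)))
        d[(z$start[i] + 1L):z$end[i]] <- 0
    }
    d
  })
  names(out) <- names(genome)
  out
}

#' Simulate a gene annotation
#'
#' Places non-overlapping gene intervals uniformly until the requested
#' fraction of the genome is covered; used to study insertion-site bias
#' relative to genes.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param fraction Target genic fraction of the genome.
#' @param mean_len Mean gene length, bases (exponential length model,
#'   minimum 200 bp).
#' @param seed RNG seed.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), sorted.
#' @export
simulate_genes <- function(chrom_lengths, fraction = 0.2222,
                           mean_len = 3000, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  .with_seed(.stream_seed(seed, "genes"), {
    out <- list()
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      target <- fraction * L
      occupied <- IRanges::IRanges()
      covered <- 0
      attempts <- 0L
      while (covered < target && attempts < 1e5) {
        attempts <- attempts + 1L
        w <- max(200L, round(stats::rexp(1, 1 / mean_len)))
        s <- floor(runif(1, 0, L - w))
        cand <- IRanges::IRanges(s + 1L, s + w)
        if (IRanges::countOverlaps(cand, occupied, maxgap = 100L)) next
        occupied <- c(occupied, cand)
        covered <- covered + w
      }
      occupied <- occupied[order(IRanges::start(occupied))]
      if (length(occupied))
        out[[ch]] <- data.frame(chrom = ch,
                                start = IRanges::start(occupied) - 1L,
                                end = IRanges::end(occupied),
                                stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}

#' Expected presence/absence variants implied by a truth ledger
#'
#' Genome-specific TE insertions are expected PAVs on the carrier genome;
#' an elimination is expected on both sides (the element on A, the
#' replacement filler on B). Shared events imply none.
#'
#' @param truth Truth ledger from [simulate_pair()].
#' @param min_len Drop expected events shorter than this many bases.
#' @return data.frame `event_id`, `genome`, `chrom`, `start`, `end`, `kind`.
#' @export
expected_pavs <- function(truth, min_len = 0L) {
  te <- truth$te_events
  out <- list()
  add <- function(event_id, genome, chrom, s, e, kind) {
    if (!is.na(s) && e - s >= min_len)
      out[[length(out) + 1L]] <<- data.frame(
        event_id = event_id, genome = genome, chrom = chrom,
        start = s, end = e, kind = kind, stringsAsFactors = FALSE)
  }
  if (nrow(te)) for (i in seq_len(nrow(te))) {
    cls <- te$class[i]
    if (cls == "insertion_A")
      add(te$event_id[i], "A", te$chrom[i], te$a_elem_start[i],
          te$a_elem_end[i], "insertion")
    if (cls == "insertion_B")
      add(te$event_id[i], "B", te$chrom[i], te$b_elem_start[i],
          te$b_elem_end[i], "deletion")
    if (cls == "elimination_B") {
      add(te$event_id[i], "A", te$chrom[i], te$a_elem_start[i],
          te$a_elem_end[i], "insertion")
      add(te$event_id[i], "B", te$chrom[i], te$b_elem_start[i],
          te$b_elem_end[i], "deletion")
    }
  }
  if (!length(out))
    return(.empty_df(event_id = character(), genome = character(),
                     chrom = character(), start = integer(), end = integer(),
                     kind = character()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write a simulation to disk
#'
#' FASTA for each genome (80-column wrap), one tab-separated table per truth
#' ledger category, and a plain-text key=value echo of the configuration.
#'
#' @param sim From [simulate_pair()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_genome(sim$genome_A, file.path(outdir, "genome_A.fa"))
  write_genome(sim$genome_B, file.path(outdir, "genome_B.fa"))
  for (nm in names(sim$truth)) {
    write.table(sim$truth[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- sim$config
  if (!is.null(cfg)) {
    scalar <- vapply(cfg, function(x)
      is.atomic(x) && length(x) <= 2 && !is.null(x), logical(1))
    lines <- vapply(names(cfg)[scalar], function(k)
      paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1))
    writeLines(lines, file.path(outdir, "config.txt"))
  }
  invisible(outdir)
}
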