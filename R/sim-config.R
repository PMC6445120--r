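#' Configuration for the synthetic genome-pair simulator
#'
#' Describes a pair of descendant genomes ("A" and "B") derived from a common
#' ancestor: substitutions, small indels, LTR retrotransposon insertions with
#' 4-6 bp target-site duplications (TSDs) and TG...CA-terminal LTR pairs,
#' element eliminations, N-gap masking of genome B, and terminal TTTAGGG
#' telomere arrays. The seed fully determines both genomes and the truth
#' ledger.
#'
#' The event model mirrors a pair of homozygous cultivar genomes that split
#' from a common ancestor: shared elements predate the split and are present
#' in both genomes with two TSD copies; genome-specific insertions carry two
#' TSD copies in the carrier and exactly one TSD copy (no intervening
#' sequence) at the orthologous point of the other genome; eliminations
#' replace the element in B with unrelated sequence or a short (<100 bp)
#' remnant between the two TSD copies.
#'
#' @param seed Integer master seed. Independent RNG streams are derived from
#'   it per event category, so e.g. changing the SNP rate does not reshuffle
#'   TE placements.
#' @param n_chromosomes,chrom_length Genome shape (bases per chromosome).
#' @param gc_fraction Ancestral GC content, in (0, 1).
#' @param snp_rate Substitutions per site between the two descendants.
#' @param small_indel_rate Small indel events per site (per genome).
#' @param indel_geom_prob,max_indel Indel length model: 1 + Geometric(p),
#'   capped.
#' @param te_library Optional list of families, each
#'   `list(name =, ltr =, internal =)` with character sequences; LTRs must
#'   start with the first half and end with the second half of
#'   `ltr_terminal_motif`. Default: three families built deterministically
#'   from the seed (LTR lengths 1000, 1274 and 800 bp).
#' @param n_shared,n_insertions_A,n_insertions_B,n_eliminations TE event
#'   counts by class.
#' @param elimination_mode `"mixed"` (default), `"replacement"` or
#'   `"remnant"`; `remnant_fraction` applies in mixed mode.
#' @param remnant_fraction Fraction of eliminations leaving a <100 bp remnant.
#' @param tsd_length_range TSD length bounds, within \[4, 6\].
#' @param ltr_terminal_motif Terminal dinucleotide motif of each LTR
#'   ("TGCA": LTRs start TG and end CA).
#' @param telomere_unit Telomere repeat unit (plant-type TTTAGGG).
#' @param telomere_copies_range Range of unit copies appended per chromosome
#'   end (default matches observed chromosome-scale arrays, 294-1073).
#' @param n_gaps,gap_length_range N-gap masking of genome B.
#' @param subst_rate Molecular clock, substitutions per site per year
#'   (default 1.3e-8).
#' @param divergence_time_years Time since the A/B split. Default is derived
#'   from the SNP rate and the clock, `snp_rate / (2 * subst_rate)`, so the
#'   genome-wide divergence and the clock are mutually consistent.
#' @param ltr_age_range_years Age range of genome-specific insertions.
#' @param shared_age_range_years Age range of shared (pre-split) elements;
#'   must not fall below the divergence time.
#' @param te_flank_snp_multiplier Relative substitution-rate elevation within
#'   `te_flank_zone` bases of a TE insertion point (1 = no elevation).
#' @param te_flank_zone Width of the elevated-rate zone, bases.
#' @param genes Optional data.frame of gene intervals (`chrom`, `start`,
#'   `end`) used for insertion-site bias.
#' @param genic_insertion_relprob Relative acceptance probability for TE
#'   placements falling inside a gene (1 = unbiased).
#' @param end_exclusion No events are placed within this many bases of a
#'   chromosome end (telomere zone).
#' @param n_snps,n_indels Optional explicit event counts overriding the
#'   rate-derived counts.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 2.5e6,
                       gc_fraction = 0.38,
                       snp_rate = 0.002,
                       small_indel_rate = 1e-5,
                       indel_geom_prob = 0.25,
                       max_indel = 50L,
                       te_library = NULL,
                       n_shared = 60L,
                       n_insertions_A = 30L,
                       n_insertions_B = 15L,
                       n_eliminations = 10L,
                       elimination_mode = c("mixed", "replacement", "remnant"),
                       remnant_fraction = 0.66,
                       tsd_length_range = c(4L, 6L),
                       ltr_terminal_motif = "TGCA",
                       telomere_unit = "TTTAGGG",
                       telomere_copies_range = c(294L, 1073L),
                       n_gaps = 20L,
                       gap_length_range = c(1000L, 3000L),
                       subst_rate = 1.3e-8,
                       divergence_time_years = NULL,
                       ltr_age_range_years = c(1e5, 2e6),
                       shared_age_range_years = c(5e5, 3e6),
                       te_flank_snp_multiplier = 1,
                       te_flank_zone = 500L,
                       genes = NULL,
                       genic_insertion_relprob = 1,
                       end_exclusion = 10000L,
                       n_snps = NULL,
                       n_indels = NULL) {
  elimination_mode <- match.arg(elimination_mode)
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  if (chrom_length <= 0 || n_chromosomes <= 0)
    stop("chromosome count and length must be positive")
  if (tsd_length_range[1] < 4 || tsd_length_range[2] > 6 ||
      tsd_length_range[1] > tsd_length_range[2])
    stop("tsd_length_range must lie within [4, 6]")
  if (snp_rate < 0 || snp_rate >= 1) stop("invalid snp_rate")
  if (subst_rate <= 0) stop("invalid substitution rate")
  if (is.null(divergence_time_years))
    divergence_time_years <- if (snp_rate > 0) snp_rate / (2 * subst_rate) else 0
  if (is.null(te_library))
    te_library <- .default_te_library(seed, gc_fraction, ltr_terminal_motif)
  .validate_te_library(te_library, ltr_terminal_motif)
  max_te <- max(vapply(te_library, function(f)
    2L * nchar(f$ltr) + nchar(f$internal), integer(1)))
  if (chrom_length < 10 * max_te)
    stop("chrom_length must be at least 10x the longest TE consensus")
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), gc_fraction = gc_fraction,
    snp_rate = snp_rate, small_indel_rate = small_indel_rate,
    indel_geom_prob = indel_geom_prob, max_indel = as.integer(max_indel),
    te_library = te_library, n_shared = as.integer(n_shared),
    n_insertions_A = as.integer(n_insertions_A),
    n_insertions_B = as.integer(n_insertions_B),
    n_eliminations = as.integer(n_eliminations),
    elimination_mode = elimination_mode,
    remnant_fraction = remnant_fraction,
    tsd_length_range = as.integer(tsd_length_range),
    ltr_terminal_motif = ltr_terminal_motif,
    telomere_unit = telomere_unit,
    telomere_copies_range = as.integer(telomere_copies_range),
    n_gaps = as.integer(n_gaps),
    gap_length_range = as.integer(gap_length_range),
    subst_rate = subst_rate,
    divergence_time_years = divergence_time_years,
    ltr_age_range_years = ltr_age_range_years,
    shared_age_range_years = shared_age_range_years,
    te_flank_snp_multiplier = te_flank_snp_multiplier,
    te_flank_zone = as.integer(te_flank_zone),
    genes = genes,
    genic_insertion_relprob = genic_insertion_relprob,
    end_exclusion = as.integer(end_exclusion),
    n_snps = if (is.null(n_snps)) NULL else as.integer(n_snps),
    n_indels = if (is.null(n_indels)) NULL else as.integer(n_indels))
  class(cfg) <- "sim_config"
  cfg
}

# Three deterministic LTR-RT families; LTR lengths bracket the 1-1.3 kb range
# typical of intact plant elements.
.default_te_library <- function(seed, gc, motif) {
  m5 <- substr(motif, 1, 2); m3 <- substr(motif, 3, 4)
  .with_seed(.stream_seed(seed, "te") + 7L, {
    mk <- function(name, ltr_len, internal_len) {
      ltr <- paste0(m5, .random_dna(ltr_len - 4L, gc), m3)
      list(name = name, ltr = ltr, internal = .random_dna(internal_len, gc))
    }
    list(mk("famA", 1000L, 3000L),
         mk("famB", 1274L, 1549L),
         mk("famC", 800L, 2400L))
  })
}

.validate_te_library <- function(lib, motif) {
  m5 <- substr(motif, 1, 2); m3 <- substr(motif, 3, 4)
  for (f in lib) {
    stopifnot(!is.null(f$name), nchar(f$ltr) >= 100, nchar(f$internal) > 0)
    if (substr(f$ltr, 1, 2) != m5 ||
        substr(f$ltr, nchar(f$ltr) - 1L, nchar(f$ltr)) != m3)
      stop("LTR of family ", f$name, " does not carry the ", motif,
           " terminal motif")
  }
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "x", x$chrom_length, "bp, seed", x$seed,
      "\n  snp_rate", x$snp_rate, "| TE events",
      x$n_shared, "shared /", x$n_insertions_A, "ins_A /",
      x$n_insertions_B, "ins_B /", x$n_eliminations, "elim",
      "| gaps", x$n_gaps, "\n")
  invisible(x)
}
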