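---
title: "Methods: comparative analysis of a simulated genome pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of a simulated genome pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and layout

`genomepair` implements the bespoke computations used when two
chromosome-scale assemblies of closely related, effectively homozygous
genotypes are compared directly: assembly QC scans, reciprocal gap closure,
structural and presence/absence variation (PAV), cross-genome LTR
retrotransposon (LTR-RT) dynamics, and presence/absence marker
co-segregation. The repository is organised as an analysis: the numbered
drivers under `analysis/` run each stage on a simulated genome pair and
write their tables under `results/`, while every computation lives in the
package so the tests and `scripts/acceptance.R` exercise the same code.

Because no public genome pair is required, a simulator generates the study
system, and its truth ledger is the oracle for every downstream stage.

# The simulator and its event model

`sim_config()` + `simulate_pair()` build an ancestral genome (i.i.d. bases
at a configurable GC fraction, default 0.38 as is typical for a rosaceous
nuclear genome) and derive two descendants, "A" and "B". Events:

* **Substitutions.** A fixed count, `round(snp_rate * genome length)`, of
  positions differ between the descendants; each difference is assigned to
  one lineage at random. The default `snp_rate = 0.002` matches the
  observed density of ~2 differences per kb between closely related apple
  cultivar assemblies. The divergence time defaults to
  `snp_rate / (2 * rate)` with the clock `rate = 1.3e-8`
  substitutions/site/year, so genome-wide divergence and the clock are
  mutually consistent (~77 ky for the defaults).
* **Small indels.** `1 + Poisson` lengths capped at 50 bp, at `1e-5`
  events/site — sparse enough that 500-bp flanks are almost always
  indel-free, which is what real flank anchoring relies on.
* **LTR-RT events.** Each element is family consensus LTR+internal+LTR,
  with LTRs starting `TG` and ending `CA` and a 4-6 bp target-site
  duplication (TSD) copied from the insertion point. Classes: `shared`
  (present in both genomes, inserted before the split), `insertion_A` /
  `insertion_B` (carrier has two TSD copies, the other genome exactly one
  TSD copy with no intervening sequence), and `elimination_B` (A carries
  the element; in B the sequence between the TSD copies is replaced by
  unrelated sequence, or by a <100 bp remnant — both observed modes are
  available, mixed by default at the observed ~2:1 remnant ratio).
  Aging applies independent Poisson substitution processes to each LTR and
  the internal region, so the expected raw LTR-LTR divergence after time
  `t` is `K = 2 * rate * t`; shared elements are aged to the split, then
  each genome's copy continues independently, giving cross-genome element
  divergence equal to the genome-wide rate. The first and last two bases
  of each LTR (the terminal motif) are exempt from aging, reflecting the
  structural constraint on intact elements; this removes 4 of ~1000 sites
  from the clock and is negligible for dating.
* **Gaps.** Intervals of genome B are masked to N; the pre-mask sequence
  is recorded as the closure truth. Event placement is
  rejection-resampled with per-category padding so that gaps and elements
  keep clean 500-bp flanks; substitutions are excluded only from TSD
  sites, indel footprints and gap interiors — flanks deliberately keep
  their substitutions, since flank divergence is what the CNS analyses
  measure.
* **Telomeres.** Terminal `TTTAGGG` arrays (reverse complement at the 5'
  end), 294-1073 copies by default — the span observed at real
  chromosome ends.

One RNG stream per event category is derived from the master seed, so
changing, say, the SNP rate cannot reshuffle element placements. Ledger
coordinates are final (post-insertion), 0-based half-open.

What the simulator does **not** emulate: heterozygosity (both study
genotypes are homozygous lines), nested/fragmented repeats, tandem repeat
arrays other than telomeres, sequencing error, and real repeat landscapes
two orders of magnitude denser. Passing recovery tests therefore shows the
logic is correct on clean, structurally faithful events — not that the
detector would enumerate intact elements in a real 650-Mb genome (the
published analyses use dedicated repeat pipelines for that step; here
annotations are consumed, not produced).

# Anchoring engine

All stages share one placement engine (`anchor_fragments()`): k-mer seeds
(k = 15, stride 25) matched with `Biostrings::matchPDict`, clustered on
the diagonal, then verified either by a gap-free mismatch count at the
seeded diagonal or by a local Smith-Waterman in a padded window
(match 2, mismatch -3, gap open 5, extend 2; N never counts as a match;
coverage is measured on the query, identity per alignment column).
Placements are ranked deterministically (identity, coverage, chromosome,
start). The default identity floor of 0.8 for secondary hits is a
package decision — the flank-anchoring protocol it reimplements specifies
only the coverage threshold (>= 80%) and the placement-count bound.

# Gap closure

Gaps are maximal N-runs merged at <= 500 bp separation. For each merged
gap the 500-bp flanks are anchored in the donor and four criteria apply in
order: (i) both flanks anchored (coverage >= 0.8) within 500 kb, same
chromosome and orientation — among admissible placement pairs the one
minimising the intervening span is chosen, with an exact tie failing as
ambiguous; (ii) the **summed** placement count of the two flanks < 5 (the
per-flank reading is available by flag); (iii) no N in the donor
intervening sequence; (iv) corroboration by either anchoring in any
parity assembly or >90% of positions at depth > 3 — the two routes are
alternatives (OR), and when neither source is supplied the criterion is
skipped and flagged rather than silently passed. The first failing
criterion is recorded, which the tests observe directly. Patching
replaces the merged N-span with the donor intervening sequence; on
simulated pairs every patch is byte-identical to the pre-mask truth
because substitutions are excluded from gap interiors (flank
substitutions do not affect the patch, which starts at the inner anchor
edges).

# PAV detection and indel validation

A whole-genome anchoring chain tiles genome A (1-kb tiles), keeps
uniquely placed tiles and chains them per chromosome and strand by
longest collinear subsequence. Repetitive tiles are deliberately left
unaligned; the depth filter decides their fate, mirroring read-based
practice. Unaligned regions are merged at <= 50 bp, split/removed at N
positions and filtered at strictly > 100 bp. Because the chain has
tile-width boundary slop, each candidate region is first shrunk to its
longest run of positions below the depth cutoff and then the rule itself
applies: mean cross-genotype depth < 10% of the genome-wide mean (N
positions excluded). PAVs on B are deletions and on A insertions,
matching the read-versus-reference convention in which B-specific
sequence is a deletion. Indel candidates are validated by re-anchoring
the +/-500-bp context flanks and comparing the inner-span difference
between the genomes with the candidate length (tolerance
`max(20%, 50 bp)` — a package decision, since the source protocol states
only "a large insertion or clip"); borders and length are recalculated
from the anchor placements, which makes validation exactly symmetric
under swapping the genome roles.

# LTR-RT classification and dating

The detector pairs 16-mers recurring at a conserved separation, refines
boundaries by enumerating terminal-motif positions (window 400 bp outward
— aged LTRs may lack intact k-mers near their boundaries) and demands
identical TSD copies and LTR-LTR identity >= 0.9. Framings are scored by
matched-minus-penalised columns so trimmed or extended framings of the
true pair lose; candidates whose "LTR" contains a complete nested element
are chimeras of two nearby same-family copies and are dropped; remaining
overlaps are resolved by weighted interval scheduling, under which two
genuine elements always outscore a chimeric span covering parts of both.

Classification anchors each element's 500-bp flanks (immediately outside
the TSDs) in both genomes; non-unique anchoring discards the element,
counted per genome, mirroring the two-stage removal in the published
protocol. The B intervening sequence then decides: >100 bp with a local
alignment hit to the A element is `Shared` (split at 0.99 global identity
of the counterpart sequence — identity over the whole element, a logged
choice); a single TSD copy with no intervening sequence is `Insertion`
(up to 10 bp of anchor jitter beyond one TSD is tolerated, since an
absolute zero is not testable against alignment-edge noise); no local hit
with two or zero TSD copies is `Elimination`; anything else `Unknown`.
The BLAST e-value screen of the original is replaced by a local
alignment score floor (default 100 ~ a 50-bp perfect match).

Dating uses `T = K / (2 * rate)` with `rate = 1.3e-8`
substitutions/site/year; `K` is measured between an element's own two
LTRs, raw by default with a Jukes-Cantor-corrected mode
(`-(3/4) log(1 - 4K/3)`), since the original does not state a
correction. The Poisson clock sets a hard variance floor on recovery:
for 1-kb LTRs, `sd(T-hat)/T = 1 / sqrt(2 * rate * T * L)`, about 20% at
1 MY. The acceptance suite measures a relative RMSE of ~0.19-0.21 over
ages 0.1-2 MY, which is this floor, not estimator bias (the JC-corrected
estimator is unbiased to first order); a materially smaller error would
require longer LTRs or averaging over many elements.

The cumulative-substitution analyses compare A and B copies of element
flanks: per-element `S_f` over the two 500-bp flanks, a control `S_c`
from a region 9 kb away, the rate formula
`V = (S_f - S_c)/T_ltr + S_c/(2 T_div)` (negative values are reported
as-is; `T_div` has no published value and is a required input, defaulted
in the simulator to the value consistent with the SNP rate), sliding
400-bp flank profiles with ten equal interior bins, a control
distribution from randomly placed blocks compared tile-by-tile (tiles
whose mismatches cluster densely sit on structural edges and are
excluded from the control, which measures background substitutions), a
100,000-year sliding window of flank CNS over element age, and
gene-distance histograms in 100-bp bins against a uniform control.

# Marker analysis

A junction marker is any >= 20-bp sequence spanning an insertion
boundary: carriers contain it, non-carriers contain only its separated
halves. Search is exact by default in assemblies with a mismatch
tolerance for noisy reads (the original retrieved junctions from read
archives without stating a tolerance). In-silico PCR reports products as
the inclusive span of both primers, with the last three 3' bases of each
primer required to match exactly — standard PCR specificity that the
published marker implicitly relies on. Co-segregation tabulates marker
against phenotype over samples with known phenotype and a usable assay;
`perfect` means concordance exactly 1.

# Problem sizes and determinism

The analysis drivers use a 2 x 2.5-Mb pair with 115 elements, 20 gaps
and 10,000 substitutions; the acceptance script uses the same scale for
gap closure and classification, a 2 x 1-Mb pair for PAV, and 200 aged
elements for dating — sizes at which every stage completes in a few
minutes on one CPU while keeping per-stage event counts large enough for
the stated tolerances. All stages are deterministic given the seed; the
acceptance script derives every stream from its `--seed` argument.

# Known limitations

* The element detector is specified to be complete on simulator-style
  elements only; solo LTRs, nested insertions and diverged fragments are
  out of scope.
* The PAV depth filter takes depth tracks as input and makes no claim of
  equivalence between assembly-derived and read-derived depth.
* The heterochromatin scan is a repeat-density proxy; the simulated
  genomes are too repeat-poor to produce blocks, so the driver exercises
  it against constructed annotations and the tests against a
  sliding-window oracle.
* Expression-dependent analyses of element activity require RNA-seq and
  are not implemented.
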