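#' Generate the ancestral genome
#'
#' I.i.d. bases at the configured GC fraction; no N bases; bit-identical
#' under the same config (the ancestor has its own RNG stream).
#'
#' @param config A [sim_config()].
#' @return Named DNAStringSet (`chr01`, `chr02`, ...).
#' @export
generate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- .with_seed(.stream_seed(config$seed, "ancestor"), {
    vapply(seq_len(config$n_chromosomes),
           function(i) .random_dna(config$chrom_length, config$gc_fraction),
           character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  out
}

#' Age an LTR retrotransposon element under a constant clock
#'
#' Each LTR accumulates substitutions as an independent Poisson process at
#' `rate` substitutions per site per year, so the expected raw LTR-LTR
#' divergence after `age_years` is `2 * rate * age_years`; the internal
#' region is mutated at the same per-site rate. The first and last two bases
#' of each LTR (the terminal motif) are left untouched, as they are under
#' structural constraint in intact elements.
#'
#' @param element Element sequence (character or DNAString), structured as
#'   LTR + internal + LTR.
#' @param ltr_len Length of each LTR in bases.
#' @param age_years Age of the insertion, years (>= 0).
#' @param rate Substitutions per site per year.
#' @param seed Optional seed for reproducible aging.
#' @return The mutated element as a character string.
#' @export
age_ltr <- function(element, ltr_len, age_years, rate = 1.3e-8, seed = NULL) {
  if (age_years < 0 || rate < 0) stop("age and rate must be non-negative")
  element <- as.character(.as_dna(element))
  run <- function() .age_element(element, ltr_len, age_years, rate)
  if (is.null(seed)) run() else .with_seed(seed, run())
}

.age_element <- function(element, ltr_len, age_years, rate) {
  n <- nchar(element)
  stopifnot(n >= 2 * ltr_len)
  if (age_years == 0) return(element)
  lam <- rate * age_years
  regions <- list(
    ltr5 = seq.int(3L, ltr_len - 2L),
    internal = if (n > 2 * ltr_len) seq.int(ltr_len + 1L, n - ltr_len) else integer(),
    ltr3 = seq.int(n - ltr_len + 3L, n - 2L))
  for (idx in regions) {
    if (!length(idx)) next
    element <- .mutate_positions(element, rpois(1L, lam * length(idx)), idx)
  }
  element
}

#' Derive the descendant genome pair and its truth ledger
#'
#' Applies the configured SNPs, small indels, TE insertions/eliminations,
#' telomere arrays and N-gap masking to the ancestor, producing genomes A
#' and B plus a complete event ledger in final (post-insertion) 0-based
#' half-open coordinates. Event placements are rejection-resampled to avoid
#' collisions; an over-dense configuration raises an error.
#'
#' @param ancestor From [generate_ancestor()].
#' @param config The same [sim_config()].
#' @return list with `genome_A`, `genome_B` (DNAStringSet) and `truth`, a
#'   list of data.frames `snps`, `indels`, `te_events`, `gaps`, `telomeres`.
#' @export
derive_pair <- function(ancestor, config) {
  stopifnot(inherits(config, "sim_config"))
  anc_chr <- as.character(ancestor)
  chroms <- names(ancestor)
  lens <- nchar(anc_chr)
  names(lens) <- chroms

  te <- .with_seed(.stream_seed(config$seed, "te"),
                   .place_te_events(config, chroms, lens, anc_chr))
  gaps <- .with_seed(.stream_seed(config$seed, "gap"),
                     .place_gaps(config, chroms, lens, te$reserved))
  indels <- .with_seed(.stream_seed(config$seed, "indel"),
                       .place_indels(config, chroms, lens, gaps$reserved))
  snps <- .with_seed(.stream_seed(config$seed, "snp"),
                     .place_snps(config, chroms, lens, anc_chr,
                                 te$events, gaps$events, indels$events))
  te$events <- .with_seed(.stream_seed(config$seed, "age"),
                          .build_te_sequences(te$events, config))
  telo <- .with_seed(.stream_seed(config$seed, "telomere"),
                     .draw_telomeres(config, chroms))

  edits <- .compose_edits(config, chroms, anc_chr, te$events, gaps$events,
                          indels$events, snps, telo)
  built_A <- .build_genome(anc_chr, edits, "A")
  built_B <- .build_genome(anc_chr, edits, "B")
  truth <- .assemble_truth(te$events, gaps$events, indels$events, snps, telo,
                           built_A$coords, built_B$coords)
  # mask gaps in B last, recording the pre-mask truth sequence
  if (nrow(truth$gaps)) {
    for (i in seq_len(nrow(truth$gaps))) {
      g <- truth$gaps[i, ]
      s <- built_B$seqs[[g$chrom]]
      truth$gaps$truth_seq[i] <- substr(s, g$start + 1L, g$end)
      substr(s, g$start + 1L, g$end) <- strrep("N", g$end - g$start)
      built_B$seqs[[g$chrom]] <- s
    }
  }
  gA <- Biostrings::DNAStringSet(unlist(built_A$seqs)); names(gA) <- chroms
  gB <- Biostrings::DNAStringSet(unlist(built_B$seqs)); names(gB) <- chroms
  list(genome_A = gA, genome_B = gB, truth = truth)
}

#' Simulate a genome pair in one call
#'
#' @param config A [sim_config()].
#' @return list with `ancestor`, `genome_A`, `genome_B`, `truth`, `config`.
#' @export
simulate_pair <- function(config) {
  anc <- generate_ancestor(config)
  out <- derive_pair(anc, config)
  c(list(ancestor = anc), out, list(config = config))
}

# ---- placement ------------------------------------------------------------

# pads keep event neighbourhoods clean enough for 500-bp flank anchoring
.TE_PAD <- 700L
.GAP_PAD <- 700L
.INDEL_PAD <- 10L

.place_on_free <- function(reserved, chrom, lo, hi, width, pad,
                           accept = NULL, max_attempts = 2000L) {
  for (i in seq_len(max_attempts)) {
    p <- floor(runif(1, lo, hi - width))
    if (!is.null(accept) && !accept(p)) next
    cand <- IRanges::IRanges(p + 1L - pad, p + width + pad)
    if (!length(reserved[[chrom]]) ||
        !IRanges::countOverlaps(cand, reserved[[chrom]])) {
      reserved[[chrom]] <- c(reserved[[chrom]], cand)
      return(list(pos = p, reserved = reserved))
    }
  }
  stop("event placement failed after ", max_attempts,
       " attempts: configuration too dense")
}

.place_te_events <- function(config, chroms, lens, anc_chr) {
  classes <- c(rep("shared", config$n_shared),
               rep("insertion_A", config$n_insertions_A),
               rep("insertion_B", config$n_insertions_B),
               rep("elimination_B", config$n_eliminations))
  reserved <- setNames(lapply(chroms, function(x) IRanges::IRanges()), chroms)
  if (!length(classes))
    return(list(events = NULL, reserved = reserved))
  genes <- config$genes
  ev <- vector("list", length(classes))
  chrom_pick <- sample(chroms, length(classes), replace = TRUE,
                       prob = lens / sum(lens))
  for (i in seq_along(classes)) {
    ch <- chrom_pick[i]
    fam_i <- sample(seq_along(config$te_library), 1L)
    tsd_len <- sample(seq(config$tsd_length_range[1],
                          config$tsd_length_range[2]), 1L)
    accept <- NULL
    if (!is.null(genes) && config$genic_insertion_relprob < 1) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      accept <- function(p) {
        inside <- any(p >= g$start & p < g$end)
        !inside || runif(1) < config$genic_insertion_relprob
      }
    }
    pl <- .place_on_free(reserved, ch, config$end_exclusion,
                         lens[[ch]] - config$end_exclusion, tsd_len, .TE_PAD,
                         accept = accept)
    reserved <- pl$reserved
    age_range <- if (classes[i] %in% c("shared", "elimination_B"))
      config$shared_age_range_years else config$ltr_age_range_years
    ev[[i]] <- data.frame(
      event_id = sprintf("te%03d", i), class = classes[i],
      family = config$te_library[[fam_i]]$name, fam_i = fam_i,
      chrom = ch, anc_pos = pl$pos, tsd_len = tsd_len,
      tsd = substr(anc_chr[[ch]], pl$pos + 1L, pl$pos + tsd_len),
      age_years = runif(1, age_range[1], age_range[2]),
      stringsAsFactors = FALSE)
  }
  list(events = do.call(rbind, ev), reserved = reserved)
}

.place_gaps <- function(config, chroms, lens, reserved) {
  if (!config$n_gaps) return(list(events = NULL, reserved = reserved))
  chrom_pick <- sample(chroms, config$n_gaps, replace = TRUE,
                       prob = lens / sum(lens))
  ev <- vector("list", config$n_gaps)
  for (i in seq_len(config$n_gaps)) {
    w <- sample(seq(config$gap_length_range[1], config$gap_length_range[2]), 1L)
    ch <- chrom_pick[i]
    pl <- .place_on_free(reserved, ch, config$end_exclusion,
                         lens[[ch]] - config$end_exclusion, w, .GAP_PAD)
    reserved <- pl$reserved
    ev[[i]] <- data.frame(gap_id = sprintf("gap%03d", i), chrom = ch,
                          anc_start = pl$pos, anc_end = pl$pos + w,
                          stringsAsFactors = FALSE)
  }
  list(events = do.call(rbind, ev), reserved = reserved)
}

.place_indels <- function(config, chroms, lens, reserved) {
  n <- if (!is.null(config$n_indels)) 2L * config$n_indels
       else round(2 * config$small_indel_rate * sum(lens))
  if (!n) return(list(events = NULL, reserved = reserved))
  chrom_pick <- sample(chroms, n, replace = TRUE, prob = lens / sum(lens))
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    type <- sample(c("insertion", "deletion"), 1L)
    len <- min(1L + rpois(1L, 1 / config$indel_geom_prob), config$max_indel)
    genome <- sample(c("A", "B"), 1L)
    ch <- chrom_pick[i]
    w <- if (type == "deletion") len else 0L
    pl <- .place_on_free(reserved, ch, config$end_exclusion,
                         lens[[ch]] - config$end_exclusion, max(w, 1L),
                         .INDEL_PAD)
    reserved <- pl$reserved
    ev[[i]] <- data.frame(indel_id = sprintf("ind%03d", i), genome = genome,
                          chrom = ch, anc_start = pl$pos,
                          anc_end = pl$pos + w, type = type, len = len,
                          seq = if (type == "insertion")
                            .random_dna(len, config$gc_fraction) else "",
                          stringsAsFactors = FALSE)
  }
  list(events = do.call(rbind, ev), reserved = reserved)
}

# SNPs may fall anywhere except inside masked gaps, TSD sites or indel
# footprints; an optional elevated-rate zone near TE insertion points
# emulates the mutagenic neighbourhood of fresh insertions.
.place_snps <- function(config, chroms, lens, anc_chr, te, gaps, indels) {
  n_base <- if (!is.null(config$n_snps)) config$n_snps
            else round(config$snp_rate * sum(lens))
  excluded <- setNames(lapply(chroms, function(x) IRanges::IRanges()), chroms)
  add_excl <- function(excl, ch, s0, e0) {
    excl[[ch]] <- c(excl[[ch]], IRanges::IRanges(s0 + 1L, e0))
    excl
  }
  if (!is.null(gaps)) for (i in seq_len(nrow(gaps)))
    excluded <- add_excl(excluded, gaps$chrom[i], gaps$anc_start[i] - 2L,
                         gaps$anc_end[i] + 2L)
  if (!is.null(te)) for (i in seq_len(nrow(te)))
    excluded <- add_excl(excluded, te$chrom[i], te$anc_pos[i] - 2L,
                         te$anc_pos[i] + te$tsd_len[i] + 2L)
  if (!is.null(indels)) for (i in seq_len(nrow(indels)))
    excluded <- add_excl(excluded, indels$chrom[i], indels$anc_start[i] - 2L,
                         indels$anc_end[i] + 2L)
  excluded <- lapply(excluded, IRanges::reduce)

  draw <- function(ch, lo, hi) floor(runif(1, lo, hi))
  pos_list <- list()
  place <- function(n, sampler) {
    got <- 0L; attempts <- 0L
    while (got < n && attempts < 50L * n + 1000L) {
      attempts <- attempts + 1L
      s <- sampler()
      ch <- s$chrom; p <- s$pos
      if (p < config$end_exclusion || p >= lens[[ch]] - config$end_exclusion)
        next
      if (length(excluded[[ch]]) &&
          IRanges::countOverlaps(IRanges::IRanges(p + 1L, p + 1L),
                                 excluded[[ch]])) next
      key <- paste0(ch, ":", p)
      if (!is.null(pos_list[[key]])) next
      pos_list[[key]] <<- c(chrom = ch, pos = p)
      got <- got + 1L
    }
    got
  }
  place(n_base, function() {
    ch <- sample(chroms, 1L, prob = lens / sum(lens))
    list(chrom = ch, pos = draw(ch, 0, lens[[ch]]))
  })
  if (config$te_flank_snp_multiplier > 1 && !is.null(te) && nrow(te)) {
    zone <- config$te_flank_zone
    extra <- round((config$te_flank_snp_multiplier - 1) * config$snp_rate *
                     2 * zone * nrow(te))
    place(extra, function() {
      i <- sample(nrow(te), 1L)
      side <- sample(c(-1L, 1L), 1L)
      off <- sample.int(zone, 1L)
      p <- if (side < 0) te$anc_pos[i] - off
           else te$anc_pos[i] + te$tsd_len[i] + off - 1L
      list(chrom = te$chrom[i], pos = p)
    })
  }
  if (!length(pos_list))
    return(.empty_df(chrom = character(), anc_pos = integer(),
                     ancestral = character(), a_base = character(),
                     b_base = character()))
  df <- data.frame(chrom = vapply(pos_list, `[[`, "", "chrom"),
                   anc_pos = as.integer(vapply(pos_list, `[[`, "", "pos")),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$anc_pos), , drop = FALSE]
  rownames(df) <- NULL
  df$ancestral <- vapply(seq_len(nrow(df)), function(i)
    substr(anc_chr[[df$chrom[i]]], df$anc_pos[i] + 1L, df$anc_pos[i] + 1L), "")
  which_g <- sample(c("A", "B"), nrow(df), replace = TRUE)
  derived <- vapply(df$ancestral, function(b)
    sample(setdiff(DNA_BASES4, b), 1L), "")
  df$a_base <- ifelse(which_g == "A", derived, df$ancestral)
  df$b_base <- ifelse(which_g == "B", derived, df$ancestral)
  df
}

# ---- element sequence construction ---------------------------------------

.build_te_sequences <- function(te, config) {
  if (is.null(te) || !nrow(te)) return(te)
  t_div <- config$divergence_time_years
  rate <- config$subst_rate
  te$elem_A <- NA_character_; te$elem_B <- NA_character_
  te$ltr_len <- NA_integer_
  for (i in seq_len(nrow(te))) {
    fam <- config$te_library[[te$fam_i[i]]]
    consensus <- paste0(fam$ltr, fam$internal, fam$ltr)
    ltr_len <- nchar(fam$ltr)
    te$ltr_len[i] <- ltr_len
    cls <- te$class[i]
    if (cls %in% c("shared", "elimination_B")) {
      pre_split <- max(te$age_years[i] - t_div, 0)
      base <- .age_element(consensus, ltr_len, pre_split, rate)
      te$elem_A[i] <- .age_element(base, ltr_len, t_div, rate)
      if (cls == "shared") {
        te$elem_B[i] <- .age_element(base, ltr_len, t_div, rate)
      } else {
        mode <- config$elimination_mode
        if (mode == "mixed")
          mode <- if (runif(1) < config$remnant_fraction) "remnant"
                  else "replacement"
        filler_len <- if (mode == "remnant") sample(10:99, 1L)
                      else sample(500:2000, 1L)
        te$elem_B[i] <- .random_dna(filler_len, config$gc_fraction)
        te$elim_mode <- te$elim_mode %||% NA_character_
        te$elim_mode[i] <- mode
      }
    } else {
      elem <- .age_element(consensus, ltr_len, te$age_years[i], rate)
      if (cls == "insertion_A") te$elem_A[i] <- elem else te$elem_B[i] <- elem
    }
  }
  te
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.draw_telomeres <- function(config, chroms) {
  lo <- config$telomere_copies_range[1]; hi <- config$telomere_copies_range[2]
  do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, end = c("5prime", "3prime"),
               copies = sample(seq(lo, hi), 2L, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
}

# ---- edit composition -----------------------------------------------------

# One edit per event: ancestral interval [astart, aend) replaced by repl_A
# in genome A and repl_B in genome B (NA = keep the ancestral segment).
.compose_edits <- function(config, chroms, anc_chr, te, gaps, indels, snps,
                           telo) {
  ed <- list()
  add <- function(cat, id, chrom, astart, aend, repl_A, repl_B) {
    ed[[length(ed) + 1L]] <<- data.frame(
      cat = cat, id = id, chrom = chrom, astart = astart, aend = aend,
      repl_A = repl_A, repl_B = repl_B, stringsAsFactors = FALSE)
  }
  if (!is.null(te)) for (i in seq_len(nrow(te))) {
    with_tsd <- function(x) paste0(te$tsd[i], x, te$tsd[i])
    s <- te$anc_pos[i]; e <- s + te$tsd_len[i]
    cls <- te$class[i]
    repl_A <- switch(cls,
      shared = , elimination_B = , insertion_A = with_tsd(te$elem_A[i]),
      insertion_B = NA_character_)
    repl_B <- switch(cls,
      shared = , elimination_B = with_tsd(te$elem_B[i]),
      insertion_B = with_tsd(te$elem_B[i]),
      insertion_A = NA_character_)
    add("te", te$event_id[i], te$chrom[i], s, e, repl_A, repl_B)
  }
  if (!is.null(gaps)) for (i in seq_len(nrow(gaps)))
    add("gap", gaps$gap_id[i], gaps$chrom[i], gaps$anc_start[i],
        gaps$anc_end[i], NA_character_, NA_character_)
  if (!is.null(indels)) for (i in seq_len(nrow(indels))) {
    repl <- if (indels$type[i] == "insertion")
      paste0(indels$seq[i]) else ""
    if (indels$type[i] == "insertion") {
      a <- indels$anc_start[i]; b <- a
    } else {
      a <- indels$anc_start[i]; b <- indels$anc_end[i]
    }
    add("indel", indels$indel_id[i], indels$chrom[i], a, b,
        if (indels$genome[i] == "A") repl else NA_character_,
        if (indels$genome[i] == "B") repl else NA_character_)
  }
  if (!is.null(snps) && nrow(snps)) for (i in seq_len(nrow(snps)))
    add("snp", sprintf("snp%05d", i), snps$chrom[i], snps$anc_pos[i],
        snps$anc_pos[i] + 1L,
        if (snps$a_base[i] != snps$ancestral[i]) snps$a_base[i] else NA_character_,
        if (snps$b_base[i] != snps$ancestral[i]) snps$b_base[i] else NA_character_)
  # telomeres as edits at the chromosome termini
  unit <- config$telomere_unit
  unit_rc <- .gp_revcomp(unit)
  for (ch in chroms) {
    tl <- telo[telo$chrom == ch, ]
    c5 <- tl$copies[tl$end == "5prime"]; c3 <- tl$copies[tl$end == "3prime"]
    add("telomere", paste0(ch, "_5p"), ch, 0L, 0L,
        strrep(unit_rc, c5), strrep(unit_rc, c5))
    L <- nchar(anc_chr[[ch]])
    add("telomere", paste0(ch, "_3p"), ch, L, L,
        strrep(unit, c3), strrep(unit, c3))
  }
  edits <- do.call(rbind, ed)
  edits <- edits[order(edits$chrom, edits$astart, edits$aend), , drop = FALSE]
  # overlapping replacement footprints would corrupt coordinates
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, ]
    if (any(e$astart[-1] < head(e$aend, -1)))
      stop("internal error: overlapping event footprints on ", ch)
  }
  rownames(edits) <- NULL
  edits
}

.build_genome <- function(anc_chr, edits, which) {
  repl_col <- paste0("repl_", which)
  seqs <- list(); coords <- list()
  for (ch in names(anc_chr)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    anc <- anc_chr[[ch]]
    pieces <- character(2L * nrow(e) + 1L)
    fs <- integer(nrow(e)); fe <- integer(nrow(e))
    cur <- 0L; flen <- 0L
    for (i in seq_len(nrow(e))) {
      keep <- substr(anc, cur + 1L, e$astart[i])
      pieces[2L * i - 1L] <- keep
      flen <- flen + nchar(keep)
      repl <- e[[repl_col]][i]
      if (is.na(repl)) repl <- substr(anc, e$astart[i] + 1L, e$aend[i])
      pieces[2L * i] <- repl
      fs[i] <- flen
      flen <- flen + nchar(repl)
      fe[i] <- flen
      cur <- e$aend[i]
    }
    pieces[2L * nrow(e) + 1L] <- substr(anc, cur + 1L, nchar(anc))
    seqs[[ch]] <- paste(pieces, collapse = "")
    coords[[ch]] <- data.frame(id = e$id, fs = fs, fe = fe,
                               stringsAsFactors = FALSE)
  }
  list(seqs = seqs, coords = do.call(rbind, coords))
}

# Join the event tables with the final coordinates recorded per genome.
# Replacement spans [repl_start, repl_end) cover the whole edited footprint
# (TSD + element + TSD for a carried TE); element body spans exclude TSDs.
.assemble_truth <- function(te, gaps, indels, snps, telo,
                            coords_A, coords_B) {
  iA <- setNames(seq_len(nrow(coords_A)), coords_A$id)
  iB <- setNames(seq_len(nrow(coords_B)), coords_B$id)
  fsA <- function(id) coords_A$fs[iA[id]]; feA <- function(id) coords_A$fe[iA[id]]
  fsB <- function(id) coords_B$fs[iB[id]]; feB <- function(id) coords_B$fe[iB[id]]

  if (!is.null(snps) && nrow(snps)) {
    ids <- sprintf("snp%05d", seq_len(nrow(snps)))
    snps_out <- data.frame(
      chrom = snps$chrom, pos_A = fsA(ids), pos_B = fsB(ids),
      ancestral = snps$ancestral, a_base = snps$a_base, b_base = snps$b_base,
      stringsAsFactors = FALSE)
  } else {
    snps_out <- .empty_df(chrom = character(), pos_A = integer(),
                          pos_B = integer(), ancestral = character(),
                          a_base = character(), b_base = character())
  }

  if (!is.null(te) && nrow(te)) {
    id <- te$event_id
    carrier_A <- te$class %in% c("shared", "insertion_A", "elimination_B")
    carrier_B <- te$class %in% c("shared", "insertion_B", "elimination_B")
    te_out <- data.frame(
      event_id = id, class = te$class, family = te$family, chrom = te$chrom,
      tsd = te$tsd, tsd_len = te$tsd_len, age_years = te$age_years,
      ltr_len = te$ltr_len,
      elim_mode = if ("elim_mode" %in% names(te)) te$elim_mode else NA_character_,
      a_repl_start = fsA(id), a_repl_end = feA(id),
      b_repl_start = fsB(id), b_repl_end = feB(id),
      stringsAsFactors = FALSE)
    te_out$a_elem_start <- ifelse(carrier_A, te_out$a_repl_start + te$tsd_len,
                                  NA_integer_)
    te_out$a_elem_end <- ifelse(carrier_A, te_out$a_repl_end - te$tsd_len,
                                NA_integer_)
    te_out$b_elem_start <- ifelse(carrier_B, te_out$b_repl_start + te$tsd_len,
                                  NA_integer_)
    te_out$b_elem_end <- ifelse(carrier_B, te_out$b_repl_end - te$tsd_len,
                                NA_integer_)
    te_out$elem_A <- te$elem_A
    te_out$elem_B <- te$elem_B
  } else {
    te_out <- .empty_df(event_id = character(), class = character(),
                        family = character(), chrom = character(),
                        tsd = character(), tsd_len = integer(),
                        age_years = numeric(), ltr_len = integer(),
                        elim_mode = character(),
                        a_repl_start = integer(), a_repl_end = integer(),
                        b_repl_start = integer(), b_repl_end = integer(),
                        a_elem_start = integer(), a_elem_end = integer(),
                        b_elem_start = integer(), b_elem_end = integer(),
                        elem_A = character(), elem_B = character())
  }

  if (!is.null(gaps) && nrow(gaps)) {
    gaps_out <- data.frame(
      gap_id = gaps$gap_id, chrom = gaps$chrom,
      start = fsB(gaps$gap_id), end = feB(gaps$gap_id),
      a_start = fsA(gaps$gap_id), a_end = feA(gaps$gap_id),
      truth_seq = NA_character_, stringsAsFactors = FALSE)
  } else {
    gaps_out <- .empty_df(gap_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          a_start = integer(), a_end = integer(),
                          truth_seq = character())
  }

  if (!is.null(indels) && nrow(indels)) {
    id <- indels$indel_id
    indels_out <- data.frame(
      indel_id = id, genome = indels$genome, chrom = indels$chrom,
      type = indels$type, len = indels$len, seq = indels$seq,
      a_start = fsA(id), a_end = feA(id),
      b_start = fsB(id), b_end = feB(id), stringsAsFactors = FALSE)
  } else {
    indels_out <- .empty_df(indel_id = character(), genome = character(),
                            chrom = character(), type = character(),
                            len = integer(), seq = character(),
                            a_start = integer(), a_end = integer(),
                            b_start = integer(), b_end = integer())
  }

  list(snps = snps_out, indels = indels_out, te_events = te_out,
       gaps = gaps_out, telomeres = telo)
}
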