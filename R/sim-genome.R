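# Synthetic-region simulator with planted ground truth.
#
# A region is a random background into which feature "blocks" (LTR elements
# in one of nine fates, DNA transposons, tandem arrays, gene-movement
# footprints) are spliced; genes are annotated over background intervals.
# Every planted feature is recorded in a truth table so downstream stages
# can be validated without any external data.

TRUTH_COLS <- c("feature_id", "kind", "start", "end", "strand", "family",
                "class", "fate", "age_years", "evidence", "pattern",
                "parent", "role")

truth_row <- function(feature_id, kind, start, end, strand = "+",
                      family = NA_character_, class = NA_character_,
                      fate = NA_character_, age_years = NA_real_,
                      evidence = NA_character_, pattern = NA_character_,
                      parent = NA_character_, role = NA_character_) {
  data.frame(feature_id = feature_id, kind = kind,
             start = as.integer(start), end = as.integer(end),
             strand = strand, family = family, class = class, fate = fate,
             age_years = age_years, evidence = evidence, pattern = pattern,
             parent = parent, role = role, stringsAsFactors = FALSE)
}

empty_truth <- function() {
  truth_row(character(0), character(0), integer(0), integer(0),
            character(0), character(0), character(0), character(0),
            numeric(0), character(0), character(0), character(0),
            character(0))[0, ]
}

bind_truth <- function(...) {
  rows <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(rows)) return(empty_truth())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Generate a random background sequence
#'
#' @param length sequence length in bp (> 0).
#' @param gc_fraction expected G+C proportion.
#' @param seed integer seed; identical calls return identical sequence.
#' @return a character scalar of A/C/G/T.
#' @export
make_background <- function(length, gc_fraction = 0.43, seed = 1) {
  if (!is_scalar_number(length) || length <= 0)
    stopf("background length must be positive")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stopf("gc_fraction must be in (0, 1)")
  with_seed(seed, chars_seq(random_dna_chars(as.integer(length), gc_fraction)))
}

# ---- element block construction -------------------------------------------

resolve_family <- function(spec_family, lib, idx, role = "LTR") {
  fams <- unique(lib$family[lib$role == role])
  if (!length(fams)) stopf("library has no %s families", role)
  if (is.na(spec_family)) fams[(idx - 1L) %% length(fams) + 1L]
  else {
    if (!spec_family %in% fams) stopf("family '%s' not in library", spec_family)
    spec_family
  }
}

# Build the sequence block and relative-coordinate truth for one LTR
# element.  Layout: [left flank motif][element][right flank motif]; the
# element truth interval excludes the TSD copies (they are host sequence).
build_element_block <- function(spec, config, fid, fam_idx = 1L) {
  lib <- config$library
  r <- config$rate; kappa <- config$kappa
  fam <- resolve_family(spec$family, lib, fam_idx)
  consL <- seq_chars(lib_seq(lib, fam, "LTR"))
  consI <- seq_chars(lib_seq(lib, fam, "internal"))
  age <- spec$age_years
  tl <- spec$tsd_length

  with_seed(derive_seed(config$seed, fid), {
    # ancestral element diverges from the family consensus for `age`, then
    # each LTR copy (and the internal region) evolves independently for
    # `age` after insertion; pairwise LTR-LTR divergence is therefore the
    # K2P expectation at path length 2*age.
    anc_ltr <- evolve_k2p(consL, age, r, kappa)
    ltr5 <- chars_seq(evolve_k2p(anc_ltr, age, r, kappa))
    ltr3 <- chars_seq(evolve_k2p(anc_ltr, age, r, kappa))
    int  <- chars_seq(evolve_k2p(evolve_k2p(consI, age, r, kappa), age, r, kappa))
    tsd  <- if (tl > 0) chars_seq(random_dna_chars(tl, config$gc_fraction)) else ""
    rnd  <- function(n) if (n > 0) chars_seq(random_dna_chars(n, config$gc_fraction)) else ""

    fate <- spec$fate
    # pieces: list of (sequence, role or NA); roles become truth part rows
    pieces <- switch(fate,
      IntactLTR = list(list(tsd, NA), list(ltr5, "five_prime_LTR"),
                       list(int, "internal"), list(ltr3, "three_prime_LTR"),
                       list(tsd, NA)),
      IntactWithoutTSD = list(list(rnd(tl), NA), list(ltr5, "five_prime_LTR"),
                              list(int, "internal"),
                              list(ltr3, "three_prime_LTR"), list(tsd, NA)),
      SoloWithTSD = list(list(tsd, NA), list(ltr5, "LTR"), list(tsd, NA)),
      SoloWithoutTSD = list(list(rnd(tl), NA), list(ltr5, "LTR"),
                            list(tsd, NA)),
      TruncatedSolo = {
        keep <- max(1L, round(spec$trunc_fraction * nchar(ltr5)))
        list(list(substr(ltr5, 1L, keep), "partial_LTR"))
      },
      ThreePrimeLTRDeleted = list(list(ltr5, "five_prime_LTR"),
                                  list(int, "internal")),
      FivePrimeLTRDeleted = list(list(int, "internal"),
                                 list(ltr3, "three_prime_LTR")),
      PartiallyDeleted = {
        L <- nchar(int)
        k <- max(1L, round(0.15 * L))
        left <- substr(int, 1L, k)
        right <- substr(int, L - k + 1L, L)
        mh <- sample(2:10, 1L) # microhomology at the deletion junction
        if (k > mh)
          right <- paste0(substr(left, k - mh + 1L, k),
                          substr(right, mh + 1L, nchar(right)))
        list(list(ltr5, "five_prime_LTR"), list(left, "partial_internal"),
             list(right, "partial_internal"),
             list(ltr3, "three_prime_LTR"))
      },
      RecombinationComplex = {
        fam2 <- if (is.na(spec$family2)) {
          fams <- setdiff(ltr_families(lib), fam)
          if (!length(fams)) stopf("RecombinationComplex needs >= 2 families")
          fams[(fam_idx - 1L) %% length(fams) + 1L]
        } else spec$family2
        consL2 <- seq_chars(lib_seq(lib, fam2, "LTR"))
        consI2 <- seq_chars(lib_seq(lib, fam2, "internal"))
        ltrB <- chars_seq(evolve_k2p(evolve_k2p(consL2, age, r, kappa), age, r, kappa))
        intB <- chars_seq(evolve_k2p(evolve_k2p(consI2, age, r, kappa), age, r, kappa))
        hA <- substr(int, 1L, floor(nchar(int) * 0.6))
        hB <- substr(intB, nchar(intB) - floor(nchar(intB) * 0.6) + 1L, nchar(intB))
        list(list(ltr5, "five_prime_LTR"), list(hA, "partial_internal"),
             list(hB, "partial_internal:2"),
             list(ltrB, "three_prime_LTR:2"))
      },
      stopf("unhandled fate '%s'", fate))

    seqs <- vapply(pieces, function(p) p[[1]], character(1))
    roles <- vapply(pieces, function(p) {
      if (is.na(p[[2]])) NA_character_ else p[[2]]
    }, character(1))
    lens <- nchar(seqs)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L

    part_idx <- which(!is.na(roles) & lens > 0)
    el_start <- min(starts[part_idx]); el_end <- max(ends[part_idx])

    parts <- lapply(part_idx, function(i) {
      role_i <- roles[i]
      fam_i <- fam
      if (grepl(":2$", role_i)) { # RecombinationComplex second-family parts
        role_i <- sub(":2$", "", role_i)
        fams <- setdiff(ltr_families(lib), fam)
        fam_i <- if (is.na(spec$family2))
          fams[(fam_idx - 1L) %% length(fams) + 1L] else spec$family2
      }
      truth_row(paste0(fid, ".", role_i, ".", i), "part", starts[i], ends[i],
                family = fam_i, age_years = age, parent = fid, role = role_i)
    })
    has_tsd <- fate %in% c("IntactLTR", "SoloWithTSD")
    el <- truth_row(fid, "ltr_element", el_start, el_end, family = fam,
                    class = lib$class[lib$family == fam & lib$role == "LTR"],
                    fate = fate, age_years = age,
                    evidence = if (has_tsd && tl > 0) chars_seq(tsd) else NA_character_)
    list(seq = paste0(seqs, collapse = ""),
         truth = do.call(bind_truth, c(list(el), parts)),
         fid = fid, nest_in = spec$nest_in)
  })
}

build_dna_block <- function(spec, config, fid, idx = 1L) {
  lib <- config$library
  fams <- unique(lib$family[lib$role == "DNA"])
  if (!length(fams)) stopf("library has no DNA-transposon consensi")
  fam <- if (is.na(spec$family)) fams[(idx - 1L) %% length(fams) + 1L] else spec$family
  cons <- lib_seq(lib, fam, "DNA")
  if (is.null(cons)) stopf("family '%s' has no DNA consensus", fam)
  with_seed(derive_seed(config$seed, fid), {
    s <- chars_seq(evolve_k2p(seq_chars(cons), 2 * spec$age_years,
                              config$rate, config$kappa))
    cls <- lib$class[lib$family == fam & lib$role == "DNA"]
    list(seq = s,
         truth = truth_row(fid, "dna_te", 1L, nchar(s), family = fam,
                           class = cls, age_years = spec$age_years),
         fid = fid, nest_in = NA)
  })
}

build_tandem_block <- function(spec, config, fid) {
  with_seed(derive_seed(config$seed, fid), {
    unit <- chars_seq(random_dna_chars(spec$period, config$gc_fraction))
    s <- strrep(unit, spec$copies)
    list(seq = s,
         truth = truth_row(fid, "tandem_array", 1L, nchar(s),
                           evidence = unit,
                           role = sprintf("period=%d;copies=%d",
                                          spec$period, spec$copies)),
         fid = fid, nest_in = NA)
  })
}

# Footprint blocks.  Pattern B returns two blocks (donor + acceptor);
# pattern E is built by the region assembler (needs a source gene).
build_footprint_blocks <- function(spec, config, fid) {
  gc <- config$gc_fraction
  with_seed(derive_seed(config$seed, fid), {
    rnd <- function(n) chars_seq(random_dna_chars(n, gc))
    switch(spec$pattern,
      A_tsd_capture = {
        tsd <- rnd(spec$tsd_length)
        te <- rnd(spec$te_length)
        gene <- rnd(spec$gene_length)
        s <- paste0(tsd, te, gene, tsd)
        o <- nchar(tsd)
        tr <- bind_truth(
          truth_row(fid, "footprint", 1L, nchar(s), evidence = tsd,
                    pattern = "A_tsd_capture"),
          truth_row(paste0(fid, ".te"), "dna_te", o + 1L, o + nchar(te),
                    family = "TE_UNK", class = "Unclassified", parent = fid),
          truth_row(paste0(fid, ".gene"), "gene", o + nchar(te) + 1L,
                    o + nchar(te) + nchar(gene), parent = fid),
          truth_row(paste0(fid, ".gene.exon1"), "part", o + nchar(te) + 1L,
                    o + nchar(te) + nchar(gene),
                    parent = paste0(fid, ".gene"), role = "exon"))
        list(list(seq = s, truth = tr, fid = fid, nest_in = NA))
      },
      B_shared_border = {
        motif <- rnd(spec$border_length)
        gene <- rnd(spec$gene_length)
        donor <- paste0(gene, motif)
        acceptor <- paste0(gene, motif)
        mk <- function(tag, s, pat) {
          gid <- paste0(fid, ".", tag)
          bind_truth(
            truth_row(gid, "gene", 1L, nchar(gene),
                      parent = if (tag == "acceptor") paste0(fid, ".donor") else NA_character_),
            truth_row(paste0(gid, ".exon1"), "part", 1L, nchar(gene),
                      parent = gid, role = "exon"),
            if (!is.null(pat))
              truth_row(fid, "footprint", 1L, nchar(s), evidence = motif,
                        pattern = "B_shared_border",
                        parent = paste0(fid, ".donor")))
        }
        list(list(seq = donor, truth = mk("donor", donor, NULL),
                  fid = paste0(fid, ".donorblock"), nest_in = NA),
             list(seq = acceptor, truth = mk("acceptor", acceptor, TRUE),
                  fid = paste0(fid, ".acceptorblock"), nest_in = NA))
      },
      C_helitron_capture = {
        h5 <- rnd(300); h3 <- rnd(300)
        gene <- rnd(spec$gene_length)
        s <- paste0(h5, gene, h3)
        tr <- bind_truth(
          truth_row(fid, "footprint", 1L, nchar(s), pattern = "C_helitron_capture"),
          truth_row(paste0(fid, ".helitron"), "dna_te", 1L, nchar(s),
                    family = "HELITRON_SIM", class = "Helitron", parent = fid),
          truth_row(paste0(fid, ".gene"), "gene", nchar(h5) + 1L,
                    nchar(h5) + nchar(gene), parent = fid),
          truth_row(paste0(fid, ".gene.exon1"), "part", nchar(h5) + 1L,
                    nchar(h5) + nchar(gene), parent = paste0(fid, ".gene"),
                    role = "exon"))
        list(list(seq = s, truth = tr, fid = fid, nest_in = NA))
      },
      D_tandem_flank = {
        unitL <- rnd(spec$period); unitR <- rnd(spec$period)
        aL <- strrep(unitL, spec$copies); aR <- strrep(unitR, spec$copies)
        gene <- rnd(spec$gene_length)
        s <- paste0(aL, gene, aR)
        gs <- nchar(aL) + 1L; ge <- nchar(aL) + nchar(gene)
        tr <- bind_truth(
          truth_row(fid, "footprint", 1L, nchar(s),
                    evidence = paste(unitL, unitR, sep = "|"),
                    pattern = "D_tandem_flank"),
          truth_row(paste0(fid, ".arrL"), "tandem_array", 1L, nchar(aL),
                    evidence = unitL, parent = fid,
                    role = sprintf("period=%d;copies=%d", spec$period, spec$copies)),
          truth_row(paste0(fid, ".gene"), "gene", gs, ge, parent = fid),
          truth_row(paste0(fid, ".gene.exon1"), "part", gs, ge,
                    parent = paste0(fid, ".gene"), role = "exon"),
          truth_row(paste0(fid, ".arrR"), "tandem_array", ge + 1L, nchar(s),
                    evidence = unitR, parent = fid,
                    role = sprintf("period=%d;copies=%d", spec$period, spec$copies)))
        list(list(seq = s, truth = tr, fid = fid, nest_in = NA))
      },
      stopf("unknown footprint pattern '%s'", spec$pattern))
  })
}

build_retrocopy_block <- function(spec, config, fid, exon_seqs, source_id) {
  s <- paste0(exon_seqs, collapse = "")
  gid <- paste0(fid, ".gene")
  tr <- bind_truth(
    truth_row(fid, "footprint", 1L, nchar(s), pattern = "E_retrocopy",
              parent = source_id),
    truth_row(gid, "gene", 1L, nchar(s), parent = source_id),
    truth_row(paste0(gid, ".exon1"), "part", 1L, nchar(s), parent = gid,
              role = "exon"))
  list(seq = s, truth = tr, fid = fid, nest_in = NA)
}

#' Plant one LTR element into a sequence
#'
#' Constructs an element of the requested family, age and fate (mutating
#' each LTR copy independently under the K2P process so that expected
#' pairwise LTR divergence is `2 * rate * age`), flanks it with a
#' target-site duplication where the fate retains one, and splices it into
#' the sequence.
#'
#' @param sequence character scalar of A/C/G/T.
#' @param spec a [plant_spec()].
#' @param config a [sim_config()] (supplies library, rate, kappa, seed).
#' @return list with `sequence` (the new sequence) and `truth` (truth rows
#'   in the coordinates of the new sequence).
#' @export
plant_element <- function(sequence, spec, config) {
  if (!is.na(spec$nest_in))
    stopf("nest_in is only resolved by simulate_region()")
  blk <- build_element_block(spec, config, "E001")
  insert_block(sequence, blk, spec$position, config, "E001")
}

#' Plant one gene-movement footprint into a sequence
#'
#' @param sequence character scalar.
#' @param pattern one of the five footprint patterns (see
#'   [footprint_spec()]).
#' @param params a [footprint_spec()] or argument list for one; pattern E
#'   additionally requires `exon_seqs`, the donor gene's exon sequences.
#' @param config a [sim_config()].
#' @return list with `sequence` and `truth`.
#' @export
plant_footprint <- function(sequence, pattern, params = list(), config) {
  if (!pattern %in% FOOTPRINT_PATTERNS)
    stopf("unknown footprint pattern '%s'", pattern)
  exon_seqs <- params$exon_seqs
  params$exon_seqs <- NULL
  spec <- if (inherits(params, "footprint_spec")) params
          else do.call(footprint_spec, c(list(pattern = pattern), params))
  if (pattern == "E_retrocopy") {
    if (is.null(exon_seqs))
      stopf("pattern E needs exon_seqs (the donor gene's exons)")
    blocks <- list(build_retrocopy_block(spec, config, "F001", exon_seqs,
                                         spec$source_gene %||% NA_character_))
  } else {
    blocks <- build_footprint_blocks(spec, config, "F001")
  }
  out <- list(sequence = sequence, truth = empty_truth())
  for (i in seq_along(blocks)) {
    res <- insert_block(out$sequence, blocks[[i]], spec$position, config,
                        paste0("F001.", i))
    out$sequence <- res$sequence
    out$truth <- bind_truth(out$truth, res$truth)
  }
  out
}

# splice one block into `sequence` at `position` ("random" or 1-based
# offset meaning: block begins before the base currently at `position`)
insert_block <- function(sequence, blk, position, config, stream_key) {
  n <- nchar(sequence)
  pos <- if (identical(position, "random"))
    with_seed(derive_seed(config$seed, paste0(stream_key, ":pos")),
              sample(seq(1000L, max(1001L, n - 1000L)), 1L))
  else as.integer(position)
  if (pos < 1L || pos > n + 1L) stopf("position %d outside sequence", pos)
  newseq <- paste0(substr(sequence, 1L, pos - 1L), blk$seq,
                   substr(sequence, pos, n))
  tr <- blk$truth
  tr$start <- as.integer(tr$start + pos - 1L)
  tr$end <- as.integer(tr$end + pos - 1L)
  list(sequence = newseq, truth = tr)
}
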