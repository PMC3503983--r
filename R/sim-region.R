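# Region assembly: anchors every planted block at a background offset,
# splices blocks in from left to right, annotates genes over background
# intervals, and returns the final sequence with a truth table in final
# coordinates.

GENE_EXONS  <- c(300L, 240L, 300L)
GENE_INTRONS <- c(150L, 120L)

gene_length_bp <- function() sum(GENE_EXONS) + sum(GENE_INTRONS)

#' Simulate a synthetic region with planted ground truth
#'
#' Generates the background, builds every configured feature block
#' (elements, DNA transposons, tandem arrays, footprints), resolves
#' nesting, lays out genes and insertion anchors with a minimum gap, and
#' assembles the final sequence.  Identical configurations produce
#' byte-identical sequences and truth tables.
#'
#' @param config a [sim_config()].
#' @return a `sim_region`: list with `region_id`, `sequence`, `length`,
#'   `truth` (data frame), `library` and `config`.
#' @export
simulate_region <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lib <- config$library
  bg <- make_background(config$region_length, config$gc_fraction,
                        derive_seed(config$seed, "background"))
  n_bg <- nchar(bg)

  blocks <- list()
  for (i in seq_along(config$elements)) {
    fid <- sprintf("E%03d", i)
    blocks[[length(blocks) + 1L]] <-
      c(build_element_block(config$elements[[i]], config, fid, fam_idx = i),
        list(position = config$elements[[i]]$position))
  }
  for (i in seq_along(config$dna_tes)) {
    fid <- sprintf("D%03d", i)
    blocks[[length(blocks) + 1L]] <-
      c(build_dna_block(config$dna_tes[[i]], config, fid, idx = i),
        list(position = config$dna_tes[[i]]$position))
  }
  for (i in seq_along(config$tandems)) {
    fid <- sprintf("T%03d", i)
    blocks[[length(blocks) + 1L]] <-
      c(build_tandem_block(config$tandems[[i]], config, fid),
        list(position = config$tandems[[i]]$position))
  }
  retro_specs <- list()
  for (i in seq_along(config$footprints)) {
    sp <- config$footprints[[i]]
    fid <- sprintf("F%03d", i)
    if (sp$pattern == "E_retrocopy") {
      retro_specs[[length(retro_specs) + 1L]] <- list(spec = sp, fid = fid)
      next
    }
    for (b in build_footprint_blocks(sp, config, fid))
      blocks[[length(blocks) + 1L]] <- c(b, list(position = sp$position))
  }

  # resolve nesting: splice guests into their hosts before layout
  fids <- vapply(blocks, function(b) b$fid, character(1))
  nested <- which(vapply(blocks, function(b) !is.na(b$nest_in), logical(1)))
  for (gi in nested) {
    guest <- blocks[[gi]]
    hi <- match(guest$nest_in, fids)
    if (is.na(hi)) stopf("nest_in target '%s' not found", guest$nest_in)
    blocks[[hi]] <- nest_guest(blocks[[hi]], guest, config)
  }
  if (length(nested)) {
    blocks <- blocks[-nested]
    fids <- fids[-nested]
  }

  # gene layout over the background, then anchors for all blocks
  lay_seed <- derive_seed(config$seed, "layout")
  occupied <- list()
  glen <- gene_length_bp()
  genes <- list()
  with_seed(lay_seed, {
    place <- function(width) {
      for (try in 1:2000) {
        a <- sample(seq(1000L, max(1001L, n_bg - width - 1000L)), 1L)
        ok <- TRUE
        for (iv in occupied)
          if (interval_overlap(a - config$min_gap, a + width + config$min_gap,
                               iv[1], iv[2]) > 0) { ok <- FALSE; break }
        if (ok) return(a)
      }
      stopf("region too crowded: cannot place a feature of width %d", width)
    }
    for (g in seq_len(config$n_genes)) {
      a <- place(glen)
      occupied[[length(occupied) + 1L]] <- c(a, a + glen - 1L)
      genes[[length(genes) + 1L]] <- a
    }
    for (bi in seq_along(blocks)) {
      pos <- blocks[[bi]]$position
      a <- if (identical(pos, "random")) place(0L) else as.integer(pos)
      occupied[[length(occupied) + 1L]] <- c(a, a)
      blocks[[bi]]$anchor <- a
    }
    for (ri in seq_along(retro_specs)) {
      a <- place(0L)
      occupied[[length(occupied) + 1L]] <- c(a, a)
      retro_specs[[ri]]$anchor <- a
    }
  })

  # gene truth (background coordinates) and exon sequences
  gene_truth <- empty_truth()
  gene_exons <- list()
  for (g in seq_along(genes)) {
    gid <- sprintf("G%03d", g)
    a <- genes[[g]]
    widths <- as.integer(rbind(GENE_EXONS, c(GENE_INTRONS, 0L)))[1:5]
    ends <- a - 1L + cumsum(widths)
    starts <- ends - widths + 1L
    exon_iv <- cbind(starts[c(1, 3, 5)], ends[c(1, 3, 5)])
    gene_truth <- bind_truth(
      gene_truth,
      truth_row(gid, "gene", a, a + glen - 1L),
      do.call(bind_truth, lapply(1:3, function(e)
        truth_row(sprintf("%s.exon%d", gid, e), "part",
                  exon_iv[e, 1], exon_iv[e, 2], parent = gid, role = "exon"))))
    gene_exons[[gid]] <- vapply(1:3, function(e)
      substr(bg, exon_iv[e, 1], exon_iv[e, 2]), character(1))
  }

  # retrocopy blocks need their source gene's exon sequences
  for (rs in retro_specs) {
    src <- rs$spec$source_gene
    if (is.na(src)) src <- names(gene_exons)[1] %||%
        stopf("pattern E needs a planted multi-exon gene")
    if (is.null(gene_exons[[src]])) stopf("source gene '%s' not found", src)
    blk <- build_retrocopy_block(rs$spec, config, rs$fid,
                                 gene_exons[[src]], src)
    blk$anchor <- rs$anchor
    blocks[[length(blocks) + 1L]] <- blk
  }

  # assemble: splice blocks at their anchors, left to right
  if (length(blocks)) {
    ord <- order(vapply(blocks, function(b) b$anchor, numeric(1)))
    blocks <- blocks[ord]
    anchors <- vapply(blocks, function(b) b$anchor, numeric(1))
    lens <- vapply(blocks, function(b) nchar(b$seq), numeric(1))
    shift_before <- cumsum(c(0, lens))[seq_along(lens)]
    pieces <- character(0)
    prev <- 1L
    truth <- empty_truth()
    for (j in seq_along(blocks)) {
      pieces <- c(pieces, substr(bg, prev, anchors[j] - 1L), blocks[[j]]$seq)
      prev <- anchors[j]
      tr <- blocks[[j]]$truth
      off <- anchors[j] + shift_before[j] - 1L
      tr$start <- tr$start + off
      tr$end <- tr$end + off
      truth <- bind_truth(truth, tr)
    }
    pieces <- c(pieces, substr(bg, prev, n_bg))
    sequence <- paste0(pieces, collapse = "")
    bg_shift <- function(x)
      x + vapply(x, function(xi) sum(lens[anchors <= xi]), numeric(1))
  } else {
    sequence <- bg
    truth <- empty_truth()
    bg_shift <- identity
  }
  if (nrow(gene_truth)) {
    gene_truth$start <- as.integer(bg_shift(gene_truth$start))
    gene_truth$end <- as.integer(bg_shift(gene_truth$end))
    truth <- bind_truth(truth, gene_truth)
  }
  truth$start <- as.integer(truth$start)
  truth$end <- as.integer(truth$end)
  truth <- truth[order(truth$start, truth$end, truth$feature_id), ]
  rownames(truth) <- NULL
  stopifnot(all(truth$start >= 1), all(truth$end <= nchar(sequence)))

  structure(list(region_id = config$region_id, sequence = sequence,
                 length = nchar(sequence), truth = truth, library = lib,
                 config = config),
            class = "sim_region")
}

# splice a guest element block into its host's internal region
nest_guest <- function(host, guest, config) {
  internal <- host$truth[host$truth$kind == "part" &
                           host$truth$role %in% c("internal", "partial_internal"), ]
  span <- if (nrow(internal)) c(min(internal$start) + 10L, max(internal$end) - 10L)
          else {
            el <- host$truth[host$truth$kind == "ltr_element", ]
            c(el$start + 10L, el$end - 10L)
          }
  off <- with_seed(derive_seed(config$seed, paste0(guest$fid, ":nest")),
                   sample(span[1]:span[2], 1L))
  L <- nchar(guest$seq)
  tr <- host$truth
  grow <- tr$start < off & tr$end >= off
  shift <- tr$start >= off
  tr$end[grow] <- tr$end[grow] + L
  tr$start[shift] <- tr$start[shift] + L
  tr$end[shift] <- tr$end[shift] + L
  gt <- guest$truth
  gt$start <- gt$start + off - 1L
  gt$end <- gt$end + off - 1L
  gt$parent[gt$kind == "ltr_element"] <- host$fid
  host$seq <- paste0(substr(host$seq, 1L, off - 1L), guest$seq,
                     substr(host$seq, off, nchar(host$seq)))
  host$truth <- bind_truth(tr, gt)
  host
}

#' @export
print.sim_region <- function(x, ...) {
  cat(sprintf("<sim_region> %s: %d bp, %d truth records\n",
              x$region_id, x$length, nrow(x$truth)))
  print(table(x$truth$kind))
  invisible(x)
}

# ---- truth emission and round trip ----------------------------------------

GFF_TYPE <- c(gene = "gene", ltr_element = "LTR_retrotransposon",
              dna_te = "DNA_transposon", tandem_array = "tandem_repeat",
              footprint = "gene_movement_footprint")
ROLE_TYPE <- c(five_prime_LTR = "long_terminal_repeat",
               three_prime_LTR = "long_terminal_repeat",
               LTR = "long_terminal_repeat",
               partial_LTR = "long_terminal_repeat",
               internal = "TE_internal", partial_internal = "TE_internal",
               exon = "exon")

truth_to_granges <- function(truth, region_id) {
  type <- ifelse(truth$kind == "part", unname(ROLE_TYPE[truth$role]),
                 unname(GFF_TYPE[truth$kind]))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(region_id, nrow(truth)),
    ranges = IRanges::IRanges(start = truth$start, end = truth$end),
    strand = truth$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = rep("ltrfate", nrow(truth)), type = type,
    ID = truth$feature_id,
    Parent = truth$parent, family = truth$family, class = truth$class,
    fate = truth$fate, age_years = truth$age_years,
    tsd = ifelse(truth$kind == "ltr_element", truth$evidence, NA_character_),
    evidence = truth$evidence, pattern = truth$pattern, role = truth$role)
  gr
}

#' Write a simulated region to disk
#'
#' Emits the sequence as wrapped FASTA, the features as GFF3 (1-based
#' inclusive, with `ID`, `family`, `fate`, `age_years`, `tsd` and `pattern`
#' attributes), the repeat library FASTA, and a tab-separated truth sidecar
#' whose read-back ([read_region()]) reproduces every record exactly.
#'
#' @param region a `sim_region`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
emit_truth <- function(region, dir) {
  stopifnot(inherits(region, "sim_region"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(region$region_id, ".fa")),
             gff3 = file.path(dir, paste0(region$region_id, ".gff3")),
             truth = file.path(dir, "truth.tsv"),
             library = file.path(dir, "library.fa"))
  ss <- Biostrings::DNAStringSet(region$sequence)
  names(ss) <- region$region_id
  Biostrings::writeXStringSet(ss, paths["fasta"], width = 60)
  if (nrow(region$truth)) {
    gr <- truth_to_granges(region$truth, region$region_id)
    rtracklayer::export(gr, paths["gff3"], format = "gff3")
  } else {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", region$region_id,
                         region$length)),
               paths["gff3"])
  }
  write.table(region$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  write_repeat_library(region$library, paths["library"])
  invisible(paths)
}

#' @rdname emit_truth
#' @export
read_region <- function(dir) {
  fa <- list.files(dir, pattern = "\\.fa$", full.names = TRUE)
  fa <- setdiff(fa, file.path(dir, "library.fa"))
  if (length(fa) != 1L) stopf("expected one region FASTA in %s", dir)
  ss <- Biostrings::readDNAStringSet(fa)
  truth <- read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE,
                      colClasses = c(rep("character", 2), rep("integer", 2),
                                     rep("character", 4), "numeric",
                                     rep("character", 4)))
  lib <- read_repeat_library(file.path(dir, "library.fa"))
  structure(list(region_id = names(ss)[1], sequence = as.character(ss[[1]]),
                 length = nchar(as.character(ss[[1]])), truth = truth,
                 library = lib, config = NULL),
            class = "sim_region")
}
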