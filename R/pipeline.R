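# One-call pipeline: annotate -> classify -> date -> summarize ->
# scan-movement, with a resolved-configuration manifest so a rerun with the
# same config is byte-identical.

PIPELINE_KEYS <- c("fasta", "library", "genes_gff3", "out_dir", "seed",
                   "region_id", "pair_params", "match_params",
                   "fate_params", "rate", "movement_params")

#' Build a pipeline configuration
#'
#' @param fasta path to the region FASTA.
#' @param library path to the repeat-library FASTA.
#' @param out_dir output directory.
#' @param genes_gff3 optional path to a gene GFF3.
#' @param seed integer seed recorded in the manifest.
#' @param region_id region name (defaults to the FASTA record name).
#' @param pair_params,match_params,fate_params,movement_params named lists
#'   overriding stage defaults.
#' @param rate substitution rate for dating.
#' @return a `pipeline_config` list; unknown keys are rejected.
#' @export
pipeline_config <- function(fasta, library, out_dir, genes_gff3 = NULL,
                            seed = 1, region_id = NULL,
                            pair_params = list(), match_params = list(),
                            fate_params = list(), rate = 1.3e-8,
                            movement_params = list()) {
  cfg <- list(fasta = fasta, library = library, genes_gff3 = genes_gff3,
              out_dir = out_dir, seed = as.integer(seed),
              region_id = region_id, pair_params = pair_params,
              match_params = match_params, fate_params = fate_params,
              rate = rate, movement_params = movement_params)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), PIPELINE_KEYS)
  if (length(unknown))
    stopf("unknown pipeline config key(s): %s",
          paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

read_gene_annotations <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  is_gene <- mc$type == "gene"
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    sprintf("gene%03d", seq_along(gr))
  genes <- data.frame(feature_id = ids[is_gene],
                      start = GenomicRanges::start(gr)[is_gene],
                      end = GenomicRanges::end(gr)[is_gene],
                      stringsAsFactors = FALSE)
  is_exon <- mc$type == "exon"
  parent <- if ("Parent" %in% names(mc))
    vapply(mc$Parent, function(p) if (length(p)) as.character(p)[1]
           else NA_character_, character(1))
  else rep(NA_character_, length(gr))
  exons <- data.frame(parent = parent[is_exon],
                      start = GenomicRanges::start(gr)[is_exon],
                      end = GenomicRanges::end(gr)[is_exon],
                      stringsAsFactors = FALSE)
  genes$n_exons <- vapply(genes$feature_id, function(id)
    sum(exons$parent == id), integer(1))
  genes$exon_bp <- vapply(genes$feature_id, function(id) {
    e <- exons[exons$parent %in% id, ]
    as.integer(sum(e$end - e$start + 1L))
  }, integer(1))
  genes
}

#' Run the full analysis pipeline on one region
#'
#' Stages: structural annotation (LTR pairs + library matching), fate
#' classification with mechanisms and tendency, insertion dating,
#' composition/profile summary, and movement-footprint scanning.  All
#' outputs are TSV/GFF3 under `out_dir`, plus `manifest.yaml` recording
#' every resolved parameter and the md5 checksum of every output; rerunning
#' the same configuration reproduces the bundle byte for byte.
#'
#' @param config a [pipeline_config()] (or path to its YAML).
#' @return invisibly, a named list of result data frames and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$fasta, config$library, config$genes_gff3))
    if (!file.exists(f)) stopf("input file not found: %s", f)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ss <- Biostrings::readDNAStringSet(config$fasta)
  sequence <- as.character(ss[[1]])
  region_id <- config$region_id %||% sub(" .*", "", names(ss)[1])
  library <- read_repeat_library(config$library)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  elements <- stage("annotate",
    annotate_region(sequence, library, pair_params = config$pair_params,
                    match_params = config$match_params))
  fates <- stage("classify",
    classify_fates(elements, library, sequence,
                   params = do.call(fate_params, config$fate_params)))
  tendency <- if (length(elements))
    stage("classify", region_tendency(elements, fates, library)) else NULL
  dates <- stage("date", date_elements(elements, sequence, r = config$rate))

  genes <- if (!is.null(config$genes_gff3))
    stage("genes", read_gene_annotations(config$genes_gff3))
  else data.frame(feature_id = character(0), start = integer(0),
                  end = integer(0), n_exons = integer(0),
                  exon_bp = integer(0))

  eldf <- as.data.frame(elements)
  te_ann <- data.frame(start = eldf$start, end = eldf$end,
                       family = eldf$family, class = eldf$class,
                       feature_id = eldf$element_id,
                       intact = fates$category %in% "IntactLTR",
                       stringsAsFactors = FALSE)
  comp <- stage("summarize",
    composition_table(te_ann, nchar(sequence), region_id))
  gyp <- comp$rows$percent[comp$rows$class == "Ty3/Gypsy"]
  cop <- comp$rows$percent[comp$rows$class == "Ty1/Copia"]
  profile <- region_profile(if (length(gyp)) gyp else 0,
                            if (length(cop)) cop else 0,
                            gene_density(nchar(sequence), nrow(genes)))
  mp <- config$movement_params
  tp <- list(min_period = mp$min_period %||% 2,
             max_period = mp$max_period %||% 10,
             min_copies = mp$min_copies %||% 5,
             max_mismatch_frac = mp$max_mismatch_frac %||% 0)
  arrays <- stage("scan-movement",
    do.call(find_tandem_arrays, c(list(sequence = sequence), tp)))
  footprints <- stage("scan-movement", rbind(
    scan_tsd_capture(sequence, te_ann, genes,
                     min_tsd = mp$min_tsd %||% 8,
                     max_gap = mp$max_gap %||% 2000),
    scan_helitron_capture(te_ann, genes),
    scan_tandem_flank(genes, arrays, window = mp$window %||% 500)))

  paths <- c(elements = "elements.tsv", fates = "fates.tsv",
             dates = "dates.tsv", composition = "composition.tsv",
             footprints = "footprints.tsv")
  paths <- vapply(paths, function(p) file.path(config$out_dir, p),
                  character(1))
  wr <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE, na = "NA")
  wr(eldf, paths["elements"])
  fates_out <- fates
  fates_out$label <- fate_labels()[fates_out$category]
  wr(fates_out, paths["fates"])
  wr(dates, paths["dates"])
  comp_out <- comp$rows
  comp_out$percent <- round(comp_out$percent, 2)
  wr(comp_out, paths["composition"])
  wr(footprints, paths["footprints"])

  manifest <- list(
    package = "ltrfate",
    version = as.character(utils::packageVersion("ltrfate")),
    region_id = region_id, region_length = nchar(sequence),
    seed = config$seed, rate = config$rate,
    parameters = list(pair = config$pair_params, match = config$match_params,
                      fate = config$fate_params,
                      movement = config$movement_params),
    tendency = if (!is.null(tendency))
      tendency[c("tendency", "bp_inserted", "bp_removed_inferred")] else NULL,
    profile = unclass(profile),
    gene_count = nrow(genes),
    checksums = as.list(setNames(unname(tools::md5sum(unname(paths))),
                                 basename(unname(paths)))))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(elements = elements, fates = fates, dates = dates,
                 composition = comp, profile = profile, arrays = arrays,
                 footprints = footprints, tendency = tendency,
                 paths = c(paths, manifest = file.path(config$out_dir,
                                                       "manifest.yaml"))))
}
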