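# Region profiling: TE composition tables, gene density, Gypsy/Copia
# balance and a descriptive chromatin indicator.

te_class_group <- function(class) {
  ifelse(class %in% RNA_CLASSES, "I",
         ifelse(class %in% DNA_CLASSES, "II", NA_character_))
}

#' TE composition table for a region
#'
#' Computes per-class masked base pairs and percent of region length.
#' Overlapping/nested TE intervals are flattened by attributing every base
#' to the innermost (shortest enclosing, i.e. most recently inserted)
#' element, so class totals are conserved and no base is counted twice.
#' Intact-element subsets are reported separately and never added into the
#' class totals.
#'
#' @param annotations data frame with columns `start`, `end`, `class` and
#'   optionally `intact` (logical) and `family`.
#' @param region_length region length in bp.
#' @param region_id label for printing.
#' @return a `composition_table`: list with `rows` (per-class `masked_bp`
#'   and `percent`), `class_totals` (Class I / Class II), `intact`
#'   (informational subsets) and `region_length`.
#' @export
composition_table <- function(annotations, region_length,
                              region_id = "region") {
  stopifnot(is.data.frame(annotations), region_length >= 1)
  if (nrow(annotations)) {
    if (any(annotations$start < 1 | annotations$end > region_length |
              annotations$start > annotations$end))
      stopf("annotation interval outside [1, %d]", region_length)
  }
  owner <- integer(region_length) # 0 = unmasked
  if (nrow(annotations)) {
    widths <- annotations$end - annotations$start + 1L
    for (i in order(-widths)) # paint widest first; innermost overwrites
      owner[annotations$start[i]:annotations$end[i]] <- i
  }
  bp_of <- function(idx) {
    if (!length(idx)) 0L else sum(tabulate(owner, nbins = max(1L, nrow(annotations)))[idx])
  }
  cls <- unique(annotations$class)
  rows <- data.frame(
    class = cls,
    group = te_class_group(cls),
    masked_bp = vapply(cls, function(cc) bp_of(which(annotations$class == cc)),
                       numeric(1)),
    stringsAsFactors = FALSE)
  rows$percent <- 100 * rows$masked_bp / region_length
  rows <- rows[order(rows$group, rows$class), , drop = FALSE]
  totals <- data.frame(group = c("I", "II"))
  totals$masked_bp <- vapply(totals$group, function(g)
    sum(rows$masked_bp[!is.na(rows$group) & rows$group == g]), numeric(1))
  totals$percent <- 100 * totals$masked_bp / region_length
  intact <- if ("intact" %in% names(annotations)) {
    grp <- te_class_group(annotations$class)
    sub <- c(`Intact LTR` = "I_LTR", `Intact DNA TE` = "II")
    idx_ltr <- which(annotations$intact %in% TRUE &
                       annotations$class %in% LTR_CLASSES)
    idx_dna <- which(annotations$intact %in% TRUE & grp %in% "II")
    data.frame(subset = c("Intact LTR", "Intact DNA TE"),
               masked_bp = c(bp_of(idx_ltr), bp_of(idx_dna)),
               stringsAsFactors = FALSE)
  } else data.frame(subset = character(0), masked_bp = numeric(0))
  if (nrow(intact)) intact$percent <- 100 * intact$masked_bp / region_length
  structure(list(region_id = region_id, region_length = region_length,
                 rows = rows, class_totals = totals, intact = intact),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %s (%d bp)\n", x$region_id,
              x$region_length))
  r <- x$rows
  r$percent <- round(r$percent, 2) # report layer; internals stay in bp
  print(r, row.names = FALSE)
  t <- x$class_totals
  t$percent <- round(t$percent, 2)
  print(t, row.names = FALSE)
  invisible(x)
}

#' Convert a simulated truth table to TE composition annotations
#'
#' @param truth truth data frame from [simulate_region()].
#' @return data frame suitable for [composition_table()].
#' @export
truth_to_te_annotations <- function(truth) {
  te <- truth[truth$kind %in% c("ltr_element", "dna_te"), , drop = FALSE]
  data.frame(start = te$start, end = te$end, family = te$family,
             class = te$class,
             intact = (te$kind == "ltr_element" & te$fate %in% "IntactLTR") |
               te$kind == "dna_te",
             stringsAsFactors = FALSE)
}

#' Gene density of a region
#'
#' @param region_length region length in bp.
#' @param n_genes number of annotated gene models (pseudogenes included).
#' @return kb per gene (`region_length/1000/n_genes`); `NA` when
#'   `n_genes` is zero.
#' @export
gene_density <- function(region_length, n_genes) {
  if (!is_scalar_number(region_length) || region_length < 0 ||
      !is_count(n_genes))
    stopf("region_length and n_genes must be non-negative")
  if (n_genes == 0L) return(NA_real_)
  region_length / 1000 / n_genes
}

#' Region profile: gene density and Gypsy/Copia balance
#'
#' @param gypsy_percent,copia_percent percent of region masked by Ty3/Gypsy
#'   and Ty1/Copia elements.
#' @param gene_density kb per gene (see [gene_density()]).
#' @return a `region_profile` list.
#' @export
region_profile <- function(gypsy_percent, copia_percent, gene_density) {
  structure(list(gypsy_percent = gypsy_percent,
                 copia_percent = copia_percent,
                 gene_density = gene_density),
            class = "region_profile")
}

#' Descriptive chromatin indicator for a region
#'
#' Low gene density together with a high Gypsy:Copia ratio characterises
#' heterochromatic regions (Gypsy elements prefer heterochromatin, Copia
#' elements euchromatin); the reverse pattern is euchromatin-like.  Purely
#' descriptive -- no cytological claim.
#'
#' @param profile a [region_profile()].
#' @param density_threshold gene density (kb/gene) above which a region
#'   counts as gene-poor.
#' @param ratio_threshold Gypsy:Copia percent ratio above which the region
#'   counts as Gypsy-dominated.
#' @param eps floor for the denominator percent.
#' @return `"heterochromatin-like"`, `"euchromatin-like"` or
#'   `"indeterminate"`.
#' @export
chromatin_indicator <- function(profile, density_threshold = 20,
                                ratio_threshold = 2, eps = 0.01) {
  g <- profile$gypsy_percent
  c_ <- profile$copia_percent
  d <- profile$gene_density
  if (is.na(d)) return("indeterminate")
  if (g / max(c_, eps) >= ratio_threshold && d >= density_threshold)
    return("heterochromatin-like")
  if (c_ / max(g, eps) >= ratio_threshold && d < density_threshold)
    return("euchromatin-like")
  "indeterminate"
}

#' Published TE composition of the Ghd7 orthologous regions
#'
#' Percent-of-region-length TE composition across thirteen grass
#' genomes/accessions (ten Oryza, Brachypodium distachyon, Sorghum bicolor,
#' Zea mays) for the Ghd7 orthologous regions, as published.  Component
#' rows sum to the class totals at the report layer; intact-element rows
#' are informational subsets, not included in the totals.
#'
#' @return data frame: `label`, `group` ("I"/"II"), `type` ("component",
#'   "intact", "total") and one numeric column per genome.
#' @export
ghd7_reference_composition <- function() {
  path <- system.file("extdata", "ghd7_te_composition.tsv",
                      package = "ltrfate", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Class total from component percent rows
#'
#' Report-layer arithmetic: the class total is the sum of its component
#' subfamily percentages (intact subsets excluded), rounded to two
#' decimals.
#'
#' @param tbl data frame in the layout of [ghd7_reference_composition()].
#' @param group `"I"` or `"II"`.
#' @param column genome column name.
#' @return numeric scalar.
#' @export
class_total_percent <- function(tbl, group, column) {
  comp <- tbl[tbl$group == group & tbl$type == "component", column]
  round(sum(comp), 2)
}
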