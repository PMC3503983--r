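# Repeat "library": one row per consensus sequence.  LTR-retrotransposon
# families contribute two rows (role "LTR" and role "internal"); DNA
# transposon families one row (role "DNA").  Class labels follow the usual
# plant-repeat vocabulary (Ty1/Copia, Ty3/Gypsy, LINE, SINE, MITE/Tourist,
# MITE/Stowaway, hAT, En-Spm, MuDR, Helitron, Unclassified).

LTR_CLASSES <- c("Ty1/Copia", "Ty3/Gypsy")
DNA_CLASSES <- c("MITE/Tourist", "MITE/Stowaway", "hAT", "En-Spm", "MuDR",
                 "Helitron", "Unclassified")
RNA_CLASSES <- c("Ty1/Copia", "Ty3/Gypsy", "LINE", "SINE", "Unclassified-RNA")

#' Build a repeat library of random family consensi
#'
#' Generates per-family LTR and internal-region consensus sequences (plus
#' optional DNA-transposon consensi) deterministically from a seed.  The
#' simulator plants elements as mutated copies of these consensi, and the
#' annotator uses the same library for homology matching, which is exactly
#' the role a curated repeat library plays on real data.
#'
#' @param n_ltr_families number of LTR-retrotransposon families.
#' @param ltr_length,internal_length consensus LTR and internal lengths (bp).
#' @param n_dna_families number of DNA-transposon families.
#' @param dna_length DNA-transposon consensus length (bp).
#' @param gc_fraction consensus G+C proportion.
#' @param seed integer seed; identical inputs give byte-identical libraries.
#' @return a `repeat_library`: data frame with columns `family`, `class`,
#'   `role` and `sequence`.
#' @export
make_repeat_library <- function(n_ltr_families = 8, ltr_length = 1000,
                                internal_length = 5000, n_dna_families = 4,
                                dna_length = 1500, gc_fraction = 0.43,
                                seed = 1) {
  if (!is_count(n_ltr_families) || n_ltr_families < 1)
    stopf("need at least one LTR family")
  rows <- list()
  for (i in seq_len(n_ltr_families)) {
    fam <- sprintf("RLX%02d", i)
    cls <- LTR_CLASSES[(i - 1) %% 2 + 1]
    ltr <- with_seed(derive_seed(seed, paste0(fam, ":ltr")),
                     chars_seq(random_dna_chars(ltr_length, gc_fraction)))
    int <- with_seed(derive_seed(seed, paste0(fam, ":int")),
                     chars_seq(random_dna_chars(internal_length, gc_fraction)))
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, class = cls, role = c("LTR", "internal"),
      sequence = c(ltr, int), stringsAsFactors = FALSE)
  }
  if (n_dna_families > 0) {
    for (i in seq_len(n_dna_families)) {
      fam <- sprintf("DTX%02d", i)
      cls <- DNA_CLASSES[(i - 1) %% length(DNA_CLASSES) + 1]
      cons <- with_seed(derive_seed(seed, paste0(fam, ":dna")),
                        chars_seq(random_dna_chars(dna_length, gc_fraction)))
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, class = cls, role = "DNA", sequence = cons,
        stringsAsFactors = FALSE)
    }
  }
  lib <- do.call(rbind, rows)
  validate_repeat_library(lib)
}

validate_repeat_library <- function(lib) {
  stopifnot(is.data.frame(lib),
            all(c("family", "class", "role", "sequence") %in% names(lib)))
  if (any(!nzchar(lib$sequence))) stopf("library consensi must be non-empty")
  if (anyDuplicated(lib[, c("family", "role")]))
    stopf("duplicate family/role rows in repeat library")
  class(lib) <- c("repeat_library", "data.frame")
  lib
}

lib_row <- function(lib, family, role) {
  i <- which(lib$family == family & lib$role == role)
  if (length(i) != 1L) return(NULL)
  lib[i, , drop = FALSE]
}

lib_seq <- function(lib, family, role) {
  r <- lib_row(lib, family, role)
  if (is.null(r)) NULL else r$sequence
}

ltr_families <- function(lib) unique(lib$family[lib$role == "LTR"])

# consensus full-length geometry of one family: 2 LTRs + internal
lib_full_length <- function(lib, family) {
  l <- lib_seq(lib, family, "LTR")
  i <- lib_seq(lib, family, "internal")
  if (is.null(l)) return(NA_integer_)
  2L * nchar(l) + if (is.null(i)) 0L else nchar(i)
}

#' Write / read a repeat library as FASTA
#'
#' Family metadata travel in the description line as `key=value` pairs
#' (`family=...; role=LTR|internal|DNA; class=...`).
#'
#' @param lib a `repeat_library`.
#' @param path FASTA file path.
#' @export
write_repeat_library <- function(lib, path) {
  ss <- Biostrings::DNAStringSet(lib$sequence)
  names(ss) <- sprintf("%s#%s family=%s role=%s class=%s",
                       lib$family, lib$role, lib$family, lib$role, lib$class)
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' @rdname write_repeat_library
#' @export
read_repeat_library <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  get_kv <- function(nm, key) {
    m <- regmatches(nm, regexpr(sprintf("%s=[^ ]+", key), nm))
    sub(sprintf("^%s=", key), "", m)
  }
  nm <- names(ss)
  lib <- data.frame(family = get_kv(nm, "family"),
                    class = get_kv(nm, "class"),
                    role = get_kv(nm, "role"),
                    sequence = as.character(ss),
                    stringsAsFactors = FALSE)
  rownames(lib) <- NULL
  validate_repeat_library(lib)
}
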