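#' Amplicon reference panel
#'
#' The assay targets one amplicon per chromosome class: an autosomal locus
#' (copy number 2 in every bird), a Z-linked locus (1 copy in females, 2 in
#' males) and a W-linked locus (at most 1 copy, females only). The W and Z
#' loci form a gametologue pair: the W sequence is the Z sequence diverged by
#' independent per-base substitutions.
#'
#' @param species species preset label (`"booby"` or `"frigatebird"`, or any
#'   free label).
#' @param seed integer seed; panels are byte-identical for a fixed seed.
#' @param divergence per-base substitution probability deriving the W
#'   amplicon from its Z gametologue; must be in `[0, 0.25)`.
#' @param amplicon_length amplicon size in bases (default 550).
#' @return A `reference_panel`: list with `species` and `loci`, a data.frame
#'   with columns `name`, `chrom_class` (AUTOSOMAL/Z/W), `sequence`,
#'   `gametologue_of`.
#' @examples
#' panel <- make_reference("booby", seed = 1, divergence = 0.1)
#' panel$loci[, c("name", "chrom_class")]
#' @export
make_reference <- function(species, seed = 1L, divergence = 0.1,
                           amplicon_length = 550L) {
  if (!is.numeric(divergence) || length(divergence) != 1L ||
      is.na(divergence) || divergence < 0 || divergence >= 0.25) {
    stop("`divergence` must be a single value in [0, 0.25)")
  }
  local_seed(derive_seed(seed, "panel", species), {
    auto <- paste(sample(DNA_BASES, amplicon_length, replace = TRUE),
                  collapse = "")
    z <- paste(sample(DNA_BASES, amplicon_length, replace = TRUE),
               collapse = "")
    w <- mutate_sequence(z, divergence)
    loci <- data.frame(
      name = paste0(c("AUTO_", "Z_", "W_"), species),
      chrom_class = c("AUTOSOMAL", "Z", "W"),
      sequence = c(auto, z, w),
      gametologue_of = c(NA_character_, paste0("W_", species),
                         paste0("Z_", species)),
      stringsAsFactors = FALSE
    )
    structure(list(species = species, loci = loci),
              class = "reference_panel")
  })
}

# Substitute each base independently with probability `rate`, always to a
# different base (a substitution never silently restores the original).
mutate_sequence <- function(seq, rate) {
  if (rate == 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit],
                         function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  }
  paste(bases, collapse = "")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> species=%s, %d loci (%s)\n", x$species,
              nrow(x$loci), paste(x$loci$chrom_class, collapse = "/")))
  invisible(x)
}

panel_locus <- function(panel, chrom_class) {
  i <- which(panel$loci$chrom_class == chrom_class)
  if (length(i) != 1L) stop("panel must contain exactly one ", chrom_class,
                            " locus")
  panel$loci[i, ]
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "reference_panel"))
  if (anyDuplicated(panel$loci$name)) stop("locus names must be unique")
  if (!all(c("AUTOSOMAL", "Z", "W") %in% panel$loci$chrom_class)) {
    stop("panel must contain at least one AUTOSOMAL, one Z and one W locus")
  }
  if (!all(grepl("^[ACGT]+$", panel$loci$sequence))) {
    stop("locus sequences must contain only A/C/G/T")
  }
  invisible(panel)
}

#' Write a reference panel as FASTA
#'
#' @param panel a [make_reference()] panel.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(panel, path) {
  validate_panel(panel)
  x <- Biostrings::DNAStringSet(panel$loci$sequence)
  names(x) <- sprintf("%s class=%s", panel$loci$name, panel$loci$chrom_class)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference panel from FASTA
#'
#' Locus classes are taken from a `class=` comment when present, otherwise
#' inferred from a leading `AUTO`/`Z`/`W` token in the name.
#'
#' @param path FASTA path.
#' @param species species label for the panel.
#' @return A `reference_panel`.
#' @export
read_panel_fasta <- function(path, species = "unknown") {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub(" .*$", "", names(x))
  cls <- ifelse(grepl("class=", names(x)),
                sub("^.*class=([A-Z]+).*$", "\\1", names(x)),
                c(AUTO = "AUTOSOMAL", Z = "Z", W = "W")[
                  sub("_.*$", "", ids)])
  loci <- data.frame(name = ids, chrom_class = unname(cls),
                     sequence = as.character(x),
                     gametologue_of = NA_character_,
                     stringsAsFactors = FALSE)
  panel <- structure(list(species = species, loci = loci),
                     class = "reference_panel")
  validate_panel(panel)
}
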