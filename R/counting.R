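#' Per-locus unique-read counts from a SAM/BAM alignment
#'
#' Counts records that represent unique, confident alignments: primary
#' (neither secondary 0x100 nor supplementary 0x800), mapped, and with
#' MAPQ >= `mapq_min`. Each mate of a pair is counted independently.
#' SAM input is converted through [Rsamtools::asBam()] internally.
#'
#' @param sam_path path to a SAM or BAM file whose reference names match the
#'   panel's locus names.
#' @param panel a [make_reference()] panel (or any `reference_panel`).
#' @param mapq_min minimum mapping quality (default 20); records with
#'   missing MAPQ are excluded.
#' @return named integer vector of counts, one entry per panel locus (zero
#'   where no read passed).
#' @export
counts_from_sam <- function(sam_path, panel, mapq_min = 20L) {
  validate_panel(panel)
  bam <- if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else sam_path
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("rname", "flag",
                                                  "mapq")))[[1]]
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  mapq_ok <- !is.na(res$mapq) & res$mapq >= mapq_min
  keep <- !unmapped & !secondary & !supplementary & mapq_ok
  rnames <- as.character(res$rname)
  seen <- unique(rnames[!is.na(rnames)])
  unknown <- setdiff(seen, panel$loci$name)
  if (length(unknown)) {
    stop("reference name(s) absent from panel: ",
         paste(unknown, collapse = ", "))
  }
  tab <- table(factor(rnames[keep], levels = panel$loci$name))
  counts <- as.integer(tab)
  names(counts) <- panel$loci$name
  counts
}

#' Per-locus counts by alignment-free k-mer assignment
#'
#' Each read is assigned to the panel locus sharing the strictly greatest
#' number of its canonical k-mers; reads with a tie for the maximum or with
#' no k-mer overlap at all are discarded as non-unique. This is the
#' alignment-free analogue of unique mapping.
#'
#' @param reads a [fastq_reads()] object or character vector of sequences.
#' @param panel a `reference_panel`.
#' @param k odd k-mer size (default 25).
#' @return named integer vector of counts per panel locus.
#' @export
assign_by_kmer <- function(reads, panel, k = 25L) {
  validate_panel(panel)
  check_k(k)
  seqs <- if (inherits(reads, "fastq_reads")) reads$seq else
    as.character(reads)
  locus_sets <- lapply(panel$loci$sequence, canonical_kmers, k = k)
  counts <- integer(nrow(panel$loci))
  names(counts) <- panel$loci$name
  for (s in seqs) {
    km <- canonical_kmers(s, k)
    if (!length(km)) next
    ov <- vapply(locus_sets, function(ls) sum(km %in% ls), integer(1))
    m <- max(ov)
    if (m == 0L || sum(ov == m) > 1L) next  # non-unique: discard
    counts[which.max(ov)] <- counts[which.max(ov)] + 1L
  }
  counts
}

#' Assemble a count matrix from per-sample count vectors
#'
#' @param sample_counts named list mapping sample id to a named count vector
#'   (as returned by [counts_from_sam()] or [assign_by_kmer()]).
#' @param provenance provenance label for the matrix.
#' @return a `count_matrix`.
#' @export
bind_sample_counts <- function(sample_counts,
                               provenance = c("sam", "kmer_assign")) {
  provenance <- match.arg(provenance)
  stopifnot(length(sample_counts) > 0, !is.null(names(sample_counts)))
  loci <- names(sample_counts[[1]])
  m <- do.call(rbind, lapply(sample_counts, function(x) x[loci]))
  rownames(m) <- names(sample_counts)
  colnames(m) <- loci
  count_matrix(m, provenance = provenance)
}
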