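#' @importFrom Biostrings DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet reverseComplement
#' @importFrom S4Vectors mcols
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Plain-character wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' In-memory FASTQ record set
#'
#' A minimal container for FASTQ records: read id (including any
#' whitespace-separated comment, where the simulator stores its truth tag),
#' sequence and Phred+33 quality string.
#'
#' @param id character vector of read ids (description line without the `@`).
#' @param seq character vector of sequences.
#' @param qual character vector of quality strings; defaults to constant Q40.
#' @return A `fastq_reads` object (data.frame with columns id, seq, qual).
#' @export
fastq_reads <- function(id = character(0), seq = character(0), qual = NULL) {
  stopifnot(length(id) == length(seq))
  if (is.null(qual)) qual <- vapply(nchar(seq), function(n) strrep("I", n), "")
  stopifnot(length(qual) == length(seq), all(nchar(qual) == nchar(seq)))
  out <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                    qual = as.character(qual), stringsAsFactors = FALSE)
  class(out) <- c("fastq_reads", "data.frame")
  out
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (uncompressed or gzip).
#' @return A [fastq_reads()] object; ids keep the full description line.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  fastq_reads(id = names(x), seq = as.character(x),
              qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a FASTQ file
#'
#' @param reads a [fastq_reads()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "fastq_reads"))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Extract the truth tag from simulated read ids
#'
#' Simulated reads carry `locus=<name>` in the description comment; returns
#' NA for reads without a tag.
#'
#' @param id character vector of read ids.
#' @return character vector of source locus names.
#' @export
truth_locus <- function(id) {
  m <- regmatches(id, regexpr("locus=[^ ]+", id))
  out <- rep(NA_character_, length(id))
  out[grepl("locus=", id)] <- sub("^locus=", "", m)
  out
}

# Write a TSV with '#'-prefixed metadata header lines (tool version, seed,
# config hash) so downstream readers can skip them uniformly.
write_tsv_meta <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("lowdetect"))
  writeLines(c(sprintf("# lowdetect %s", version),
               sprintf("# %s", meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Evaluate code under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a stream-specific 31-bit seed from a base seed, so independent
# stages (cohort, counts, reads, bootstrap) never share an RNG stream.
# LCG-style rolling hash; multiplier kept small so doubles stay exact.
derive_seed <- function(seed, ...) {
  key <- utf8ToInt(paste(c(seed, ...), collapse = "/"))
  h <- 11
  for (ch in key) h <- (h * 69069 + ch) %% 2147483647
  as.integer(h)
}
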