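#' Canonical k-mers of DNA sequences
#'
#' A canonical k-mer is the lexicographic minimum of a k-mer and its reverse
#' complement, making matching strand-independent. Windows containing
#' non-ACGT characters are skipped; sequences shorter than k contribute
#' nothing.
#'
#' @param seqs character vector of DNA sequences.
#' @param k odd k-mer size.
#' @param unique drop duplicates if TRUE.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmers <- function(seqs, k, unique = TRUE) {
  check_k(k)
  seqs <- toupper(seqs)
  out <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    starts <- seq_len(n)
    km <- substring(s, starts, starts + k - 1L)
    km[grepl("^[ACGT]+$", km)]
  }), use.names = FALSE)
  if (!length(out)) return(character(0))
  rc <- revcomp(out)
  out <- ifelse(out <= rc, out, rc)
  if (unique) unique(out) else out
}

# scalar-friendly reverse complement avoiding S4 dispatch in tight loops
rc_chr <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s)))),
         "", USE.NAMES = FALSE)
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) ||
      k %% 2 == 0 || k < 11 || k > 31) {
    stop("k must be an odd integer in [11, 31] ",
         "(even k makes canonical form ill-defined for palindromes)")
  }
  invisible(as.integer(k))
}

#' Build a canonical k-mer set from reads
#'
#' @param reads a [fastq_reads()] object or character vector of sequences.
#' @param k odd k-mer size (default 25).
#' @return A `kmer_set`: list with `k` and sorted character `kmers`.
#' @examples
#' ks <- build_kmer_set(c("ACGTACGTACGTACGTACGTACGTA"), k = 25)
#' length(ks$kmers)
#' @export
build_kmer_set <- function(reads, k = 25L) {
  seqs <- if (inherits(reads, "fastq_reads")) reads$seq else
    as.character(reads)
  km <- sort(canonical_kmers(seqs, k))
  structure(list(k = as.integer(k), kmers = km), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> k=%d, %d canonical k-mers\n", x$k,
              length(x$kmers)))
  invisible(x)
}

#' Subtract reads shared with a male k-mer set
#'
#' Partitions female reads into candidate W-specific reads and reads shared
#' with the male read set. A read is *shared* iff the fraction of its
#' canonical k-mers present in `male_kmers` is at least `shared_threshold`;
#' everything else is *specific*. Reads shorter than k are conservatively
#' routed to shared (fraction 1) with a warning.
#'
#' @param female_reads a [fastq_reads()] object.
#' @param male_kmers a [build_kmer_set()] object built from male reads.
#' @param shared_threshold shared-fraction cutoff in `(0, 1]` (default 0.5).
#' @return A `subtraction_result`: list with `specific` and `shared`
#'   ([fastq_reads()]), and `fractions`, a data.frame
#'   (id, shared_fraction, class).
#' @examples
#' male <- build_kmer_set("ACGTACGTACGTACGTACGTACGTACGT", k = 25)
#' fem <- fastq_reads("r1", "ACGTACGTACGTACGTACGTACGTACGT")
#' subtract_reads(fem, male)$fractions
#' @export
subtract_reads <- function(female_reads, male_kmers,
                           shared_threshold = 0.5) {
  stopifnot(inherits(male_kmers, "kmer_set"))
  if (!is.numeric(shared_threshold) || shared_threshold <= 0 ||
      shared_threshold > 1) {
    stop("shared_threshold must lie in (0, 1]")
  }
  if (!inherits(female_reads, "fastq_reads")) {
    female_reads <- fastq_reads(seq_along(female_reads), female_reads)
  }
  k <- male_kmers$k
  frac <- vapply(female_reads$seq, function(s) {
    km <- canonical_kmers(s, k, unique = FALSE)
    if (!length(km)) return(NA_real_)
    mean(km %in% male_kmers$kmers)
  }, numeric(1), USE.NAMES = FALSE)
  short <- is.na(frac)
  if (any(short)) {
    warning(sum(short), " read(s) shorter than k routed to shared")
    frac[short] <- 1
  }
  shared <- frac >= shared_threshold
  fractions <- data.frame(id = female_reads$id, shared_fraction = frac,
                          class = ifelse(shared, "shared", "specific"),
                          stringsAsFactors = FALSE)
  structure(list(specific = female_reads[!shared, , drop = FALSE],
                 shared = female_reads[shared, , drop = FALSE],
                 fractions = fractions),
            class = "subtraction_result")
}

#' @export
print.subtraction_result <- function(x, ...) {
  cat(sprintf("<subtraction_result> %d specific / %d shared\n",
              nrow(x$specific), nrow(x$shared)))
  invisible(x)
}

#' Assemble unitigs from reads
#'
#' Builds the de Bruijn graph over the canonical k-mers of the input reads
#' and emits its maximal non-branching paths (unitigs) of length >= k.
#' Adjacency is defined by k-1 overlap within the k-mer set. Each unitig is
#' reported in canonical orientation (lexicographic minimum of the unitig
#' and its reverse complement) and the output is sorted lexicographically,
#' so the result is byte-deterministic.
#'
#' @param reads a [fastq_reads()] object or character vector.
#' @param k odd k-mer size (default 25).
#' @return character vector of unitig sequences (possibly named FASTA-ready
#'   via [write_unitigs_fasta()]); empty with a warning when no k-mer
#'   survives.
#' @export
build_unitigs <- function(reads, k = 25L) {
  check_k(k)
  seqs <- if (inherits(reads, "fastq_reads")) reads$seq else
    as.character(reads)
  if (!length(seqs)) stop("at least one read is required")
  kmers <- canonical_kmers(seqs, k)
  if (!length(kmers)) {
    warning("no k-mers; returning empty set")
    return(character(0))
  }
  kmers <- sort(kmers)

  canon <- function(x) {
    rc <- rc_chr(x)
    ifelse(x <= rc, x, rc)
  }
  has <- function(x) canon(x) %in% kmers
  succ <- function(w) {
    cand <- paste0(substring(w, 2L), DNA_BASES)
    cand[has(cand)]
  }
  pred <- function(w) {
    cand <- paste0(DNA_BASES, substring(w, 1L, nchar(w) - 1L))
    cand[has(cand)]
  }

  visited <- new.env(hash = TRUE, parent = emptyenv())
  mark <- function(km) assign(canon(km), TRUE, envir = visited)
  seen <- function(km) !is.null(get0(canon(km), envir = visited))

  walk <- function(start) {
    # extend forward from an oriented k-mer while the path is non-branching
    path <- start
    mark(start)
    cur <- start
    repeat {
      nxt <- succ(cur)
      if (length(nxt) != 1L) break
      if (length(pred(nxt)) != 1L) break
      if (seen(nxt)) break
      path <- c(path, substring(nxt, nchar(nxt), nchar(nxt)))
      mark(nxt)
      cur <- nxt
    }
    paste(path, collapse = "")
  }

  unitigs <- character(0)
  # starts: oriented k-mers whose backward extension is not unique
  for (km in kmers) {
    for (w in unique(c(km, rc_chr(km)))) {
      if (seen(km)) next
      p <- pred(w)
      if (length(p) != 1L || length(succ(p)) != 1L) {
        unitigs <- c(unitigs, walk(w))
      }
    }
  }
  # leftovers are perfect cycles; break each at its smallest oriented k-mer
  for (km in kmers) {
    if (!seen(km)) unitigs <- c(unitigs, walk(km))
  }
  rc <- rc_chr(unitigs)
  sort(unique(ifelse(unitigs <= rc, unitigs, rc)))
}

#' Write unitigs as FASTA
#'
#' @param unitigs character vector from [build_unitigs()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_unitigs_fasta <- function(unitigs, path) {
  x <- Biostrings::DNAStringSet(unitigs)
  names(x) <- sprintf("unitig_%d len=%d", seq_along(unitigs),
                      nchar(unitigs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
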