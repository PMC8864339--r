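#' Hamming distance between equal-length DNA strings
#'
#' Ungapped, case-insensitive position-by-position comparison; any position
#' where either base is outside A/C/G/T (ambiguity codes, N, gaps) counts as
#' a mismatch.
#'
#' @param a,b DNA strings of equal length.
#' @return nonnegative integer mismatch count.
#' @examples
#' count_mismatches("ACGT", "AGGA")
#' @export
count_mismatches <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  valid <- av %in% DNA_BASES & bv %in% DNA_BASES
  sum(av != bv | !valid)
}

#' Screen W-specific primer pairs against the Z gametologue
#'
#' Slides primer-sized windows along a pre-aligned W/Z gametologue region
#' and keeps windows with at least `min_mismatches` mismatches versus the Z
#' sequence — the specificity rule that keeps a W primer from amplifying the
#' Z copy. Surviving forward (plus-strand) and reverse (minus-strand)
#' windows are paired when the implied product length falls within
#' `target_product` +/- `tolerance`.
#'
#' Mismatch counts are strand-symmetric, so reverse primers are scored on
#' the plus-strand window and reported as its reverse complement.
#'
#' @param w_seq,z_seq pre-aligned (ungapped, equal-length) W and Z sequences.
#' @param primer_len primer length in bases (default 20).
#' @param min_mismatches minimum W-vs-Z mismatches per primer (default 2).
#' @param target_product desired amplicon size in bases (default 550).
#' @param tolerance allowed deviation from `target_product` (default 50).
#' @return list with `windows` (all surviving windows: start0 0-based,
#'   strand, sequence, mismatches) and `pairs` (forward/reverse
#'   combinations: fwd_start0, rev_start0, fwd_seq, rev_seq, fwd_mismatches,
#'   rev_mismatches, product_length). Empty data.frames when nothing
#'   survives.
#' @export
screen_w_primers <- function(w_seq, z_seq, primer_len = 20L,
                             min_mismatches = 2L, target_product = 550L,
                             tolerance = 50L) {
  w_seq <- toupper(w_seq); z_seq <- toupper(z_seq)
  if (nchar(w_seq) != nchar(z_seq)) {
    stop("w_seq and z_seq must be pre-aligned to equal length")
  }
  stopifnot(primer_len >= 1, min_mismatches >= 0, target_product > 0,
            tolerance >= 0)
  L <- nchar(w_seq)
  if (primer_len > L) stop("primer_len exceeds sequence length")
  starts <- seq_len(L - primer_len + 1L)
  wins_w <- substring(w_seq, starts, starts + primer_len - 1L)
  wins_z <- substring(z_seq, starts, starts + primer_len - 1L)
  mm <- mapply(count_mismatches, wins_w, wins_z, USE.NAMES = FALSE)
  keep <- mm >= min_mismatches

  windows <- rbind(
    data.frame(start0 = starts - 1L, strand = "forward",
               sequence = wins_w, mismatches = mm,
               stringsAsFactors = FALSE)[keep, , drop = FALSE],
    data.frame(start0 = starts - 1L, strand = "reverse",
               sequence = revcomp_safe(wins_w), mismatches = mm,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  )
  rownames(windows) <- NULL

  fwd <- windows[windows$strand == "forward", , drop = FALSE]
  rev <- windows[windows$strand == "reverse", , drop = FALSE]
  pairs <- empty_pairs()
  if (nrow(fwd) && nrow(rev)) {
    grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
    # product spans from the forward primer 5' end to the reverse primer
    # 5' end (the far end of the minus-strand window)
    prod_len <- (rev$start0[grid$r] + primer_len) - fwd$start0[grid$f]
    ok <- prod_len > 0 & abs(prod_len - target_product) <= tolerance
    if (any(ok)) {
      grid <- grid[ok, , drop = FALSE]
      pairs <- data.frame(
        fwd_start0 = fwd$start0[grid$f],
        rev_start0 = rev$start0[grid$r],
        fwd_seq = fwd$sequence[grid$f],
        rev_seq = rev$sequence[grid$r],
        fwd_mismatches = fwd$mismatches[grid$f],
        rev_mismatches = rev$mismatches[grid$r],
        product_length = prod_len[ok],
        stringsAsFactors = FALSE)
      pairs <- pairs[order(pairs$fwd_start0, pairs$rev_start0), ,
                     drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  if (!nrow(windows)) message("no primer window passed the mismatch rule")
  list(windows = windows, pairs = pairs)
}

empty_pairs <- function() {
  data.frame(fwd_start0 = integer(0), rev_start0 = integer(0),
             fwd_seq = character(0), rev_seq = character(0),
             fwd_mismatches = integer(0), rev_mismatches = integer(0),
             product_length = integer(0), stringsAsFactors = FALSE)
}

# revcomp that tolerates ambiguity codes by passing non-ACGT through chartr
# of the core alphabet only (screen windows may contain N).
revcomp_safe <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(chartr("ACGTacgt",
                                                       "TGCAtgca", s)))),
         "", USE.NAMES = FALSE)
}

#' Write a primer screen report as TSV
#'
#' @param screen result of [screen_w_primers()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_primer_tsv <- function(screen, path) {
  write_tsv_meta(screen$windows, path,
                 meta = sprintf("%d windows, %d pairs",
                                nrow(screen$windows), nrow(screen$pairs)))
}
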