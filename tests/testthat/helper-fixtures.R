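# Shared fixture builders: everything is generated in code at test time.

# Deterministic random DNA string
rand_dna <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# brute-force reverse complement, independent of the package's
brute_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force canonical k-mers of one sequence
brute_canonical <- function(s, k) {
  n <- nchar(s) - k + 1
  if (n < 1) return(character(0))
  km <- vapply(seq_len(n), function(i) substr(s, i, i + k - 1), "")
  km <- km[!grepl("[^ACGT]", km)]
  vapply(km, function(x) min(x, brute_rc(x)), "", USE.NAMES = FALSE)
}

# error-free reads tiling a sequence end to end with the given step
tiling_reads <- function(s, read_length = 75, step = 10) {
  starts <- unique(c(seq(1, nchar(s) - read_length + 1, by = step),
                     nchar(s) - read_length + 1))
  fastq_reads(id = paste0("t", starts),
              seq = substring(s, starts, starts + read_length - 1))
}

# minimal SAM text file over the panel's loci
write_test_sam <- function(path, panel, records) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", panel$loci$name,
                      nchar(panel$loci$sequence)))
  body <- vapply(records, function(r) {
    if (bitwAnd(r$flag, 4L) != 0L) {
      return(paste(r$qname, r$flag, "*", 0, 0, "*", "*", 0, 0,
                   strrep("A", 30), strrep("I", 30), sep = "\t"))
    }
    seq <- substr(panel$loci$sequence[match(r$rname, panel$loci$name)],
                  1, 30)
    paste(r$qname, r$flag, r$rname, 1, r$mapq, "30M", "*", 0, 0,
          seq, strrep("I", 30), sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# small simulation preset used where full default depth is unnecessary
fast_params <- function(...) sim_params(mean_depth = 2000, ...)
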