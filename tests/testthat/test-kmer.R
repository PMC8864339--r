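test_that("a 25 bp read yields exactly one canonical 25-mer", {
  ks <- build_kmer_set("ACGTACGTACGTACGTACGTACGTA", k = 25)
  expect_length(ks$kmers, 1)
})

test_that("k-mer sets are strand-symmetric", {
  s <- rand_dna(80, seed = 21)
  a <- build_kmer_set(s, k = 25)
  b <- build_kmer_set(brute_rc(s), k = 25)
  expect_identical(a$kmers, b$kmers)
  # brute-force canonicalization agrees
  expect_setequal(a$kmers, unique(brute_canonical(s, 25)))
})

test_that("empty input and non-ACGT windows are handled", {
  expect_length(build_kmer_set(character(0), k = 25)$kmers, 0)
  s <- paste0(rand_dna(30, 1), "N", rand_dna(30, 2))
  ks <- build_kmer_set(s, k = 25)
  expect_setequal(ks$kmers, unique(brute_canonical(s, 25)))
  expect_true(length(ks$kmers) > 0)
})

test_that("even or out-of-range k is rejected", {
  expect_error(build_kmer_set("ACGT", k = 24), "odd")
  expect_error(build_kmer_set("ACGT", k = 9), "odd")
})

test_that("subtraction with an empty male set keeps every read specific", {
  reads <- fastq_reads(paste0("r", 1:5),
                       vapply(1:5, function(i) rand_dna(60, i), ""))
  empty <- structure(list(k = 25L, kmers = character(0)),
                     class = "kmer_set")
  res <- subtract_reads(reads, empty)
  expect_equal(nrow(res$specific), 5)
  expect_equal(nrow(res$shared), 0)
  expect_true(all(res$fractions$shared_fraction == 0))
})

test_that("a female read identical to a male read is shared at fraction 1", {
  s <- rand_dna(75, seed = 31)
  mk <- build_kmer_set(s, k = 25)
  res <- subtract_reads(fastq_reads("r1", s), mk)
  expect_equal(nrow(res$shared), 1)
  expect_equal(res$fractions$shared_fraction, 1)
})

test_that("classification equals a brute-force k-mer membership recount", {
  # W reads diverged from Z at 10%: classify, then recount by hand
  pn <- make_reference("booby", seed = 41, divergence = 0.1)
  male <- list(sample_id = "m", sex = "M", loss_fraction = 0)
  fem <- list(sample_id = "f", sex = "F", loss_fraction = 0)
  par <- sim_params(mean_depth = 60, error_rate = 0)
  m_reads <- simulate_reads(pn, male, par, seed = 41)
  f_reads <- simulate_reads(pn, fem, par, seed = 42)
  mk <- build_kmer_set(m_reads$mate1, k = 25)
  res <- subtract_reads(f_reads$mate1, mk, shared_threshold = 0.5)

  brute_frac <- vapply(f_reads$mate1$seq, function(s) {
    km <- brute_canonical(s, 25)
    mean(km %in% mk$kmers)
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(res$fractions$shared_fraction, brute_frac)
  expect_equal(res$fractions$class,
               ifelse(brute_frac >= 0.5, "shared", "specific"))
  # planted-truth recovery: reads with zero male k-mer overlap are all
  # W-truth and classified specific
  w_truth <- truth_locus(f_reads$mate1$id) == "W_booby"
  expect_true(all(res$fractions$class[brute_frac == 0] == "specific"))
  expect_true(all(w_truth[brute_frac == 0]))
  # reads fully contained in male loci are shared
  expect_true(all(res$fractions$class[brute_frac == 1] == "shared"))
})

test_that("reads shorter than k are conservatively routed to shared", {
  mk <- build_kmer_set(rand_dna(60, 1), k = 25)
  reads <- fastq_reads(c("long", "short"),
                       c(rand_dna(60, 2), "ACGTACGT"))
  expect_warning(res <- subtract_reads(reads, mk), "shorter than k")
  expect_true("short" %in% res$shared$id)
  expect_equal(res$fractions$shared_fraction[res$fractions$id == "short"],
               1)
})

test_that("raising the shared threshold never shrinks the specific set", {
  pn <- make_reference("booby", seed = 51, divergence = 0.05)
  fem <- list(sample_id = "f", sex = "F", loss_fraction = 0)
  f_reads <- simulate_reads(pn, fem,
                            sim_params(mean_depth = 40, error_rate = 0.01),
                            seed = 51)
  mk <- build_kmer_set(c(pn$loci$sequence[pn$loci$chrom_class != "W"]),
                       k = 25)
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8, 1),
                  function(t) nrow(subtract_reads(f_reads$mate1, mk,
                                                  shared_threshold = t)$specific),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("subtraction partitions the input", {
  pn <- make_reference("booby", seed = 61)
  fem <- list(sample_id = "f", sex = "F", loss_fraction = 0)
  f_reads <- simulate_reads(pn, fem, sim_params(mean_depth = 30),
                            seed = 61)
  mk <- build_kmer_set(pn$loci$sequence[pn$loci$chrom_class == "Z"], 25)
  res <- subtract_reads(f_reads$mate1, mk)
  expect_equal(nrow(res$specific) + nrow(res$shared), nrow(f_reads$mate1))
  expect_setequal(c(res$specific$id, res$shared$id), f_reads$mate1$id)
})

test_that("unitigs reconstruct a 550 bp locus from tiling reads", {
  locus <- make_reference("booby", seed = 71)$loci$sequence[3]
  reads <- tiling_reads(locus, read_length = 75, step = 10)
  uni <- build_unitigs(reads, k = 25)
  expect_length(uni, 1)
  expect_true(uni == locus || uni == brute_rc(locus))
})

test_that("disconnected reads give one unitig each; output deterministic", {
  r1 <- rand_dna(60, seed = 81)
  r2 <- rand_dna(60, seed = 82)
  # ensure no shared k-mer between the two components
  stopifnot(!any(brute_canonical(r1, 25) %in% brute_canonical(r2, 25)))
  uni <- build_unitigs(c(r1, r2), k = 25)
  expect_length(uni, 2)
  expect_identical(uni, build_unitigs(c(r2, r1), k = 25))
  path1 <- withr::local_tempfile(fileext = ".fa")
  path2 <- withr::local_tempfile(fileext = ".fa")
  write_unitigs_fasta(uni, path1)
  write_unitigs_fasta(build_unitigs(c(r1, r2), k = 25), path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("unitig builder warns and returns empty on k-mer-free input", {
  expect_warning(uni <- build_unitigs("ACGT", k = 25), "no k-mers")
  expect_length(uni, 0)
  expect_error(build_unitigs(character(0), k = 25), "at least one read")
})
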