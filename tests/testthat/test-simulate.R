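test_that("count means track chromosome copy numbers", {
  # Law-of-large-numbers check: with no loss and mild overdispersion the
  # female W/autosome and Z/autosome count ratios approach 1/2.
  pn <- make_reference("booby", seed = 1)
  ch <- make_cohort("booby", seed = 1)
  big <- do.call(rbind, lapply(1:40, function(i) {
    x <- make_cohort("booby", seed = i)
    x$sample_id <- paste0(x$sample_id, "_", i)
    x
  }))
  class(big) <- c("cohort", "data.frame")
  cm <- simulate_counts(big, pn, sim_params(mean_depth = 1000,
                                            dispersion = 1000), seed = 4)
  w <- paste0("W_booby"); a <- paste0("AUTO_booby"); z <- paste0("Z_booby")
  n <- nrow(big)
  ratio_w <- mean(cm$counts[, w]) / mean(cm$counts[, a])
  ratio_z <- mean(cm$counts[, z]) / mean(cm$counts[, a])
  # 3 Monte-Carlo SEs of the ratio estimate
  se <- 3 * sqrt(2 / n) * 0.5 * sqrt(1 / 1000 + 1 / 500)
  expect_lt(abs(ratio_w - 0.5), se + 0.01)
  expect_lt(abs(ratio_z - 0.5), se + 0.01)
})

test_that("complete loss zeroes W counts; males are ZZ with no W", {
  pn <- make_reference("booby", seed = 2)
  ch <- make_cohort("booby", loss_profile = c(old = 1), seed = 2)
  cm <- simulate_counts(ch, pn, fast_params(), seed = 2)
  old <- ch$sample_id[ch$group == "old"]
  expect_true(all(cm$counts[old, "W_booby"] == 0))
  expect_true(all(cm$counts[setdiff(ch$sample_id, old), "W_booby"] > 0))

  males <- data.frame(sample_id = paste0("m", 1:20), species = "booby",
                      sex = "M", age_years = 1, group = "nestling",
                      loss_fraction = 0)
  cm_m <- simulate_counts(males, pn, fast_params(), seed = 3)
  expect_true(all(cm_m$counts[, "W_booby"] == 0))
  # ZZ males: Z mean matches autosomal mean (both 2 copies)
  expect_equal(mean(cm_m$counts[, "Z_booby"]),
               mean(cm_m$counts[, "AUTO_booby"]),
               tolerance = 0.1)
})

test_that("expected W counts decrease strictly with loss fraction", {
  pn <- make_reference("booby", seed = 5)
  means <- vapply(c(0, 0.25, 0.5, 0.75), function(f) {
    ch <- make_cohort("booby",
                      loss_profile = list(nestling = f, young = f,
                                          middle = f, old = f), seed = 7)
    cm <- simulate_counts(ch, pn, fast_params(), seed = 7)
    mean(cm$counts[, "W_booby"])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("counts are reproducible under a seed and round-trip as TSV", {
  pn <- make_reference("booby", seed = 1)
  ch <- make_cohort("booby", seed = 1)
  a <- simulate_counts(ch, pn, fast_params(), seed = 10)
  b <- simulate_counts(ch, pn, fast_params(), seed = 10)
  expect_identical(a$counts, b$counts)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(a, path)
  back <- read_counts_tsv(path)
  expect_identical(unname(back$counts), unname(a$counts))
  expect_identical(back$sample_ids, a$sample_ids)
})

test_that("error-free simulated reads are exact substrings of their locus", {
  pn <- make_reference("booby", seed = 3)
  fem <- list(sample_id = "f1", sex = "F", loss_fraction = 0)
  rd <- simulate_reads(pn, fem, sim_params(mean_depth = 30, error_rate = 0),
                       seed = 3)
  expect_gt(nrow(rd$mate1), 0)
  for (m in rd) {
    src <- truth_locus(m$id)
    for (i in seq_len(nrow(m))) {
      locus_seq <- pn$loci$sequence[pn$loci$name == src[i]]
      hit <- grepl(m$seq[i], locus_seq, fixed = TRUE) ||
        grepl(brute_rc(m$seq[i]), locus_seq, fixed = TRUE)
      expect_true(hit, info = m$id[i])
    }
  }
})

test_that("males yield no W-tagged reads; FASTQ output is deterministic", {
  pn <- make_reference("booby", seed = 4)
  male <- list(sample_id = "m1", sex = "M", loss_fraction = 0)
  rd <- simulate_reads(pn, male, sim_params(mean_depth = 30), seed = 5)
  expect_false(any(truth_locus(rd$mate1$id) == "W_booby"))
  expect_false(any(truth_locus(rd$mate2$id) == "W_booby"))

  rd2 <- simulate_reads(pn, male, sim_params(mean_depth = 30), seed = 5)
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(rd$mate1, f1)
  write_fastq(rd2$mate1, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("FASTQ writer/reader round-trips ids, sequences and qualities", {
  rd <- fastq_reads(id = c("a locus=W_x", "b locus=AUTO_x"),
                    seq = c("ACGTACGT", "TTGGCCAA"))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rd, path)
  back <- read_fastq(path)
  expect_equal(back$id, rd$id)
  expect_equal(back$seq, rd$seq)
  expect_equal(back$qual, rd$qual)
  expect_equal(truth_locus(back$id), c("W_x", "AUTO_x"))
})

test_that("read_length longer than the amplicon is rejected", {
  pn <- make_reference("booby", seed = 1)
  fem <- list(sample_id = "f1", sex = "F", loss_fraction = 0)
  expect_error(
    simulate_reads(pn, fem, sim_params(read_length = 600), seed = 1),
    "read_length")
})
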