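#' Simulation parameters for the amplicon assay
#'
#' Defaults emulate the targeted-sequencing arm of the assay: roughly 6e4
#' unique reads per locus per sample (about a third of the ~1.9e5
#' unique-mapped reads per sample reported for the smaller of the two
#' species' runs), ~12% between-sample depth variation, and negative-binomial
#' overdispersion capturing PCR amplification stochasticity (size parameter
#' 50, i.e. ~14% per-locus technical CV on top of Poisson noise).
#'
#' @param mean_depth expected unique reads per autosomal locus per sample.
#' @param depth_cv coefficient of variation of the per-sample lognormal
#'   depth multiplier.
#' @param efficiency named vector of per-locus amplification-efficiency
#'   multipliers; loci not named get 1.
#' @param dispersion negative-binomial size: variance = mu + mu^2/dispersion.
#' @param error_rate per-base substitution probability for read simulation,
#'   in `[0, 0.25)`.
#' @param read_length simulated read length in bases (default 75).
#' @return A `sim_params` list.
#' @export
sim_params <- function(mean_depth = 60000, depth_cv = 0.12,
                       efficiency = NULL, dispersion = 50,
                       error_rate = 0.001, read_length = 75L) {
  stopifnot(mean_depth > 0, depth_cv >= 0, dispersion > 0,
            error_rate >= 0, error_rate < 0.25, read_length > 0)
  if (length(efficiency) && any(efficiency <= 0)) {
    stop("all efficiencies must be positive")
  }
  structure(list(mean_depth = mean_depth, depth_cv = depth_cv,
                 efficiency = efficiency, dispersion = dispersion,
                 error_rate = error_rate,
                 read_length = as.integer(read_length)),
            class = "sim_params")
}

locus_efficiency <- function(params, locus_names) {
  eff <- rep(1, length(locus_names))
  names(eff) <- locus_names
  if (length(params$efficiency)) {
    hit <- intersect(names(params$efficiency), locus_names)
    eff[hit] <- params$efficiency[hit]
  }
  eff
}

# Per-locus chromosome copy number for one sample: autosomes 2; Z 1 (F) or
# 2 (M); W 1 - loss_fraction (F) or 0 (M).
copy_state <- function(chrom_class, sex, loss_fraction) {
  vapply(chrom_class, function(cl) {
    switch(cl,
           AUTOSOMAL = 2,
           Z = if (sex == "F") 1 else 2,
           W = if (sex == "F") 1 - loss_fraction else 0)
  }, numeric(1))
}

#' Simulate a per-sample x per-locus unique-read count matrix
#'
#' Counts follow a negative binomial with mean
#' `mu = mean_depth * depth_factor * efficiency * copies / 2` and variance
#' `mu + mu^2 / dispersion`. The division by 2 pins the autosome at its two
#' chromosome copies, so coverage ratios read directly in chromosome copies
#' and the nestling W median lands at one copy. Per-sample depth factors are
#' lognormal with mean 1 and CV `depth_cv`.
#'
#' @param cohort a [make_cohort()] data.frame.
#' @param panel a [make_reference()] panel.
#' @param params a [sim_params()] list.
#' @param seed integer seed.
#' @return A `count_matrix`: list with integer `counts`
#'   (samples x loci), `sample_ids`, `locus_names`, `provenance`.
#' @examples
#' ch <- make_cohort("booby", seed = 1)
#' pn <- make_reference("booby", seed = 1)
#' cm <- simulate_counts(ch, pn, sim_params(mean_depth = 1000), seed = 1)
#' head(cm$counts)
#' @export
simulate_counts <- function(cohort, panel, params = sim_params(),
                            seed = 1L) {
  validate_cohort(cohort)
  validate_panel(panel)
  stopifnot(inherits(params, "sim_params"))
  n <- nrow(cohort)
  loci <- panel$loci
  eff <- locus_efficiency(params, loci$name)
  local_seed(derive_seed(seed, "counts"), {
    sdlog <- sqrt(log1p(params$depth_cv^2))
    depth_factor <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    counts <- matrix(0L, nrow = n, ncol = nrow(loci),
                     dimnames = list(cohort$sample_id, loci$name))
    for (j in seq_len(nrow(loci))) {
      copies <- vapply(seq_len(n), function(i)
        copy_state(loci$chrom_class[j], cohort$sex[i],
                   cohort$loss_fraction[i]), numeric(1))
      mu <- params$mean_depth * depth_factor * eff[j] * copies / 2
      counts[, j] <- ifelse(mu == 0, 0L,
                            stats::rnbinom(n, mu = mu,
                                           size = params$dispersion))
    }
    count_matrix(counts, provenance = "simulated")
  })
}

#' Construct a count matrix container
#'
#' @param counts nonnegative integer matrix, samples x loci, with dimnames.
#' @param provenance one of `"sam"`, `"kmer_assign"`, `"simulated"`,
#'   `"file"`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts,
                         provenance = c("simulated", "sam", "kmer_assign",
                                        "file")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, sample_ids = rownames(counts),
                 locus_names = colnames(counts), provenance = provenance),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d samples x %d loci (%s)\n",
              nrow(x$counts), ncol(x$counts), x$provenance))
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' Rows are samples, columns are loci; the first column is `sample_id`.
#'
#' @param cm a `count_matrix`.
#' @param path TSV path.
#' @param meta extra `#` header lines.
#' @return `path` (writer) or a `count_matrix` (reader).
#' @export
write_counts_tsv <- function(cm, path, meta = character(0)) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(sample_id = cm$sample_ids, cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_meta(df, path, meta)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_meta(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  count_matrix(m, provenance = "file")
}

#' Simulate paired FASTQ reads for one sample
#'
#' Reads are drawn uniformly along each locus present in the sample's
#' genotype; the W locus is omitted for males, and for females the number of
#' W reads scales with `1 - loss_fraction` (the lost-cell fraction
#' contributes none). Mates are drawn independently (no insert-size model);
#' each mate is taken from a uniformly chosen strand. Substitution errors are
#' applied per base at `error_rate`; qualities are constant Q40. Each read id
#' carries the source locus as a `locus=<name>` comment for truth-tracking.
#'
#' @param panel a [make_reference()] panel.
#' @param sample one-row slice of a [make_cohort()] data.frame (or a list
#'   with `sample_id`, `sex`, `loss_fraction`).
#' @param params a [sim_params()] list; `mean_depth` here is the expected
#'   read-pair count per autosomal locus.
#' @param seed integer seed.
#' @return list with `mate1` and `mate2`, each a [fastq_reads()] object.
#' @export
simulate_reads <- function(panel, sample, params = sim_params(),
                           seed = 1L) {
  validate_panel(panel)
  stopifnot(inherits(params, "sim_params"))
  loci <- panel$loci
  if (params$read_length > min(nchar(loci$sequence))) {
    stop("read_length exceeds the shortest locus length")
  }
  eff <- locus_efficiency(params, loci$name)
  local_seed(derive_seed(seed, "reads", sample$sample_id), {
    sdlog <- sqrt(log1p(params$depth_cv^2))
    depth_factor <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    mates <- list(mate1 = NULL, mate2 = NULL)
    for (j in seq_len(nrow(loci))) {
      copies <- copy_state(loci$chrom_class[j], sample$sex,
                           sample$loss_fraction)
      mu <- params$mean_depth * depth_factor * eff[j] * copies / 2
      n_pairs <- if (mu == 0) 0L else
        stats::rnbinom(1, mu = mu, size = params$dispersion)
      if (n_pairs == 0) next
      for (m in 1:2) {
        reads <- draw_reads(loci$sequence[j], n_pairs, params$read_length,
                            params$error_rate)
        ids <- sprintf("%s_%s_%06d/%d locus=%s", sample$sample_id,
                       loci$name[j], seq_len(n_pairs), m, loci$name[j])
        mates[[m]] <- rbind(mates[[m]], fastq_reads(ids, reads))
      }
    }
    for (m in 1:2) {
      if (is.null(mates[[m]])) mates[[m]] <- fastq_reads()
      class(mates[[m]]) <- c("fastq_reads", "data.frame")
    }
    mates
  })
}

# n reads of length L from uniform start positions on a uniformly chosen
# strand, with iid substitution errors.
draw_reads <- function(locus_seq, n, read_length, error_rate) {
  max_start <- nchar(locus_seq) - read_length + 1L
  starts <- sample.int(max_start, n, replace = TRUE)
  reads <- substring(locus_seq, starts, starts + read_length - 1L)
  flip <- stats::runif(n) < 0.5
  if (any(flip)) reads[flip] <- revcomp(reads[flip])
  if (error_rate > 0) {
    n_err <- stats::rbinom(n, read_length, error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(read_length, n_err[i])
      b <- strsplit(reads[i], "")[[1]]
      b[pos] <- vapply(b[pos],
                       function(x) sample(setdiff(DNA_BASES, x), 1L), "")
      reads[i] <- paste(b, collapse = "")
    }
  }
  reads
}
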