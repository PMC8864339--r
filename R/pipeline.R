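#' Build a validated pipeline configuration
#'
#' A single structured configuration drives all stages of the pipeline
#' (simulate -> subtract -> count -> copynum -> test -> power). Unknown keys
#' are rejected so typos never silently fall back to defaults.
#'
#' @param config named list (e.g. from [yaml::read_yaml()]); see Details.
#' @details Recognised keys: `design`, `seed`, `stages` (character subset of
#'   simulate/subtract/count/copynum/test/power), `loss_profile`,
#'   `divergence`, `mean_depth`, `depth_cv`, `dispersion`, `error_rate`,
#'   `read_length`, `k`, `shared_threshold`, `mapq_min`, `alpha`,
#'   `calibration_group`, `outlier_rule`, `power_group`, `f_grid`,
#'   `n_reps`.
#' @return validated `run_config` list with defaults filled in.
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    design = "booby", seed = 1L,
    stages = c("simulate", "copynum", "test"),
    loss_profile = NULL, divergence = 0.1,
    mean_depth = 60000, depth_cv = 0.12, dispersion = 50,
    error_rate = 0.001, read_length = 75L,
    k = 25L, shared_threshold = 0.5, mapq_min = 20L,
    alpha = 0.05, calibration_group = "nestling", outlier_rule = "iqr",
    power_group = NULL, f_grid = c(0, 0.1, 0.2, 0.3), n_reps = 200L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  allowed <- c("simulate", "subtract", "count", "copynum", "test", "power")
  bad <- setdiff(cfg$stages, allowed)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Run the LOW-detection pipeline end to end
#'
#' Executes the requested stages in order and writes every stage output into
#' `out_dir` as plain text (TSV/FASTA/FASTQ) plus a machine-readable
#' `summary.json`. Every TSV carries `#` header lines with the tool version,
#' seed and config hash; re-running with the same config reproduces
#' byte-identical outputs.
#'
#' The `subtract` and `count` stages operate on simulated reads from a small
#' male/female pair of the configured design (the read-level arm of the
#' pipeline); `copynum` and `test` run on the cohort count matrix.
#'
#' @param config a [run_config()] (or plain list passed through it).
#' @param out_dir output directory (created if missing).
#' @return the summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("lowrun")) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  meta <- c(sprintf("seed=%d", cfg$seed), sprintf("config=%s", hash))
  params <- sim_params(mean_depth = cfg$mean_depth, depth_cv = cfg$depth_cv,
                       dispersion = cfg$dispersion,
                       error_rate = cfg$error_rate,
                       read_length = cfg$read_length)
  summary <- list(version = as.character(utils::packageVersion("lowdetect")),
                  seed = cfg$seed, config_hash = hash, design = cfg$design,
                  stages = cfg$stages)
  need <- function(stage, produced) {
    if (!stage %in% cfg$stages || !produced) {
      stop("stage requires missing upstream output: ", stage)
    }
  }

  panel <- make_reference(cfg$design, seed = cfg$seed,
                          divergence = cfg$divergence)
  write_panel_fasta(panel, file.path(out_dir, "panel.fa"))
  cohort <- NULL; counts <- NULL; cn_tab <- NULL

  if ("simulate" %in% cfg$stages) {
    cohort <- make_cohort(cfg$design, loss_profile = cfg$loss_profile,
                          seed = cfg$seed)
    counts <- simulate_counts(cohort, panel, params, seed = cfg$seed)
    write_cohort_tsv(cohort, file.path(out_dir, "cohort.tsv"), meta)
    write_counts_tsv(counts, file.path(out_dir, "counts.tsv"), meta)
    summary$n_samples <- nrow(cohort)
  }

  if ("subtract" %in% cfg$stages) {
    # read-level arm: one male, one female bird at reduced depth
    read_params <- sim_params(mean_depth = 200, depth_cv = cfg$depth_cv,
                              dispersion = cfg$dispersion, error_rate = 0,
                              read_length = cfg$read_length)
    male <- list(sample_id = "male_ref", sex = "M", loss_fraction = 0)
    female <- list(sample_id = "female_ref", sex = "F", loss_fraction = 0)
    m_reads <- simulate_reads(panel, male, read_params, seed = cfg$seed)
    f_reads <- simulate_reads(panel, female, read_params, seed = cfg$seed)
    write_fastq(f_reads$mate1, file.path(out_dir, "female_R1.fastq"))
    mk <- build_kmer_set(rbind(m_reads$mate1, m_reads$mate2), k = cfg$k)
    sub <- subtract_reads(f_reads$mate1, mk,
                          shared_threshold = cfg$shared_threshold)
    write_tsv_meta(sub$fractions, file.path(out_dir, "subtraction.tsv"),
                   meta)
    uni <- build_unitigs(sub$specific, k = cfg$k)
    write_unitigs_fasta(uni, file.path(out_dir, "unitigs.fa"))
    summary$subtract <- list(n_specific = nrow(sub$specific),
                             n_shared = nrow(sub$shared),
                             n_unitigs = length(uni))
    if ("count" %in% cfg$stages) {
      kc <- assign_by_kmer(f_reads$mate1, panel, k = cfg$k)
      write_tsv_meta(data.frame(locus = names(kc), count = as.integer(kc)),
                     file.path(out_dir, "female_kmer_counts.tsv"), meta)
      summary$count <- as.list(kc)
    }
  } else if ("count" %in% cfg$stages) {
    need("subtract", FALSE)
  }

  if ("copynum" %in% cfg$stages) {
    if (is.null(counts)) need("simulate", FALSE)
    cn_tab <- copy_number_table(counts, cohort,
                                group = cfg$calibration_group)
    write_tsv_meta(cn_tab, file.path(out_dir, "copy_number.tsv"), meta)
    summary$copynum <- list(
      nestling_median_cn_W =
        stats::median(cn_tab$cn_W[cn_tab$group == cfg$calibration_group]),
      excluded = attr(cn_tab, "excluded"))
  }

  if ("test" %in% cfg$stages) {
    if (is.null(cn_tab)) need("copynum", FALSE)
    reports <- lapply(c("W", "Z"), function(mk)
      test_report(cn_tab, mk, alpha = cfg$alpha,
                  group_order = cohort_design(cfg$design)$group,
                  outlier_rule = cfg$outlier_rule))
    names(reports) <- c("W", "Z")
    for (mk in names(reports)) {
      write_tsv_meta(reports[[mk]]$pairwise,
                     file.path(out_dir, sprintf("tests_%s.tsv", mk)), meta)
    }
    summary$test <- lapply(reports, function(r)
      list(n_significant = nrow(r$significant),
           trend_slope = r$trend$slope, trend_p = r$trend$p_slope,
           n_outliers = length(r$trend$outlier_ids)))
  }

  if ("power" %in% cfg$stages) {
    grp <- cfg$power_group
    if (is.null(grp)) {
      grp <- utils::tail(cohort_design(cfg$design)$group, 1)
    }
    pc <- power_curve(cfg$design, grp, cfg$f_grid, params,
                      alpha = cfg$alpha, n_reps = cfg$n_reps,
                      seed = cfg$seed, calib = cfg$calibration_group)
    write_tsv_meta(pc, file.path(out_dir, "power.tsv"), meta)
    summary$power <- pc
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
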