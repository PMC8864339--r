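#' Monte-Carlo power of the assay for a planted mosaic-loss fraction
#'
#' Runs the full pipeline per replicate — simulate a cohort with
#' `loss_fraction = f` planted in `affected_group`, simulate counts, apply
#' the autosomal correction and nestling calibration, run the pairwise
#' BH-corrected Mann-Whitney tests — and scores a detection when the
#' adjusted p for the (calibration group vs affected group) comparison on
#' the W marker falls below `alpha`. Power is the detection fraction with a
#' Clopper-Pearson 95% interval. Replicate seeds are derived from `seed`
#' and the replicate index only, so runs at different `f` share random
#' numbers (low-variance monotonicity comparisons).
#'
#' @param design cohort design (`"booby"` or `"frigatebird"`).
#' @param affected_group group carrying the planted loss; must differ from
#'   the calibration group.
#' @param f mosaic-loss fraction in `[0, 1]`.
#' @param params a [sim_params()] list.
#' @param alpha significance level (default 0.05).
#' @param n_reps Monte-Carlo replicates (>= 100).
#' @param seed integer seed.
#' @param calib calibration group label.
#' @return A `power_result`: list `loss_fraction`, `design`, `n_reps`,
#'   `alpha`, `power`, `ci_low`, `ci_high`, `seed`.
#' @export
run_power <- function(design, affected_group, f, params = sim_params(),
                      alpha = 0.05, n_reps = 200L, seed = 1L,
                      calib = calibration_group(design)) {
  stopifnot(f >= 0, f <= 1, n_reps >= 100)
  if (identical(affected_group, calib)) {
    stop("affected group equals the calibration group (confounded design)")
  }
  spec <- cohort_design(design)
  if (!affected_group %in% spec$group) {
    stop("unknown group for design ", design, ": ", affected_group)
  }
  lp <- stats::setNames(list(f), affected_group)
  hits <- vapply(seq_len(n_reps), function(rep) {
    rep_seed <- derive_seed(seed, "power-rep", rep)
    ch <- make_cohort(design, loss_profile = lp, seed = rep_seed)
    pn <- make_reference(design, seed = rep_seed)
    cm <- simulate_counts(ch, pn, params, seed = rep_seed)
    tab <- copy_number_table(cm, ch, group = calib)
    pw <- compare_groups(tab$cn_W, tab$group)
    row <- (pw$group_a == calib & pw$group_b == affected_group) |
      (pw$group_b == calib & pw$group_a == affected_group)
    pw$p_adj[row] < alpha
  }, logical(1))
  ci <- stats::binom.test(sum(hits), n_reps)$conf.int
  structure(list(loss_fraction = f, design = design,
                 affected_group = affected_group, n_reps = n_reps,
                 alpha = alpha, power = mean(hits), ci_low = ci[1],
                 ci_high = ci[2], seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "<power_result> %s, f=%.2f in %s: power %.3f [%.3f, %.3f] (%d reps)\n",
    x$design, x$loss_fraction, x$affected_group, x$power, x$ci_low,
    x$ci_high, x$n_reps))
  invisible(x)
}

#' Power curve over a grid of mosaic-loss fractions
#'
#' [run_power()] at each grid point with common random numbers across
#' points (identical replicate seeds), so sampling noise largely cancels
#' when comparing grid points.
#'
#' @inheritParams run_power
#' @param f_grid numeric vector of loss fractions in `[0, 1]`.
#' @return data.frame `f`, `power`, `ci_low`, `ci_high`, `n_reps`, `alpha`,
#'   `design`.
#' @export
power_curve <- function(design, affected_group, f_grid,
                        params = sim_params(), alpha = 0.05,
                        n_reps = 200L, seed = 1L,
                        calib = calibration_group(design)) {
  if (!length(f_grid)) stop("f_grid must be non-empty")
  stopifnot(all(f_grid >= 0), all(f_grid <= 1))
  rows <- lapply(f_grid, function(f) {
    pr <- run_power(design, affected_group, f, params, alpha, n_reps,
                    seed, calib)
    data.frame(f = f, power = pr$power, ci_low = pr$ci_low,
               ci_high = pr$ci_high, n_reps = n_reps, alpha = alpha,
               design = design, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
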