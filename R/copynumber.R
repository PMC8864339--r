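#' Autosomal depth correction of W/Z coverages
#'
#' All samples share the same autosomal copy number, so each sample's
#' autosomal count measures its sequencing depth. The correction factor is
#' the ratio of a sample's autosomal count to the cross-sample median
#' autosomal count; dividing the sample's W and Z counts by this factor
#' cancels depth differences (the correction is multiplicative because
#' coverage scales multiplicatively with depth; an additive variant is
#' available for sensitivity analysis).
#'
#' Samples with a zero autosomal count have an undefined factor and are
#' excluded with a warning, never silently dropped.
#'
#' @param counts a `count_matrix`.
#' @param autosomal_locus,w_locus,z_locus locus (column) names; default to
#'   the panel naming of [make_reference()] when unambiguous.
#' @param mode `"ratio"` (default) or `"additive"` (subtracts the autosomal
#'   deviation from the median instead of dividing by the ratio).
#' @return data.frame with columns `sample_id`, `factor` (ratio mode only;
#'   NA in additive mode), `corrected_W`, `corrected_Z`. Attribute
#'   `excluded` lists sample ids dropped for zero autosomal counts.
#' @examples
#' m <- matrix(c(100, 200, 400, 50, 100, 200, 60, 110, 230), ncol = 3,
#'             dimnames = list(paste0("s", 1:3), c("A", "W", "Z")))
#' autosomal_correct(count_matrix(m), "A", "W", "Z")
#' @export
autosomal_correct <- function(counts, autosomal_locus = NULL,
                              w_locus = NULL, z_locus = NULL,
                              mode = c("ratio", "additive")) {
  stopifnot(inherits(counts, "count_matrix"))
  mode <- match.arg(mode)
  nm <- default_locus(counts$locus_names, autosomal_locus, "AUTO")
  wm <- default_locus(counts$locus_names, w_locus, "W")
  zm <- default_locus(counts$locus_names, z_locus, "Z")
  if (nrow(counts$counts) < 2L) stop("need at least 2 samples")
  A <- counts$counts[, nm]
  W <- counts$counts[, wm]
  Z <- counts$counts[, zm]
  zero <- A == 0
  if (any(zero)) {
    warning("excluding ", sum(zero),
            " sample(s) with zero autosomal counts: ",
            paste(counts$sample_ids[zero], collapse = ", "))
  }
  ids <- counts$sample_ids[!zero]
  A <- A[!zero]; W <- W[!zero]; Z <- Z[!zero]
  if (mode == "ratio") {
    f <- A / stats::median(A)
    out <- data.frame(sample_id = ids, factor = f,
                      corrected_W = W / f, corrected_Z = Z / f,
                      stringsAsFactors = FALSE)
  } else {
    d <- A - stats::median(A)
    out <- data.frame(sample_id = ids, factor = NA_real_,
                      corrected_W = pmax(W - d, 0),
                      corrected_Z = pmax(Z - d, 0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- counts$sample_ids[zero]
  out
}

default_locus <- function(locus_names, given, prefix) {
  if (!is.null(given)) {
    if (!given %in% locus_names) stop("locus not in count matrix: ", given)
    return(given)
  }
  hit <- locus_names[startsWith(locus_names, prefix)]
  if (length(hit) != 1L) {
    stop("cannot infer ", prefix, " locus; pass the column name explicitly")
  }
  hit
}

#' Calibrate corrected coverages to chromosome copy numbers
#'
#' Divides each sample's depth-corrected coverage by the median corrected
#' coverage of the calibration group (nestlings: birds too young to have
#' accumulated mosaic loss, carrying exactly one W and one Z). After the
#' call the calibration-group median copy number is exactly 1, so values
#' read directly in chromosome copies.
#'
#' @param norm output of [autosomal_correct()].
#' @param cohort a [make_cohort()] data.frame covering the samples.
#' @param marker `"W"` or `"Z"`.
#' @param group calibration group label (default `"nestling"`).
#' @return data.frame `sample_id`, `group`, `cn` (chromosome copies).
#' @export
calibrate <- function(norm, cohort, marker = c("W", "Z"),
                      group = "nestling") {
  marker <- match.arg(marker)
  validate_cohort(cohort)
  col <- paste0("corrected_", marker)
  stopifnot(col %in% names(norm))
  grp <- cohort$group[match(norm$sample_id, cohort$sample_id)]
  if (anyNA(grp)) stop("cohort metadata missing for sample(s): ",
                       paste(norm$sample_id[is.na(grp)], collapse = ", "))
  anchor <- norm[[col]][grp == group]
  if (!length(anchor)) stop("empty calibration group: ", group)
  med <- stats::median(anchor)
  if (med <= 0) stop("calibration-group median coverage is not positive")
  data.frame(sample_id = norm$sample_id, group = grp,
             cn = norm[[col]] / med, stringsAsFactors = FALSE)
}

#' Full copy-number table from counts and cohort metadata
#'
#' Convenience composition of [autosomal_correct()] and [calibrate()] for
#' both sex-linked markers.
#'
#' @inheritParams autosomal_correct
#' @param cohort a [make_cohort()] data.frame.
#' @param group calibration group label.
#' @return data.frame `sample_id`, `group`, `age_years`, `factor`,
#'   `corrected_W`, `corrected_Z`, `cn_W`, `cn_Z`.
#' @examples
#' ch <- make_cohort("booby", seed = 1)
#' pn <- make_reference("booby", seed = 1)
#' cm <- simulate_counts(ch, pn, sim_params(mean_depth = 2000), seed = 1)
#' head(copy_number_table(cm, ch))
#' @export
copy_number_table <- function(counts, cohort, autosomal_locus = NULL,
                              w_locus = NULL, z_locus = NULL,
                              group = "nestling",
                              mode = c("ratio", "additive")) {
  norm <- autosomal_correct(counts, autosomal_locus, w_locus, z_locus,
                            mode = mode)
  cw <- calibrate(norm, cohort, "W", group)
  cz <- calibrate(norm, cohort, "Z", group)
  out <- data.frame(
    sample_id = norm$sample_id,
    group = cw$group,
    age_years = cohort$age_years[match(norm$sample_id, cohort$sample_id)],
    factor = norm$factor,
    corrected_W = norm$corrected_W,
    corrected_Z = norm$corrected_Z,
    cn_W = cw$cn, cn_Z = cz$cn,
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- attr(norm, "excluded")
  out
}

#' Estimate the mosaic-loss fraction of a group
#'
#' Inverts the copy-number model: the expected W copy number of a female
#' with mosaic-loss fraction f is 1 - f, so f is estimated as
#' `max(0, 1 - mean(cn))` over the group, clamped to `[0, 1]`, with a
#' seeded bootstrap percentile interval.
#'
#' Because every copy number in a cohort shares the same calibration anchor
#' (the nestling median), the anchor's own sampling noise shifts a whole
#' replicate jointly. When `calib_group` is given, the bootstrap therefore
#' resamples the calibration group alongside the target group and re-derives
#' the anchor in each resample, so the interval reflects calibration
#' uncertainty as well. With `calib_group = NULL` the anchor is treated as
#' fixed (appropriate when copy numbers are calibrated externally).
#'
#' @param cn numeric copy-number vector (e.g. `cn_W` from
#'   [copy_number_table()]).
#' @param groups group label per sample (same length as `cn`).
#' @param group group to estimate.
#' @param calib_group calibration group to resample jointly (default
#'   `NULL`: anchor fixed at 1).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return list `estimate`, `ci_low`, `ci_high`, `n`, `n_boot`.
#' @export
estimate_loss <- function(cn, groups, group, calib_group = NULL,
                          n_boot = 1000L, conf = 0.95, seed = 1L) {
  stopifnot(length(cn) == length(groups))
  x <- cn[groups == group]
  if (!length(x)) stop("empty group: ", group)
  a <- if (is.null(calib_group)) 1 else cn[groups == calib_group]
  if (!length(a)) stop("empty calibration group: ", calib_group)
  f_hat <- function(v, anchor) {
    min(1, max(0, 1 - mean(v) / stats::median(anchor)))
  }
  est <- f_hat(x, a)
  boots <- local_seed(derive_seed(seed, "boot", group), {
    vapply(seq_len(n_boot), function(b) {
      xb <- x[sample.int(length(x), replace = TRUE)]
      ab <- if (is.null(calib_group)) 1 else
        a[sample.int(length(a), replace = TRUE)]
      f_hat(xb, ab)
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(estimate = est, ci_low = qs[1], ci_high = qs[2], n = length(x),
       n_boot = n_boot)
}
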