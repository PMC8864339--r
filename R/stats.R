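#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples,
#' with midranks for ties. The p value is two-sided: computed by exact
#' enumeration of all rank assignments when `min(n_x, n_y) <= 8` and the
#' pooled sample is tie-free, otherwise by the normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @return list `U` (statistic for `x` vs `y`), `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))   # U = 0, p = 1/3 by enumeration
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (min(nx, ny) <= 8L && !ties) {
    # exact: U is rank-determined, so enumerate all C(N, nx) subsets
    subsets <- utils::combn(N, nx)
    Us <- colSums(matrix(r[subsets], nrow = nx)) - nx * (nx + 1) / 2
    mid <- nx * ny / 2
    p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-9)
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  d <- max(0, abs(U - mu) - 0.5)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-d / sqrt(sigma2)))
  list(U = U, p = p, method = "normal")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment: sort p ascending, multiply the i-th by
#' m/i, enforce monotone non-decreasing from the largest down, cap at 1;
#' results returned in the original order.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return adjusted p values, same order as input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))  # step-up monotonicity
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise group comparisons of copy numbers
#'
#' Tests every unordered pair of groups with [mann_whitney()] and adjusts
#' the family of pairwise p values with [bh_adjust()] (the family is the set
#' of pairwise comparisons for one marker).
#'
#' @param cn numeric copy-number vector.
#' @param groups group label per sample.
#' @param group_order optional label ordering for the report (defaults to
#'   first appearance).
#' @return data.frame `group_a`, `group_b`, `n_a`, `n_b`, `U`, `p_raw`,
#'   `p_adj`, sorted by (group_a, group_b) in `group_order`.
#' @export
compare_groups <- function(cn, groups, group_order = NULL) {
  stopifnot(length(cn) == length(groups))
  levs <- if (is.null(group_order)) unique(groups) else group_order
  stopifnot(all(groups %in% levs), length(levs) >= 2)
  pairs <- utils::combn(levs, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    xa <- cn[groups == a]; xb <- cn[groups == b]
    mw <- mann_whitney(xa, xb)
    data.frame(group_a = a, group_b = b, n_a = length(xa),
               n_b = length(xb), U = mw$U, p_raw = mw$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_raw)
  out[order(match(out$group_a, levs), match(out$group_b, levs)), ,
      drop = FALSE]
}

#' Age trend of copy number with outlier exclusion
#'
#' Flags outliers on the copy-number response by the 1.5 x IQR rule
#' (values beyond `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`), excludes them, and fits
#' ordinary least squares `cn ~ age` with a two-sided t test on the slope.
#' A zero-variance response yields slope 0 with p reported as 1.
#'
#' @param cn numeric copy-number vector.
#' @param ages numeric ages in years, same length.
#' @param ids optional sample ids for reporting outliers.
#' @param outlier_rule `"iqr"` (default) or `"none"`.
#' @return list `slope` (copy-number units per year), `intercept`,
#'   `p_slope`, `n_used`, `outlier_ids`.
#' @export
age_trend <- function(cn, ages, ids = NULL,
                      outlier_rule = c("iqr", "none")) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(length(cn) == length(ages))
  if (is.null(ids)) ids <- as.character(seq_along(cn))
  out_mask <- rep(FALSE, length(cn))
  if (outlier_rule == "iqr") {
    q <- stats::quantile(cn, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out_mask <- cn < q[1] - 1.5 * iqr | cn > q[2] + 1.5 * iqr
  }
  keep <- !out_mask
  if (sum(keep) < 3L) stop("fewer than 3 samples after outlier exclusion")
  y <- cn[keep]; a <- ages[keep]
  if (stats::var(y) == 0 || stats::var(a) == 0) {
    slope <- if (stats::var(a) == 0) NA_real_ else 0
    return(list(slope = slope, intercept = mean(y), p_slope = 1,
                n_used = sum(keep), outlier_ids = ids[out_mask]))
  }
  fit <- stats::lm(y ~ a)
  # an exactly linear response is a legitimate input here; summary.lm warns
  sm <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(sm["a", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       p_slope = unname(sm["a", "Pr(>|t|)"]),
       n_used = sum(keep), outlier_ids = ids[out_mask])
}

#' Full inference report for one marker
#'
#' Pairwise BH-corrected Mann-Whitney comparisons across age groups plus the
#' age-trend linear fit, mirroring the two views of the copy-number data
#' (grouped box plots and the per-age dot plot).
#'
#' @param cn_table output of [copy_number_table()].
#' @param marker `"W"` or `"Z"`.
#' @param alpha significance level (default 0.05).
#' @param group_order optional group ordering.
#' @param outlier_rule passed to [age_trend()].
#' @return list `marker`, `alpha`, `pairwise` (data.frame),
#'   `trend` (list), `significant` (pairwise rows with `p_adj < alpha`).
#' @export
test_report <- function(cn_table, marker = c("W", "Z"), alpha = 0.05,
                        group_order = NULL,
                        outlier_rule = c("iqr", "none")) {
  marker <- match.arg(marker)
  cn <- cn_table[[paste0("cn_", marker)]]
  pw <- compare_groups(cn, cn_table$group, group_order)
  tr <- age_trend(cn, cn_table$age_years, ids = cn_table$sample_id,
                  outlier_rule = outlier_rule)
  list(marker = marker, alpha = alpha, pairwise = pw, trend = tr,
       significant = pw[pw$p_adj < alpha, , drop = FALSE])
}
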