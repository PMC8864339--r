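#' Simulate a study cohort
#'
#' Builds a female cohort matching one of the two study designs. The
#' `booby` design has four age bands: 13 nestlings-fledglings (0-1 y),
#' 19 young adults (2-7 y), 10 middle-aged adults (8-11 y) and 19 old adults
#' (12-18 y); 61 females in all. The `frigatebird` design has 12 nestlings
#' aged 1 month (1/12 y) and 29 adults aged 6-30 y; 41 females. Individual
#' ages are drawn uniformly within each band (nestling frigatebirds are all
#' exactly 1 month old).
#'
#' A mosaic-loss fraction can be planted per group through `loss_profile`;
#' it is the fraction of blood cells lacking the W chromosome, so the
#' expected W copy number of an affected female is `1 - loss_fraction`.
#'
#' @param design `"booby"` or `"frigatebird"`.
#' @param loss_profile named list/vector mapping group labels to loss
#'   fractions in `[0, 1]`; groups not named get 0.
#' @param seed integer seed.
#' @return A `cohort` data.frame with columns `sample_id`, `species`, `sex`,
#'   `age_years`, `group`, `loss_fraction`.
#' @examples
#' ch <- make_cohort("booby", loss_profile = c(old = 0.3), seed = 1)
#' table(ch$group)
#' @export
make_cohort <- function(design = c("booby", "frigatebird"),
                        loss_profile = NULL, seed = 1L) {
  design <- match.arg(design)
  spec <- cohort_design(design)
  bad <- setdiff(names(loss_profile), spec$group)
  if (length(bad)) stop("unknown group(s) in loss_profile: ",
                        paste(bad, collapse = ", "))
  lp <- unlist(loss_profile)
  if (length(lp) && (any(lp < 0) || any(lp > 1))) {
    stop("loss fractions must lie in [0, 1]")
  }
  local_seed(derive_seed(seed, "cohort", design), {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      g <- spec[i, ]
      ages <- if (g$age_min == g$age_max) rep(g$age_min, g$n) else
        stats::runif(g$n, g$age_min, g$age_max)
      data.frame(group = g$group, age_years = ages,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$sample_id <- sprintf("%s_%03d", substr(design, 1, 4),
                             seq_len(nrow(out)))
    out$species <- design
    out$sex <- "F"
    out$loss_fraction <- 0
    if (length(lp)) {
      for (g in names(lp)) out$loss_fraction[out$group == g] <- lp[[g]]
    }
    out <- out[, c("sample_id", "species", "sex", "age_years", "group",
                   "loss_fraction")]
    class(out) <- c("cohort", "data.frame")
    out
  })
}

# Group sizes and age bands for the two study designs.
cohort_design <- function(design) {
  switch(design,
    booby = data.frame(
      group = c("nestling", "young", "middle", "old"),
      n = c(13L, 19L, 10L, 19L),
      age_min = c(0, 2, 8, 12),
      age_max = c(1, 7, 11, 18),
      stringsAsFactors = FALSE),
    frigatebird = data.frame(
      group = c("nestling", "adult"),
      n = c(12L, 29L),
      age_min = c(1 / 12, 6),
      age_max = c(1 / 12, 30),
      stringsAsFactors = FALSE),
    stop("unknown design: ", design)
  )
}

#' Nestling calibration group of a design
#'
#' Nestlings have had no time to accumulate mosaic loss and anchor the
#' one-copy calibration of W and Z.
#'
#' @param design cohort design label.
#' @return group label used for calibration.
#' @export
calibration_group <- function(design) "nestling"

validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "sex", "age_years", "group",
                  "loss_fraction") %in% names(cohort)))
  if (anyDuplicated(cohort$sample_id)) stop("sample ids must be unique")
  if (any(cohort$age_years < 0)) stop("ages must be nonnegative")
  if (any(cohort$loss_fraction < 0 | cohort$loss_fraction > 1)) {
    stop("loss fractions must lie in [0, 1]")
  }
  if (any(cohort$sex == "M" & cohort$loss_fraction > 0)) {
    stop("males carry no W chromosome to lose (loss_fraction must be 0)")
  }
  invisible(cohort)
}

#' Write cohort metadata as TSV
#'
#' @param cohort a [make_cohort()] data.frame.
#' @param path output path.
#' @param meta extra `#` header lines.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path, meta = character(0)) {
  write_tsv_meta(as.data.frame(cohort), path, meta)
}

#' Read cohort metadata from TSV
#' @param path TSV written by [write_cohort_tsv()].
#' @return a `cohort` data.frame.
#' @export
read_cohort_tsv <- function(path) {
  out <- read_tsv_meta(path)
  class(out) <- c("cohort", "data.frame")
  validate_cohort(out)
}
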