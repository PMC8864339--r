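---
title: "Coverage-based detection of mosaic W-chromosome loss: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based detection of mosaic W-chromosome loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowdetect)
```

## The measurement model

A female bird with mosaic W loss carries the W chromosome in only a
fraction `1 - f` of her blood cells. Three co-amplified loci — one
autosomal (2 copies in every cell), one Z-linked (1 copy in females) and
one W-linked (`1 - f` copies on average) — turn targeted sequencing
coverage into a copy-number assay. Two normalizations make the W coverage
interpretable:

1. **Autosomal depth correction.** All samples share the same autosomal
   copy number, so the per-sample autosomal count `A_i` measures sequencing
   depth. The correction factor is the ratio `A_i / median_j(A_j)` and the
   W and Z counts are divided by it. We use a ratio rather than a
   difference because coverage scales multiplicatively with depth; an
   additive correction would not cancel a doubled library. An additive mode
   (`mode = "additive"` in `autosomal_correct()`) is retained for
   sensitivity analysis only.
2. **Nestling calibration.** Nestlings and fledglings have had no time to
   accumulate mosaic loss, so their depth-corrected W coverage corresponds
   to exactly one chromosome copy. Dividing all corrected coverages by the
   nestling median pins the nestling median copy number at exactly 1, and
   every other sample's value then reads directly in chromosome copies,
   with expectation `1 - f`. Z is calibrated the same way on the same
   group (a female carries one Z).

Both steps are medians, not means, so single aberrant samples do not drag
the anchors. Samples with a zero autosomal count have an undefined factor
and are excluded with an explicit warning and a record in the output
attribute, never silently.

## Marker discovery and primer screening

W-linked sequence is found by subtraction: reads present in females but
absent in males. "Shared with males" must be made operational; we define a
female read as shared when at least half of its canonical k-mers (k = 25,
the lexicographic minimum of each 25-mer and its reverse complement) occur
in the male read set. The 50% threshold tolerates sequencing errors near
read ends while still removing reads of autosomal or Z origin; it is a
parameter (`shared_threshold`), and raising it can only enlarge the
specific set (a property the tests assert). Canonical (strand-collapsed)
k-mers are used because library strandedness cannot be assumed for
arbitrary inputs. Reads shorter than k carry no k-mer evidence and are
conservatively discarded as shared. Surviving reads are assembled by a
deliberately minimal unitig builder — maximal non-branching paths of the
de Bruijn graph, emitted in canonical orientation and lexicographic order —
which is enough to reconstruct a 550 bp amplicon from tiling reads and is
byte-deterministic; it is not a transcriptome assembler (no bubble popping,
no isoform logic).

W-specific primers must not amplify the diverged Z copy (the gametologue).
The screen slides primer-length windows over the pre-aligned W/Z pair and
requires at least 2 mismatches (ungapped Hamming distance; ambiguous bases
count as mismatches, the conservative choice for specificity). Whether such
a rule should weight 3' mismatches more is a real assay-design question,
but with no stated basis for a position weighting we count over the whole
primer. Primer length defaults to 20 bp and the amplicon target to
550 ± 50 bp — typical assay values, both configurable. Thermodynamic
scoring (Tm, GC, dimers) is out of scope.

## Counting and its two routes

"Uniquely mapped" is operationalized twice. The SAM route counts primary
records (not secondary 0x100 or supplementary 0x800, not unmapped) with
MAPQ ≥ 20 — the standard proxy for unique alignment; each mate counts
independently. The alignment-free route assigns a read to the locus sharing
the strictly greatest number of canonical k-mers, discarding ties and
zero-overlap reads. On a panel whose loci are ≥ 10% diverged, the k-mer
route reproduces the simulator's truth tags exactly (asserted in tests).

## The synthetic cohort generator

The generator exists so every stage is testable without any sequencing
download; its defaults are the study conditions, not knobs:

- **Designs.** Booby: 13 nestlings–fledglings (0–1 y), 19 young adults
  (2–7 y), 10 middle-aged (8–11 y), 19 old (12–18 y). Frigatebird: 12
  nestlings (1 month) and 29 adults (6–30 y). Individual ages are not
  published, so ages are drawn uniformly within each band.
- **Depth.** `mean_depth = 60000` expected unique reads per locus —
  roughly a third of the ~185,000 unique-mapped reads per sample of the
  smaller sequencing run, split evenly over the three loci (per-locus
  efficiencies default to 1 because no per-locus differences are
  reported). `depth_cv = 0.12` matches the reported between-sample
  s.d./mean of total reads (≈ 23,000 / 185,600).
- **Noise.** Counts are negative binomial, variance `mu + mu^2/50`. Pure
  Poisson noise would be unrealistically clean for PCR-amplified material;
  size 50 adds ~14% per-locus technical CV, the order of magnitude of
  replicate variation in quantitative PCR-based assays. At these depths the
  Poisson term is negligible and the technical CV dominates, which is the
  regime the real assay operates in.
- **Reads.** 75 bp (the sequencing configuration of the assay), uniform
  start positions, uniformly chosen strand, iid substitution errors,
  independent mates (no insert-size model, no indels, no quality-profile
  model). Truth tags travel in the FASTQ description comment, not the id,
  so standard parsers round-trip them.

What passing tests on these data do **not** show: robustness to per-locus
amplification efficiency drift between samples, GC or length bias,
contamination, or mapping artefacts — real-data effects the generator does
not emulate. The autosomal correction removes global depth only.

## Inference

Group comparisons use the Mann–Whitney U statistic with midranks. The
two-sided p value is computed by full enumeration of rank assignments when
`min(n) ≤ 8` and the pooled sample is tie-free (exactness is cheap there:
at most C(16,8) = 12,870 subsets), otherwise by the normal approximation
with tie correction and a 0.5 continuity correction; the two branches agree
to well under 0.01 at the switch point. The Benjamini–Hochberg family is
the set of pairwise comparisons for one marker (six for the booby design,
one for the frigatebird, where the adjustment is the identity).

The age trend is ordinary least squares of copy number on age with a
two-sided t test on the slope. "Excluding outliers" is made concrete as the
1.5×IQR rule on the copy-number response, with `outlier_rule = "none"` to
disable; which specific observations the original analysis excluded is not
recoverable, only the rule is reproduced. A zero-variance response returns
slope 0 with p = 1 rather than an error.

`estimate_loss()` inverts the copy-number model, `f = max(0, 1 - mean cn)`,
clamped to [0, 1], with a seeded percentile bootstrap. Because the
calibration anchor (the nestling median) is shared by every sample in a
cohort, its sampling noise moves a whole replicate coherently; the
bootstrap therefore resamples the calibration group jointly with the target
group and re-derives the anchor per resample (`calib_group` argument).
With the anchor treated as fixed the interval ignores that component and
under-covers badly; with joint resampling the 95% interval covers a planted
loss of 0.2 in ≈ 95% of simulated cohorts.

## Power analysis

Power is estimated by Monte-Carlo simulation of the full pipeline. The
detection event is fixed to one interpretable comparison — BH-adjusted
calibration-group-vs-affected-group p < α on the W marker — rather than
"any significant pair", so the power curve answers a single design
question. Replicate seeds depend only on the base seed and replicate index,
giving common random numbers across grid points; monotonicity of power in
`f` then holds with low variance. Note that at `f = 0` this adjusted
per-pair rejection rate sits well below α (the BH adjustment controls the
family), which is why type-I calibration is checked on the raw
per-comparison rate instead (measured ≈ 0.05 over null cohorts).

## Numerical and reproducibility choices

- Every stochastic function takes a seed; internal streams are derived
  from it with a deterministic integer hash keyed by stage name, so
  stages never share an RNG stream and any stage rerun in isolation
  reproduces its output byte-for-byte.
- Test-suite and acceptance-script problem sizes are desk-scale by design:
  200 replicates for parameter recovery, 500–1000 null cohorts for type-I
  calibration, 100–200 replicates per power-curve point. These sizes give
  Monte-Carlo standard errors comfortably inside the asserted bands.
- Ties in k-mer assignment are discarded, not broken randomly, so counting
  is deterministic.
- SAM coordinates follow the SAM convention (1-based); all internal
  offsets are 0-based half-open; primer windows are reported 0-based.

## Known limitations

- The subtraction rule is a k-mer membership heuristic, not read-pair-aware
  and with no error correction; heavily diverged W regions with Z-like
  ends can be lost at the default threshold.
- Copy numbers are cross-sectional; the package fits no longitudinal or
  mixed models.
- The count model ignores per-locus efficiency drift between samples; if a
  real assay's W primer efficiency varied systematically with sample age
  (e.g. DNA degradation), the method would confound that with loss — a
  limitation of the assay itself, not just the simulator.
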