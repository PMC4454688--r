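---
title: "Methods: mtDNA quantification and viability thresholding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA quantification and viability thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoEmbryo)
```

# Scope

`mitoEmbryo` implements the quantitative machinery linking the
mitochondrial DNA content of embryo biopsies to maternal age,
aneuploidy and implantation potential: relative quantification by the
2^−ΔΔCt method, a bin-based read-depth aneuploidy caller, an NGS
mtDNA-fraction measure with heteroplasmy estimation, a
viability-threshold classifier with retrospective derivation and a
blinded prospective harness, and the cohort-level comparisons. A
synthetic-cohort generator provides data with the statistical structure
these analyses assume, so every stage can be exercised and validated
without sequencing data.

This vignette documents the models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions taken
where the methods left genuine choices open.

# Relative quantification by 2^−ΔΔCt

A sample is assayed in triplicate for a mitochondrial target and for
the multicopy nuclear Alu element; the Alu signal controls for the
number of cells in the biopsy and for amplification-efficiency
differences after whole-genome amplification. With mean cycle
thresholds `Ct_mt` and `Ct_alu`,

* `ΔCt = Ct_mt − Ct_alu`,
* `ΔΔCt = ΔCt_test − ΔCt_reference`, where the reference ΔCt comes from
  a single run-constant reference sample, and
* `RQ = 2^−ΔΔCt`.

Assumptions: a doubling per cycle (amplification efficiency exactly 2,
the ΔΔCt method's standard assumption; no efficiency correction is
applied) and one reference ΔCt per analysis run, supplied as
configuration — the reference sample's ΔCt is not a universal constant
and must be stated with any analysis.

**Triplicate aggregation** is by arithmetic mean. The assay protocol
specifies triplicates but no outlier rule, so the package flags rather
than drops: a triplicate whose sample standard deviation exceeds
`maxSd` (default 0.5 cycles, a conventional replicate-agreement bound
for TaqMan assays) is marked `high_replicate_sd` but still quantified,
keeping the pipeline total. A missing replicate is an error — silent
imputation would bias RQ by up to a factor of 2 per cycle of error.

**Classification** against the qPCR viability cutoff (default RQ
0.003) uses a strict inequality: `RQ > cutoff` is high/abnormal. The
reference dataset bundled with the package classifies a sample at
0.0033 as high while no sample sits exactly at 0.003, so the strict
boundary is the deterministic choice consistent with every published
label; a value exactly at the cutoff is low/normal.

# Read-depth copy-number calling

The caller starts from per-bin read counts over a `BinGrid`. Real
grids have variable genomic width with fixed mappability content (100
uniquely mapping 36-mers per bin); since mappability tracks are out of
scope, `syntheticBinGrid()` builds fixed-width bins and records
`mappable36mers = 100`. Any externally produced grid can be read from
the BED-like TSV format (0-based half-open coordinates; reads are
assigned to bins by start position, a read at a bin's `end` belongs to
the next bin).

Stages, in order:

1. **Filtering** removes unmapped reads, duplicates, reads below a
   mapping-score floor and reads with more than one mismatch. The
   mapping-score floor has no published value, so `minMappingScore` is
   a required argument rather than a default masquerading as one.
2. **GC/reference normalization**: counts are divided by the median
   count of their 1% GC stratum relative to the global median, then by
   the bin's in-silico `referenceWeight`. Strata with fewer than 20
   bins are merged with neighbours. A stratified median is
   deterministic and robust to the strong coverage bias of
   whole-genome-amplified shallow sequencing; the in-silico reference
   is realized as a per-bin weight (identity by default) because no
   published reference data set is available to ship.
3. **Copy number**: `CN_i = normalized_i / median(autosomal
   normalized) × 2`. The autosomal median is exactly 2 by construction
   for every sample; sex chromosomes are excluded from the normalizing
   median but still scored. Zero-count bins keep CN 0 — no masking.
4. **Smoothing**: a 13-bin sliding median per chromosome. Smoothing
   never crosses a chromosome boundary. At chromosome edges the window
   shrinks symmetrically (at position `i` of an `n`-bin chromosome the
   half-width is `min(6, i−1, n−i)`), which keeps edge bins instead of
   discarding them; the interior uses `stats::runmed`.
5. **Calls**: each chromosome's state is the median of its smoothed
   values — gain at ≥ 2.5, loss at ≤ 1.5, else neutral. The cutoffs
   are the midpoints between integer copy states, the natural
   deterministic choice where no numeric cutoff is published, and are
   exposed as configuration. With a declared sample sex, X and Y are
   assessed against their expected copies (the cutoffs shift by
   expected − 2); without one their medians are reported with state
   `NA` and do not enter the verdict. The sample verdict is aneuploid
   when any assessed chromosome is non-neutral.

The pipeline is equivariant under rescaling of all counts, so
sequencing depth cancels everywhere except through counting noise.

# NGS mitochondrial fraction and heteroplasmy

The sequencing analogue of RQ is the share of aligned bases on the
mitochondrial genome, reported in percent:
`100 × mito / (mito + nuclear)`. Bases, not reads, are tallied (read
counts differ only by a constant read-length factor, which cancels in
the ratio when lengths are uniform); the percent-of-total convention
matches how the paired viability cutoff (0.07%) is stated.
Classification is strict, mirroring the qPCR rule.

Heteroplasmy is estimated per site from pileup counts as the
alternate-allele fraction `f = alt / (ref + alt)` on the 16,569 bp
mitochondrial genome (treated as linear positions; pileup input is
already position-resolved, so no junction logic is needed). A site is
reported heteroplasmic when depth ≥ `minDepth` (default 20) and
`minFraction ≤ f ≤ 1 − minFraction` (default 0.05), homoplasmic-alternate
above `1 − minFraction`; homoplasmic-reference sites are not listed.
The depth and fraction floors are package defaults: at the ~150×
design depth, a 5% minor allele is seen ~7.5 times in expectation,
enough to separate it from sequencing error at reasonable error rates,
while depth 20 keeps the binomial standard error of `f` below ~11
percentage points. Mutation-load comparison counts heteroplasmic sites
per sample and compares groups two-tailed (Welch by default, Wilcoxon
available); groups under 2 samples skip the test with a warning.

# Viability threshold

`deriveThreshold()` formalizes the retrospective rule: the cutoff is
the smallest multiple of a rounding grid strictly greater than the
largest value among implanting embryos, so no training implanter
exceeds it by construction. Whether the published 0.003 was obtained
by rounding on the RQ scale or sits exactly at the training maximum is
not stated anywhere; both modes are therefore supported —
`deriveThreshold()` (which yields 0.003 at a 0.003 grid whenever the
training implanter maximum is below 0.003) and `fixedThreshold()` —
without asserting which produced the published value.

`evaluateCohort()` reports, on embryos with known outcome: the
negative predictive value (share of above-cutoff embryos failing to
implant — the prediction being *non*-viability, NPV is the relevant
figure of merit), implantation rates below the cutoff and overall, and
the share of non-implanters above the cutoff. NPV is not applicable
(`NA`) when no embryo exceeds the cutoff. `blindedValidate()` enforces
id-disjoint training and test cohorts and touches test outcomes only
inside the evaluation step.

Outcome is binary ongoing-clinical-pregnancy; biochemical-only
pregnancies are not modelled.

# Cohort statistics

All group comparisons are unpaired two-tailed t-tests. Welch's variant
is the default — the safer choice under the unequal group variances
that log-normal RQ distributions produce — with the pooled variant
available for strict classical replication; no log transformation is
applied by default, and neither choice is asserted as the original
analysis's. No multiple-testing correction is applied across the
(three) comparisons; raw p-values are reported. The younger/older age
boundary is 38 (inferred from the published group ranges 26–37 vs
38–42) and configurable. Degenerate inputs follow explicit
conventions: two zero-variance groups with equal means give `t = 0,
p = 1`, with unequal means `t = ±Inf, p = 0`.

Per-age summaries report count, range and mean per ploidy group, with
single-embryo groups showing the value as the range and `NA` for the
mean, matching the published table convention.

# The synthetic-cohort generator

The generator encodes the study conditions the analyses assume. Its
defaults are fixed once, on the following grounds:

* **Cohort composition**: ages 26–42 with per-age weights and per-age
  aneuploidy rates equal to the 302-blastocyst reference cohort's
  composition (99/302 aneuploid overall).
* **Latent RQ**: log-normal around a stage-dependent age trend. RQ
  spans two orders of magnitude within single ages in published
  summaries, so log-scale variation is the simplest consistent model;
  `rqLognormalSigma = 1.0` (natural log) reproduces that spread.
  Baseline 0.0015 at age 34 sits mid-range of published euploid
  per-age means.
* **Effect sizes are configuration, not constants**: the source
  analyses report directions and p-values but no magnitudes. Defaults
  (blastocyst +10%/year, cleavage −10%/year, aneuploidy ×1.8) were
  chosen so that cohorts of 302 embryos reach p < 0.05 for the age and
  ploidy comparisons in at least 80% of replicates — i.e. the defaults
  make the simulated study as powered as the reported one — and are
  consistent with the spread of published per-age group means.
* **Outcome coupling**: euploid blastocysts receive an outcome
  (implantation probability 0.47, the retrospective cohort's 42/89);
  implanters are constrained below `viabilityCutoff` (default 0.003),
  and a fraction `nonimplanterElevatedFraction` (default 0.30) of
  non-implanters is resampled above it, the remainder below. Both
  resamplings use exact inverse-CDF truncated log-normal draws. This
  makes the above-cutoff share among non-implanters exactly binomial
  with the configured rate. Whether elevated non-implanters follow a
  distinct distribution or the tail of the common one is unknown; the
  truncated-tail model is used, and the elevated fraction is
  configuration rather than an assertion.
* **Cleavage stage**: outcomes are drawn without any RQ coupling — no
  outcome association exists at that stage, and cleavage-stage
  blastomeres carry RQ an order of magnitude above the blastocyst
  cutoff scale (baseline 0.05), so the viability constraint is
  blastocyst-specific. Aneuploid embryos are never transferred
  (outcome `unknown`), and cleavage-stage embryos are generated
  euploid, matching the transferred-cohort design.
* **The generator's null**: the outcome coupling is itself one of the
  generator's effects. Because implanters are truncated below the
  cutoff while untransferred aneuploids are not, leaving the coupling
  active with all multiplicative effects at 1 still separates the
  ploidy groups by construction. The fully null configuration is
  therefore `blastocystAgeEffect = cleavageAgeEffect =
  aneuploidyEffect = 1`, `nonimplanterElevatedFraction = 0` **and**
  `viabilityCutoff = Inf` (no truncation anywhere); under it the
  cohort comparisons' p-values are uniform.
* **Counts and pileups**: per-bin counts are negative-binomial with
  `variance = μ + φμ²` (default `φ = 0.1`, reflecting real but
  unquantified WGA overdispersion; `φ = 0` gives Poisson) around
  `μ = meanReadsPerBin × (copies/2) × gcBias(GC) × referenceWeight`,
  with a quadratic GC-bias curve (default peaking at mid-GC). Pileup
  depths are Poisson (default mean 150, the sequencing design's target
  depth over the mitochondrial genome) with binomial alternate counts
  at the planted fraction, or at the error rate (default 0.002)
  elsewhere.
* **Cross-assay link**: the latent NGS fraction is a deterministic
  monotone image of the latent RQ, `percent = 0.07/√0.003 × √RQ`,
  chosen to pass through the paired assay cutoffs (RQ 0.003 ↔ 0.07%)
  so cross-assay concordance is preserved; the square-root exponent
  matches the log-log slope of published paired sample values.
* **Seeding**: one master seed; every operation (and every record
  within table-level operations) derives a deterministic substream, so
  cohorts are bit-reproducible and per-record draws are independent of
  evaluation order.

What the generator does **not** emulate: mosaicism and segmental
aneuploidy (whole chromosomes only), sequence-level reads (counts and
pileups only), inter-run qPCR batch effects, WGA locus dropout
structure beyond global overdispersion, and any morphology covariates.
Consequently, passing tests demonstrate that the pipeline recovers the
structure it is designed for; they do not certify performance on real
WGA material, where bias is more structured than a smooth GC curve.

# Numerical conventions and degenerate inputs

* All classification inequalities are strict (`>` cutoff ⇒ abnormal /
  non-viable) at every threshold, consistently across assays.
* Threshold derivation uses `floor(max/grid + 1e−9) + 1` grid steps so
  a training maximum sitting exactly on a grid multiple still rounds
  strictly up, and floating-point quotients a hair under an integer do
  not round twice.
* All-zero count vectors are an error (failed sample), as is a zero
  autosomal median; empty filtered alignment sets are allowed;
  off-grid reads are dropped with a tally, never an error.
* Copy-number medians over even numbers of bins interpolate (R's
  default median), so chromosome medians need not be multiples of 0.5.
* The sliding-median window must be odd; a window wider than a
  chromosome shrinks symmetrically at every position.

# Validation problem sizes

The test suite validates the stochastic properties at sizes chosen to
make Monte-Carlo error small relative to the margins being checked:
planted-aneuploidy recovery over 200 simulated samples on a
22-chromosome, 880-bin grid at 30 reads/bin (sensitivity and
specificity ≥ 99%); the sliding median against an independent
brute-force oracle on 1,000 random profiles; threshold recovery on 200
cohorts of 89 transfers; null calibration over 500 cohorts of 302
(Kolmogorov–Smirnov at α = 0.01) and power over 200 cohorts of 302.
The acceptance script recomputes the same quantities at comparable
sizes from a caller-supplied seed.

# Known limitations

* The aneuploidy caller targets whole-chromosome events; segmental
  changes shorter than about half a chromosome dilute the chromosome
  median below the call cutoffs by design.
* The GC normalization assumes bias is a function of GC alone within
  1% strata; replication-timing or fragment-length biases fold into
  the reference weights or remain.
* Heteroplasmy calls carry position and fraction only — no functional
  annotation, haplogroup assignment or deletion-breakpoint detection.
* The threshold machinery treats assay values as exchangeable across
  runs; inter-laboratory calibration of RQ (different reference
  samples, different ΔCt baselines) is out of scope and must be
  handled upstream.
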