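---
title: "Methods: quality gates, dual-pool filtering and concordance for a targeted tumor panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality gates, dual-pool filtering and concordance for a targeted tumor panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelval)
library(dplyr)
```

## The analytical problem

Molecular diagnostics laboratories that adopt a targeted amplicon panel for
FFPE tumor specimens face two coupled questions: *is each specimen good
enough to sequence*, and *is the assay's variant detection concordant with
an orthogonal reference standard*. panelval implements the computational
side of that workflow for a 26-gene dual-pool amplicon panel:

1. **Pre-sequencing quality gates** on each specimen (tumor-cell content,
   DNA amplifiability, library fragment size) that decide who gets
   sequenced at all.
2. **Dual-pool variant filtering**: each sample is amplified in two
   independent primer pools (A and B); artifact suppression comes from
   requiring concordant evidence in both.
3. **Coverage assessment** per amplicon and per exon region, with a
   cross-pool compensation rule.
4. **Diagnostic-accuracy statistics** against a reference standard
   (pyrosequencing / allele-specific PCR / Sanger results supplied as
   truth labels), with exact Clopper–Pearson intervals.
5. A **seeded synthetic cohort generator** that replaces patient data, so
   every stage is testable offline.

FFPE DNA is fragmented and chemically damaged, which is why amplifiability
(not just concentration) is gated, and why a strict pre-analytical cascade
loses a substantial fraction of specimens before sequencing.

## Quality gates

**QC1 — tumor-cell content (TCC).** A pathologist scores the percentage of
neoplastic nuclei. At ≥ 30% the specimen passes outright. Between 10% and
30% the tumor area is macrodissected when feasible; when it is not, DNA is
isolated directly from the whole section (the sample proceeds, at a known
risk of diluted variant signal). Below 10% the gate fails. The flowchart we
implement defines no path below 10%, so the conservative choice is a hard
fail; clinical-override escapes exist only at the ΔCq gate, where the
source workflow actually used them.

**QC2 — ΔCq amplifiability.** Sample and non-FFPE control DNA are
amplified in qPCR triplicate and

$$\Delta C_q = \overline{C_q}^{\,\text{sample}} - \overline{C_q}^{\,\text{control}}.$$

Larger values mean poorer amplifiable template. Classification:
ΔCq < 4 *good* (the vendor-recommended band), 4 ≤ ΔCq < 6 *acceptable* (the
extended laboratory cut-off), ΔCq ≥ 6 *fail* unless an explicit clinical
request overrides. Both inequalities are strict — a ΔCq of exactly 6.0
fails — because the defining rules are consistently written as strict
("< 4", "< 6"). Triplicates tolerate a single dropped well (mean over ≥ 2
replicates); requiring all three would make replicate dropout untestable
while adding no information. Specimens that never underwent the ΔCq assay
are recorded as *not assessed*; skipping the gate does not itself block
sequencing, since unassessed specimens demonstrably sequence successfully.

**QC3 — library size.** Fragment-size peaks in the closed band
[300, 330] bp pass. The band is read as inclusive: the defining phrase is a
range, and only products *under 300 bp* are explicitly excluded. QC3 is
assessed only when the earlier gates allow library preparation; otherwise
it is *not assessed*.

A sample is **sequenced** iff QC1 did not fail, QC2 is
good/acceptable/overridden/not-assessed, and QC3 passed; otherwise it is an
**NGS fail**. Run-level flow-cell metrics (cluster density against the
optimal 1000–1400 clusters/mm² window, cluster-passing-filter, Q30) are
annotated per run but never gate individual samples.

## Dual-pool variant filtering

Each sequenced sample yields one call set per pool. Calls are merged on the
variant key (contig, position, ref, alt) after trimming shared allele
prefixes/suffixes, so that the two callers' indel spellings match; full
left-alignment against a reference genome is out of scope, and
prefix/suffix trimming suffices for calls emitted from the same alignments.
The merged record keeps per-pool depth and VAF; the cumulative depth is the
sum over present pools and the combined VAF the depth-weighted mean.

The reporting rule is a three-way partition:

* **EXCLUDED** — combined VAF < 3%. The threshold applies to the combined
  VAF (the quantity reported per variant), not per pool; the defining rule
  carries no pool qualification.
* **PASS** — present in both pools, cumulative depth ≥ 1000× and no
  strand-bias flag. "Cumulative 1000×" and "average 500× per pool" are
  arithmetically identical for two pools and the implementation uses the
  cumulative reading; a strict per-pool minimum (each pool ≥ 500×) is
  exposed as `per_pool_min = TRUE` for laboratories that read the rule that
  way, default off.
* **REVIEW** — everything else: single-pool calls, depth shortfalls,
  strand-biased calls. These are kept for manual interpretation, not
  discarded.

Strand bias is consumed as an upstream caller flag (FILTER/INFO key,
default `SB`); no strand-bias statistic is computed internally, because the
rule being modelled treats it as a caller-provided condition. Clinical
classification (pathogenic … benign) is likewise annotation passthrough
with vocabulary validation — no database lookups.

This per-variant depth rule is deliberately distinct from the per-exon
coverage QC below; neither substitutes for the other.

## Coverage assessment

Per-amplicon coverage is the arithmetic mean of per-position depth over the
amplicon (or is supplied pre-aggregated). The exon-level pool mean is the
unweighted mean of that pool's amplicon means for the region — amplicon
lengths are not part of the panel description, so weighting by length is
not an option. An exon region:

* **passes** when a single pool's mean reaches 1000×;
* **passes by compensation** when neither pool reaches 1000× alone but
  pool A + pool B does — the "cumulatively counting the second pool" rule;
* **fails** below 1000× cumulatively. A region covered by amplicons of only
  one pool has nothing to compensate with and can only pass outright or
  fail.

The cohort report aggregates coverage over samples before judging regions
(a per-sample mode is available), lists failing regions first, and assigns
every region exactly one status.

## The bundled panel model

The bundled manifest encodes the panel's topology: 26 genes, 82 exons, 178
amplicons in pools A and B, with split exons (e.g. APC 15 in three
sub-regions, PTEN 1/5/6 in two each) and grouped exons (TP53 2–4, 5–6, 8–9
sharing amplicon sets) modelled as distinct region records — 83 region
records spanning the 82 distinct exons. Genomic coordinates are synthetic
but self-consistent (each gene occupies a disjoint 1 Mb block; BED
convention, 0-based half-open, converted once at the variant-lookup
boundary): every computation depends only on which amplicon covers which
region in which pool, never on absolute positions. Within a region,
amplicons alternate pools starting with A. Per-gene amplicon totals are
fixed by the panel description; where the per-exon split within a gene is
not, it was chosen once so the documented coverage narrative holds: AKT1
exon 2 and STK11 exon 6 are single-amplicon, single-pool regions (they can
fail but never compensate), while EGFR exon 21 and STK11 exons 1/4/8 carry
amplicons in both pools (they can compensate). One consequence of the fixed
totals: TP53 exon 11 ends up with a single amplicon in this illustrative
layout and therefore cannot compensate, which is a limitation of the
manifest, not of the compensation rule.

## Concordance statistics

Each validation outcome is one known variant (or the wild-type status of a
variant-free sample) assessed by one center: 48 samples × 3 centers = 144
outcomes, of which 87 are reference-positive (29 variant samples × 3) and
57 reference-negative. Outcomes tally into TP/FP/FN/TN per variant outcome,
not per sample — a wild-type sample contributes one not-detected outcome
per center. From the 2×2 table:

$$\text{sens} = \frac{TP}{TP+FN},\quad
  \text{spec} = \frac{TN}{FP+TN},\quad
  \text{acc} = \frac{TP+TN}{N},\quad
  \text{PPV} = \frac{TP}{TP+FP},\quad
  \text{NPV} = \frac{TN}{FN+TN}.$$

Confidence intervals are exact Clopper–Pearson, computed by inverting the
two binomial tails through Beta quantiles
(`qbeta(α/2, x, n−x+1)` / `qbeta(1−α/2, x+1, n−x)`), with the conventions
lower = 0 at x = 0 and upper = 1 at x = n. The test suite checks these
endpoints against an independent tail-sum inversion oracle for every
(x, n ≤ 12) at 10⁻⁶ and verifies empirical coverage ≥ 95% − 1 point on
10,000 simulated draws per scenario.

Percent presentation uses round-half-up to integer percent, matching how
validation tables are conventionally printed. One caveat surfaced by the
acceptance checks: for the reference 2×2 table (TP 80, FP 3, FN 7, TN 54)
the NPV is 54/61 = 88.52%, which no rounding rule consistent with the other
four metrics can present as the reference figure of 88% — the package
reports 89% and the corresponding acceptance expectation is left failing
rather than special-cased.

The detection shortfall (100 · (ref − panel)/ref over detected variants)
and the detected-fraction of a clinical cohort (100 · detected/sequenced)
use the same presentation rule.

**Sample-size planning.** The planning operation exposes two selectable
formulas — a closed-form one-sample normal approximation
(n = p(1−p)(z₁₋α/₂+z_power)²/d², at the most conservative p = 0.5 by
default) and the per-group two-sample comparison of
`stats::power.prop.test` — and records which was used. The historical
planning figure this workflow descends from cannot be attributed to a
specific test, so the operation makes no claim to reproduce it.

## The synthetic cohort generator

The generator replaces the study's patient data with a seeded emulation of
its statistical structure. Defaults are the study conditions, fixed once:

* **Cohort size** 399; **tumor-type mix** led by gastrointestinal (29%),
  hematologic (18%), lung (13%); **specimen mix** dominated by biopsies
  (64%).
* **QC strata**: the joint distribution of ΔCq band × terminal outcome,
  with cell probabilities taken as cell count / 399 (e.g. good-band
  detected 159/399); 37/399 of samples skip the ΔCq assay. Samples drawn
  into a failing outcome with a passing ΔCq band realise their failure at
  the library-size gate; band-fail samples that nonetheless sequenced carry
  the clinical-override flag. Cq triplicates are placed at the control mean
  plus the drawn ΔCq with mean-zero replicate noise, so the realised band
  is exact.
* **Gene spectrum** led by TP53 (28%), KRAS (16%), APC (10%), PIK3CA (8%)
  over 23 genes (normalised to sum to one); **consequence mix** 81/9/7%
  missense/stop-gain/frameshift with the minor in-frame/splice/start-lost
  classes (reported 2/1/1/1%) rescaled into the residual 3% mass;
  **clinical classes** 78% pathogenic / 19% VUS.
* **VAF range** [3.23%, 68.97%] (uniform), the observed detection range;
  **per-pool depth** log-normal centred on 2500× (sdlog 0.4), comfortably
  above the 500×/pool scale of real runs; **dropout** 2% per non-primary
  variant (zero-depth in one pool, exercising the both-pools rule);
  **strand-bias flags** 1%; **artifact calls** at 2% of sequenced samples,
  always defective (sub-3% VAF or single-pool) — the class of call the
  dual-pool design exists to suppress. Variant-positive samples carry
  1 + Poisson(0.9) variants, matching roughly 1.9 variants per positive
  sample.

All draws come from one seeded stream in a fixed order, so identical
configurations produce byte-identical files — the property the round-trip
and determinism tests pin down.

For the inter-laboratory design there are two generators. The truth-level
one emits the 48 × 3 outcome table directly with exact error injection
(`n_miss`, `n_fp`), so any 2×2 table can be realised. The call-level one
generates actual dual-pool call sets per outcome and injects *defects*
(single-pool, sub-3% VAF, sub-1000× depth, strand-bias) at `miss_rate`, and
clean spurious dual-pool calls at `fp_rate`; because a defect always fails
the PASS filter and a clean call always passes it, the planted operating
characteristics are exactly 1 − miss_rate and 1 − fp_rate, which is what
the end-to-end recovery check exploits. Detection there is defined as
carrying ≥ 1 PASS variant in KRAS/NRAS/BRAF — REVIEW calls need a human
and are deliberately not auto-detected.

**What the generator does not emulate**: read-level data (no FASTQ/BAM),
sequencing error models, FFPE deamination chemistry, inter-center batch
effects, correlated multi-variant haplotypes, and real genomic
coordinates. Passing tests therefore demonstrate the correctness of the
decision logic and statistics on data with the assumed structure — not the
wet-lab performance of any assay.

## Numerical and testing choices

* Thresholds are compared with plain floating-point comparisons; all gate
  inputs (percentages, bp, Cq) are far from precision limits.
* Ties/boundaries: TCC 30% passes, 10% enters the low band; ΔCq 4 and 6
  fall upward into the stricter class; library 300 and 330 both pass.
* Deterministic ordering everywhere a table is emitted (spectra by
  descending count then lexical value; coverage reports failures-first).
* Problem sizes in the test suite were chosen to keep the full run around
  a minute while leaving sampling-error margins honest: 10,000 randomized
  calls for the filter partition, 10,000 draws per Clopper–Pearson coverage
  scenario, a 2,000-sample cohort for mix recovery, and a 2,001-outcome
  (667 × 3) cohort for end-to-end sensitivity/specificity recovery within
  3 binomial standard errors.
* The acceptance script recomputes the headline validation interval by
  rebuilding the 144-outcome truth set with the observed 7 misses and 3
  spurious calls, tallying it, and inverting the sensitivity proportion
  80/87 — not by quoting numbers.

## Worked example

```{r example}
# A small simulated cohort, end to end
report <- run_pipeline(list(seed = 7, cohort = list(n_samples = 60),
                            validation = list(n_samples = 48, n_centers = 3,
                                              miss_rate = 0.08,
                                              fp_rate = 0.05)))
report$qc_summary
report$filter_counts
head(report$coverage)
tidy(report$concordance)
```

## Known limitations

* The panel manifest is topologically faithful but positionally synthetic;
  coordinate-dependent analyses (liftover, annotation joins) are out of
  scope.
* Clinical classification is passthrough; the package never queries
  variant databases.
* Reproducibility/repeatability coefficients and inter-rater agreement are
  not computed; the concordance module covers diagnostic accuracy only.
* The panel detects SNVs and small indels only — gene fusions and copy
  number are outside the assay's design, hence outside the model.
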