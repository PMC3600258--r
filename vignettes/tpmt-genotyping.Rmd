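---
title: "Allele-specific real-time PCR genotyping of TPMT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific real-time PCR genotyping of TPMT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmtqpcr)
```

## The assay and its interpretation model

Thiopurine S-methyltransferase (TPMT) inactivates thiopurine drugs;
patients carrying two nonfunctional *TPMT* alleles risk severe
myelosuppression at standard doses, and carriers of one such allele have
intermediate enzyme activity. The clinically dominant nonfunctional star
alleles are defined by three SNPs: c.238G>C (\*2), c.460G>A (\*3B),
c.719A>G (\*3C), with \*3A carrying c.460G>A and c.719A>G in cis.

The assay this package interprets is a duplex allele-specific real-time
PCR: for each SNP, each sample is run in two wells whose primers have a
3' terminus matching either the wild-type or the variant base. A matched
template amplifies on time; a mismatched one amplifies many cycles late
or never. Every well co-amplifies a *GAPDH* internal positive control
(IPC) on a second dye channel, so reaction failure is distinguishable
from true allele absence.

Interpretation is a threshold rule on the difference of threshold cycles
(Ct) between the two wells of a SNP:

* both wells amplified and $\Delta C_t = |C_t^{wt} - C_t^{var}| <$ 2
  cycles: heterozygote;
* $\Delta C_t \ge 2$: homozygote for the allele with the smaller
  (earlier) Ct;
* only one well amplified within 45 cycles: homozygote for that allele
  (the limiting case of a very large $\Delta C_t$; we record
  $\Delta C_t$ as 45 minus the defined Ct, floored at the threshold);
* neither amplified: no call (`NO_AMPLIFICATION`).

The 2-cycle threshold is principled rather than empirical: at perfect
doubling efficiency each cycle is a factor of 2, so 2 cycles correspond
to a $\ge$4-fold difference in amplifiable template — impossible for a
germline heterozygote, whose allelic ratio is 1:1. A $\Delta C_t$
*exactly* at 2 is therefore treated as evidence of imbalance
(homozygote). In practice the two classes are widely separated: in our
simulated validation panel all homozygous SNPs show $\Delta C_t > 8$ and
all heterozygous SNPs $< 1$, so the precise tie-break never decides a
real call.

A well's interpretation is gated on its IPC: the reaction counts as
successful only if the IPC crossed threshold strictly before cycle 30.
An IPC failure in either of a SNP's two wells voids that SNP only —
QC is per reaction, not per sample. DNA input below 5 ng/µL raises the
advisory `LOW_INPUT` flag without suppressing the call, because the
minimum input is a reproducibility requirement, not an interpretation
rule; unknown input raises `LOW_INPUT_UNKNOWN`.

## Ct estimation from raw curves

Instrument Cq algorithms are proprietary, so the package implements a
transparent classic procedure (`compute_ct()`):

1. **Baseline correction**: ordinary least squares line through cycles
   3–15 (cycles 1–2 excluded for settling artifacts), subtracted from
   the whole curve. This absorbs constant background and linear drift,
   making the estimate invariant to fluorescence shift and, with the
   auto threshold, to positive rescaling.
2. **Threshold**: 10× the baseline residual SD (the classic "10-sigma"
   rule), floored at $10^{-6}$ of the plate's maximum corrected
   fluorescence so noise-free curves still get a positive threshold.
3. **Crossing**: the first cycle at which the corrected signal reaches
   the threshold, stays above it for at least two consecutive cycles,
   *and keeps growing by at least 25% per cycle across the crossing*.
   The two-cycle guard rejects single-cycle noise spikes; the growth
   guard rejects the slow linear creep that an imperfectly fitted
   baseline leaves in late cycles (real amplification is exponential at
   threshold, growing $\sim e^k$ per cycle, so the 1.25 factor is far
   below any genuine crossing and far above any baseline artifact).
4. **Interpolation**: between the last sub-threshold and first
   supra-threshold cycle, on log fluorescence when both values are
   positive (the signal is exponential there, so log interpolation is
   unbiased; linear interpolation of a convex exponential would be
   systematically early), falling back to linear otherwise.

Against the simulator's closed-form crossing oracle, the estimator's
median absolute error at default noise is below 0.1 cycles (property
test over 1,000 curves). The residual error is dominated by
extrapolating the baseline fit ~15–25 cycles forward, which is inherent
to baselining from early cycles.

## Diplotype assignment and phenotype

Per-SNP genotypes are unphased, so the star-allele diplotype is obtained
by exhaustive enumeration over all unordered pairs of panel alleles; a
pair is consistent when, for every SNP, the number of pair members
carrying its variant is 0/1/2 for hom-wt/het/hom-var. For the default
panel the classic ambiguity is the double heterozygote c.460G>A +
c.719A>G: \*1/\*3A (cis) and \*3B/\*3C (trans) are indistinguishable.
Two resolution policies are implemented (`ambiguity_policy`):

* `prior` (default): rank by population prior product with a factor 2
  for heterozygous pairs (Hardy–Weinberg pairing). With the shipped
  priors (\*1 0.95, \*3C 0.03, \*3A 0.015, \*3B 0.0049, \*2 0.0001 —
  configurable defaults reflecting \*3C predominance in East Asian
  populations, **not** measured cohort values) the \*1/\*3A explanation
  wins with normalized score ≈0.99.
* `worst_case`: report the candidate with more nonfunctional alleles
  (\*3B/\*3C, poor metabolizer) — clinically conservative, since the two
  explanations differ in dosing consequence.

Either way the call is flagged ambiguous and all alternatives are kept
in the report with their scores and phenotypes. Phenotype is the count
of nonfunctional alleles mapped through the panel: 0 → normal, 1 →
intermediate, 2 → poor; any no-call SNP makes it indeterminate.

Note that not every abstract genotype vector is explainable: e.g.
hom-var at both c.238G>C and c.460G>A would require a haplotype carrying
both SNPs, which no declared allele does. Such vectors (biologically
implausible, and absent from any real pair of panel alleles) raise an
error rather than a silent call; the test suite enumerates all 27
genotype vectors against a brute-force oracle to pin down exactly which
are consistent.

## The simulator

The generative model (`sim_params()`, `simulate_well()`,
`simulate_panel()`) exists so every downstream module is testable
without instrument data. It emulates:

* **Copies→Ct law**: $C_t = A - \log_E(\text{copies}) + m\,[\text{mismatch}]$
  with intercept $A = 38$ cycles (Ct of one matched copy), efficiency
  $E = 2$, and mismatch penalty $m = 12$ cycles. $E = 2$ makes the
  "ΔCt 2 ⇔ 4-fold" identity exact; $m = 12$ comfortably reproduces the
  observed >8-cycle homozygote separation while keeping mismatched
  reactions visible within 45 cycles at typical input. Mismatch is a
  fixed penalty rather than per-cycle breakthrough kinetics — one
  falsifiable parameter that suffices for the separation behavior.
* **Detection**: each template copy independently seeds a detectable
  amplification with probability $p$ (binomial thinning; the Poisson
  low-template limit falls out, and $p = 1$ is exactly deterministic,
  which the recovery properties rely on). The binomial zero class is
  what produces detection failures in dilution series. Defaults:
  $p = 0.05$, with a per-SNP override of $0.01$ for c.719A>G. These are
  *calibrated, not measured*: they are chosen so the ≥95%-correct LOD
  of the default assay is $10^2$ copies/reaction and that of the less
  sensitive c.719A>G assay is $10^3$, and the LOD tests are regression
  tests of that calibration, not independent evidence.
* **Noise**: per-well Gaussian Ct noise (SD 0.15 cycles), IPC Ct ~
  N(24, 0.3²), per-reading fluorescence noise (SD 0.01 on a plateau of
  3 fluorescence units).
* **Curves**: baseline 0.5 + drift 0.002/cycle + logistic sigmoid
  (steepness k = 1.8/cycle) positioned so the noise-free corrected
  signal crosses the nominal threshold exactly at the well's model Ct;
  `crossing_cycle()` gives the closed-form crossing at any threshold
  and serves as the estimator's oracle.
* **Input conversion**: 1 ng/µL ≙ 1,000 copies/µL (the assay's stated
  calibration constant — higher than the ~300 copies/ng expected from
  3.3 pg/haploid genome; we take the stated constant as the default and
  expose it as `copies_per_ng` rather than resolving the discrepancy),
  and 5 µL template per reaction, so the validation panel's 10 ng/µL
  samples carry 5×10⁴ copies/reaction.
* **The validation panel preset** (`paper_panel_strata()`): 244
  patients (234 \*1/\*1, 10 \*1/\*3C) plus \*1/\*3B and \*1/\*3C
  reference cell-line DNAs, reproducing the published cohort
  composition, including its 2.05% (10/488) \*3C allele frequency among
  patients.

All randomness flows from one integer seed; a given seed reproduces
output files bit-identically.

What the simulator deliberately does **not** model: fluorophore spectral
crosstalk, plate-position and edge effects, PCR inhibitors (IPC failures
can only be injected, not emerge), primer-dimer artifacts, template
degradation, and non-logistic curve pathologies. Passing tests therefore
show the interpretation logic is correct *given* curves that look like
clean instrument output — they do not validate robustness to real-world
artifacts beyond the modeled noise.

## Validation statistics

`concordance()` scores exact per-sample genotype agreement against a
reference method (samples with any no-call are excluded from the
comparable set and listed). `allele_frequencies()` counts variant
alleles (2 per hom-var, 1 per het) over two alleles per called sample,
with exact Clopper–Pearson 95% intervals; percentages are rounded
half-even to two decimals, so 10/488 prints 2.05. `hwe_exact_test()` is
the exact conditional Hardy–Weinberg test (full enumeration of
heterozygote counts given the allele counts) — preferred over χ² because
expected minor-homozygote counts are far below 1 at these frequencies;
it is verified against an independent ratio-recurrence oracle to 1e-9.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full curve-level
pipeline on the complete 246-sample panel (1,476 wells, 2,952
45-cycle curves — a few seconds), 1,000-curve estimator accuracy sweeps,
20-replicate dilution series over 10⁷–10² copies/reaction, and
brute-force enumerations (15 allele pairs × 27 genotype vectors). These
sizes match the study design being emulated; nothing is scaled down.
`scripts/acceptance.R --seed N --out f.json` re-simulates the panel from
the given seed and recomputes the headline numbers from scratch.

## Known limitations

* The Ct estimator is a transparent reimplementation of common practice,
  not the instrument's proprietary algorithm; equivalence is asserted
  only against the simulator's analytic oracle.
* No inconclusive zone is implemented between the heterozygote and
  homozygote ΔCt regimes (the validated assay reported none); a
  borderline ΔCt near 2 is always called.
* \*6 (c.539A>T) ships commented out in the panel file and is off by
  default; enabling it requires wells for the extra SNP.
* Star-allele priors are configuration defaults for ambiguity ranking
  only; they should be replaced with population-appropriate values
  before clinical interpretation of ambiguous calls.
* The package interprets assays; it does not design primers/probes nor
  generate dosing recommendations.
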