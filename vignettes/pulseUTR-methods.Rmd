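---
title: "Methods: differential nascent proteomes and 5'-UTR translational features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential nascent proteomes and 5'-UTR translational features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseUTR)
```

## Scope and scientific background

`pulseUTR` analyses pulsed metabolic-labelling proteomics experiments of
the AHA-SILAC type: two genotypes (here called wild type and mutant, as
in studies of eIF2B-mutant astrocytes) are SILAC-labelled, pulsed with
the methionine analogue azidohomoalanine so that newly synthesised
proteins can be click-enriched, and quantified by mass spectrometry as
one mutant/wild-type ratio per protein per biological replicate. The
package starts **after** spectrum processing: its inputs are protein
ratio tables, transcript records, annotation flags and metabolite peak
tables. Raw MS acquisition, database search and peptide-level
quantification are out of scope by design.

Downstream of the differential calls, the package asks the questions a
translational-control study asks of its hit list: are
secretory-pathway proteins (signal peptide and/or transmembrane domain)
over-represented among regulated proteins, and do the 5'-UTRs of the
mRNAs encoding regulated proteins differ in length, GC content,
predicted structure (ΔG) or upstream open reading frame (uORF) burden?
A small metabolite screen (median normalisation, presence calls,
medium uptake/secretion) completes the pipeline.

Because studies of this kind often deposit no reusable accession, the
package ships a synthetic-data module that generates **every** input
with planted ground truth, so each stage is testable end to end.

## Differential synthesis calls

Each SILAC replicate yields one ratio per protein, so the test is a
two-sided one-sample t-test of the oriented log2(mutant/wt) ratios
against 0 with `n_detected - 1` degrees of freedom. Whether the
original Perseus analysis ran a one- or two-sample test is typically
unstated in such studies; the one-sample form is the one that matches
the ratio data model, and we adopt it as a documented choice.

* **Label-swap orientation.** In a label-swap design the isotope labels
  are reversed in half the replicates; `orient_ratios()` negates those
  columns so every column means log2(mutant/wt). The operation is
  idempotent and the analysis is equivariant under negating all values
  and flipping all flags.
* **Detection filter.** Proteins quantified in fewer than `min_reps`
  (default 3) replicates are routed to a `filtered` set, inclusive
  boundary. Missing values are encoded as absent cells, never zeros,
  because the filter counts presence.
* **Degenerate rows.** A row with fewer than two present values, or
  zero variance around a non-zero mean, cannot be tested and is
  reported (not dropped) as `degenerate` with undefined p. The exact
  all-zero row is the one zero-variance case with a well-defined
  answer (t = 0, p = 1, not significant) and is reported as such.
* **No multiple-testing correction drives the calls** — significance is
  the raw p < `alpha` (default 0.05), matching common practice for this
  assay; a Benjamini–Hochberg FDR column is emitted as supplementary
  output only.
* **Volcano conventions.** x is the mean log2 fold change (fold change
  2 ↦ 1) and y is −log10 p (p = 0.05 ↦ ≈ 1.301). Figure legends in the
  literature occasionally print other thresholds for the y-axis; the
  package always uses the mathematical value.

## Secretory-pathway targeting enrichment

Signal-peptide and transmembrane flags are **inputs** (produced
upstream by predictors such as SignalP or genome annotation); the
package never predicts them from sequence. A protein is
"SP-targeting" if it has a signal peptide OR a transmembrane domain,
counted once (union, inclusion–exclusion: `n_targeting = n_sp + n_tm −
n_both`).

Percentages are rounded half-up to one decimal. The **union
percentage** is computed as `pct_sp + pct_tm − pct_both` on the
*rounded* percentages rather than by rounding `100·n_targeting/n`.
This is deliberate: it is the only convention under which a
one-decimal summary table is internally consistent (the two differ in
the second decimal, e.g. 38/72 = 52.78 rounds to 52.8 but 37.5 + 33.3
− 18.1 = 52.7), and it matches how published tables of this kind are
assembled. The exact fractions are always emitted alongside.

Enrichment is tested with a Pearson chi-square on the 2×2 table of
disjoint groups (regulated vs non-regulated × targeting vs not); the
alternative comparison against all proteins including the regulated
ones is a one-line change of the contingency table. The Yates
continuity correction is exposed and off by default. Groups may
overlap in the descriptive summaries (up-regulated ⊂ regulated), so
group assignment is a mapping, not a partition.

## 5'-UTR features

The 5'-UTR of a transcript record is bases 1..`cds_start − 1`,
normalised to uppercase RNA (T → U). UTRs shorter than 13 nt are
excluded from all feature analyses (`reason = "min_length"`), because
start codons that close to the cap initiate inefficiently; the
boundary is inclusive at 13.

A uORF is operationally a **start codon with adequate context**, not a
complete ORF: a codon from {AUG, CUG, GUG, UUG, ACG} lying entirely
within the UTR, with a purine (A/G) at −3 and a G at +4 (numbering the
first codon base as +1). Choices worth making explicit:

* The context rule is applied to **all five** codons, not only AUG.
  Near-cognate starts are only plausible initiators in strong context,
  and the rule object (`uorf_rule()`) makes the AUG-only alternative a
  one-argument change.
* No in-frame stop codon is required — the operational definition is
  start + context only.
* Candidates with i < 4 (no −3 base on the transcript) are **not**
  counted: the required context cannot be evaluated, and counting
  unverifiable candidates would be anti-conservative.
* The +4 base may fall at or beyond the CDS start (it is read from the
  full transcript); the codon itself must be fully upstream.
* All three frames are scanned and overlapping hits all count; `N`
  never matches any codon or context position.
* All coordinates at every interface are 1-based inclusive.

GC content is `100·(#G + #C)/length` with `N` counted in the
denominator only.

## Folding model (ΔG proxy)

Published analyses of UTR structure typically use an external
thermodynamic folding server. A full nearest-neighbour
parameterisation is out of scope here; instead the package ships a
documented simple pair-energy model: each GC pair contributes −3, AU
−2, GU −1 (model units, symmetric), every pair must enclose at least 3
unpaired bases, and the minimum total energy over all pseudoknot-free
structures is found by the classical O(n³) dynamic programme with
traceback (implemented in C++). Consequences to keep in mind:

* **Absolute ΔG values are not comparable to thermodynamic
  predictions.** Only within-run contrasts (regulated vs non-regulated
  distributions under the same model) are meaningful. The folding
  backend behind `compute_features()` is pluggable (`fold_model`
  argument), so a thermodynamic folder can be substituted.
* Traceback ties are broken deterministically (pairing the left end
  with the smallest optimal partner is preferred over leaving it
  unpaired), so output is reproducible.
* The exhaustive enumeration oracle `brute_force_mfe()` (no
  memoisation, guard at 22 nt) validates the DP exactly in the tests.
* A symmetric pair model is symmetric under sequence **reversal**; it
  is *not* generally symmetric under reverse complement, because a GU
  pair maps to AC, which cannot pair. Tests assert the reversal
  symmetry.
* Sequences longer than `max_length` (default 5000 nt) are refused,
  never silently truncated.

## Variant-proportional group comparison

A protein translated from k mRNA variants contributes each variant
with weight 1/k, so proteins with many variants do not skew the group
histograms. k is recomputed **after** the 13-nt exclusion, so weights
always sum to 1 per protein (whether the original analyses recomputed
k is unstated; the alternative is a trivial variation and conservation
of mass per protein seemed the more defensible invariant). Proteins
with no included variant are excluded with a message.

Length histograms use the published bins [13, 150), [150, 550],
(550, ∞) — "short" is < 150, "long" is > 550, boundary values stay in
the middle bin. uORF counts use the integer bins 0..7 and "8 or more".
Exact bin edges for published chi-squares are rarely printed; these
are taken from the accompanying text and exposed as configuration.

Two comparison methods are provided:

* **`permutation` (default).** The Pearson chi-square statistic is
  computed on the *unrounded* weighted counts and its null is built by
  shuffling group labels over proteins (variants travel with their
  protein); p = (1 + #{perm ≥ obs}) / (1 + n_perm). This is the
  statistically proper treatment of fractional weights.
* **`chi-square-rounded`.** Weighted counts are rounded half-up to
  integers and the ordinary chi-square test applied. This mirrors
  summary-table practice and is provided for comparability; it is not
  recommended for inference.

The permutation stream is seeded, proteins are put in canonical
(sorted) order before permuting, and the statistic is symmetric in the
two groups, so p-values are invariant to group label names and to
input row order.

## Metabolite screen

* **Median normalisation** scales each sample so all sample medians
  (over detected, i.e. nonzero, metabolites) equal the global median of
  sample medians. Per-sample (not per-metabolite) normalisation is the
  standard reading of "normalised on median peak intensity"; the
  operation is idempotent and zeros are preserved.
* **Presence calls** (cell compartment): a metabolite is detected in a
  genotype at a timepoint if at least `min_fraction` (default 1,
  "consistently detected") of replicates exceed the threshold; a
  genotype is called positive when detected at *every* timepoint, and
  the pattern (both / wt-only / mutant-only / neither) derives from the
  two genotype calls. The default threshold — half the smallest
  nonzero normalised intensity — and the replicate fraction are
  configuration, since assays of this type report direction but not
  cutoffs.
* **Uptake/secretion** (medium compartment): mean conditioned-medium
  intensity per genotype versus the unconditioned reference, with a
  default 20% relative margin; below → consumed, above → secreted,
  else unchanged.

## What the synthetic generator emulates — and what it does not

Defaults encode the structure of the motivating study type: 1240
quantified proteins, ~6.5% regulated with 90% upward bias
(`up_bias = 0.9`, i.e. 72 of 80 up), log2 effect 1, replicate noise SD
0.25, four replicates with labels reversed in two, 10% missing cells;
regulated-up UTR lengths log-normal around ~450 nt versus ~180 nt for
unregulated and ~133 nt for down-regulated (down-regulated transcripts
in such studies are reported with short UTRs, median ≈ 133); uORF
planting rates 2.5 / 1.0 / 0.5 per UTR (up / null / down); annotation
flag probabilities matching the observed group marginals; and one
metabolite present only in mutant cells at both timepoints, with four
consumed and four secreted medium metabolites at 3-fold shifts. Medium
samples use n = 2 replicates (as such screens report) and cell samples
n = 3, a typical size where none is stated; LC-MS replicate intensity
noise is log-normal with σ = 0.15 (CV ≈ 15%, realistic for peak
intensities).

Each generator draws from its own named substream of the master seed,
so generators are mutually independent and the whole study is
byte-reproducible.

Features of real data **not** emulated: protein-level presence
heterogeneity (missingness here is i.i.d. per cell, whereas real
detectability is protein-driven), peptide-to-protein roll-up noise,
correlated replicates, database-version-dependent transcript sets,
real UTR sequence composition (generated UTRs are i.i.d. nucleotides
at fixed GC outside planted motifs), nearest-neighbour folding
thermodynamics, and chromatography/identification artefacts in the
metabolite screen. Passing tests therefore demonstrate correctness of
the algorithms and calibration of the statistics under the stated
generative model — not that the biological conclusions of any real
study follow.

## Numerical and edge-case conventions

* Rounding is half away from zero wherever one-decimal percentages are
  produced (base `round()` is round-half-even).
* uORF planting overwrites 7-nt motifs (−3 purine | codon | +4 G) at
  non-overlapping positions ≥ 3 nt from the 5' end, so every planted
  start is scannable; re-scanning finds all planted starts plus any
  incidental ones.
* The variants-per-protein distribution is a truncated geometric
  (p = 0.5, cap `variants_per_protein_max`): most proteins have one
  variant, a minority several, which matches annotation databases
  qualitatively; no study states this distribution.
* Sensitivity ("recovery") of the differential test is measured among
  planted proteins that pass the replicate-detection filter: a protein
  missing from ≥ 2 of 4 replicates is unreachable by any test, and its
  loss is an (intended) property of the filter, which is tested
  separately. The unconditional rate is also reported by the
  acceptance script.
* Simulation sizes used in the checks: null calibration with 5000
  proteins; effect recovery with 2000; UTR feature detection with 200
  regulated vs 200 non-regulated proteins over 20 seeded repeats with
  999-permutation tests; scanner/folder oracle sweeps over 500 and 300
  random sequences. Folding is skipped (`fold_model = NULL`) in the
  large feature simulations, where the compared features are length
  and uORF burden.

## Known limitations

* The ΔG proxy ranks structured vs unstructured UTRs but its absolute
  values are model units; any statement about thermodynamic stability
  of a real transcript set requires dropping in a thermodynamic folder.
* Chi-square on weighted counts ("paper mode") is improper for
  fractional weights; use the permutation default for inference.
* The uORF definition is a context-qualified start codon; analyses that
  require a complete upstream ORF (with stop) will count fewer uORFs.
* Presence calls use a hard threshold; borderline intensities flip the
  pattern and the `consistent_across_timepoints` flag should be
  consulted.
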