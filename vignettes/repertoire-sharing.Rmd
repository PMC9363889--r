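---
title: "Methods: quantifying clonal sharing between BCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying clonal sharing between BCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repshare)
```

## The analysis model

`repshare` treats a sequenced BCR heavy-chain library as a multiset of
*molecules*: each unique molecular identifier (UMI) attached before
amplification marks one input mRNA molecule, and PCR duplicates of that
molecule collapse to a single count. A *clone* within a sample is the
set of molecules sharing a CDR3 nucleotide sequence together with the V
and J gene call; its frequency is its molecule share of the sample.
Quantifying on molecules rather than raw reads removes amplification
bias, which matters particularly for plasma-cell-rich tissue where BCR
mRNA expression per cell can differ by a factor of 5–50.

Three assumptions are built in:

* UMI collisions (one UMI on two different clone keys) are split into
  distinct molecules. This is conservative, order-independent, and
  avoids inventing a majority rule. No UMI error correction is applied;
  `collapse_umis()` is a pluggable stage if 1-mismatch merging is ever
  needed.
* Gene calls are compared at gene level (allele suffixes stripped on
  input, configurable off), since clone identity is defined by the
  recombined gene, not the allele call of the aligner.
* For *cross-sample* matching the clone key is reduced to the CDR3
  alone (`project_to_cdr3()`). Somatic hypermutation diversifies the
  rearrangement outside the CDR3 between compartments, so requiring V/J
  equality across samples would split genuinely clonally related
  sequences. Within-sample keys keep V and J.

Whether CDR3 matching should be at nucleotide or amino-acid level is a
genuinely open choice; nucleotide is the default (it is the stricter
criterion and does not require translated input), and `mode = "aa"` is
available throughout.

## Depth standardization

Clone counts and overlap statistics depend strongly on sequencing
depth, so every sample is reduced to a common depth before any
statistic is computed. `subsample_repertoire()` draws exactly `depth`
molecules uniformly *without replacement* (clone counts are
multivariate hypergeometric); the default depth is 9,736 molecules.
Summaries and similarity indices are computed only after this step —
standardizing first is what makes the 0.5% dominance threshold mean the
same thing in every sample. Samples below the target depth are an error
by default (`shallow_policy = "keep_all"` opts out, leaving the sample
flagged unstandardized and excluded from pairwise comparison, because
similarity estimates at unequal depth are not comparable).

Seeding is hierarchical: one master seed, with each sample's draw
seeded by `derive_seed(master, sample_id)`. Adding a sample to a cohort
therefore never changes the subsample drawn for any other sample.

## Highly expanded clones

A clone is *highly expanded* (HEC) when its post-standardization
frequency is at least 0.5%, boundary inclusive. At depth 9,736 this is
a floor of 49 molecules (49/9736 ≈ 0.503%; 48 molecules ≈ 0.493% does
not qualify). `summarize_repertoire()` reports the clone count, HEC
count and *HEC impact* — the summed HEC frequency as a percentage,
i.e. how much of the repertoire the dominant clones occupy.

## Pairwise similarity

**Top-N clonal retrieval** takes each sample's N most expanded
CDR3-projected clones (default N = 25) and reports the percentage of
keys common to the two lists. With both lists of fixed size the measure
is symmetric. Ranking ties at position N are broken deterministically:
molecule count descending, then CDR3 in C-locale lexicographic order —
reproducibility across platforms and locales is worth more than any
particular tie convention. If a repertoire has fewer than N clones the
overlap is computed over the largest common list size, with a warning
and the effective N recorded.

**The Chao-modified Sørensen index** estimates total-repertoire
similarity while correcting for shared clones missed by finite
sampling. From the shared clone counts it forms U (estimated relative
abundance in A of clones shared with B) and V (symmetric), each a raw
shared-abundance sum plus a correction term driven by the
singleton/doubleton counts of shared clones, and returns 2UV/(U+V).
Numerical conventions, all surfaced in the returned components so
alternates can be audited:

* a zero doubleton count in the correction denominator is replaced by 1
  (the convention used by the standard implementations of this
  estimator family);
* U and V are capped at 1 before forming the index;
* no shared clones gives index 0 exactly, with no 0/0.

The bias-corrected form is the default; `variant = "uncorrected"`
drops the correction terms, since published analyses do not always
state which form was used. The test suite pins the estimator to an
independent brute-force evaluation (tolerance 1e-12) and to the U/V
components implied by `vegan`'s abundance-based Chao index.

**Overlap-plot data** places every clone of a pair's union at its two
frequencies (percent); clones absent from one sample sit at a
pseudo-frequency floor of half the minimum representable frequency
(0.5/depth) and are flagged not-detected — the floor is a display
convention only and never enters any statistic.

Comparison classes are assigned from the manifest: two ST biopsy sites
of one joint (`ST_ST_within_joint`), ST across joints
(`ST_ST_between_joints`), ST vs SF of the same joint (`ST_SF`), ST or
SF vs blood (`ST_PB`, `SF_PB`). Samples are never compared across
patients: clone identity is private to a patient.

## Group statistics

`compare_groups()` and `anova_tukey()` map comparisons to standard
tests — unpaired Mann–Whitney U, paired t, one-way ANOVA with Tukey's
multiple comparison — delegating the computation to base R. All tests
are two-sided with significance at p < 0.05; a per-call choice of test
is deliberate because the appropriate test depends on the pairing
structure of the comparison, not on the metric. Paired comparisons with
zero-variance differences are flagged degenerate and report no p-value.
No multiple-testing correction is applied beyond Tukey within an ANOVA
family. One-tailed variants are not provided by default; where a
one-sided test is wanted the caller can halve the reported two-sided p
only when the observed direction matches the prior hypothesis.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the pipeline targets:
per patient, two ST biopsy sites in each of two joints, SF from the
first joint, and PB. Its defaults are calibrated to the repertoire
profiles of inflamed-joint compartments at depth 9,736 — ST with about
1,337–1,420 observed clones, ~30 HECs covering ~50–55% of molecules;
SF with ~2,188 clones; PB with ~5,407 clones, ~5 HECs and ~16% HEC
impact.

Construction, per sample:

* **Dominant head.** `hec_target` clones receive total frequency
  `hec_mass`. Dispersion among them comes from a per-clone
  amplification factor drawn from `plasma_amplification_range`
  (default 5–50, the plausible span of BCR mRNA expression between
  B cells and plasma cells) in ST/SF; frequencies are then clipped from
  below at `hec_floor` (0.7%, comfortably above the 0.5% detection
  threshold) by iterative water-filling, so the configured number of
  dominant clones survives subsampling.
* **Tail.** The remaining mass follows a Zipf distribution
  (exponent 0.4) over a pool whose size is solved numerically so that
  the *expected number of observed clones* at the calibration depth
  equals the configured `richness`. With this exponent the largest tail
  clone stays below 0.5% in every default compartment, so HEC counts
  are controlled by the head alone.
* **Sharing.** Each patient has a master pool of dominant
  inflammation-associated clones. A joint inherits master clones with
  probability g, a sample inherits its joint's clones with probability
  s, SF with probability u, and PB directly from the master pool with
  probability b. These are solved from the user-facing pairwise
  parameters so that the probability that a dominant clone of one
  sample is dominant in its partner equals `rho_within_joint` for two
  sites of a joint (s²), `rho_between_joints` for any ST pair across
  joints (s²g²), `rho_st_sf` (s·u) and `rho_blood` (s·g·b). The
  hierarchy implies `rho_between_joints ≤ rho_within_joint` (and the
  analogous root constraints), which the configuration validates. The
  default rhos (0.17, 0.09, 0.08, 0.10) reproduce the observed mean
  top-25 retrieval ordering across comparison classes.
* **Identity hygiene.** CDR3s (length 30–60 nt, multiples of 3) embed a
  patient tag and a batch tag, so clones can never collide across
  patients or between a sample's private clones and another sample's —
  chance-overlap baselines are exactly zero by construction rather than
  approximately small. UMIs are 12-nt index encodings, collision-free
  within a sample. Each molecule carries a raw-read multiplicity
  (1 + Poisson) so UMI collapse has work to do.

Everything is reproducible from the master seed, with patient- and
sample-level streams derived from it. Default molecules per sample is
20,000 (the pre-standardization depth is otherwise unconstrained by the
analysis; 15,000–30,000 is the realistic range for this library type).

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: somatic hypermutation (no clonal
lineages or mutated CDR3 variants), sequencing error, UMI errors,
isotype structure, and shared *rare* clones (sharing is modelled for
dominant clones only, so the generator's Chao-Sørensen values are
conservative relative to repertoires whose tails also overlap).

## Validation problem sizes

The test suite validates the estimators against independent oracles
(brute-force Chao evaluation on 100 random count tables; exact
Mann–Whitney enumeration at group sizes ≤ 8; naive group-by for UMI
collapse) and the pipeline against the generator's ground truth:
frequency unbiasedness of subsampling over 200 seeded draws; a sharing
sweep rho ∈ {0, 0.25, 0.5, 0.75, 1} with 20 seeds per point on
single-joint ST pairs, checking monotonicity of both overlap metrics
and the zero-sharing chance bound (100·N/richness); and 20 replicate
two-patient cohorts at the default configuration, checking the
compartment calibration targets and the within-joint ≥ between-joint ≥
blood ordering. These sizes keep the full suite in a few minutes while
leaving Monte-Carlo standard errors well inside the asserted margins.

## Known limitations

* Clonal relatedness by similarity (hypermutation-aware lineage
  clustering) is out of scope; identity is exact CDR3 (+V/J) match.
* The Chao-Sørensen estimator is undefined in spirit when one
  repertoire is empty; the implementation errors rather than returning
  a value.
* `recover_parameters()` reports realized (not nominal) sharing, since
  a finite cohort's Bernoulli draws make the two differ.
* Light-chain pairing and single-cell resolution are outside the data
  model.
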