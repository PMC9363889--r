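# repshare

Clonal sharing analysis of B-cell receptor (BCR) repertoires across
immune compartments.

## The problem

In chronic joint inflammation such as rheumatoid arthritis, B-cell
clones expand locally in synovial tissue (ST), circulate into synovial
fluid (SF), and appear at low frequency in peripheral blood (PB). A
central question for receptor-targeted therapy is whether *different*
inflamed sites in the same patient are dominated by the *same* B-cell
clones. `repshare` implements the quantitative repertoire workflow used
to answer that question from UMI-annotated BCR heavy-chain
rearrangement data:

1. **Clonotype calling.** Reads are collapsed by unique molecular
   identifier (UMI) into molecules; a clone is a unique CDR3 sequence in
   combination with its V and J gene. Molecule counts, not raw read
   counts, quantify clones.
2. **Depth standardization.** Every sample is subsampled without
   replacement to a common depth (default N = 9,736 molecules) so
   richness and overlap statistics are comparable.
3. **Highly expanded clones (HECs).** Clones at within-sample frequency
   ≥ 0.5% (inclusive) are called HECs; their count and combined
   frequency ("HEC impact") summarize clonal dominance.
4. **Pairwise sharing.** Within each patient, samples are compared by
   **top-25 clonal retrieval** (percentage of one sample's 25 most
   expanded clones that are also in the partner's top 25, matched by
   CDR3 alone) and by the **Chao-modified abundance-based Sørensen
   index**.

For shared clone counts X_i (sample A, depth n) and Y_i (sample B,
depth m), the estimator computes

    U = Σ X_i/n + ((m−1)/m) · f₊₁/(2·f₊₂) · Σ_{Y_i=1} X_i/n
    V = Σ Y_i/m + ((n−1)/n) · f₁₊/(2·f₂₊) · Σ_{X_i=1} Y_i/m

where f₊₁/f₊₂ count shared clones that are singletons/doubletons in B
(f₁₊/f₂₊ in A), a zero doubleton count is replaced by 1, U and V are
capped at 1, and the index is 2UV/(U+V) ∈ [0, 1]. The correction terms
estimate the relative abundance of shared clones missed by incomplete
sampling.

A calibrated synthetic cohort generator (`generate_cohort()`) produces
multi-patient, multi-compartment repertoires with known ground-truth
sharing, so the whole pipeline is testable without sequencing data.

## Worked example

```r
library(repshare)

cohort   <- generate_cohort(cohort_config(n_patients = 2, master_seed = 42))
analysis <- analyze_cohort(cohort$samples, cohort$manifest, seed = 42)
analysis
```

```
<repertoire_analysis> 12 samples at depth 9736, 30 pairs

Per-compartment summary:
  group n    mean       sd
1 ST_SP 4 1345.75 10.68878
2 ST_IP 4 1422.50 11.56143
3    SF 2 2193.50 12.02082
4    PB 2 5375.00 39.59798

Top-N retrieval by comparison class:
                 group n mean       sd
1   ST_ST_within_joint 4 18.0 5.163978
2 ST_ST_between_joints 8 12.5 4.503967
3                ST_SF 4  9.0 6.000000
4                ST_PB 8  2.0 2.138090
5                other 4  3.0 3.829708
6                SF_PB 2  0.0 0.000000
```

Reading the output: each compartment's clone count after
standardization to 9,736 molecules (synovial tissue ~1,300–1,400 clones,
blood ~5,400), then the mean top-25 clonal retrieval per comparison
class. Two biopsy sites of the same joint share the most dominant
clones (18% of the top 25), contralateral joints somewhat fewer
(12.5%), and blood almost none (2%) — dominant synovial clones are
patient-specific and tissue-resident. The same ordering holds for the
Chao-Sørensen index on the full repertoires
(`aggregate_stats(analysis$overlaps, "chao_sorensen",
"comparison_class")`).

File-based workflows use `simulate_cohort()` / `run_pipeline()` (or the
thin CLI in `inst/scripts/repshare.R`), which read AIRR Rearrangement
TSVs plus a sample manifest and write summary, overlap, comparison and
overlap-plot tables with a JSON provenance record.

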