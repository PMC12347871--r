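# cmaMRD

Biomarker discovery from chromosomal microarray (CMA) segment calls for
**MRD-positive remission in adult B-ALL**.

Patients with B-cell acute lymphoblastic leukemia who remain positive for
minimal residual disease (MRD) after induction therapy are at high risk of
relapse. CMA profiles each leukemic genome as segments of copy-number gain,
(mosaic) loss, and copy-neutral loss of heterozygosity (cnLOH). This package
implements the full analysis path from raw segment tables to candidate
biomarker regions, for analysts working with SNP-array data in hematologic
malignancies:

1. **Segment QC** — validity filters per event class (markers ≥ 50 for
   cnLOH and gains, ≥ 20 for losses; |mean log2 ratio| > 0.25 for
   copy-number events) and landscape size filters (> 500 kb CNV,
   > 5 Mb cnLOH).
2. **Gene-by-event encoding** — binary features `"GENE:event"`, set on any
   ≥ 1 bp overlap between a QC-passed segment and a gene; mosaic losses
   merge into `loss`.
3. **Random-forest ranking** — stratified k-fold cross-validated accuracy
   and normalized Gini importance; feature direction (risk vs favorable)
   from group carrier frequencies.
4. **Permutation test** — B label shuffles; the reported significance is
   the add-one estimator

   p = (1 + #{null ≥ observed}) / (B + 1),

   whose attainable minimum at B = 1000 is 1/1001 ≈ 0.001.
5. **Univariate validation** — two-sided Fisher exact test
   (point-probability convention) per feature, sample odds ratio ad/bc with
   Haldane–Anscombe correction, Benjamini–Hochberg adjustment.
6. **Cluster detection** — chains of same-event, genomically contiguous
   top genes (gap ≤ 1 Mb, ≥ 5 genes), labelled by cytoband.
7. **Matched reference** — triple sex/age-matched healthy pool as a
   population frequency baseline, with per-feature Fisher comparison.
8. **Synthetic cohorts** — a generator that reproduces the assumed study
   layout (17 MRD⁺ / 18 MRD⁻ patients, 105-member reference pool, three
   planted aberration clusters, background noise), so the entire pipeline
   is testable without any protected data.

The methods vignette (`vignettes/cma-mrd-workflow.Rmd`) documents the
model, every tunable parameter and the design decisions.

## Worked example

```r
library(cmaMRD)
res <- runPipeline(simConfig = SimulationConfig(), outDir = "run1",
                   seed = 1, model = ModelConfig(nPermutations = 200,
                                                 seed = 101))
#> [simulate] 35 patients, 105 references, 205+571 segments
#> [qc] 205 patient segments retained
#> [encode] 83 features x 35 samples
#> [classifier] observed accuracy 0.742, p = 0.0199
#> [stats] 83 features tested, 3 cluster(s)
#> [match] mean |age diff| 0.99 years

res$clusters[, c("label", "event", "n_genes", "freq_mrd_pos",
                 "freq_mrd_neg", "freq_reference")]
#>              label event n_genes freq_mrd_pos freq_mrd_neg freq_reference
#> 2            16q13  loss      12    0.3529412   0.00000000      0.0000000
#> 1 19q13.2-19q13.31 cnLOH      12    0.8235294   0.27777778      0.4190476
#> 3           7p22.3  loss      12    0.6470588   0.05555556      0.0000000

res$permutation
#> PermutationResult: observed accuracy 0.7417, 200 permutation(s), p = 0.0199
#>   null accuracies: min 0.158 / median 0.504 / max 0.825
```

Reading the output: the simulated cohort carries three planted recurrent
lesions, and the pipeline recovers all three as co-localized clusters with
the correct event types. The 19q13-like cnLOH cluster is frequent in
MRD-positive patients (14/17 here), present at an intermediate rate in the
healthy reference pool (~0.42), and rarer in MRD-negative patients — the
signature of a population-polymorphic region that is nevertheless enriched
with poor treatment response. The two loss clusters ride on broad
subclonal arm-level deletions and are absent from the reference pool. The
classifier's cross-validated accuracy (0.74 in this run) sits above the
entire bulk of the permutation null (p ≈ 0.02 at 200 permutations; more
permutations sharpen the attainable minimum). All stage outputs
(`importance.tsv`, `feature_stats.tsv`, `clusters.json`, `matching.tsv`,
`reference_comparison.tsv`, `summary.json`, `manifest.json`) are written
to `outDir`.

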