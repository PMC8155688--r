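# cnasig

Discriminative copy-number aberration (CNA) signatures for cancer subtypes,
from segmented copy-number profiles.

Tumor genomes accumulate gains and losses of chromosomal segments. Most of
that landscape is shared — passenger noise plus near-universal events such as
whole-arm losses — and says little about what distinguishes one cancer type
from another. `cnasig` extracts the *discriminative* part: it bins segment
data onto cytobands and genes as amplification/deletion channel features,
trains a denoising autoencoder on the normalized feature matrix, scores each
input feature by layer-wise relevance propagation (LRP) from the learned
encoding,

```
R_j = sum_k [ a_j w_jk / (b_k + sum_j' a_j' w_j'k) ] R_k
```

aggregates per-feature relevance over all samples, and thresholds it into a
compact feature panel (cytobands first, then the genes of the selected
bands). Downstream, the package derives per-subtype signatures — panel genes
whose alteration frequency in an ICD-O (topography, morphology) group
significantly exceeds the cohort background (one-sided binomial,
Benjamini–Hochberg) — merges subtypes whose signatures correlate at Pearson
r > 0.9 within an organ, partitions panel genes into focal features and
regional groups by 5-Mb adjacency merging, and trains a class-balanced
random forest that predicts subtype (and organ of origin, by mapping
predicted subtype labels). A cohort simulator with full ground truth makes
every stage testable offline.

Intended users: computational cancer-genomics groups working with
platform-independent segment data (log2-ratio segments with ICD-O-coded
sample metadata) who want discriminative CNA features and subtype
signatures rather than recurrence peaks.

## Worked example

A three-sample fixture small enough to check by hand:

```r
library(cnasig)

fx <- toy_fixture()          # 3 samples, 2 chromosomes, 7 segments
fm <- build_matrix(fx$segments, fx$cytobands)
as.data.frame(fm)
#>   sample_id 1p__amp 1p__del 1q__amp 1q__del 2p__amp 2p__del 2q__amp 2q__del
#> 1        S1     0.5    0.00    0.00       0     0.0    0.00       0       1
#> 2        S2     0.5    0.00    0.50       0     0.0    0.00       0       0
#> 3        S3     0.0    0.25    0.05       0     0.2    0.15       0       0
```

Each value is the coverage-fraction-weighted |log2 ratio| on one channel:
sample S1's +0.5 segment spans all of band 1p, so `1p__amp = 0.5`; S3's
+0.25 segment covers one fifth of 1q, so `1q__amp = 0.05`.

The full pipeline on the built-in synthetic cohort (6 subtypes across 3
organs, 150 samples each, on a 300-bin toy genome; runs in minutes on one
CPU):

```r
co  <- simulate_cohort(default_scenario())
qc  <- qc_filter(co$segments, co$metadata[, 1:4])
tg  <- co$config$genome
tp  <- run_two_phase(qc$segments, tg$cytobands, tg$genes,
                     ae_config(seed = 101))
extraction_summary(tp)
#> # A tibble: 4 × 4
#>   phase  step   representation n_channel_features
#> 1 phase1 input  cytobands                     600
#> 2 phase1 output cytobands                     298
#> 3 phase2 input  genes                         900
#> 4 phase2 output genes                         275
```

Phase 1 reduces 600 cytoband channel-features (300 bins × amp/del) to a
selected panel; phase 2 re-runs the extraction on the genes of the selected
bands. On this scenario the panel recovers every planted
subtype-discriminative locus. Signatures, merging, and classification:

```r
groups <- group_subtypes(qc$metadata, min_samples = 50)
merged <- merge_subtypes(groups, tp$gene_matrix, tp$gene_panel,
                         r_threshold = 0.9)
head(merged$signatures, 3)
#> # A tibble: 3 × 6
#>   label        gene   channel frequency intensity  q_value
#> 1 C34.9|8070/3 G2.26B amp         0.753     0.380 7.74e-31
#> 2 C34.9|8070/3 G2.27A amp         0.733     0.672 3.30e-45
#> 3 C34.9|8070/3 G2.28A amp         0.733     0.688 3.62e-47

ds <- make_dataset(tp$gene_matrix, merged$groups, merged$signatures)
cv <- cross_validate(ds, k = 5, seed = 11)
glance(cv)
#> subtype macro-F1 ~0.97, organ macro-F1 ~0.97 on the synthetic cohort
```

Each signature row reads: in subtype `C34.9|8070/3` (lung, squamous-cell
morphology), gene `G2.27A` is amplified in 73% of samples at mean normalized
intensity 0.67, against a far lower cohort background (q ≈ 1e-45). Genes on
the simulated ubiquitous arms — altered at equal frequency in every subtype
— never enter any signature.

A stage-chaining runner with a YAML config and manifest is available as
`run_pipeline()` (CLI wrapper in `inst/cli/cnasig.R`), writing every
artifact (panels, signatures, feature groups, confusion matrices) as TSV.

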