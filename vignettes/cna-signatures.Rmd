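---
title: "Discriminative CNA signatures: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative CNA signatures: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cnasig)
```

# The problem

Somatic copy-number aberrations (CNAs) — gains and losses of genomic
segments — accumulate in tumors and differ between cancer types. Most CNA
analyses characterize tumors by the coverage of known driver genes or
recurrent focal peaks; that view is blind to the long tail of less frequent
but type-specific aberrations, and it is dominated by changes that are so
common across cancers (whole-arm losses, hallmark deletions) that they say
little about what a sample *is*. `cnasig` takes the complementary view: find
the features of a copy-number landscape that make a sample or a subtype
*distinguishable*, build per-subtype signatures from them, and test how far
those signatures identify cancer subtype and organ of origin.

The pipeline has five stages, each usable on its own:

1. **segio** — read and validate segment tables, sample metadata (ICD-O-3
   morphology/topography codes), cytoband and gene annotations; sample-level
   QC.
2. **featmat** — map segments onto cytobands or genes as a samples ×
   channel-feature matrix, amplifications and deletions as separate
   channels, normalized to [0, 1].
3. **hybrid model** — train a denoising autoencoder on the matrix, score
   every input feature by layer-wise relevance propagation (LRP) from the
   learned encoding, aggregate and threshold into a feature panel; run
   twice (cytobands, then the genes of the selected cytobands).
4. **signatures / feature groups** — per-subtype signatures of
   significantly altered panel genes; correlation-based merging of
   redundant subtypes; partition of panel genes into focal features and
   regional groups by 5-Mb adjacency.
5. **classifier** — class-balanced random forest predicting subtype, with
   organ of origin obtained by mapping predicted subtype labels.

A synthetic cohort simulator with complete ground truth drives all tests.

# Input assumptions

Segment files are tab-separated (`sample_id`, `chromosome`, `start`, `end`,
`value`), one row per contiguous segment, with `value` a normalized log2
ratio: positive = amplification, negative = deletion, 0 = neutral. The
package assumes input already lifted to a single genome build and
amplitude-normalized; those preprocessing steps belong to upstream tools and
are out of scope here. Coordinates are 0-based half-open everywhere
internally; both `chr8` and `8` chromosome dialects are accepted and
normalized to bare names (1–22, X, Y; the mitochondrial genome is not
supported). Overlapping segments within one sample are a hard error rather
than being silently merged: normalized input should be disjoint, and silent
merging would hide upstream faults.

QC removes samples with fewer than `min_segments` segments (default 3,
inclusive threshold) and — when `require_codes` is set — samples lacking
either ICD-O code. Both rules are configurable; every rejection is logged
with a reason (`too_few_segments`, `incomplete_diagnosis`, `no_metadata`).

# The feature matrix

For feature $f$ (a cytoband or a gene) and channel $c \in \{\text{amp},
\text{del}\}$, the raw value for a sample is

$$x_{f,c} \;=\; \sum_{s\,:\,\mathrm{sign}(s) = c}
\frac{|s \cap f|}{|f|}\,\bigl|\log_2\text{-ratio}(s)\bigr|,$$

the coverage-fraction-weighted aberration load. This captures both the
extent and the amplitude of overlap, is additive over disjoint segment
sets, and is invariant to splitting a segment into abutting pieces — all
properties the test suite checks. Amplifications and deletions are kept as
separate channels because their amplitude distributions differ and the
model should be free to weight them independently.

Each channel is normalized to [0, 1] by dividing by the channel's q-th
percentile over all its entries and clipping (default `q = 99`, robust to
single outlier segments; `q = 100` gives exact max-division and is used in
exact-arithmetic tests). Normalization is per cohort and per channel, not
per sample: relative amplitudes between samples are informative and should
survive scaling.

# The hybrid feature extractor

## Denoising autoencoder

The extractor trains a small fully connected autoencoder: encoder
`input → input/2 → input/8`, decoder mirrored, rectifier (ReLU) activations
on hidden layers and the encoding, sigmoid output (matching inputs in
[0, 1]). Training minimizes mean squared reconstruction error of the
*clean* input from a *masked* copy — each presentation independently zeroes
a fraction `noise_fraction = 0.2` of entries — with Adam (learning rate
1e-3), batch 64, 200 epochs, and decoupled weight decay 1e-3. The denoising
objective is what makes the bottleneck informative: a masked feature can
only be restored from its correlated partners, so the encoding concentrates
on co-occurring structure (subtype-specific aberration blocks) rather than
on isolated noise. Weight decay complements it by shrinking input weights
that carry no reconstruction information toward zero; without decay such
weights persist at their random initialization scale and pollute the
relevance ranking. A plain (non-denoising) autoencoder is available via
`variant = "basic"`.

Everything is seeded: weight initialization (Glorot uniform), epoch
shuffles, and masking all derive from `config$seed`, and two runs with one
config are bit-identical. Training runs on base R matrix operations; at the
problem sizes this package targets (hundreds to a few thousand features,
hundreds to thousands of samples) a desk-scale CPU run takes minutes, and a
deliberately compact exact implementation beats an opaque dependency for
auditability.

## Layer-wise relevance propagation

LRP distributes a quantity defined at the encoding back to the inputs with
the basic propagation rule

$$R_j \;=\; \sum_k \frac{a_j w_{jk}}{b_k + \sum_{j'} a_{j'} w_{j'k}}\, R_k,$$

where $a$ are activations, $w$ weights, and the bias enters the denominator
as the index-0 term. For bias-free networks the rule conserves total
relevance at every layer exactly (a property the tests verify to 1e-6
relative, against a brute-force implementation that materializes every
$a_j w_{jk}$ share, to 1e-8).

Two numerical/semantic choices matter and were made deliberately:

* **Stabilizer.** When a denominator's magnitude falls below `epsilon`, a
  term of matching sign is added. A token epsilon (1e-9) only prevents
  division by zero; empirically, near-zero denominators produce heavy-tailed
  per-sample relevances (isolated samples contributing thousands of times
  the median) that dominate any summed aggregate. The shipped default is
  `epsilon = 0.01`, the classic LRP-epsilon role of absorbing relevance that
  flows through weak activations; `epsilon = 0` remains available and is
  what the conservation tests use.
* **Initial relevance.** The pipeline propagates each sample's encoding
  *deviation from the cohort-mean encoding* (`reference = "mean"`), not the
  raw activation vector. The encoding is interrogated for what
  distinguishes samples; a unit whose activation is near-constant across
  the cohort carries none of that information, and propagating raw
  activations would hand the largest summed relevance to whatever is
  common, not to what is discriminative. `lrp_relevance()` defaults to raw
  activations (`reference = "none"`) so the propagation rule itself can be
  tested in its textbook form; `run_two_phase()` uses the mean reference.

Relevance is computed from the clean (uncorrupted) input. Per
channel-feature, absolute relevances are summed over all samples — absolute,
so amplification- and deletion-channel contributions of opposite sign
cannot cancel — and divided by the maximum, giving weights in [0, 1].

## Selection and the two-phase run

Features with normalized weight ≥ `threshold` are selected (default 0.1;
boundary ties all kept; raising the threshold can only shrink the set). A
`top_fraction` mode is available for a count-based reading of the same
step. Phase 1 runs on cytobands — a mid-resolution binning correlated with
gene density and chromosome structure — and phase 2 re-runs the identical
machinery on the protein-coding genes of the selected bands (a gene belongs
to the band containing its midpoint, so boundary-straddling genes are
assigned exactly once). Per-phase seeds derive from the run seed.

## What the extractor can and cannot exclude

On the canonical synthetic scenario the extractor recovers essentially all
planted subtype-discriminative features. Shared ("ubiquitous") aberrations
— present at high frequency in every subtype — are a harder case, and it is
worth being precise about what the method achieves:

* Deviation-referenced relevance plus a meaningful epsilon ranks
  discriminative features *above* ubiquitous ones (the top of the ranking
  is discriminative).
* Full exclusion at the default threshold is **not** achieved for shared
  events whose carrier frequency (0.9) and normalized amplitude are
  comparable to discriminative events. The reason is structural, not a
  tuning artifact: the summed-|relevance| aggregate gives any presence/
  absence bit a mass proportional to $2p(1-p)\,n\,s$ per encoding unit,
  which for $p = 0.9$ is within a small factor of a discriminative block's
  ($p \approx 0.12$ cohort-wide) regardless of architecture; spreading an
  event over many bins dilutes per-feature relevance only by roughly the
  square root of its width, because a coherent block also earns
  proportionally larger encoding activations. An unsupervised
  reconstruction objective has no further signal with which to tell
  "frequent everywhere" from "frequent in one subtype" at a 10× margin.
* Where the exclusion *does* hold, robustly and by construction, is one
  stage later: a feature at equal frequency in every subtype can never pass
  the signature test's requirement that the subtype's alteration frequency
  exceed the cohort background. In every canonical run, zero genes from the
  shared arms appear in any subtype signature. That is the operational
  sense in which ubiquitous aberrations are "non-typical" for this
  pipeline: they do not survive into signatures, classifiers, or feature
  groups.

# Subtype signatures

Samples are grouped by (topography, morphology); groups under 50 samples
are dropped (strict `<`, so exactly 50 survives). For every selected
(gene, channel), the group's alteration count (samples with nonzero
normalized value) is tested against the cohort-wide background alteration
frequency with a one-sided exact binomial test, Benjamini–Hochberg adjusted
within the group; entries with $q < 0.05$ *and* group frequency above
background form the signature, with intensity the group mean of the
normalized values. "Significantly altered" admits many formalizations; this
one is conventional, exactly computable (no asymptotics at group size 50),
and — as the type-I simulation in the test suite shows — calibrated:
random cohort subsamples yield a non-empty signature in well under 5% of
draws.

Signature similarity is Pearson correlation over the union of the two
signatures' entries with absent entries at intensity 0, so both membership
and intensity differences matter. Within each organ, the pair with the
highest correlation strictly above 0.9 is merged — the more specific
morphology (by an explicit parent-map hierarchy, since ICD-O code strings
do not reliably encode generality) absorbed into the more general; at equal
or unknown level the larger group wins, with lexicographic tie-breaks — the
merged signature is regenerated, and the process repeats. Greedy
highest-first merging with deterministic tie-breaks makes runs reproducible
and terminates in at most $n - 1$ merges per organ; afterwards no surviving
within-organ pair correlates above the threshold.

For reporting, signatures are clustered by average-linkage hierarchical
clustering on correlation distance ($1 - r$), and gene-family enrichment of
the panel uses a one-sided binomial test of each family's panel count
against its background proportion, reported when $p < 0.05$ and at least 5
panel genes belong to the family.

# Focal and regional feature groups

Panel genes of one channel are swept left to right per chromosome; a gene
joins the open group when the gap from the previous member's end to its
start is at most 5 Mb (inclusive; "within 5 Mb" is read as genomic distance
between the elements, with a center-to-center option available). Singleton
groups are focal features; larger groups are regional. The sweep provably
equals a union-find transitive closure over all pairs — the suite checks
1,000 random instances including exact-boundary distances. Per subtype, a
group's amplitude is the mean normalized value over member genes × subtype
samples. Amplification and deletion panels are grouped independently.

# Classifier

Features are the signature genes' normalized intensities; labels are the
post-merge subtypes. Classes are rebalanced to the median class size —
larger classes sampled without replacement, smaller with replacement; no
synthetic interpolation, so every training row is a bit-exact copy of a
real sample — and a 500-tree random forest (ranger, √p features per split,
mandatory seed) is trained. Organ predictions are the subtype predictions
pushed through the subtype → organ map, which makes the organ confusion
matrix exactly the subtype confusion aggregated by that map.

Evaluation is stratified 5-fold cross-validation on the *original* samples
with balancing applied inside each training fold only; resampled duplicates
can therefore never leak into a test fold. This is the minimal defensible
protocol when oversampling is in play. Reports pool predictions over folds:
per-class precision/recall/F1, macro-F1, accuracy, and the correlation of
per-class F1 with class size.

# The simulator and what passing tests mean

`simulate_cohort()` generates cohorts with three event layers: per-archetype
discriminative aberrations (independent Bernoulli carriage per sample,
normal amplitude with the channel's sign, normal boundary jitter truncated
to the chromosome), shared ubiquitous aberrations applied to every
archetype, and Poisson passenger segments with log-uniform sizes at
length-weighted random positions. Overlaps within a sample are resolved by
letting the larger-|value| event keep the contested bases, preserving the
non-overlap invariant without inventing subclonal mixing. Truth tables
record every planted event and the expected channel-features per archetype.

The canonical scenario (`default_scenario()`): 6 archetypes across 3 organs
(two sibling subtypes per organ) × 150 samples on a 300-bin toy genome (6
chromosomes × 50 × 1 Mb). Each archetype carries 4 focal discriminative
aberrations (2 bins wide, amplitude 0.8 ± 0.15, carrier 0.7) on the q arm
of its own chromosome. Three ubiquitous events — emulating the arm-level
losses and gains that are near-universal in real tumor cohorts — each span
a full 25-bin p arm at one-copy amplitude (0.5 ± 0.1), carrier 0.9, shared
by all archetypes. Passengers arrive at rate 10 per sample, 0.2–20 Mb,
amplitude N(0, 0.4) with sub-0.05 values dropped as unobservable. Amplitude
and span values are the package's own choices of realistic magnitudes
(high-level focal events vs one-copy arm-level events); carrier
frequencies, archetype counts, and the genome size define the scenario.

What the simulator does *not* model — tumor purity, subclonality,
allele-specific copy number, platform-specific noise spectra, waviness, or
correlated passenger structure — bounds what green tests mean: they
demonstrate the pipeline's mechanics (recovery of planted discriminative
structure over passenger noise, calibration of the signature test,
determinism), not performance on real tumor profiles.

# Problem sizes and numerical choices

The suite and the acceptance script run the canonical 900 × 600 scenario
once and share it; the pipeline-determinism check uses a reduced cohort (6 ×
40 samples, 25 epochs), since determinism is scale-free. These sizes were
chosen so a complete run stays comfortable on a single desktop CPU.
Degenerate inputs are handled explicitly: all-zero channels stay zero under
normalization; an all-zero relevance aggregate is an error rather than a
silent NaN; correlation of empty signatures returns NA with a warning;
empty gene panels abort the two-phase run with a "threshold too strict"
error. Ties are deterministic everywhere (boundary ties in selection are
kept; merge ties break lexicographically; resampling and folds derive from
explicit seeds).

# Known limitations

* Ubiquitous-event suppression at the extractor stage is partial (ranked
  below discriminative features but above the default threshold when
  carrier frequency and amplitude rival discriminative events); their
  exclusion is guaranteed only at the signature stage. See the discussion
  above.
* The autoencoder is a compact dense MLP; very large feature spaces
  (whole-genome gene-level phase 1) would need minibatched BLAS or
  compiled code.
* ICD-O morphology generality requires a user-supplied parent map; no
  ontology is bundled.
* The simulator's independence assumptions (aberrations independent within
  archetype, passengers uniform) are simplifications; real cohort structure
  is richer.
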