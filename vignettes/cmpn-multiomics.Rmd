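---
title: "Isolating mPR-specific CCM1 signaling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating mPR-specific CCM1 signaling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmpnomics)
```

This vignette is the package's own account of its methods: the statistical
procedures, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design choices made where the
underlying analysis left them open.

## The analysis in one paragraph

Paired proteomic (iBAQ intensity) and RNA-seq (count) profiles of mouse
embryonic fibroblasts across three CCM1 genotypes (wild-type WT, knockout
KO, knockin KI96) and progesterone treatments (vehicle VEH vs combined
progesterone + mifepristone, PRG_MIF) are reduced to per-genotype
differentially expressed feature sets, Venn-partitioned, and passed through
two subtractive filters: features whose response tracks CCM1 protein
dosage, and features responding to progesterone through receptors other
than the membrane progesterone receptor (mPR) — the glucocorticoid receptor
and nuclear progesterone receptor, which share mifepristone as an
antagonist. What survives is read as the mPR-specific, CCM1-mediated
response; it is characterized by hypergeometric over-representation
analysis and mined for transcription-factor candidates with a
cost-sensitive SVM over fixed-length sequence embeddings.

## Differential expression

Each feature is tested with a two-sided two-sample *t*-test on
log2-transformed values. Defaults and rationale:

* **Welch vs Student** (`de_config(test=)`, default `"welch"`): the source
  analysis states only "*t*-tests". With three replicates per cell,
  variance equality is unverifiable, so the unequal-variance test is the
  safer default; the pooled-variance test is available and is what the
  worked examples in the test suite verify against closed-form values.
* **No multiple-testing correction, α = 0.05**: deliberate fidelity to the
  basal-statistics convention of the analysis being reimplemented.
  Multiplicity is handled only at the enrichment stage (BH across terms).
  Consequently ~5% of null features are expected to be called per
  contrast; the set-algebra and filtration stages operate on that premise.
* **Log scale and zeros**: whether the original tests ran on raw,
  normalized or log intensities is unstated; this package documents and
  fixes one choice — log2 after normalization. Counts receive a
  pseudo-count of 1; proteomic zeros are treated as missing for that
  feature/sample pair, and a group with fewer than two observed values
  renders the feature untestable (`p = NA`).
* **Fold-change threshold** (`log2fc_min`, default 0): the source mentions
  fold change "by category" with no cutoff, so the default classifies by
  direction only.
* **Degenerate variance**: identical constant groups give `t = 0, p = 1`;
  separated constant groups give `p = 0`.
* **Normalization**: `median_center` (default; per-sample log2 median
  becomes 0, appropriate for intensities) or `library_size` (columns
  rescaled to the mean library size, appropriate for counts); both
  preserve ids and non-negativity.

## Venn partitioning and percentages

`venn_partition()` decomposes a 2- or 3-set family into its exhaustive
`2^k − 1` disjoint regions, ordered singles → pairs → triple. Two
conventions are load-bearing:

* **The denominator is an explicit argument.** Published Venn percentages
  for these data mix denominators — total identified proteins (1059) in
  some figures, filtered totals (876, 18, 6424, 103) in others. Inferring
  it silently would be wrong half the time, so the caller must state it,
  and it must be at least the union size.
* **Rounding is half-up to one decimal** (`round_half_up()`), which
  reproduces every published percentage from its printed count and
  denominator; banker's rounding does not in general.

## Two-step filtration

`two_step_filtration()` is subtraction by two fixed feature-id filters:
layer 1 (CCM1-dosage-dependent features) then layer 2 (non-mPR antagonist
responses). Since both are set differences by fixed sets, the composite is
order-independent — a property the test suite checks on random families —
but the report attributes removals in the stated order, so
`removed_layer1`/`removed_layer2` counts do depend on order; interpret them
as "removed at this step", not "attributable only to this filter".

Two open points in the source analysis were resolved as follows. First,
how the dosage comparison was converted into a removable set is not
specified; this package supports both granularities — feature ids here, and
term-id exclusion filters in the dot-plot stage — and the pipeline uses
DE features from genotype contrasts in the vehicle arm as layer 1. Second,
the antagonist filter derives from a different species and cell line
(human U2OS vs mouse fibroblasts), so `filter_spec()` defaults to
case-insensitive gene-symbol matching; this is a documented caveat, and
exact matching is available (the synthetic pipeline uses it, since
generated ids are exact).

## Over-representation analysis

For a query of annotated size `n` against a universe of size `N`, a term
with `K` members in the universe and `k` query hits is scored
`p = P(X ≥ k)`, `X ~ Hypergeometric(N, K, n)` — upper tail only, since
only over-representation is reported. Conventions:

* **Universe** = all identified features of the modality, not the genome,
  matching the "out of the total identified proteins" framing.
* **`n`** counts only query members annotated to at least one term (after
  intersecting term members with the universe); `N` is the full universe
  size. GeneRatio is `k/n`, the dot size in comparative plots.
* **Adjustment**: the source says only "adjusted"; Benjamini–Hochberg is
  the field default and is applied within each collection category (GO and
  KEGG separately), with Bonferroni available.
* `comparative_dotplot()` integrates per-condition results, marks terms
  enriched in more than one condition as shared, and flags terms hit by
  named term-id exclusion filters — the tabular equivalent of the
  "highlighted, then eliminated" pathway-filtering convention.

## Transcription-factor prediction

The predictor follows the shape: fixed-length standardization → embedding →
cost-sensitive SVM → stratified 10-fold cross-validation → consensus.

* **Standardization** (default 1000 residues): truncation keeps the
  N-terminus; padding appends `X` at the C-terminus. The source states the
  length but not the ends; N-terminal retention is the common convention
  and is fixed here.
* **Embeddings are pluggable.** Protein-language-model encodings enter as
  external per-sequence tables (`featurize(backend = "external_table")`);
  the model itself is out of scope (pretrained weights and GPU inference
  exceed desk scale). The built-in featurizer — 20-dim amino-acid
  composition concatenated with 3-mer frequencies hashed into 400 buckets,
  L2-normalized, `X` skipped — preserves the method's shape for testing
  and is not a claim about embedding quality.
* **Costs**: `cost(c) = total / (n_classes · count(c))`, so at the
  benchmark composition (2784 NTF / 954 TF) the TF:NTF cost ratio is
  2784/954 ≈ 2.92. Kernel defaults to linear (typical for high-dimensional
  embeddings); RBF is available.
* **Consensus**: "approximately 50% of testing epochs" is read as the
  fraction of held-out evaluations (each record is held out once per CV
  round; `repeats` rounds average the indicator). The boundary is
  inclusive: fraction ≥ threshold (default 0.5) is a candidate.
* **Metrics**: `F1 = 2TP/(2TP+FP+FN)`, `specificity = TN/(TN+FP)`,
  `sensitivity = TP/(TP+FN)`, `balanced accuracy` their mean — verified as
  identities on random confusion matrices.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical structure the analysis assumes*,
not the biology:

* **Design**: 3 genotypes × treatments × 3 biological replicates (the
  study's replication), 2000 proteomic and 8000 RNA features by default —
  the order of a quantified fibroblast proteome/transcriptome scaled to
  desk size.
* **Proteomics**: log-normal intensities; per-feature log2 baseline
  uniform on [20, 30] (an iBAQ-like dynamic range), replicate noise
  Gaussian with σ = 0.5 log2 units (a typical intensity CV). No
  distribution is stated for the real data; these are free knobs, chosen
  once, not estimates.
* **RNA**: negative-binomial counts with common dispersion 0.1, mean
  `2^U(3,12)`.
* **Planted effects**: 10% of features per contrast shifted by ±2 log2
  units (sign random per feature); treatment-responsive features are split
  50/50 into mPR-specific vs non-mPR ("antagonist") — a bookkeeping flag
  that exists so the antagonist filter can be generated with a known
  coverage and guaranteed disjointness from the mPR-specific set.
* **Missingness** is off by default (a missing-at-random mask is
  available): the source never describes imputation, so tests do not rely
  on it.
* **TF benchmark**: 2784/954 NTF/TF composition; TF sequences carry a
  synthetic 7-mer motif (`CKRPLHC`, an arbitrary marker, not a real
  DNA-binding domain) planted in three non-overlapping copies, emulating
  the tandem domain arrays typical of transcription-factor families and
  giving a signal the bag-of-3-mers featurizer can detect reliably over
  200–600-residue backgrounds; NTF sequences are motif-free uniform
  background.

Hence passing tests demonstrate *procedural correctness and statistical
calibration* — exact set algebra, exact hypergeometric tails, nominal
type-I control, monotone power, recoverable planted structure — not that
the pipeline would reach the same biological conclusions on the
unreleased measured data. Real proteomes have correlated features,
batch structure, heavy-tailed noise and informative missingness, none of
which are simulated.

## Numerical and reproducibility choices

* All randomness flows from integer seeds; generators restore the caller's
  RNG state, and stage sub-seeds are derived arithmetically from the
  master seed, so `run_pipeline()` output directories are byte-identical
  across reruns with the same config.
* Percentages: half-up rounding at one decimal, as above.
* Hypergeometric tails are computed as `P(X ≥ k)` via the exact
  distribution function; the test suite certifies equality with exhaustive
  draw enumeration to 1e-12 on all universes up to size 12.
* Problem sizes in the test suite (e.g. 5000-feature null calibration,
  500-feature power curves, a 3738-sequence CV) were chosen as the
  smallest sizes at which the checked properties are statistically
  unambiguous.
* Degenerate inputs fail loudly with classed errors: overlapping DE
  groups, groups smaller than 2, denominators smaller than the union,
  single-class CV input, empty sequences, all-zero library columns.

## Known limitations

* The two filters are applied as exact (or case-folded) id subtraction;
  no orthology mapping is attempted for cross-species filters.
* ORA uses flat term lists — no ontology DAG propagation, no term
  de-duplication.
* The DE stage is deliberately plain (no moderation or dispersion
  shrinkage), inheriting the uncorrected-*t*-test convention of the
  analysis it reimplements; it should not be used as a general-purpose DE
  tool where FDR control at the feature level matters.
* The built-in sequence featurizer is a testing vehicle; for real TF
  discovery, supply protein-language-model embeddings via the external
  table backend.
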