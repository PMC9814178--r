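---
title: "Quantitative MGS profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MGS profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgsquant)
```

# The problem

Shotgun gut-metagenome case-control studies usually compare *relative*
taxon abundances. Relative abundances are compositional: a change in total
microbial load, or a bloom of a single taxon, shifts every other taxon's
relative abundance without any real change in how many cells of it are
present per gram of stool. `mgsquant` implements a quantitative profiling
pipeline that (i) turns read mappings into gene-level frequencies, (ii)
quantifies metagenomic species (MGS) pangenomes from marker genes, (iii)
rescales them by a flow-cytometry cell-count index into absolute
abundances, and (iv) runs rank-based case-control statistics with explicit
confounder handling on top. A synthetic-data generator with planted ground
truth makes every stage testable without access to sequencing data.

# From reads to gene frequencies

**Read attribution.** A read mapping uniquely to one catalogue gene counts
1 for that gene. A read mapping with equal best score to several genes is
split across its candidates proportionally to the candidates' *unique*
counts in the same sample. This is a single pass: the shared mass never
feeds back into the unique counts (the rule describes one attribution
step, not an EM iteration). When every candidate has zero unique counts
the read is split equally — the only symmetric choice that still conserves
total mass. Attribution therefore conserves reads exactly: each sample's
column sums to its record count.

**Rarefaction.** Columns are downsized to a fixed depth (default
configurable; desk-scale runs use 10^3–10^5, a production run of real data
would use 12 million) by sampling read-equivalents *without replacement*,
i.e. a multivariate hypergeometric draw. Attributed counts are fractional,
so each column is first integerized by the largest-remainder method, which
preserves the rounded column total and perturbs each gene by less than one
read-equivalent. Samples below the target depth are dropped and logged.

**Frequencies.** Counts are divided by gene length (nt) and renormalized
to sum to 1 per sample. The usual FPKM scale constants (per-kilobase,
per-million) cancel in that normalization and are deliberately omitted.
Gene richness is the number of genes with strictly positive frequency.

# MGS quantification and the cell-count index

An MGS abundance is the mean frequency of its declared marker genes
(nominally 100; the mean includes undetected markers as zeros). If
strictly fewer than 10% of the markers are detected the abundance is set
to 0 — the threshold is a strict inequality, so exactly 10% detected
counts as seen. The synthetic catalogue may declare fewer than 100
markers; the 10% rule always applies to the declared count.

The cell-count index of a sample is its measured cells-per-gram divided by
the mean over the *measured* samples; missing measurements get index 1
(logged per sample), so uncounted samples stay on the cohort-average
scale. Multiplying relative MGS abundances by the index yields absolute
abundances; a scale tag on the matrix guards against applying the
correction twice. Aggregation to higher ranks sums member MGS on whichever
scale is supplied, pooling MGS unclassified at a rank into
`unclassified_<parent>` bins. Richness only uses positivity, which a
strictly positive index cannot change, so relative and absolute richness
agree by construction.

# Functional modules

A module is an ordered list of components; each component is a set of
alternative annotation ids and is satisfied by *any* of them (module
grammars with alternative orthologs require this; the strict
complement/optional-reaction grammar of full GMM definitions is not
modelled). A module is core-present in an MGS when at least 90% of its
components are covered by core-gene annotations; the threshold is
inclusive, so 9 of 10 components is present. Presence is then refined per
sample by adding the accessory genes detected in that sample — a
monotone operation, so core presence is never lost where the MGS is
detected, and an MGS with zero abundance in a sample carries nothing
there. The module potential of a sample is the summed abundance of the
carrier MGS; it is bounded by the total community abundance.

Coverage is a ratio of small integers compared against 0.9, so the
comparison uses a 1e-9 epsilon to keep 9/10 robust to floating-point
representation.

# Statistics

Two-group contrasts use the Mann-Whitney test: exact when both groups
have at most 25 observations and no ties, the tie-corrected normal
approximation (with continuity correction) otherwise. More than two groups
use Kruskal-Wallis. Effect sizes are Cliff's Delta, computed from joint
ranks (an O(n log n) identity equal to the pairwise sign sum, ties
contributing zero). Multiplicity is controlled by Benjamini-Hochberg
step-up, one family per feature space (all MGS together; each module
database separately); significance defaults to q <= 0.1 with a secondary
p <= 0.05 tier in correlation panels. Spearman panels use average-tie
ranks and the t-approximation for p-values; cells with fewer than 4
complete pairs or a constant vector are reported as missing with a
warning.

Demographic contingency tables use Pearson chi-squared. The Yates
continuity correction is applied to 2x2 tables only — reproducing the
published sex contrast (p = 0.91) requires it, while the 2x3 smoking
contrasts (p = 3.5e-06 and p = 0.43) require it off, and this is exactly
R's conventional behaviour too.

**Adjusted richness.** "Richness adjusted for covariates" is implemented
as ordinary-least-squares residualization on an intercept plus the
covariates (one-hot categoricals, reference dropped), plus the grand mean
so the values stay on the richness scale. The source description names no
formula; residualization is the most common reading, it is linear,
deterministic, and flagged prominently here as a design choice. A
collinear design is an error naming the degenerate columns rather than a
silent drop.

# Deconfounding labels

The three-label contract — *strictly deconfounded*, *ambiguously
deconfounded*, *confounded* — is re-derived here, not ported from any
existing implementation. A feature is first screened against status and
each covariate with type-matched tests (two-level: Mann-Whitney;
multi-level: Kruskal-Wallis; continuous: Spearman), BH-adjusted within
each covariate's family. Features whose status association has q above
the threshold are *not significant*. Otherwise, for every flagged
covariate C the rank-transformed feature is fitted against nested linear
models: status is retained against C when adding status to
(intercept + C) improves the fit by a likelihood-ratio test at p <= 0.05,
and symmetrically for C against status. Status retained against every
flagged covariate (vacuously, if none) gives strictly deconfounded; some
C retained while status is not gives confounded; anything else —
neither model separates the two — is ambiguous. Because the feature
enters through its ranks, the labels are invariant to monotone transforms,
consistent with the nonparametric screen. Both thresholds (naive q <= 0.1,
nested p <= 0.05) are configurable.

# Beta diversity and ordination

Bray-Curtis dissimilarity is computed on `log10(a + pc) - log10(pc)`, so
zeros map to zero and the transform is non-negative. The pseudocount `pc`
is half the smallest non-zero abundance of the matrix by default — small
enough not to drown real signal, large enough to keep the transform
finite — and is recorded on the result; it is configurable, and a
regression test pins the behaviour of a fixed triplet under halving it.
An all-zero sample has no defined dissimilarity and is an error, not a
silent NaN.

PCoA is classical metric scaling (double-centred -D^2/2,
eigendecomposition, coordinates scaled by the square root of the positive
eigenvalues); negative eigenvalues are reported but never used for axes.
PERMANOVA uses the standard one-factor pseudo-F from total and
within-group sums of squared distances, with freely permuted labels (no
strata — matching one-factor usage), seeded, and the observed statistic
included in the reference set: p = (1 + #{F_perm >= F_obs}) / (1 + n_perm).
Pairwise PERMANOVA runs each group pair's sub-matrix and BH-adjusts across
pairs. Alpha diversity offers richness, Shannon entropy (natural log) and
Chao1; Chao1 refuses non-integer input because singleton and doubleton
counts are meaningless on continuous abundances.

# The synthetic world

The generator emulates every input the pipeline consumes. Its defaults are
fixed once and are not tuned to test outcomes:

* **Pangenomes:** 100 MGS of 150 genes (80% core, 100 markers — the
  nominal marker count; the miniature test worlds shrink both), lengths
  uniform on 300–3000 nt, matching typical prokaryotic gene lengths.
* **Abundances:** per-MGS log-normal baselines (sd 1.5 on the natural-log
  scale across MGS, per-sample noise sd 1.0) — heavy-tailed abundance
  distributions are the norm in gut metagenomes. The source study does not
  publish its abundance distributions, so these are documented defaults,
  not estimates.
* **Planted effects:** `n_da_mgs = 10` of 100 MGS carry a status effect of
  `effect_log2fc = 2` (4-fold, alternating direction) on the absolute
  scale.
* **Planted confounder:** BMI shifts by 0.8 standard deviations between
  groups (the size of the published CA/CNA BMI difference) and drives
  `n_confounded_mgs = 5` MGS at 1.5 log2 units per BMI standard deviation.
* **Cell counts** are proportional to each sample's total absolute
  abundance with 5% log-normal measurement noise; 5% of samples lose their
  measurement to exercise the impute-to-1 rule.
* **Reads:** multinomial over genes with probability proportional to gene
  length times MGS abundance; a configurable fraction are shared records
  (2–3 equal-score candidates, same MGS with probability 0.5). There is no
  base-level error model: alignment is out of scope, so reads are
  identities, not sequences.

**Total-load semantics.** `load_ratio` has two modes. `"global"`
multiplies every taxon of a case sample by the ratio: composition is then
exactly invariant, which gives the clean closed-form behaviour (relative
unchanged, absolute 2-fold) used by the unit tests. But a uniform
multiplier cannot produce a compositional artifact — if nothing changes
relatively, relative-scale tests stay null. Real load differences are
taxon-driven, so `"driver"` mode concentrates the load excess on a
designated high-abundance driver block, scaled so the expected case:control
total-load ratio equals `load_ratio`. In driver mode every other taxon's
relative abundance is suppressed in cases while its absolute abundance is
unchanged — the textbook artifact — and the acceptance suite demonstrates
that the cell-count correction restores nominal error control where the
relative-scale analysis is systematically fooled. Offering both modes
resolves a genuine tension between the closed-form scaling property and
the artifact demonstration: one mechanism cannot satisfy both.

All randomness flows from the single `seed` through stage-specific derived
seeds; identical configuration and seed reproduce every artifact
byte-for-byte, with no global RNG state left behind.

# What a green test does and does not establish

The synthetic world validates the pipeline's arithmetic and its
statistical calibration: read conservation, recovery of planted effects,
FDR control, confounder labelling, and the compositional-artifact
correction. It does **not** establish performance on real data: there is
no alignment error, no strain-level variation within an MGS, no chimeric
or contaminant reads, marker genes are exactly as declared, and cell
counts track the true load with small noise. Conclusions about real
cohorts inherit all the usual caveats of those simplifications.

# Numerical choices and degenerate inputs

* Shared-read fallback with all-zero unique counts: equal split.
* Rarefaction: largest-remainder integerization, then sequential
  hypergeometric draws (exact multivariate hypergeometric, O(genes) per
  sample, no giant expansion).
* Detection thresholds: strictly positive abundance throughout; the 10%
  marker rule strict, the 90% module rule inclusive (with a 1e-9 epsilon).
* Mann-Whitney: exact only for tie-free samples with both n <= 25.
* BH: NA p-values pass through without shrinking the family of the rest.
* Chi-squared: Yates correction clamped so identical rows give exactly 0.
* PERMANOVA p can never be 0: the observed statistic is in the reference
  set.
* Errors, not guesses, for: all-missing cell counts, all-zero samples in
  Bray-Curtis, non-integer Chao1 input, collinear adjustment designs,
  degenerate nested-model ranks, unknown gene ids in mappings.

# Known limitations

Marker selection from correlation structure, catalogue construction,
alignment, and functional annotation of genes are all upstream of this
package and taken as given. The deconfounding labels follow a stated
convention, not a published algorithm, and "ambiguously deconfounded" in
particular is this package's operational definition. The activity
analysis defines clinical activity purely from relapse counts (CA >= 1,
CNA = 0 over follow-up). Figure rendering is out of scope; every result
is a plain table.
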