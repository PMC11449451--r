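---
title: "Profiling auxin responses across plant generations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling auxin responses across plant generations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxphase)
```

# Scope and scientific background

Land plants alternate between a haploid gametophyte and a diploid sporophyte
generation, and the hormone auxin regulates development in both. In ferns
such as *Ceratopteris*, both generations are free-living, which makes it
possible to ask whether properties of the transcriptional auxin response —
which genes respond, how strongly, and through which promoter elements —
track the developmental phase (generation) or the species' phylogenetic
position. auxphase implements the downstream computational toolkit for that
comparison: promoter-element syntax analysis, differential-expression (DE)
response profiling, cross-species set comparison in orthogroup space, and
two quantitative morphometric assays. A seeded synthetic-data generator
reproduces the statistical structure each analysis assumes, so the whole
pipeline is testable end to end without any external data.

The package deliberately starts *downstream* of read mapping and DE model
fitting: DE tables (e.g. DESeq2 exports), orthogroup tables (e.g.
OrthoFinder output) and vein feature-point counts are consumed, not
produced.

# Promoter windows

Auxin response factors (ARFs) act through auxin-response elements (AuxREs)
in promoters. The unit of sequence analyzed per gene is the interval from
600 bp upstream of the transcription start site (TSS) to either the
translation start site or 1 kb downstream of the TSS, whichever is closer —
a window that captures the proximal promoter plus any 5' UTR without
running far into coding sequence.

Conventions, fixed once:

* Internal coordinates are 0-based, half-open; GFF3 (1-based, inclusive) is
  converted on parse; BED output is 0-based half-open. One convention
  everywhere removes a whole class of off-by-one errors.
* Multi-transcript genes collapse to the first-listed transcript, ties
  broken by smallest transcript id. Annotation sources rarely mark a
  canonical isoform consistently; first-listed is reproducible and
  auditable.
* Genes without an annotated CDS fall back to the full 1 kb downstream cap
  and are flagged, keeping them analyzable.
* A gene whose TSS equals its translation start contributes the 600 bp
  upstream segment only (the literal reading of "to the translation start").
* Windows are clipped at chromosome ends; windows that clip to nothing are
  skipped with a warning.
* Minus-strand windows are reverse-complemented so every emitted sequence
  reads in transcript orientation. Reverse-complementing the genome together
  with its annotation therefore leaves the emitted sequences unchanged — the
  invariant the test suite checks.

# Motif syntax: TGTCNN hexamers and spaced repeats

The AuxRE core is TGTC; the two following bases modulate ARF affinity
(TGTCGG is the high-affinity variant), so the scan unit is the hexamer
TGTCNN — 16 completions. A hexamer occurrence is any complete 6-mer
footprint whose first four bases are the core, on either strand; a
minus-strand occurrence appears as NNGACA on the given strand and is
reported at its footprint's left edge, written core-first. Both strands are
scanned because ARF binding is not strand-restricted, and the repeat
analysis needs per-occurrence strand anyway. Ambiguity codes never match.

ARFs bind cooperatively as dimers, so the spacing and relative orientation
of AuxRE pairs — the repeat *syntax* — carries signal beyond single-site
counts. For every ordered pair of non-overlapping occurrences within a
promoter, the spacer is the gap in bp between the 6-mer footprints (0–25 by
default), and the orientation is classified as:

* **DR** (direct repeat): both occurrences on the same strand;
* **IR** (inverted repeat, convergent cores): `TGTCNN ... NNGACA`;
* **ER** (everted repeat, divergent cores): `NNGACA ... TGTCNN`.

This convention matches the everted-repeat usage in the ARF literature
(divergent TGTC cores). It is invariant under reverse complementation of
the whole sequence: a DR stays a DR, an IR an IR, an ER an ER (spacer
unchanged) — a property the tests verify against a quadratic brute force.
Spacers are measured between 6-mer footprints, not 4-mer cores, because the
hexamer is the unit of analysis throughout.

## Gene-level Fisher enrichment

Following the gene-counting convention, a gene is "with" a feature if its
promoter contains at least one occurrence (or at least one repeat pair of
the given configuration); multiplicity is reported but never enters the
test. Enrichment of a foreground DEG set against the background of resting
genes (all genes with an extractable promoter that are in no foreground
set) is the one-sided Fisher exact test on the 2x2 gene-count table — the
exact hypergeometric upper tail. Raw p-values are reported (the heatmap
quantity is -log10 p); Benjamini–Hochberg q-values are emitted alongside
since a 16-hexamer or 78-configuration family invites multiple-testing
correction even though the display convention is raw p. Foreground and
background must be disjoint, and a consensus-level repeat table always has
3 orientations x 26 spacers = 78 rows.

```{r motif-demo}
scan_repeat_configurations(c(g = "TGTCGGAAATGTCGG"))
fisher_exact_enrichment(8, 10, 20, 100)
```

# Response profiles

`classify_degs()` applies the standard DEG call — adjusted p below alpha
(default 0.05), optionally with a fold-change floor (`lfc_threshold =
log2(1.25)` reproduces the non-stringent variant used for weakly inductive
systems). `response_summary()` then reports the activation:repression
balance (the auxin response is typically activation-dominated in
tracheophytes), the mean log2 fold change, and a fixed-width histogram
(default 0.25 log2 units; binning is a display choice, so it is
configurable).

`amplitude_decomposition()` addresses *where* response amplitude comes
from: ranking one direction's DEGs by |log2FC| and contrasting the k
strongest against the k weakest responders (default k = 20). If strong
responders sit at similar treated levels but much lower mock levels than
weak responders, the amplitude is driven by efficient repression in the
absence of auxin rather than stronger activation in its presence — the
diagnostic signature the generation comparison turns on. Group differences
are assessed with a rank-sum test. When fewer than 2k DEGs exist, k is
clamped to what is available (the groups then overlap) with a warning.

The "weakest responders" are by default the least-changed genes *within*
the up-regulated direction; a `direction` flag covers the alternative
reading that includes down-regulated genes. Printed group means are gene
means of per-gene condition means.

## The rank-sum test

`rank_sum_test()` enumerates all rank assignments exactly (tie-corrected
mid-ranks) when the combined sample size is at most 12, and uses the normal
approximation with continuity and tie correction beyond. The two-sided p is
`min(1, 2 * min(p_less, p_greater))`; identical samples give p = 1.

Numerical accuracy note: exhaustive comparison at the crossover size
(n = 12) shows the one-sided normal approximation stays within about 0.011
of the exact enumeration for tie-free data. The two-sided p doubles that
tail error, and heavily tied samples widen it further (worst observed
around 0.035). Agreement guarantees are therefore stated per tail on
continuous data; treat two-sided approximate p-values near a decision
boundary with small samples as indicative only.

`zscore_normalize()` is the conventional per-gene scaling of TPM matrices
before heatmap display: sample (n-1) standard deviation, constant genes
mapped to zero rather than NaN.

# Orthogroup overlap

Cross-species comparison of responsive gene sets cannot use gene ids;
orthogroups (from OrthoFinder-style tables: one row per orthogroup, one
column per species, comma-separated members) are the common currency. A
gene set maps to the set of orthogroups containing at least one of its
members; overlap between two species' responsive orthogroup sets is tested
against the exact hypergeometric null.

The universe for that test is the set of orthogroups represented in *both*
species: only jointly representable orthogroups can overlap, so including
species-specific orthogroups would inflate apparent enrichment. Note the
direction of the universe effect: shrinking the universe makes any fixed
overlap *more* expected and the p-value larger. Multi-set comparisons (up
to five species, as in phosphoproteomic comparisons) use exact set algebra
for the Venn region counts; no area-proportional layout is attempted.

# Morphometrics

## Vein-network indices

Vein networks are scored manually as four feature-point counts per leaf:
touch (vein-vein contact), end, break, and exit points. The indices are
operational definitions chosen so that "more veins, more frequently
connected" raises both cardinality and connectivity:

* absolute cardinality = T + E + B + X (total feature points);
* connectivity = T / (T + E + X), in [0, 1], 0 when the denominator is 0;
* continuity = 1 - B / (T + E + B + X), in [0, 1].

The cited venation-scoring tradition does not reprint closed formulas, so
these definitions are this package's own; they are deliberately simple
ratios, scale-invariant in the counts (tested), and should be re-derived
against the original method before any cross-study numeric comparison.
Relative indices (per-leaf index over the control-group mean) allow pooling
across experiments. Group comparison follows the classical two-stage
recipe: a two-sided F test for equal variances at alpha 0.05 decides
between the pooled-variance Student t-test and the Welch t-test.

## Nuclear-intensity ploidy quantification

Genome doubling doubles the template for a nuclear-localized fluorescent
reporter, so a ~2-fold shift in per-nucleus intensity between groups
indicates a ploidy change. The measurement chain: binarize (Otsu threshold
on a 256-bin histogram by default; fixed threshold by option), label
connected components at 4-connectivity (8 available), discard components
with area strictly below 30 px (outside the plausible nucleus size range),
and measure each surviving region's mean intensity on the *original* image.
Group summary is the ratio of median intensities with a two-sided rank-sum
test; the median resists segmentation outliers (merged nuclei, debris).
Fluorescence units are arbitrary, so only ratios and orderings are
meaningful.

# The synthetic-data generators

Every generator is a pure function of its configuration including the seed;
a single root seed expands into fixed per-component child seeds, so adding
a generator never perturbs the others' output. Each generator emits a truth
table, and the test suite verifies that every planted feature is recovered
by the corresponding scanner.

**Promoters** — i.i.d. sequences at GC 0.4 (an AT-rich plant-promoter-like
composition), 600 bp (the upstream window length), defaults 150 foreground
vs 1000 background genes. A hexamer (default TGTCGG, random strand) and/or
a consensus-level repeat (default DR with 7-bp spacer) are planted at
per-gene rates 0.4 (foreground) and 0.05 (background) at uniform
non-overlapping positions. Chance motifs arising from the background
composition are left in place — analyses must beat that background, and
rate-0 configurations estimate it.

**DE tables** — two generations share their responsive genes (default
10 000 genes, 2 000 responsive, activation fraction 0.75). Up-regulated
genes share one per-gene treated level across generations (drawn around
log2 = 7.0, a typical treated level for strong responders) but
have generation-specific mock levels (defaults 3.78 and 2.76, the two
generations' strong-responder mock means), plus shared per-gene mock
heterogeneity (sd 0.5). Activation amplitudes have a floor of 0.5 log2
units so a planted "up" label is always recoverable. Reported
per-condition values are means of 3 replicates with 0.2 log2 units of
replicate noise — a typical spread for well-expressed genes in a
good-quality RNA-seq experiment. Adjusted p-values are emulated by drawing
raw p-values (near zero for responsive genes, uniform for nulls) and
applying Benjamini–Hochberg correction; this is a stand-in for a DE fitter,
not a DE method, but it reproduces the one property downstream code sees:
essentially complete power on responsive genes with an FDR-controlled
trickle of false calls.

**Orthogroups** — 0–3 genes per species per orthogroup; per-species
responsive sets share a controlled joint core (fraction `deg_overlap_rate`
of each set) with independent remainders, so rate 0 is the independence
null.

**Veins** — negative-binomial (Poisson at dispersion 0) counts around group
means. **Nuclei** — non-overlapping rasterized discs; group-b intensities
are group-a times the planted ratio times lognormal noise (CV 0.05), on a
near-zero noisy background.

## What the generators do and do not emulate

The generators reproduce the *statistical shape* each analysis assumes:
planted motif excesses over a uniform-composition background, a shared
responsive gene set with generation-specific repression depth,
FDR-controlled significance calls, controlled orthogroup joint membership,
count dispersion, and a multiplicative intensity shift. They do not emulate
promoter nucleotide autocorrelation or CpG/TA heterogeneity, correlated
noise across genes (batch structure), annotation errors, partial orthology,
or optical artifacts (uneven illumination, touching nuclei). Passing tests
therefore demonstrate correctness of the computations and recoverability of
planted structure at realistic effect sizes — not robustness to every
failure mode of real data.

## Selection effects worth knowing about

Two visible consequences of ranking by observed fold change, both expected
and both left uncorrected because the real analysis shares them:

* the top-k groups preferentially include genes whose mock noise ran low,
  so recovered top-k mock means sit below the planted population means in
  *both* generations, while their difference — the quantity of interest —
  stays unbiased (recovered within ±0.1 of the planted 1.0 gap at the
  default problem size in the test conditions);
* the classify-then-summarise estimate of the activation fraction is
  diluted toward 0.5 by the ~5% of BH calls that are false discoveries
  (about 0.01 at the default sizes). Across random seeds the recovered
  fraction occasionally grazes the exact binomial 99% interval of the
  planted value; the truth-table realized fraction is exactly
  binomial-calibrated.

# Problem sizes and numerical choices

The test suite runs every exact-test comparison for all pooled 2x2 tables
up to N = 40 (an exact-integer regime for the enumeration oracle), 500
random sequences up to 300 bp for the scanner brute force, 100 seeds for
the planted-syntax and nuclear-ratio recovery rates, and single fixed-seed
datasets at the default generator sizes for the response-profile
recoveries. These sizes were chosen so the full suite completes in a few
minutes while keeping every stochastic check at sample sizes where its
expected margin is wide.

Other numerical conventions: p-values are floored at the smallest positive
double (so -log10 p is always finite); z-scoring a constant gene yields
zeros; vein connectivity with no non-break points is 0 by convention;
Otsu thresholding errors on constant images ("no foreground") while a
user-supplied threshold that excludes every pixel returns an empty ROI
table; component labeling at 8-connectivity merges 4-connected labels
across diagonal contacts.

# Known limitations

* Vein index formulas are internal operational definitions (see above).
* The promoter rule trusts the annotation; no TSS inference is attempted,
  and overlapping genes are not deduplicated beyond the one-transcript rule.
* The repeat-orientation naming (IR convergent, ER divergent) should be
  cross-checked against any external motif-co-occurrence tool before
  bit-level comparison of outputs.
* The two-sided normal-approximation rank-sum p inherits twice the
  one-sided tail error near the exact/approximate crossover.
* padj emulation does not model dispersion-dependent power; analyses that
  depend on the *shape* of the padj distribution near the threshold should
  not rely on the generator.
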