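---
title: "Dominance analysis in parent-hybrid trios: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance analysis in parent-hybrid trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the dominance model, the tests behind each stage, the tunable
parameters with their defaults and rationale, what the synthetic-data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The dominance model

A trio consists of a maternal parent (E), a paternal parent (G) and their
hybrid (F), each with replicated measurements — normalized expression
counts for genes and small-RNA clusters, or methylation proportions for
differentially methylated regions (DMRs). The question per feature is
ordinal: which of the three genotypes differ, and in which direction?

Two tests are combined. A two-sample Student *t*-test (equal variance,
df = n₁ + n₂ − 2) is run for each genotype pair, and Tukey's HSD is run
across the three groups (studentized range with 3 means, pooled MSE,
df = N − 3, Tukey–Kramer correction for unequal n). A pair is declared
different only when *both* tests reject at α = 0.05 — a conservative
conjunction chosen because the two tests play distinct roles (the t-test
establishes that a pair differs; Tukey ranks the genotypes with
familywise control) and because requiring agreement makes verdicts stable
under small perturbations. The verdict triple then maps onto twelve
categories through a fixed decision table:

* F above both parents → transgressive up (III if E = G, VII if E > G,
  X if E < G);
* F below both parents → transgressive down (VI if E = G, VIII if E > G,
  V if E < G);
* F = G, F ≠ E, E ≠ G → paternal dominant (II if F > E, XI if F < E);
* F = E, F ≠ G, E ≠ G → maternal dominant (IV if F > G, IX if F < G);
* all three pairs differ and F lies strictly between the parent means →
  additive (I if E < G, XII if E > G);
* anything else — including verdict triples inconsistent with the means
  ordering, which can arise from a non-transitive Tukey outcome — is
  `unclassified`.

Only the five collapsed groups (additive, maternal dominant, paternal
dominant, transgressive up/down) are used downstream; the sub-labels that
distinguish which parent is higher (VII vs X, V vs VIII) follow the
parent verdict and are reported for completeness.

### The testing scale

Expression dominance is classified on `log2(normalized count + 1)` by
default (`value_scale = "log2"`). This is a deliberate
variance-stabilization choice: negative-binomial counts have variance
µ + αµ², so on the raw scale the pooled Tukey MSE is dominated by the
highest-mean genotype and pairs involving low-mean genotypes become
nearly undetectable regardless of their fold change. On the log scale the
three groups are approximately homoscedastic and all pairwise
comparisons carry similar power. `value_scale = "identity"` restores the
literal raw-normalized-count behaviour for comparison. Methylation-level
dominance always runs on proportions, which are already bounded and
approximately homoscedastic at the read depths involved.

Even on the log scale, the additive categories are intrinsically the
hardest: an additive call needs *three* significant pairwise separations,
each spanning only half the parental fold change (the generator places
the additive hybrid at the parents' geometric midpoint, the most
detectable placement). At fold change 4, dispersion 0.05 and three
replicates, the joint power of the t + Tukey conjunction for such a
feature is roughly 0.4, which bounds overall 12-class recovery near
88–90% under those conditions. This is a property of the verdict rule at
those sample sizes, not of the implementation.

## Differential expression

The DE stage is self-contained so that the dominance classifier does not
depend on an external package, and pluggable so that a table from another
caller can replace it (`read_de_results()`).

* **Normalization** — median-of-ratios: the pseudo-reference is the
  per-feature geometric mean over samples (features containing any zero
  are excluded from the reference); a sample's factor is
  `exp(median(log(count/reference)))`. When no feature is nonzero in all
  samples the function stops with advice rather than silently switching
  reference — the caller should decide.
* **Testing** — per-feature negative-binomial Wald test on normalized
  counts: method-of-moments dispersion pooled over the two groups and
  floored at 1e-8, a 0.5 pseudo-count keeping log fold changes finite,
  standard-normal reference, Benjamini–Hochberg adjustment within each
  contrast × stage, `padj < 0.05`. No dispersion shrinkage, outlier
  replacement or independent filtering is attempted — those are
  behaviours of specific packages, not part of the specified math.
* **Design** — a single genotype factor within each stage; the default
  contrasts are hybrid vs each parent and parent vs parent. A feature is
  eligible for dominance classification when it is differential in at
  least one contrast of the stage.

A known limitation inherited from median-of-ratios: when a large fraction
of features is differential in one direction, the median ratio of the
affected samples is dragged toward the differential block and normalized
means become biased (the same failure mode exists in any
median-of-ratios implementation). The generator's default class mix is
direction-balanced, and real designs with mostly-null features satisfy
the assumption; strongly asymmetric designs should supply externally
computed size factors or DE tables.

## Methylation

Cytosine reports follow the Bismark CX dialect (1-based positions, one
row per cytosine and strand, CpG/CHG/CHH context). Cytosines whose state
was reported fewer than 3 times in a library are dropped from that
library — the usual reporting cutoff for bisulfite pipelines. Reads are
pooled into 1-kbp bins anchored at coordinate 0 of each chromosome (the
grid phase is a convention; nothing downstream depends on it).

DMR calling between two genotypes uses the two-proportion score test on
pooled read counts: with pooled proportion p̂,
z = (p̂₁ − p̂₂) / √(p̂(1 − p̂)(1/n₁ + 1/n₂)), whose square equals the
Pearson χ² of the 2×2 table — an identity the tests verify to 1e-10. A
bin is a candidate when both genotypes cover ≥ 4 cytosines, |Δ| ≥ 0.4 and
p < 0.01; the cytosine minimum is interpreted per genotype (the stricter
and deterministic reading). Candidate bins merge when separated by at
most `min_gap` bp with the same direction (the default gap 0 merges only
book-ended bins); the merged span's statistics are recomputed on pooled
counts and the span must itself satisfy all three thresholds, so every
emitted DMR passes an exact threshold audit. DMRs are called in the CpG
and CHG contexts by default; CHH bins are computed and calling in CHH is
available via `contexts`, but heterochromatic CHH differences are noisier
and are off by default.

MLD classification recomputes replicate-level methylation of each DMR
across all three genotypes and delegates to the same verdict machinery,
with two replicates per genotype (df = 3 for Tukey). The binomial noise
of a pooled region level at depth 30 over a 1-kbp bin is small (SD well
under 0.01), so two replicates suffice for the planted effect sizes.

CpG islands follow the classical criteria: 100-bp windows sliding at
step 1 must reach GC ≥ 50% and observed/expected CpG ≥ 0.6 with
obs/exp = n(CpG)·L/(n(C)·n(G)); passing windows merge, the merged span is
re-evaluated on its full extent, and only spans > 200 bp that still pass
are emitted. Because a span inherits up to one window width of slack on
each side, a planted island is recovered with boundaries within ±100 bp
of the planted core; the emitted span itself always satisfies the
criteria exactly.

## Segments and copy number

Expression clustering is assessed in non-overlapping 500-kbp windows; a
window is a candidate segment when some genotype × stage combination
contains more than 20 differential features. The threshold corresponds to
roughly 10% of the genes in a window at the gene density of a compact
crop genome (about 200 genes per 500 kbp), which is also the generator's
default density. The up/down balance is scored as
`log2((n_up + 0.5)/(n_down + 0.5))` — a pseudo-count form chosen because
a plain ratio is undefined at zero denominators and asymmetric between
directions. Scores are Z-normalized within each segment across its
genotype × stage cells, and a candidate is retained when the Z range
across genotypes reaches `z_range_thresh` (default 1.5) in at least one
stage. This explicit rule replaces a visual heatmap-clustering step and
is the largest formalization in the package: the threshold is exposed,
and retention is monotone in it (raising it never adds segments). Note
that with only two genotype × stage cells the within-segment Z range is
constant (√2·|z| with two points), so the rule needs at least three
cells to discriminate — trio designs always provide them.

Copy-number calls aggregate window coverage to 25-kbp windows, estimate
the genome-wide mean and SD after excluding window depths above 100
(collapsed repeats), and call windows beyond mean ± 1 SD, merging
adjacent same-type windows. Genome-wide (not per-chromosome) estimation
is the default; the per-chromosome alternative can be had by calling per
chromosome. A 1-SD rule implies a ~32% positive rate on a perfectly null
genome (the two-sided normal tail) — the rule is deliberately inherited
as specified, and the tests verify the null rate matches that tail mass
rather than pretending the rule is specific. Planted events (0.1× and 2×
over 50 kbp) inflate the SD enough that null windows stay inside the
band, which is why recovery of planted boundaries is exact.

## Integration

* **Epialleles** — a differential gene with additive or parental-dominant
  expression is a putative epiallele when a DMR overlapping its body or
  1-kbp promoter carries the *same* dominance group. Direction
  concordance (hyper vs up) is deliberately not required: both
  proportional and inverse expression-methylation couplings occur, so
  the definition matches on the group label only.
* **Proximity association** — per feature class, a 2×2 table of
  (within 5-kbp gene flank) × (differential) tested by Pearson χ²
  without continuity correction, BH-adjusted across the family; tables
  with an expected cell below 1 are skipped with a warning rather than
  tested unreliably. Flanks exclude the gene body; body overlaps are a
  separate count. The 5-kbp distance follows the average intergenic
  spacing of compact crop genomes.
* **Correlation** — Kendall τ-b (tie-corrected) with the
  normal-approximation p-value, chosen because bulk expression is far
  from Gaussian; gene-body and promoter methylation are reported
  separately, per stage (pooling across stages is possible by
  concatenating the input pairs). Expression per gene × genotype is the
  mean normalized count over that genotype's replicates — the pooling is
  recorded in the output rather than hidden.
* **Composition** — each DMR counts toward every annotation class it
  overlaps (promoter/exon/intron/repeat are not mutually exclusive);
  distance to the nearest gene is 0 when overlapping, otherwise the gap
  between nearest ends, with ties broken toward the smaller gene
  identifier for determinism.

## The synthetic-data generator

The generator emulates the trio design end to end so that every stage has
planted truth: negative-binomial counts (gamma–Poisson, constant
dispersion 0.05 — replicate-level dispersion of the real data is not
reported, so a typical bulk-RNA-seq value is used and exposed in the
config), twelve planted mean patterns built from the fold-change
parameter (default 4; additive hybrids at the geometric midpoint,
transgressive hybrids one fold-change step beyond the extreme parent),
three count replicates and two methylation replicates, binomial
methylation at depth 30 over an AT-rich genome (36% GC, so background
windows fail the island GC criterion while obs/exp hovers near 1),
planted 1-kbp methylation regions whose proportion triples encode the
same twelve categories (two-level patterns at (1 ± δ)/2 with δ = 0.5;
three-level patterns at fixed anchors 0.05/0.5/0.95 so that every
"different" pair stays detectable inside [0, 1]), planted CG-repeat
islands, Poisson window coverage with multiplier CNVs aligned to 25-kbp
boundaries, and sRNA clusters with planted length histograms and
structure flags. Mild per-sample library factors (±20%) exercise
normalization. Truth sidecars are plain TSVs.

Default problem sizes — two 500-kbp chromosomes, 400 genes, 100 features
per dominance category, 10 methylation regions per category — keep a full
verification run in tens of seconds while leaving every rate estimated
from at least dozens of planted instances; individual checks scale the
sizes up (12,000 features for moment checks) or down as the statistic
requires.

What the generator does **not** emulate, and hence what passing tests do
not establish about real data: read-level artifacts (alignment error,
bisulfite conversion failure, M-bias), positional correlation of
methylation beyond region structure, dispersion trends with expression
level, isomiR variation, and biological covariance between the omics
layers (planted expression and methylation truths are independent except
where a test plants them jointly). Recovery rates on synthetic data are
therefore upper bounds under the model's assumptions, not field accuracy
claims.

## Numerical conventions and degenerate inputs

All internal coordinates are 0-based half-open; GFF3 converts at the I/O
boundary (start − 1). Touching intervals do not overlap; book-ended
intervals merge at gap 0. Zero-variance pairs with equal means are
"equal", with different means "different" (the limit of the t statistic).
Degenerate pooled proportions (0 or 1) give score-test p = 1. Constant
vectors make Kendall τ undefined and are reported as missing with a
warning. Fewer than 10 coverage windows after outlier exclusion is an
error (the SD would be unstable). Ties in genotype means are broken by
the fixed role order (E, F, G), and every output table is sorted, so all
outputs are byte-deterministic under a fixed seed.
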