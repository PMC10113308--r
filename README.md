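# triomics

Multi-omics dominance analysis for parent–parent–hybrid trios.

When a hybrid (F) is profiled together with its maternal (E) and paternal
(G) parents, every differential feature — a gene, a small-RNA cluster, or a
differentially methylated region (DMR) — can be placed relative to its
parents: does the hybrid track one parent (parental dominance), sit between
them (additivity), or exceed both (transgression)? `triomics` implements
this classification for bulk RNA-seq counts, sRNA cluster counts and
whole-genome bisulfite data, together with the surrounding machinery a
trio study needs: differential calling, DMR detection, CpG-island and
copy-number scanning, segmental expression bias, and
expression–methylation integration. A synthetic-data generator with
machine-readable planted truth makes every stage testable end to end.

## The classification at its core

For each feature, replicate-level normalized values of the three genotypes
are compared pairwise. A pair is declared different only when **both** a
two-sample Student *t*-test and Tukey's HSD (3 groups, pooled MSE,
df = N − 3) separate it at α = 0.05. The verdict triple
(F vs E, F vs G, E vs G) maps onto twelve categories and five collapsed
groups:

| group | categories | pattern |
|---|---|---|
| additive | I, XII | E ≠ G, F strictly between |
| paternal dominant | II, XI | F = G ≠ E |
| maternal dominant | IV, IX | F = E ≠ G |
| transgressive up | III, VII, X | F above both parents |
| transgressive down | V, VI, VIII | F below both parents |

Any other verdict combination is `unclassified`. The same taxonomy applied
to DMR methylation proportions gives methylation-level dominance (MLD),
with transgressive groups reported as hyper-/hypomethylated.

Around it:

* **Differential expression** — median-of-ratios size factors and a
  per-feature negative-binomial Wald test (method-of-moments dispersion,
  Benjamini–Hochberg adjustment, padj < 0.05). The stage is pluggable: an
  externally produced table in the same TSV dialect drops in via
  `read_de_results()`.
* **DMR calling** — per-cytosine reports (Bismark CX dialect) pooled into
  1-kbp bins per context (CpG/CHG/CHH); a two-proportion score test
  (z² = Pearson χ² of the 2×2 table) with thresholds p < 0.01,
  |Δ| ≥ 0.4, ≥ 4 covered cytosines per genotype; adjacent same-direction
  bins merge.
* **CpG islands** — sliding 100-bp windows with GC ≥ 50%,
  obs/exp CpG = n(CpG)·L/(n(C)·n(G)) ≥ 0.6, merged spans > 200 bp.
* **CNVs** — 25-kbp coverage windows beyond mean ± 1 SD (depths > 100
  excluded from the estimation), adjacent same-type windows merged.
* **Segments** — 500-kbp windows with > 20 DEGs; up/down balance scored
  as log2((n_up + 0.5)/(n_down + 0.5)), Z-normalized within the segment,
  retained when the Z range across genotypes reaches 1.5 in some stage.
* **sRNA clusters** — miRNA candidates (≥ 80% of primary reads at
  20–24 nt, < 5 unpaired bases, hairpin flag Y/N15/N14/N13) vs putative
  24-nt siRNAs (≥ 80% exactly 24 nt, no hairpin evidence).
* **Integration** — putative epialleles (differential genes whose body or
  1-kbp promoter carries a DMR with the *same* dominance group),
  flank-association χ² tests with BH adjustment, Kendall τ-b
  methylation–expression correlation, DMR feature composition and
  distance-to-gene distributions.

## Worked example

Simulate a trio with 15 features per dominance category plus 320
non-differential features, call differential expression, and classify:

```r
library(triomics)

cats <- c("I","II","III","IV","V","VI","VII","VIII","IX","X","XI","XII")
cfg <- sim_config(seed = 42,
  n_features_per_class = setNames(c(rep(15L, 12), 320L), c(cats, "null")))
sim    <- simulate_trio_counts(cfg)
counts <- filter_zero_features(sim$counts)
de     <- call_de(counts, sim$design)
glance(de)
#> # A tibble: 3 × 5
#>   stage   contrast             n_tested  n_de frac_de
#>   <chr>   <chr>                   <int> <int>   <dbl>
#> 1 OS15_F0 hybrid_vs_maternal        500   164   0.328
#> 2 OS15_F0 hybrid_vs_paternal        500   176   0.352
#> 3 OS15_F0 paternal_vs_maternal      500   171   0.342

eld <- classify_dominance(counts, sim$design, de)
dominance_summary(eld)
#> # A tibble: 5 × 6
#>   stage   omic  group                  n percent n_unclassified
#>   <chr>   <chr> <chr>              <int>   <dbl>          <int>
#> 1 OS15_F0 gene  additive              18    9.89             46
#> 2 OS15_F0 gene  maternal_dominant     35   19.2              46
#> 3 OS15_F0 gene  paternal_dominant     38   20.9              46
#> 4 OS15_F0 gene  transgressive_down    45   24.7              46
#> 5 OS15_F0 gene  transgressive_up      46   25.3              46
```

Each `n_de` counts features at padj < 0.05 in that genotype contrast; the
summary gives each collapsed group's share of the classified DE features
(here 92.5% of DE-passing features recover their planted group; the
additive class is hardest because all three pairwise separations must
reach significance with three replicates). `autoplot()` methods exist for
differential results, dominance summaries, DMR sets and segment tables,
and `run_pipeline(pipeline_config(...))` drives the whole analysis —
simulation through segments/CNV — into a directory of TSV/BED tables plus
planted-truth sidecars and a run manifest.

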