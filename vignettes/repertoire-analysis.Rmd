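---
title: "Methods: repertoire statistics, design choices and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire statistics, design choices and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
```

## The setting

`clonotrace` analyses bulk CDR3β clonotype tables from T-cell receptor
sequencing of paired tissues — a draining lymph node and the inflamed joint
it serves — sampled at an early and a late phase of inflammatory disease,
with adjuvant-only controls. The questions the statistics answer are: how
many distinct clones does each repertoire contain, how unevenly are reads
concentrated in the biggest clones, how many clones do two repertoires share
relative to their sizes, does V-gene usage differ between groups, and do the
most expanded clones of the joint occupy top ranks in the paired node.

Everything operates on clone tables: one row per clonotype with the CDR3β
nucleotide sequence, its amino-acid translation, TRBV/TRBJ gene labels and a
read count. Alignment, clonotype assembly, UMI handling and error correction
are upstream concerns and out of scope.

## Clone identity

What counts as "the same clone" is a parameter, not an assumption. Four
identity levels are supported: the CDR3β nucleotide sequence (`nt`, the
default for clonality and diversity), the amino-acid sequence (`aa`, the
default for cross-repertoire matching, where convergent recombination makes
amino-acid identity the meaningful notion of sharing), and variants that
append the V and J gene labels (`nt_vj`, `aa_vj`) for pipelines whose
clonotype keys include gene calls. Allele suffixes (`*01`) are stripped on
ingest because usage is analysed at the gene level. Matching is exact string
equality throughout — no fuzzy or distance-based clone matching.

Collapsing merges rows that share a key, summing reads; the representative
sequence and gene fields come from the member with the most reads (ties: the
lexicographically smallest nucleotide sequence). Reads are always conserved
by collapsing and pooling, and the suite tests that invariant on random
inputs.

## The D50 index and its interpretation points

D50 is the percentage of ranked clones needed to accumulate half of the
reads. It has two branches keyed on the number of unique clones `U`:

* `U ≥ 10,000` — ranks are taken within the 10,000 most abundant clones and
  divided by 10,000;
* `U < 10,000` — ranks run over all clones and are divided by `U`.

Two points in the definition are genuinely open to interpretation, and both
are explicit switches rather than silent choices:

1. **"Reaches half"** is implemented as the smallest rank whose cumulative
   read count is at least half the reference total — the rank is integral
   and no interpolation is applied, which keeps the index exactly
   reproducible and makes the uniform-repertoire value `ceil(U/2)·100/U`.
2. **The reference total in the large branch**: by default the 50% point is
   measured against the summed reads of the top 10,000 clones (the
   truncation within which ranks are expressed). Measuring against all reads
   instead is available as `d50(, reference_total = "all")`. The truncated
   variant is the default because it keeps the two branches structurally
   identical (both measure 50% of the mass they rank over).

The branch applied is recorded in every result and logged per sample in
pipeline outputs, because values from different branches are not directly
comparable near the boundary. `U = 10,000` itself uses the large branch.

Ties in read count are broken by the lexicographically smallest nucleotide
sequence so that ranking, D50 and top-N statistics are deterministic. This
matters for testing, not for the science: any fixed tie order gives the same
D50 up to the tie block.

## Homeostasis bins, top-N mass and thresholds

The clonal-space homeostasis profile partitions read mass over fixed rank
bins — the top 10 clones, then the next 25, 500, 3,000, 10,000 and 100,000
(boundaries 10, 35, 535, 3,535, 13,535, 113,535). For repertoires with at
most 113,535 clones the six proportions are a partition of read mass and sum
to one; mass beyond the last bin is reported separately as a remainder, not
silently dropped.

The count of clones at or above a read threshold (`count_clones_at_least`)
supports the data-driven expansion readout where the threshold is the median
clone read count of a control sample. The median uses the lower-median
convention for even counts so the threshold is always an achievable integer
read count.

## The normalised overlap index

Overlap between two repertoires is the number of exactly shared CDR3β
amino-acid sequences divided by the product of total read counts,
`s/(N₁·N₂)`. The read-product denominator is kept exactly as defined even
though it yields very small numbers (two 5·10⁴-read samples sharing 100
sequences score 4·10⁻⁸); a display scale (default 1, typically 10⁶) applies
to reporting only and never to stored counts. A testable consequence of the
formula — doubling every read in both repertoires divides the index by four —
is asserted in the suite. The alternative denominator used by some packages
(product of unique clone counts) is available as a named variant, not the
default.

Because the denominator is a read product, the index confounds sharing with
sequencing depth; within a cohort sequenced to comparable depth that is a
size correction, across very different depths it is not. This is a property
of the index itself, worth keeping in mind when comparing studies.

## Gene usage, PCA and per-gene comparisons

Usage vectors give each TRBV (or TRBJ) gene's share of the repertoire,
weighted by reads (default — repertoire frequencies derive from read counts)
or by unique clones; both are provided because either convention is
defensible and they differ exactly when expansion is gene-biased. Usage
matrices are dense over the union of observed genes with zero for absent
genes, so every row lies on the simplex, and genes follow a numeric-aware
order (TRBV2 before TRBV12-1) fixed once so loadings and tables are
reproducible.

The PCA centres columns but does not variance-scale them by default:
frequencies already share a scale, and unit-scaling would inflate rare,
noisy genes. Scaling is a switch (`usage_pca(, scale. = TRUE)`). Component
signs follow a deterministic convention — the largest-magnitude loading of
each component is made positive — so scores are stable across platforms.

Per-gene group differences are tested gene-by-gene with a two-sample test
(Welch by default) and Šidák family-wise correction `1-(1-p)^m` over the `m`
genes, which mirrors a per-gene multiple-comparisons readout without
committing to a particular ANOVA layout; the long-format gene × group
two-way ANOVA (Type II sums of squares) is available as
`gene_usage_anova()` for the figure-style omnibus question.

## Cross-site tracking and the censored-rank policy

`cross_site_ranks()` is oriented: it takes the joint's top-N clones (N = 10
by default) into the node's ranking, never the reverse. A joint clone absent
from the node has no rank; the default policy censors it to `U+1`, one past
the node's clone count, so every top joint clone contributes a pair and
absence is informative (it pushes ρ down). Dropping absent clones instead is
available for sensitivity; with fewer than three usable pairs the
correlation is reported as undefined with the reason, never silently NA.
Spearman's ρ is used unconditionally; the D'Agostino–Pearson omnibus
normality statistic is computed on the ranks and reported alongside as
information, but never switches the estimator — a single code path keeps
results reproducible. The omnibus test requires n ≥ 8 and says so rather
than extrapolating.

## Group statistics

`student_t` (pooled variance) and `welch_t` (Welch–Satterthwaite df) are
two-sided with explicit degenerate handling: identical constant groups give
statistic 0 and p = 1; constant groups with different means give an infinite
statistic, p = 0 and a `degenerate` flag, rather than an error mid-pipeline.
The two-way ANOVA uses Type II sums of squares because the study layouts are
unbalanced (unequal group sizes); the fully degenerate all-equal case is
reported as F = 0, p = 1. The suite verifies the empirical type-I error of
both t tests at α = 0.05 stays within [0.03, 0.07] over 10,000 null
replicates.

## The synthetic cohort generator

The generator exists so that every stage — ingest, diversity, overlap, PCA,
tracking, statistics — can be exercised end to end, with known ground truth,
on data with the structure the analysis assumes. Each repertoire is a
two-component mixture over a fixed clone universe:

* `n_expanded` dominant clones holding `expanded_mass` of the read
  probability (split uniformly, or unevenly via `expanded_weights`);
* `n_background` clones with Zipf(`tail_exponent`) probabilities normalised
  to the remaining mass — the standard minimal heavy-tailed model for
  antigen-experienced repertoires.

Reads are drawn once from a multinomial at the requested depth; clones
sampled zero times drop out, which is the only gap between designed and
realised quantities. CDR3β sequences are random in-frame, stop-free codon
strings of 9–15 codons (27–45 nt) — only exact-match identity matters
downstream, so no V(D)J recombination model is simulated. V/J labels are
drawn per clone from named profiles; two built-in V profiles encode a
focused (TRBV12/13-family-dominated) and a broadened (TRBV1/2/3/5/19-boosted)
usage pattern.

Paired samples realise a designed number of shared amino-acid sequences
*exactly at the universe level before read sampling*: shared clones are
copied from the node universe into joint slots, and all other sequences are
generated disjoint (collisions are regenerated). Under the late-phase rule
all joint expanded clones are copies of the node's most abundant clones in
matching order — their joint probabilities decrease linearly so the designed
rank order survives sampling noise; under the early-phase rule a stated
fraction of joint expanded clones is de novo and the shared ones are
assigned in shuffled order. One master seed expands to per-pair seeds by a
counter scheme (`master + 7919·index`, mod 2³¹−1) recorded in the manifest,
so any single pair regenerates in isolation.

### Default study conditions

The default cohort is 3 arms × 5 subjects × 2 tissues at 5·10⁴ reads per
sample — sizes chosen as a realistic sorted-cell bulk experiment and used
unchanged by the analysis drivers, the test suite and the acceptance script:

| arm | node | joint | sharing | rule |
|---|---|---|---|---|
| early inflamed | mass 0.18 over 4,000 bg clones, focused V | mass 0.44 over 2,000 | 400 | early (half the joint's top clones absent from the node) |
| late inflamed | mass 0.02 over 9,000 bg clones, broad V | mass 0.44 over 2,000 | 100 | late (all joint top clones from the node's top) |
| late control | mass 0.05 over 4,500, focused V | mass 0.29 over 900 | 150 | early-style |

The node parameters encode the designed progression — early nodes
antigen-focused (a few percent-scale clones, ~4,000 sequences), late nodes
polyclonal (~9,000 low-frequency sequences with broadened V usage) — and the
joints stay clonally dominated at both phases. Sharing decreasing from 400
to 100 encodes divergence of the two sites' repertoires with time, while the
late rule encodes the accumulation of the node's dominant clones in the
joint. The Zipf exponent 0.6 keeps the background heavy-tailed but flat
enough that the designed expanded clones, not background fluctuations,
occupy the top ranks — that is what makes the designed top-10 mass
recoverable from the observed top-10 read share (the suite checks recovery
to ±0.02 at depth 10⁵ over 50 seeds, and that mean D50 decreases strictly in
the expanded mass over {0.1, 0.3, 0.5, 0.7}).

### What passing on synthetic data does and does not show

The generator emulates the *statistical shape* the analysis assumes: clone
identity is noiseless, read counts are exactly multinomial, sharing is
planted exactly, and every clone's gene label is known. Real data violate
each of these — PCR amplification bias and sequencing error inflate
singleton diversity, clonotype assembly merges or splits clones, depths vary
between samples, and gene calls can be ambiguous. Green tests therefore
establish that the statistics are implemented correctly and that the
pipeline recovers designed effects of realistic magnitude from sampled
counts; they do not validate robustness to upstream noise, and none of the
printed descriptive values from any particular sequencing study are targets
the simulation is tuned to reproduce.

## Degenerate inputs and numerical conventions, collected

* Empty repertoires: readable (with a warning) and writable; D50, top-N,
  homeostasis and median error out explicitly — these statistics are
  undefined, not zero.
* Zero or missing read counts: rejected by default; lenient mode
  (`strict_counts = FALSE`) imputes 1 and is opt-in.
* Out-of-frame amino-acid markers (`_`): rejected at validation.
* All ranking tie-breaks: lexicographic on the nucleotide sequence, C
  locale (radix order), fixed at ingest.
* PCA: constant columns dropped only under scaling; components capped at
  `min(samples − 1, genes)`.
* Spearman p-values use the asymptotic approximation (ties are possible
  after censoring, so the exact null is unavailable anyway).

## Known limitations

* Exact-match identity only; convergent clones differing by one residue are
  distinct. This is deliberate (matching the "exact overlap" definition)
  but understates sharing between deeply mutated datasets.
* The read-product overlap denominator makes cross-study comparison
  depth-sensitive, as noted above.
* No rarefaction or richness estimation: clonality is the observed unique
  count and inherits its depth dependence. Comparisons are meaningful at
  matched depth, as in the simulated design.
* The Welch-based per-gene usage comparison treats genes as independent
  tests; compositional coupling (frequencies summing to 1) slightly
  negatively correlates them, making Šidák mildly conservative.
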