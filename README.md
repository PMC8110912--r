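# clonotrace

Clonality, diversity and overlap analysis of TCRβ clonotype repertoires in R.

`clonotrace` is for immunologists analysing bulk CDR3β sequencing of T-cell
repertoires across paired tissues — typically a draining lymph node and the
inflamed tissue it serves — and across disease phases. It consumes clone
tables (AIRR Rearrangement TSV or MiXCR-style exports), not raw reads:
alignment and clonotype assembly happen upstream.

## What it computes

For a repertoire with clones ranked by read count `n₍₁₎ ≥ n₍₂₎ ≥ …` and
total reads `N`:

* **Clonality** — the number `U` of unique CDR3β sequences (a richness
  count; nucleotide level by default, configurable).
* **D50 diversity index** — the percentage of ranked clones needed to reach
  half the reads. With `r = min{k : Σᵢ≤k n₍ᵢ₎ ≥ T/2}`:
  * `U ≥ 10,000`: restrict to the top 10,000 clones, `T` their summed
    reads, `D50 = r·100/10000`;
  * `U < 10,000`: `T = N`, `D50 = r·100/U`.

  Low D50 = domination by few clones; a uniform repertoire sits near 50.
* **Clonal-space homeostasis** — the fraction of reads held by clones
  ranked 1–10, 11–35, 36–535, 536–3,535, 3,536–13,535 and 13,536–113,535
  (the top 10 clones, the next 25, 500, 3,000, 10,000 and 100,000).
* **Normalised overlap index** — between repertoires 1 and 2,
  `shared / (N₁ · N₂)`, where `shared` counts exactly matching CDR3β
  amino-acid sequences; symmetric, with an optional display scale (e.g.
  10⁶) since raw values are small.
* **TRBV/TRBJ usage** — per-sample gene frequency vectors (read- or
  clone-weighted), dense usage matrices, PCA on centred V-usage rows, and
  per-gene group comparisons with Šidák family-wise correction.
* **Cross-site clone tracking** — each joint's top-10 clones looked up in
  the paired node's ranking (absent clones censored to rank `U+1` by
  default), with Spearman's ρ and a D'Agostino–Pearson normality note.
* **Group statistics** — pooled and Welch two-sample t tests and a Type II
  two-way ANOVA, with explicit degenerate-input behaviour.

A synthetic-cohort generator (`repertoire_spec()`, `generate_cohort()`)
builds paired node/joint repertoires as expanded-clones-plus-Zipf-background
mixtures with exactly realised cross-tissue sequence sharing, so the whole
workflow is testable end to end without sequencing data.

## Worked example

Simulate one late-phase animal — a polyclonal node (~9,000 low-frequency
background clones, 2% of reads in the top 10) paired with a joint dominated
by ten expanded clones (44% of reads) that are all drawn from the node's
most abundant clones:

```r
library(clonotrace)
pair <- generate_paired_sample(
  rule = "late",
  pln_spec  = repertoire_spec(n_expanded = 10, expanded_mass = 0.02,
                              n_background = 9000, tail_exponent = 0.6,
                              depth = 5e4, v_profile = trbv_profile("broad")),
  joint_spec = repertoire_spec(n_expanded = 10, expanded_mass = 0.44,
                               n_background = 2000, tail_exponent = 0.6,
                               depth = 5e4),
  sharing = 100, seed = 7, subject_id = "m1", phase = "late",
  condition = "inflamed")

d50(pair$pln)[c("clonality", "d50")]
#> $clonality  [1] 8647
#> $d50        [1] 16.35249
d50(pair$joint)[c("clonality", "d50")]
#> $clonality  [1] 2009
#> $d50        [1] 1.194624
round(homeostasis_profile(pair$joint)$proportions, 3)
#> [1] 0.440 0.081 0.248 0.230 0.000 0.000
normalized_overlap(pair$pln, pair$joint, scale = 1e6)
#> [1] 0.0384
cross_site_ranks(pair$joint, pair$pln, n = 10)
#> <cross_site_ranks> subject m1: rho = 0.976 (p = 1.47e-06), 0/10 absent
```

The node is rich (8,647 unique sequences) and even (D50 ≈ 16); the joint is
clonal (D50 ≈ 1.2) with 44% of its reads in the top bin, and its ten most
expanded clones all appear near the top of the node's ranking (ρ ≈ 0.98,
none absent) — the designed late-phase pattern.

## Full analysis workflow

Numbered drivers under `analysis/` run the complete study on the default
synthetic cohort (3 arms × 5 subjects × 2 tissues, 5·10⁴ reads/sample) and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort AIRR files + manifest
Rscript analysis/02_diversity.R       # clonality / D50 / homeostasis + tests
Rscript analysis/03_overlap_tracking.R
Rscript analysis/04_gene_usage.R      # V-usage matrix, PCA, per-gene tests
Rscript analysis/05_report.R          # tidy bundle + figures
```

Each step is a thin wrapper over exported functions (`run_pipeline()` does
all of it in one call), so the same computations are available on real
manifests of AIRR files.

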