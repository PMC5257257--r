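---
title: "Haploid gene-trap screen analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploid gene-trap screen analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtscreen)
```

# The screen and its statistical model

A haploid gene-trap screen couples three facts: (i) in near-haploid cells a
single insertion can produce a null allele; (ii) a gene-trap retrovirus
truncates a transcript when integrated in an expressed gene — always when
exonic, and only in the sense orientation when intronic, because its splice
acceptor is directional; (iii) FACS sorting on a reporter enriches cells
whose mutation moves the phenotype. Insertion sites recovered by sequencing
LTR-junction reads from the sorted population are compared with those from
the unsorted mutagenized population.

The per-gene test is deliberately simple. Let $N$ be the total number of
*inactivating* insertions (exonic either orientation + sense intronic)
across all genes in the sorted dataset, $k$ the gene's share of them, $M$
the total number of insertions (any orientation) across genes in the
control dataset and $m$ the gene's share. The one-sided Fisher exact test
on $[[k, N-k], [m, M-m]]$ asks whether the gene's relative frequency of
inactivating insertions in sorted cells exceeds its relative frequency of
any insertion in control cells; this is the hypergeometric upper tail
$P(X \ge k)$, computed via `stats::phyper` with no continuity correction
and no pseudocounts. Benjamini–Hochberg correction is applied across the
genes actually tested — those with at least one insertion in either
dataset. Testing never-hit genes would be uninformative and only inflate
the correction family; the cost is that $q$-values are defined relative to
this family, which the output records via $N$ and $M$.

Hits are called at $q < 0.01$. For comparing hits *between* screens the
$q$-value is a poor ruler (it depends on both datasets' depths), so the
package also computes the intronic orientation-bias score

$$\mathrm{IGTIOB} = \log_2\!\frac{S}{A} \cdot \ln(S \cdot A), \qquad
S = 1 + \#\{\text{sense intronic}\},\; A = 1 + \#\{\text{antisense intronic}\},$$

which depends on the sorted dataset alone. The +1 offsets keep the score
finite at zero counts (and are exclusive to this score — the Fisher table
uses raw counts). The log-ratio term carries the orientation bias, the
$\ln(S\cdot A)$ term weights it by intronic insertion load; the score is
antisymmetric and exactly zero at $S_{raw} = A_{raw}$.

# Mapping rules

Junction reads are 36 bp, so alignment ambiguity is the dominant failure
mode. A read is kept only when it has exactly one zero-mismatch placement
and no additional placement at one or two mismatches; everything else is
dropped (and counted). Reads sharing a placement collapse to one site whose
`read_support` is the read count. Sites 1–2 bp apart are then merged:

- **Strand-restricted by default.** Junction reads on opposite strands
  arise from opposite provirus orientations, which the analysis must keep
  apart; merging across strands is available behind
  `ignore_strand = TRUE` for datasets where that conservative reading is
  wrong.
- **Transitive closure.** Chains (1000, 1002, 1004) merge into one site:
  the pairwise rule is applied within connected components, since any
  fixed-order pairwise application would make the result input-order
  dependent.
- **Representative = highest read support, then lowest coordinate.** The
  retained site's support is the sum over merged members, so no evidence is
  discarded. Any deterministic rule would do; this one favours the
  best-evidenced coordinate.

Positions are 0-based half-open internally (BED on disk; refFlat is
already 0-based; GTF is converted on read). The insertion position is the
leftmost aligned base of the junction read and the GT orientation is the
alignment strand.

# Annotation choices

Gene models merge all transcripts of a gene: span = union of transcript
extents, exon union = union of exons, so an insertion in a region shared by
several transcripts is counted once. A position exonic in *any* transcript
is treated as exonic (`exon/intron` status can differ across isoforms; the
union reading is the package default — the alternative, exonic-in-all,
changes classification only in alternatively spliced regions and is not
exposed because the downstream counts proved insensitive to it in
simulation). A site overlapping two different genes is counted in each,
with orientation evaluated per gene; totals ($N$, $M$) are sums of
per-gene counts, which double-count such sites — with typical annotations
the effect is marginal, and for the non-overlapping synthetic layouts it
is exact.

Per-gene histograms (default 500-bp bins) run 5′→3′ in the gene's own
orientation, so position-restricted allele classes — e.g. a gene whose
insertions sit sense-only in the last intron — read the same way on either
strand.

# The synthetic-screen generator

The generator exists so that every downstream stage is testable without
sequencing data; its defaults are the study conditions the analysis
assumes.

- **One insertion per cell** (haploid, single-trap assumption). Population
  depth is set by `n_cells_control` / `n_cells_sorted_pool`
  (default $10^5$ each — a scaled-down screen; real screens are ~100×
  deeper, which sharpens every statistic here, so tests at this scale are
  conservative).
- **Integration positions** are a two-component mixture: with probability
  `tss_bias_weight` uniform in a `tss_window` (500 bp) downstream of a
  random gene's TSS, otherwise uniform over the genome. Retroviral
  integration is known to favour transcription start regions but the bias
  is qualitative; the default weight 0.3 was fixed once as a realistic
  middle ground and is a free parameter, not an estimate. An
  `intergenic_rate` key (default 0) can force extra intergenic mass for
  gene-dense layouts; the uniform component already yields intergenic
  insertions in proportion to intergenic space.
- **Sorting** is an independent Bernoulli draw per cell at probability
  $\min(1, \text{gate\_fraction} \times \text{multiplier})$ — simpler than
  an exact-quantile gate and equivalent in expectation. The default gate is
  0.10 (a "lowest 10%" reporter gate); stringent screens use 0.02. The
  multiplier is the carrying gene's `effect_strength` when the insertion
  qualifies under its effect class:
  - `lof_positive_regulator`: any inactivating insertion;
  - `three_prime_sense_dominant`: only sense insertions in the last
    intron (the 3′-restricted dominant-truncation class);
  - `orientation_independent_intronic`: intronic insertions of either
    orientation (the rare class whose disruption is orientation-blind);
  - `null`: base rate (enforced `effect_strength = 1`).
- **Gene layout**: non-overlapping 10-kb genes with five 200-bp exons,
  alternating strands, 10-kb gaps. The regular geometry makes per-gene
  null frequencies homogeneous, which the type-I-error tests rely on. Its
  last intron occupies the 3′ quarter of the gene, so the 3′-restricted
  allele class is geometrically visible in 500-bp histograms; tests of
  that class under a "highest 2%" gate make the qualifying insertions
  dominate the gene's sorted counts (with a 10% gate, non-qualifying
  pass-through at the base rate would dilute the signature — a property of
  the class itself, not of the implementation).
- **Determinism**: a single integer seed in the configuration drives one
  generator; `simulate_sorting` seeds once and draws control, pool and
  gate in a fixed order, so a fixed seed is bit-reproducible.
- **Alignment-report emission** contaminates clean per-read reports with
  the two ambiguity classes the uniqueness filter must remove (a second
  zero-mismatch placement, or an extra 1–2-mismatch placement, together at
  `multimap_rate`) and with 1–2-bp-offset duplicate reads
  (`near_dup_rate`) that the collapse rule must merge.

What the generator does **not** model: sequence-level reads (no FASTQ; no
aligner in the loop), PCR jackpotting and amplification bias, expression-
dependent trap efficiency, chromatin-state integration preferences beyond
the TSS window, and multi-insertion cells. Passing tests therefore
demonstrate the correctness of the analysis rules and the recoverability
of planted signals under idealized noise — not robustness to
library-preparation artefacts, which in real data are mitigated upstream
of this package (deduplication by unique sites rather than read counts is
itself the main defence).

# Cross-screen comparison

Genes enter the comparison when $q < 10^{-4}$ in at least one screen —
stringent, so that the matrix contains only genes with unambiguous
evidence somewhere. Admitted genes get IGTIOB scores in *all* screens;
a gene untested in a screen has $S_{raw}=A_{raw}=0$ and the formula itself
yields 0, so no imputation is involved.

Rows are clustered by complete linkage on city-block (L1) distances with
no normalization. The clustering is implemented in-package (Lance-Williams
complete-linkage update) rather than via `stats::hclust` because the leaf
order must be fully deterministic under ties: tied merge distances are
broken toward the pair whose first member has the lowest original row
index. On tie-free data the tree agrees with `hclust`; IGTIOB matrices are
tie-rich (many exact zeros), which is exactly where the explicit rule
matters. Clustering uses the *signed* scores; an `"absolute"` option
exists because the distance could defensibly be computed on magnitudes,
but the signed default preserves the sense/antisense polarity that the
score was designed to carry. Negative scores are clipped to 0 only in the
display matrix, after clustering.

`median_sem()` implements the reporting convention for FACS fluorescence
summaries: the sample median with its large-sample standard error
$1.253\,\sigma/\sqrt{n}$.

# Numerical and testing notes

- Fisher p-values are validated against an independent exhaustive
  enumeration of all 2×2 tables at fixed margins (log-binomial point
  masses summed over the tail) to $<10^{-12}$ relative error — all tables
  with $N+M \le 40$ exhaustively plus a seeded sample spanning
  $N+M \le 200$.
- The collapse rule is validated against an $O(n^2)$
  connected-components oracle, and clustering against a naive
  complete-linkage oracle that recomputes cluster distances from scratch.
- Simulation-based tests use fixed seeds and problem sizes of
  $2\times10^4$–$2\times10^5$ cells and 40–200 genes, chosen so the whole
  suite runs in well under a minute while planted effects at strength 50
  remain overwhelming ($q \sim 10^{-100}$) and null calibration bands
  (fraction of $p<0.05$ within $[0.017, 0.10]$, reflecting the
  conservatism of discrete exact tests) have comfortable sampling margins.
- Degenerate inputs: an empty sorted dataset is an error (nothing to
  test); genes with zero counts appear with count 0 and are excluded from
  the tested family; `k > N`-type inconsistencies are integrity errors,
  not silently clamped.

# Known limitations

- The multiple-testing family is the insertion-bearing gene set, not all
  annotated genes; $q$-values are only comparable between analyses using
  the same convention.
- Totals double-count sites in overlapping genes (see above).
- The 3′-terminal-intron rule for the dominant-truncation allele class is
  tied to the merged gene model; genes whose last intron differs between
  isoforms are resolved by the exon-union model, not per transcript.
- The TSS-bias weight is a scenario parameter; inferences about *real*
  integration bias cannot be read off the simulator.
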