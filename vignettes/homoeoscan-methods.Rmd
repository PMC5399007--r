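---
title: "Detecting homoeologous exchanges from replicated mRNAseq: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting homoeologous exchanges from replicated mRNAseq: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoeoscan)
```

## The inference problem

An allopolyploid carries two (AACC, AABB) or three (AABBDD) related
subgenomes. A homoeologous exchange (HE) replaces a chromosome segment of
one subgenome with a duplicate of the corresponding segment of the other:
copy number goes to 0× on the losing side and 2× on the gaining side,
while total gene dosage at the locus is conserved. Because transcript
abundance is, to first order, proportional to copy number, an HE leaves a
characteristic reciprocal footprint in a panel of mRNAseq profiles: one
homoeologue over-expressed and its partner silent, across a contiguous run
of neighbouring genes, in the carrier accession only.

`homoeoscan` turns this observation into a pipeline: pair homoeologues,
normalize abundance, test each (group, accession, genome) for departure
from the panel, classify the per-genome directions into dosage categories,
segment categorical calls into blocks, and render the panel as
Transcriptome Display Tile Plots (TDTPs). The same machinery runs on
low-pass DNA coverage, which distinguishes true structural change from
long-range expression dominance: on clean data the two assays must give
identical block calls, and the test suite asserts exactly that.

## Homoeologue pairing

Pairs are reciprocal best hits (RBH) between subgenome CDS sets from
12-column tabular alignments. Choices:

* **E-value threshold 1e-30** on every hit before ranking — the
  stringency appropriate for cross-subgenome CDS matches that diverged a
  few million years ago.
* **Best = highest bitscore**, not lowest E-value: bitscore is
  database-size independent and the robust standard for RBH. Ties are
  broken by lower E-value, then lexicographically smallest subject id, so
  pairing is fully deterministic. Multiple HSPs of a query–subject pair
  are collapsed to the strongest before ranking; RBH is a relation on
  gene pairs, not on local alignments.
* **Triplets require a consistent triangle**: (a,b), (a,d) and (b,d) must
  all be reciprocal best pairs. This is the most conservative rule; genes
  in broken triangles are dropped and counted, never silently recycled.

Gene positions are 0-based ordinals (ranks) along each chromosome. The
tile-plot layout and block coordinates need only rank, and only for one
"ordering" genome; base-pair coordinates, when present, are passed
through to BED export but never required.

## Quantification and filtering

Abundance is RPKM: `count / (length/1e3) / (aligned_total/1e6)`. The
aligned totals are caller-supplied — they are a mapping statistic that the
count matrix cannot reproduce — with a column-sum fallback behind an
explicit flag. Groups are removed when **any** member's panel-wide mean
RPKM (controls excluded, replicates included) falls below 0.4 for mRNAseq
or 0.01 for DNA coverage. Applying the rule per member and dropping the
whole group avoids one-sided pairs in which a quantifiable member facing
an unquantifiable partner would mimic an exchange. Missing expression
values are a hard error by default (`na_action = "zero"` opts into
imputation); silent imputation hides quantification failures.

## The dosage test

For each member gene and accession, the accession's replicate RPKM values
are tested against the scalar panel mean with a two-sided one-sample
*t*-test; direction is `high`/`low` by the sign of the mean difference
when *p* < α (default 0.01, raw), else `null`. Choices and their
rationale:

* **One-sample form.** The reference "mean of all samples" is a single
  number per gene, so the literal test is one-sample. A two-sample Welch
  variant would compare against the sample cloud instead; the one-sample
  reading is the default because it matches the reference's definition.
* **The panel mean includes the tested accession.** With *k* accessions
  of *n* replicates this shrinks the numerator variance by the factor
  `1 − n/(nk)`, making the test slightly conservative (effective size
  ≈ 0.0093 at α = 0.01, *k* = 20, *n* = 4). `exclude_self = TRUE` is
  available; the default keeps the panel mean definition simple and
  stable. For calibration studies, `panel_means` accepts known reference
  means, under which the test attains its nominal size exactly — the
  acceptance suite verifies the rejection rate within three binomial
  standard errors of α on 80,000 null tests.
* **Raw p-values.** One test per gene per accession at *P* < 0.01 is the
  method's definition; the segmental structure of real HEs (many adjacent
  concordant genes) is the practical guard against false discovery.
  Benjamini–Hochberg adjustment is available behind `p_adjust = "BH"`.
* **Untransformed RPKM.** The test operates on the RPKM scale;
  `transform = "log2"` (log2(x+1)) exists but is off by default. At the
  2×/0× effect sizes of real HEs the choice is immaterial; on the raw
  scale the deleted-copy signature is exact.
* **Zero variance.** Replicates tied exactly at the reference give
  *p* = 1 (no evidence); tied away from it give *p* = 0, direction by
  sign, and a `degenerate` flag. RPKM ties at 0 are the routine signature
  of a deleted copy and must be callable; the flag keeps them auditable.
  Fewer than two replicates yields *p* = NA, direction `null`,
  `degenerate = TRUE` — never a silent pass.

The nine dosage categories are a pure function of the two directions
(`Exchange C → A` ⇔ A high and C low: the high genome gained the low
genome's segment). For triplets the same convention generalizes:
exchanges are written `losers → gainers`, duplications/deletions list the
affected genomes, all-null is `No difference`. Combined labels use
canonical (sorted) genome order so that relabelling subgenomes permutes
categories consistently.

## Block calling and panel statistics

Block calling is run-length smoothing over the categorical calls: per
accession, chromosome and exchange direction, concordant genes at most
`max_gap = 2` non-concordant genes apart are merged, and merged runs with
at least `min_run = 10` concordant genes become blocks (maximal by
construction; `support` = concordant / spanned genes). An HMM would add
tuning burden without auditable benefit at these effect sizes — calls at
true HEs are nearly deterministic, so the simplest transparent rule wins.
Blocks never span chromosomes and are exported as 0-based half-open BED.

Panel-wide frequency counts, per homoeologue position and direction, the
accessions whose blocks cover it. Blocks touching ordinal 0 or the last
ordinal of their chromosome are flagged telomeric — ordinal extremes are
the gene-order proxies for chromosome ends. The direction bias (total
block-genes gaining each genome) summarizes asymmetries such as
preferential replacement of one subgenome. Whole-chromosome aneuploidy is
flagged when ≥ 80% of a chromosome's groups share the same single-genome
duplication or deletion category.

One behaviour worth knowing: the panel mean moves with the panel. Where
many accessions share an exchange (a hotspot), the reference shifts
toward the carriers, which weakens carrier calls and can produce
opposite-direction calls in non-carriers at the same locus. This is
inherent to a panel-relative reference, visible in extreme form on
noiseless data (where any deviation from the shifted mean is "significant"
with zero variance), and is why frequency summaries are split by
direction.

## Colour encoding and rendering

Per member gene, abundance is scaled across the plotted population by
division by its maximum (`v' = v / max(v)`), so the darkest tile marks the
highest-abundance sample, zeros stay exactly white, and the rendition is
purely relative within each homoeologue — multiplying a gene by any
constant changes nothing. The scaling function is deliberately the
simplest monotone map onto [0, 1] that preserves zeros; a 99th-percentile
cap (`method = "quantile"`) is available against single-sample outliers.
Channels: first genome → cyan, second → magenta, third → yellow (K unused).
Balanced pairs render blue (C+M), balanced triplets grey (C+M+Y); RGB
follows `r = (1−c)(1−k)` etc. The PNG/SVG writers rasterize the tile grid
directly (no graphics device), so identical inputs give identical bytes,
and every tile's rendered pixel agrees with its encoding to within 1/255
per channel — both asserted in the tests. Replicates are plotted as
adjacent rows; chromosome boundaries get a 2-px gap; marker genes draw a
1-px line at their column.

## The simulator

The generator emulates a replicated variety panel: per homoeologue group
one baseline expression level drawn log-normally (meanlog log 50,
sdlog 1 — a typical leaf-transcriptome dynamic range around tens of
RPKM), shared by the group's members (balanced 1:1); per sample a
multiplicative replicate noise factor (CV 0.1 by default); counts Poisson
around `copy_number × baseline × noise × length_kb × library_millions`
(library 5 × 10⁶, gene lengths uniform 500–3000 bp, homoeologues sharing
a length so RPKM ratios reflect copy number alone). Planted events follow
the dosage semantics exactly: exchange = gainer 2× / loser 0× (reciprocal
substitution), duplication 2×, deletion 0×, whole-chromosome gain/loss
1.5×/0.5× (one copy in or out of the euploid two). Four accessions-level
presets cover the study designs the package targets: a replicated variety
panel with a shared telomeric hotspot, a low-HE panel, a three-genome
panel with an aneuploid line, and an elevated-HE doubled-haploid
population. Three noise models serve different purposes: `poisson`
(default, realistic), `gaussian` (exact replicate CV, used where a stated
CV must hold exactly, e.g. calibration and recovery checks), and `none`
(noiseless expectations, used for the expression/coverage concordance
check). A fixed seed makes every output — including written fixture
files — byte-identical.

What the simulator does *not* model: genome dominance and expression-level
trans effects, mapping bias between homoeologues, batch structure,
length-dependent count dispersion beyond Poisson, and meiotic linkage
between events. Passing tests therefore demonstrate correctness of the
inference machinery under the stated generative model, not robustness to
every artefact of real mRNAseq; the DNA-coverage mode exists precisely
because expression alone cannot exclude dominance effects.

## Problem sizes and numerical notes

The validation suite runs at desk scale, chosen to keep statistical
resolution high while remaining quick: calibration on 2,000 balanced
groups × 20 accessions × 4 replicates (80,000 tests; three binomial
standard errors of α = 0.01 is ±0.001), recovery on 600 groups with five
planted 30-gene events, oracle comparisons on hundreds of randomized toy
instances. The per-(gene, accession) t statistics are computed by matrix
algebra in one pass; a guard clamps tiny negative sum-of-squares residues
to zero before the variance, and zero-variance cells follow the
degenerate rules above rather than producing NaN. Ordinals are re-ranked
to gap-free 0..n−1 per chromosome at load; all interval arithmetic is
0-based half-open throughout.

## Known limitations

* Copy number is inferred from relative abundance; a transcriptionally
  silenced subgenome looks like a deletion on mRNAseq alone (run the
  DNA-coverage mode to discriminate).
* The panel-relative reference weakens calls at high-frequency HE loci
  (see above); at fixation an exchange is invisible by construction.
* Single-replicate accessions cannot be tested (flagged degenerate);
  block structure, not the t-test, is then the only evidence.
* Block boundaries are gene-order resolution — no base-pair breakpoint
  refinement.
* The paired-gene universe conditions everything: genes without an RBH
  partner (or in broken triangles) are invisible to the method.
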