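---
title: "Methods: splicing specificity and RBP-sponge scoring after lncRNA knockdown"
author: "spongesplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing specificity and RBP-sponge scoring after lncRNA knockdown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongesplice)
```

## The analysis

Knocking down a long non-coding RNA (lncRNA) and sequencing the
transcriptome against matched controls yields, after event calling, a table
of differential alternative-splicing (AS) events per comparison: skipped
exons (SE), retained introns (RI), alternative 5'/3' splice sites and
mutually exclusive exons, each with a p-value, an FDR and an
inclusion-level difference. `spongesplice` takes these tables (rMATS
v3.2.5 column dialect), together with eCLIP-style RNA-binding-protein (RBP)
peak intervals and a sample sheet mapping each comparison to its
`(lncRNA, cell line)`, and carries out the downstream analysis:

1. **Significance filtering** (`filter_events()`): keep events with
   `fdr < 0.1` and `p < 0.05`, strict inequalities. Both thresholds are
   configurable; the defaults are the setting under which the
   high-confidence event catalogues in this kind of study are defined.
2. **Frequency matrices** (`build_frequency_matrix()`): per event type, a
   gene x knockdown matrix counting unique significant events; all-zero
   gene rows are dropped. Cell-type specificity is summarized as
   Venn-style overlaps of per-cell-line gene sets and the fraction of
   genes spliced in two or more cell lines (`specificity_summary()`).
3. **Proximal regions** (`extract_proximal_regions()`): each event
   contributes six anchor coordinates — start and end of the upstream
   exon, of the event-specific exon/intron, and of the downstream exon —
   and each anchor is widened by ±500 bp into a window where RBP binding
   is interrogated.
4. **Interval intersection** (`intersect_intervals()`, `bound_flags()`):
   a sort-and-sweep engine with bedtools-intersect semantics marks each
   (region, RBP) pair bound or unbound; regions are only ever tested
   against peaks from their own cell line.
5. **Binding enrichment** (`run_enrichment()`): per (cell line, lncRNA,
   RBP), the 2x2 table (focal lncRNA's regions vs all other knockdowns'
   regions, bound vs unbound) is tested with a one-sided Fisher exact
   test; p-values are Benjamini–Hochberg adjusted within each cell line
   and displayed as `-log10(adjusted p)` heatmap matrices.
6. **Sponge scoring** (`sponge_scores()`): the binding *breadth* of a
   lncRNA is the fraction of tested RBPs significantly enriched near its
   splice events. Knockdowns with broad, strong binding enrichment are
   candidates for the RBP-sponge model: an abundant lncRNA that titrates
   many RBPs, whose loss releases them onto pre-mRNA targets and perturbs
   splicing.
7. **Binding-vs-splicing correlation**
   (`binding_splicing_correlation()`): Spearman and Pearson correlation
   between per-knockdown significant SE counts and significantly bound
   RBP counts, with explicit insufficient-data and non-significance
   reporting, since per-cell-line sample sizes are small.

## The contingency table and its null convention

For a focal lncRNA in a cell line with \(N\) proximal regions in total:

|               | bound | unbound |
|---------------|-------|---------|
| focal lncRNA  | x     | y       |
| all others    | a     | b       |

with \(x + y\) the focal lncRNA's regions and \(a + b\) the background.
The one-sided p-value is the hypergeometric upper tail conditional on both
margins, computed in log-factorial (`lchoose`) arithmetic; the odds ratio
is the sample odds ratio \(xb/ya\) (infinite when \(ya = 0 < xb\)). The
two-sided variant sums all tables whose conditional probability does not
exceed the observed one, with the customary \(1 + 10^{-7}\) tie tolerance.

Two degeneracies produce *null* results rather than numbers, and nulls are
deliberately distinct from zeros throughout (serialized as `NA`, rendered
grey in heatmaps):

* an RBP bound in **every** region of the cell line (`y + b = 0`): there
  is no unbound observation, the margin is degenerate, and every test in
  that column is null — the behaviour ubiquitously binding RBPs show;
* an all-zero table.

Null tests are excluded from the BH family size `m` and from both the
numerator and denominator of the breadth score. A lncRNA whose tests are
all null gets an undefined breadth and is flagged rather than ranked 0.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fdr_max`, `pvalue_max` | 0.1, 0.05 | strict significance filter on events |
| `window` | 500 bp | half-width of proximal windows around each of the six anchors |
| `min_overlap` | 1 bp | minimum region–peak overlap (bedtools default) |
| `stranded` | FALSE | require matching strands; the stated procedure is unstranded |
| `alternative` | "greater" | binding over-representation; two-sided available |
| `method` | "BH" | adjustment across all tests of one cell line |
| `alpha` | 0.05 | adjusted-p level entering the breadth score |
| `linkage` | "average" | agglomeration for the 1 − Spearman clustering |

Counting is region-level by default; `per_gene = TRUE` collapses regions
to genes first (a gene is bound if any of its regions is), the coarser
reading in which binding is a gene-level property. Adjustment is performed
within each cell line because the heatmap panels, and the binding data
themselves, are per-cell-line.

## Clustering

Frequency and significance matrices are clustered with the
"one minus Spearman rank correlation" distance,
\(d(u,v) = 1 - \rho_s(u,v) \in [0,2]\), and average linkage. The linkage
is a deliberate choice (the distance, not the linkage, is what the
procedure pins down) and is exposed as a config key. Zero-variance
vectors, whose rank correlation is undefined, are assigned the maximal
distance 2 with a warning so they join the tree last instead of aborting
the analysis; row/column labels are pre-sorted before clustering so
equal-distance merges resolve identically across runs and the leaf order
is deterministic.

## Gene-set over-representation

`overrepresentation()` is a generic hypergeometric upper-tail test of a
query gene set against a user-supplied annotation table (GMT format), with
BH adjustment across terms and a raw `p < 0.05` report filter. It is
mathematically the one-sided Fisher test on the induced 2x2 table, which
the test suite asserts against the package's own `fisher_exact()`. The
default universe is the set of genes observable in the experiment (all
genes appearing in any event table), not the genome: an over-representation
test against a universe the assay could never have reported from is
anti-conservative. No ontology data are bundled; term databases are the
user's input.

## What the synthetic generator emulates — and what it does not

`simulate_splicing_study()` generates a study with planted, bookkept
structure so that every stage has an exact oracle:

* **Study shape.** Three cell lines x 13 knockdowns (39 comparisons),
  mirroring the scale of real CRISPRi knockdown panels; binding peaks for
  two cell lines only, so the no-binding-data path (a cell line without
  eCLIP coverage) is always exercised.
* **Events.** Each gene owns a territory of evenly spaced slots; a slot
  deterministically encodes the six exon coordinates (exon length
  1200 bp, gaps 1200 bp). All anchors are therefore ≥ 1200 bp apart and
  ±500 bp windows never overlap, so a peak planted at one anchor binds
  exactly one region and the planted flag table is exactly recoverable.
  Slots are unique per comparison within a cell line; the same gene and
  comparison index in another cell line reuses coordinates, so shared
  genes produce genuine duplicate events across cell lines for the
  deduplication path.
* **Significance** is planted by construction: significant events draw
  `p ~ U(0, pvalue_max/2)`, `fdr ~ U(0, fdr_max/2)`; non-significant
  events draw above both thresholds. Exactly `round(frac_significant * n)`
  events per comparison pass the default filter. Per-comparison event
  totals are jittered by ±20% by default so knockdowns differ in splicing
  burden; setting `n_events_jitter = 0` fixes them exactly.
* **Sharing.** The per-cell-line AS gene sets are constructed so that a
  target fraction (default 0.07) of the union is assigned to two cell
  lines; the realized fraction is recorded in the ground truth.
* **Binding.** Every (window, RBP) pair is bound independently with
  probability 0.8 for the planted sponge lncRNA and 0.1 for the
  background (a uniform background field); `saturated_rbps` bind with
  probability 1 to exercise the null-column contract. The per-window
  Bernoulli reading of "uniform background" is what keeps the planted
  truth exact.

The generator does **not** simulate reads, replicate structure, the event
caller's internal statistics, peak shapes, crosslink biases, or correlated
binding between RBPs. Green tests therefore certify the downstream
pipeline — filtering, counting, intersection, testing, scoring — on inputs
with the declared format and planted structure; they say nothing about
upstream alignment/event-calling quality on real data, and real eCLIP
backgrounds are rougher than a uniform Bernoulli field.

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open everywhere (rMATS `*_0base`
  starts taken verbatim, end columns exclusive, BED native), so no stage
  converts coordinates and abutting intervals never count as overlapping.
* Windows clip at coordinate 0; chromosome ends are not clipped because
  chromosome lengths are not an input.
* Overlapping windows from nearby anchors are kept as six distinct
  records per event — merging would silently change the contingency
  denominators.
* Event identity is the tuple (type, chromosome, strand, six
  coordinates); deduplication keeps the first occurrence.
* The sweep engine processes interval ends strictly before starts at
  equal positions, which is exactly the half-open abutment rule; output
  order is fixed (chromosome, region start, peak start) for determinism.
* `fisher_exact` is validated against direct PMF enumeration for every
  2x2 table with all margins ≤ 30 at 1e-12, and against
  `stats::fisher.test` on random tables.
* Mixed `chr1`/`1` chromosome naming is rejected under the default strict
  mode rather than silently harmonized.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on synthetic data
at desk scale, chosen to keep the full suite in the low minutes while
leaving the checked properties exact rather than approximate: interval
fixtures of 1,000 x 1,000 intervals against an all-pairs oracle (20
seeds); exhaustive Fisher enumeration over all margins ≤ 30 (~164,000
tables); sponge recovery over 25 seeds at binding density 0.8 vs 0.1 with
20 RBPs and 10 knockdowns per cell line; and type-I calibration pooled
over 10 seeds of a null study with 200 events per comparison. The null
configuration uses the larger event count on purpose: exact conditional
tests are conservative on coarse discrete supports, and wider margins
shrink the PMF step at the critical value so the attained size approaches
the nominal 0.05 from below.

## Known limitations

* Only SE and RI events flow into region extraction by default; the
  six-anchor mapping for A5SS/A3SS/MXE (long/short/flanking and
  first-exon/upstream/downstream) is implemented behind
  `allow_extended_types` and documented, but those event types are not
  part of the analyzed path.
* The breadth score is this package's operationalization of the sponge
  model; the model itself is qualitative, and breadth deliberately uses
  adjusted p-values at a single `alpha` rather than effect sizes.
* `rMATS` FDR values are trusted as given; the package never recomputes
  FDR across comparisons.
* With ~10–14 knockdowns per cell line, the binding-vs-splicing
  correlation is underpowered, and the report says so explicitly rather
  than hiding behind a point estimate.
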