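---
title: "Methods: inverse-correlation miRNA:target networks of acquired resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse-correlation miRNA:target networks of acquired resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtarnet)
```

## The model and its assumptions

`mirtarnet` analyses the standard acquired-resistance design: a parental
cell line and two or more resistant clones derived from it independently,
profiled in biological replicate on a miRNA platform and a gene platform.
The core inference is not statistical novelty but *constraint stacking*:
an interaction is reported only if it (i) involves a miRNA and a gene that
are each differentially expressed, (ii) is an experimentally validated
miRNA→target edge, (iii) shows the repression signature (opposite
directions) within a clone, and (iv) does so identically in both clones.
Each constraint is individually weak; their conjunction is what removes the
clone-private noise that dominates single-comparison DE lists.

Assumptions worth stating explicitly:

* **Linear intensities, log-normal noise.** Input matrices are
  normalized, strictly positive linear-scale intensities; all testing is on
  log2 values, where replicate noise is modelled as additive Gaussian.
* **Two-group comparisons.** Each clone is compared only with its parental
  control. With two groups, the one-way ANOVA F-test is the square of the
  pooled t; we use the Welch t-test instead, which is equal in the
  equal-variance case and robust when replicate variances differ.
  The exact moderated-variance variant used by vendor array software is not
  reproduced; with triplicates, unmoderated Welch is the conservative choice.
* **Repression is directional, not quantitative.** The inverse-correlation
  filter uses only call directions, not effect-size correlation — with
  three replicates per group, a per-edge correlation estimate would be
  noise.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `fold_threshold` | 2 | linear fold change | conventional array cutoff; non-strict (|FC| = 2 is kept) |
| `alpha` | 0.05 | FDR | strict (`adj_p < alpha`) |
| `intensity_threshold` | 50 | linear intensity | conventional expressed-probe floor; a feature is kept if its *maximum* over samples exceeds it, so a gene expressed in any one condition survives |
| `mirna_prefix` | `"hsa-miR"` | id prefix | the mature-human-miRNA wildcard as used on miRNA arrays, applied literally — it excludes `hsa-let-*`; pass `"hsa-"` to retain let-7 family members |
| `var_equal` (IC50 t-test) | `TRUE` | — | "independent t-test" in the assay convention is the classic pooled test; Welch available |

Boundary conventions are deliberate and documented rather than incidental:
fold-change non-strict, p strict, BH applied per platform matrix (all
tested features of one comparison), never across the pooled clone pairs.

## Differential expression: numerical details

* Welch p-values come from `stats::t.test()`. On noiseless data (useful in
  validation) both groups can be exactly constant, where the t statistic is
  undefined; the implementation then decides by the means alone — p = 0
  when they differ, p = 1 when equal. This degenerate branch never triggers
  on real intensities.
* Signed fold change is `2^d` for log2 difference `d >= 0` and `-2^(-d)`
  otherwise, matching the "±fold" display convention of array software;
  `|FC| = 2^|log2FC|` always holds.
* `bh_adjust()` validates and delegates to `stats::p.adjust(method = "BH")`;
  the test suite checks it against a literal step-up implementation.

## Network construction

The reference network is a deduplicated bipartite edge list; a token
appearing both as miRNA and gene is rejected as a format error. Matching is
exact string identity after whitespace trimming and case-normalisation of
the `hsa-` prefix; mature-arm suffixes (`-5p`/`-3p`) are never collapsed,
because arm identity is meaningful in validated target databases.

Clone intersection requires *identical* direction annotations on an edge in
both clones. The alternative — intersecting edge identities regardless of
direction pattern — would accept a pair that is repressed in one clone and
de-repressed in the other, which is not one consistent mechanism; published
common networks also report a single direction pattern per interaction.
The operation is commutative and idempotent, and the containment chain
common ⊆ clone ⊆ reference is property-tested on random instances.

Mapping statistics count unique node identities (DE miRNAs + DE genes
present in the network), matching the usual "x% of DE features mapped"
phrasing; ties for the most-targeted gene are all reported,
lexicographically sorted.

## Enrichment

Over-representation uses the upper-tail hypergeometric distribution
(`P(X >= k)` with set size `K`, query size `n`, universe `N`), BH-adjusted
across sets. The default universe is the union of all collection genes,
with sets and query intersected against it — the standard explicit ORA
convention when no assay-specific background is given. Published pathway
p-values from web tools depend on the database release behind them and are
not reproduced; the implementation is instead validated against exhaustive
enumeration of all `C(N, n)` draws for every universe size up to 12.
The query is the common-network *gene* set (one cell line per invocation);
miRNAs are regulators here, not pathway members.

## Dose–response and qPCR

The 4PL model `v(d) = bottom + (top - bottom) / (1 + (d/ic50)^hill)` is fit
on log10 dose by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`),
the standard choice for MTT viability curves when no model is otherwise
specified. Initialisation: top = max viability, bottom = min, hill = 1,
midpoint = median dose; the midpoint is bounded in (0, 10 × max dose].
The `converged` flag is honest: it is `FALSE` on optimiser failure *and*
when the fitted curve is not a decreasing viability curve (`hill <= 0` or
`top <= bottom`), as with viability rising in dose; no exception is thrown.
Fitting is invariant to dose reordering and to uniform rescaling of
viability (the asymptotes absorb scale). Replicate IC50s are summarised by
their arithmetic mean (displayed to 2 decimals, stored at full precision)
and compared by a two-sided pooled t-test with the usual star convention.

ΔCt quantification is `mean Ct(reference) − mean Ct(target)` with relative
expression `2^ΔCt`, optionally normalised to the parental sample; group
comparisons use the Mann–Whitney rank-sum test. Efficiency-corrected
(Pfaffl) models are out of scope.

## What the synthetic data emulates — and what it does not

`simulate_experiment()` generates log2 intensities as
`baseline + effect + noise` and exponentiates:

* baseline per feature ~ N(10, 1.5) on log2 — expressed-probe intensities,
  comfortably above the intensity-50 floor, because low-level array
  filtering is out of scope and the generator models probes that survive it;
* 50 planted miRNA→gene pairs (default) with opposite directions of
  magnitude `effect_log2fc = 2`, applied identically in every resistant
  clone;
* replicate noise SD 0.25 on log2, three replicates per group;
* 450 decoy reference edges, plus clone-private background drift:
  each non-planted feature is, per clone independently, shifted in a random
  direction with probability 0.05. Background features can form
  inverse-correlated edges inside a single clone network; the clone
  intersection removes them, which is precisely the behaviour the benchmark
  should exercise. Decoys never join two planted features — such an edge
  would be indistinguishable from signal by construction, hence not a decoy.

Matrix sizes (100 miRNAs × 120 genes by default) were fixed by a
Monte-Carlo power calculation: with a 2-log2 effect, SD 0.25 and n = 3, the
Welch test's Satterthwaite degrees of freedom fluctuate down to 2, and the
probability that a planted feature survives BH at these matrix sizes is
about 99% per feature and clone, i.e. ≈97% per planted pair through all
four call legs. The benchmark sizes are therefore a deliberately scaled-down
caricature of an array experiment, chosen so that recovery reflects the
pipeline's logic rather than raw test power.

What passing the recovery benchmark does **not** show about real data:
simulated features are independent (no co-expression blocks, no probe
cross-hybridisation), noise is homoscedastic, there are no batch effects,
and the validated reference network is complete and correct for the planted
truth. On real arrays the reference database is incomplete and biased
toward well-studied miRNAs, and fold-change directions can disagree between
probes of one gene — none of which the generator models.

## Degenerate inputs and tie-breaks

* Clustering uses 1 − Pearson correlation on log2 intensities with average
  linkage (UPGMA); the metric is undefined for a zero-variance sample, which
  is reported as an error naming the offending sample. Equal-distance merges
  follow input column order. The implementation is checked against a
  brute-force nearest-pair agglomeration oracle through cophenetic
  distances, which are invariant to merge bookkeeping.
* An empty DE set maps 0 features; the mapped percentage is reported as 0
  with an `undefined` flag rather than NaN.
* Empty networks summarise to all-zero counts and export as header-only
  edge lists.

## Problem sizes used in validation

The test suite and the acceptance script run the full pipeline on the
default 100 × 120 design (about 220 Welch tests per clone and a 500-edge
reference network), 1000 random network instances for the algebraic
properties, and exhaustive hypergeometric enumeration up to universe size
12 — all in well under a minute on one core, which makes the whole
validation surface cheap to re-run on every change.

## Known limitations

* Direction-only integration cannot rank interactions by strength;
  an edge weight (e.g. correlation across more replicates) is future work.
* BH per platform assumes the platform is the natural multiplicity family;
  users pooling many comparisons should adjust externally.
* The 4PL fit reports a single IC50 per curve; confidence intervals would
  require profile likelihood or bootstrap, not implemented.
* GraphML export carries one direction attribute per node, so a feature
  with different directions across cell lines should be exported per cell
  line.
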