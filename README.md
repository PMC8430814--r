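# mirtarnet

Integrated miRNA–mRNA inverse-correlation network analysis of acquired drug
resistance, for bulk expression microarray experiments with the classic
*parental line vs. independently derived resistant clones* design (the
motivating system is sunitinib resistance in clear cell renal cell carcinoma
cell lines, but nothing in the package is specific to that drug or tumour).

## The problem and the method

Comparing a resistant clone with its parental control typically yields
thousands of differentially expressed (DE) genes, most only indirectly
linked to the resistant phenotype — pathway enrichment over such lists is
usually uninformative. `mirtarnet` implements an integration strategy that
concentrates the signal on miRNA-regulated genes:

1. **Differential expression per clone.** For each resistant clone *c* and
   feature *i*, a Welch two-sample t-test on log2 intensities against the
   parental replicates, with Benjamini–Hochberg FDR control across the
   platform. A feature is called with signed fold change
   FC = 2^Δ (Δ = mean log2 clone − mean log2 parental; −2^(−Δ) when Δ < 0),
   at |FC| ≥ 2 and adjusted p < 0.05.
2. **Mapping onto a validated reference network.** DE miRNAs and genes are
   mapped onto an experimentally validated miRNA→target edge list
   (miRTarBase-style, user-supplied).
3. **Inverse-correlation filtering.** A reference edge is kept for a clone
   iff the miRNA and its target moved in *opposite* directions in that clone
   — the signature of miRNA-mediated repression.
4. **Clone intersection.** The two clonal networks are intersected,
   requiring identical direction annotations, giving the cell line's
   *common resistance network*: interactions reproducibly associated with
   resistance in both independently derived clones.
5. **Over-representation analysis.** Common-network genes are tested
   against GMT gene-set collections by the upper-tail hypergeometric test
   (query size *n*, set size *K*, universe *N*, overlap *k*;
   p = P(X ≥ k), BH-adjusted across sets).

Supporting assay computations are included: four-parameter logistic (4PL)
dose–response fitting for MTT viability data, with
IC50 = the dose at the midpoint of the fitted top and bottom asymptotes and
pooled-t comparison of replicate IC50s, and ΔCt qPCR quantification
(ΔCt = mean Ct(reference) − mean Ct(target), relative expression 2^ΔCt,
Mann–Whitney group comparison).

A synthetic-data generator (`simulate_experiment()`) plants known
miRNA→gene repression pairs in log-normal intensity matrices, together with
decoy reference edges and clone-private background drift, so the entire
pipeline can be benchmarked for planted-pair precision and recall.

## Worked example

Replaying the published common resistance network of the 786-O cell line
and its IC50 table (both ship with the package):

```r
library(mirtarnet)

summarize_network(published_common_network("786-O"))
#> <network_summary> 77 interactions: 5 with 5 up-miRNAs (4 genes), 72 with 17 down-miRNAs (55 genes)
#>   most targeted: HIF1A (in-degree 5)

ic <- published_ic50("resistance")
grp <- function(cl, g) ic$ic50[ic$cell_line == cl & ic$group == g]
summarize_ic50(grp("786-O", "c1"), reference = grp("786-O", "parental"))
#> <ic50_summary> mean IC50 20.34 uM (n = 3)  vs reference 7.93: p = 0.00727 **
```

The first call says the 786-O network links 5 up-regulated miRNAs to 4
repressed genes and 17 down-regulated miRNAs to 55 de-repressed genes, with
the hypoxia factor HIF1A the most-targeted gene. The second reproduces the
resistant clone's ~2.6-fold IC50 shift and its significance at p < 0.01.

End-to-end on simulated data with 50 planted repression pairs:

```r
sim <- simulate_experiment(simulation_design(seed = 1))
paths <- write_simulation(sim, "simdata")
cfg <- pipeline_config(list(
  mirna_expression = paths[["mirnas"]], gene_expression = paths[["genes"]],
  gene_annotation = paths[["gene_annotation"]],
  reference_network = paths[["reference"]], seed = 1))
report <- run_pipeline(cfg)
recovery_stats(report$common_network, sim$truth)
#> precision 1.00, recall 0.98
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`
(`simulate` and `run` subcommands over YAML design/config files).

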