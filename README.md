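# pairseq

Tools for comparing the biology recovered by single-cell (scRNA-seq) and
single-nucleus (snRNA-seq) droplet transcriptomics of patient-matched
normal and tumor tissue. Dissociating fresh tissue skews composition toward
immune cells and activates stress programs; profiling nuclei from frozen
tissue avoids both but shifts the captured transcriptome and weakens
reference-based annotation. pairseq implements one pipeline in which these
method effects can be measured, together with a synthetic paired-cohort
generator with recorded ground truth so that every stage is testable
end to end. It is aimed at analysts designing or interpreting paired
cell/nucleus studies, particularly in tumor contexts.

## What it computes

* **Quality control** — per-cell `nCount`, `nFeatures`, `percent_mt`;
  per-sample MAD outlier filtering (`median ± nmads·MAD`, MAD constant
  1.4826) with an absolute 25% mitochondrial cap; artificial-nearest-
  neighbour doublet detection at an assumed 5% doublet rate; median-scaled
  `log1p` normalization.
* **Hierarchical annotation** — weighted-kNN label transfer in reference
  PC space with per-level confidence scores in [0, 1]; cells under 0.5 are
  `unclassified`.
* **Malignancy calling** — genome-ordered windowed relative expression
  against matched Normal epithelial cells, a per-cell CNV score (mean of
  squared scaled values), and the quintile rule: epithelial cells in the
  top CNV-score quintile and bottom annotation-score quintile of their
  patient × method stratum are called malignant.
* **Pseudobulk differential expression** — summed counts per
  (type, patient, tissue, method); per-gene negative-binomial GLM with
  offsets, moment dispersion shrunk halfway to a mean trend, Wald tests,
  BH adjustment; DEG-overlap concordance against the null expectation
  `(|A|/n_A)·(|B|/n_B)·N`; Ward clustering and marker-panel PCA.
* **Ligand–receptor interactome** — mean-product edge strengths with
  geometric-mean subunits, permutation p-values, per-type in/out degrees,
  pathway aggregates.
* **Comparison metrics** — composition tables and tumor/normal transition
  ratios, Fisher exact contrasts of unclassified fractions, silhouette
  coherence on a 2-D embedding, stress-signature fractions, raw
  mitochondrial percentages, and a Type-II two-way ANOVA utility.

## A worked example

```r
library(pairseq)

p   <- sim_params(n_patients = 2, cells_per_sample = 400, n_genes = 600,
                  n_mito = 10, stress_n = 20,
                  cnv_segments = list(
                    list(chromosome = "chr2", start = 6, length = 40, fold = 2),
                    list(chromosome = "chr5", start = 6, length = 40, fold = 0.5)))
p$seed <- 3
coh   <- generate_cohort(p)
atlas <- make_reference(p, n_ref_per_type = 50)

met <- compute_cell_metrics(coh$counts, coh$genes) |>
  dplyr::left_join(coh$cells, by = "barcode")
dplyr::summarise(dplyr::group_by(met, method),
                 mean_mt = mean(percent_mt, na.rm = TRUE))
#>   method          mean_mt
#> 1 cell              11.2
#> 2 immune_depleted   15.1
#> 3 nucleus            2.59

norm <- normalize_counts(coh$counts)
ann  <- annotate_cells(norm, atlas)
truth <- dplyr::inner_join(ann[ann$level == 1, ], coh$truth$cells, "barcode")
mean(truth$label[!truth$doublet & !truth$malignant] ==
     truth$level1[!truth$doublet & !truth$malignant])
#> [1] 1
```

The mitochondrial means land on the per-method fractions the generator was
given (11.2% for cells, 2.6% for nuclei, 15.2% after immune depletion),
and the compartment-level annotation of unperturbed cells is exact at the
default 8-fold marker separation. `run_pipeline("cfg.yaml")` drives the
same stages from a config file and writes one TSV per stage plus a run
log; `inst/scripts/pairseq.R` wraps it for the shell
(`pairseq.R run --config cfg.yaml`, `pairseq.R simulate --config sim.yaml`).

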