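# lncomp

Analysis toolkit for studying long non-coding RNA (lncRNA) expression on
reannotated microarray compendia, modeled on workflows used for bovine
ovarian follicle and early-embryo transcriptomics.  The package covers the
full path from mapped probes to hub genes:

1. **Probe reannotation** — classify each mapped probe against several
   genome annotation sources: *mRNA* (≥1 bp exon overlap, same strand),
   *intronic lncRNA* (fully inside an intron, same strand), *antisense
   lncRNA* (overlapping a gene body on the opposite strand), *lincRNA* (no
   gene overlap).  One source suffices to call a probe mRNA; an lncRNA call
   requires **all** sources to concur; within-source mRNA/lncRNA conflicts
   discard the probe.  lincRNAs are stratified by nearest-gene distance
   (≤1 kb same strand = possible UTR extension; >50 kb = far), and
   redundant probes per gene are reduced to the one with the highest mean
   signal.
2. **Compendium assembly** — log2 transform, quantile normalization across
   all arrays, Spearman-correlation outlier screening, and detection
   calling: a probe is expressed on an array when its raw intensity exceeds
   the 95th percentile of that array's negative-control intensities; a
   probe is expressed *in a tissue* when detected in >65 % of its samples.
3. **Signed weighted co-expression network** — built from first
   principles: a_ij = ((1+r_ij)/2)^β (default β = 12, chosen by the
   scale-free criterion R² ≥ 0.9 with mean connectivity < 100), signed
   topological overlap, average-linkage clustering of 1−TOM with a static
   cut, minimum module size 30, eigengene-based module merging at
   dissimilarity 0.25, module eigengenes (first principal components),
   module–tissue correlations, and module composition statistics
   (mRNA/lncRNA/TF/housekeeping fractions).
4. **Enrichment** — exact upper-tail hypergeometric tests of gene sets
   (GMT) in module mRNA membership, Benjamini–Hochberg adjusted within
   namespace, filtered at adjusted p < 0.05 and q < 0.2.
5. **Hubs** — within-module Pearson edges with r > 0.7 and p < 0.05
   (strict), and hub transcription factors / genes as the nodes with the
   largest correlation-coefficient sums.
6. **Synthetic data** — a generator with planted ground truth (annotation
   sources with a controllable disagreement rate, probe classes true by
   construction, tissue-linked co-expression modules, tissue-specific
   probe sets, negative-control backgrounds, planted hubs) so every stage
   is testable without external data.

## Worked example

```r
library(lncomp)

design <- simulation_design(seed = 42,
  n_probes_per_class = c(mRNA = 220, intronic = 20, antisense = 30,
                         lincRNA = 80),
  n_modules = 5, module_sizes = rep(60, 5), within_module_cor = 0.8,
  tissues = data.frame(
    tissue = c("blastocyst", "granulosa", "oocyte", "cumulus", "two_cell"),
    n_samples = c(30, 25, 20, 15, 10), n_series = c(3, 3, 2, 2, 2)))
sim <- simulate_all(design)

# consensus classification across the three annotation sources
per <- vapply(sim$sources,
              function(s) classify_probes_one_source(sim$probes, s),
              character(nrow(sim$probes)))
labels <- classify_consensus(per, sim$probes$probe_id)
table(labels$final_class, labels$subclass)
#>          antisense intronic lincRNA none
#>   lncRNA        30       20      80    0
#>   mRNA           0        0       0  220

# normalization, detection, tissue specificity
norm <- log2_and_quantile_normalize(sim$matrix)
det <- call_detection(sim$matrix, detection_threshold(sim$negctl))
ts <- tissue_expression(det, sim$meta)
vapply(ts$specific_sets, length, 1L)
#> blastocyst  granulosa     oocyte    cumulus   two_cell
#>          8          6         12          6          4

# signed network on the planted module members
mem <- names(sim$truth$module)[sim$truth$module != "none"]
net <- build_network_modules(norm$values[mem, ], beta = 12)
table(net$assignment)
#>      blue     brown     green turquoise    yellow
#>        60        60        60        60        60
adjusted_rand_index(net$assignment[mem], sim$truth$module[mem])
#> [1] 1
round(module_trait_correlation(net$eigengenes, sim$meta)$r, 2)
#>           blastocyst granulosa oocyte cumulus two_cell
#> yellow          0.86     -0.37  -0.27   -0.24    -0.14
#> turquoise      -0.20     -0.09  -0.24    0.71    -0.10
#> blue           -0.14     -0.19  -0.07   -0.06     0.67
#> green          -0.30      0.84  -0.21   -0.18    -0.25
#> brown          -0.27     -0.21   0.76   -0.18    -0.08
```

All five planted modules are recovered exactly (adjusted Rand index 1), the
planted tissue-specific sets come back via the >65 % rule, and each
module's top-|r| tissue is its planted driver.

The full pipeline (simulate → annotate → assemble → network → enrich →
hubs) is available as `run_pipeline(config, outdir)` or from the shell via
the installed script:

```sh
lncomp run --config design.yaml --outdir out --seed 1
```

Every run writes a `manifest.json` with the probe filter funnel (mapped →
classified → concordant → deduplicated → detected) and per-file checksums.

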