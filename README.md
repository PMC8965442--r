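# switchnet

Detection of **switch genes** in case/control transcriptomes by
co-expression network cartography.

In neurodegeneration studies (e.g. spinal-cord motor neurons of ALS
patients versus controls) the genes that drive a transcriptional state
flip are often not the strongest differentially expressed genes but the
ones sitting between expression modules: weakly connected inside their own
module, heavily connected outside it, and on average *anti-correlated*
with their network neighbours. `switchnet` implements the full pipeline
that finds them, plus a planted-truth synthetic generator that makes every
stage testable without any external data.

## Method

From a genes × samples log2 expression matrix with case/control labels:

1. **Filter** — remove unexpressed genes; per gene compute
   log2FC = mean(case) − mean(control), a Welch t-test p-value and a
   Benjamini–Hochberg q-value; keep genes with
   |log2FC| ≥ log2(FC-threshold) and q ≤ α.
2. **Network** — Pearson correlation over pooled samples; edge where
   |r| ≥ threshold, signed r kept as the weight.
3. **Communities** — seeded replicate k-means (Lloyd + k-means++) on
   z-scored profiles; k from the SSE scree elbow (chord rule).
4. **Cartography** — per node the within-module degree z-score
   *Zg*, the clusterphobic coefficient *Kπ* = 1 − (k_in/k_tot)², and the
   average Pearson correlation with its neighbours (*APCC*). Hubs:
   party (APCC ≥ 0.5), date (0 ≤ APCC < 0.5), fight-club (APCC < 0);
   network hubs at Zg > 5; regions R1–R7 on the (Kπ, Zg) plane.
5. **Switch call** — `Zg < 2.5 ∧ Kπ > 0.8 ∧ APCC < 0` (all strict);
   switch genes are the R4 fight-club hubs.

Downstream tools: switch-gene biclustering, node-removal robustness curves
(average shortest path of the largest remaining component), hypergeometric
over-representation against GMT collections, degree/betweenness ranking of
TF/miRNA/chemical regulators with multi-database source consensus, and
multi-dataset overlap (Venn) tables.

## Worked example

```r
library(switchnet)

sim <- generate_synthetic(synthetic_config(seed = 1))   # planted benchmark
cfg <- run_config(dataset = "demo", fold_change = 1.5,
                  correlation_threshold = 0.5, seed = 1)
res <- run_pipeline(sim$expr, cfg)
res
#> PipelineResult 'demo': 155 genes -> 155 expressed -> 103 retained
#>   correlation threshold 0.50, 2415 edges, k = 5 communities
#>   5 switch genes called

sort(res$switch_genes)
#> [1] "SW01" "SW02" "SW03" "SW04" "SW05"
sort(sim$truth$switch_genes)      # exactly the planted switch genes
#> [1] "SW01" "SW02" "SW03" "SW04" "SW05"

res$cartography[res$cartography$is_switch,
                c("node", "zg", "kpi", "apcc", "region")]
#>     node         zg       kpi       apcc region
#> 99  SW01  1.0690450 0.9973014 -0.6618103     R4
#> 100 SW02 -0.2672612 0.9983111 -0.6827529     R4
#> 101 SW03  1.0690450 0.9958377 -0.6872820     R4
#> 102 SW04 -0.2672612 0.9981096 -0.6751538     R4
#> 103 SW05 -1.6035675 0.9991837 -0.6448670     R4
```

Each called gene has low within-module degree (Zg well under 2.5), almost
all links outside its community (Kπ ≈ 1), and strongly negative average
correlation with its partners — the switch-gene signature. The 155 → 103
filter step is the fold-change/FDR gate; the 50 planted background genes
never reach it.

For real data, `read_expression()` loads a delimited matrix + annotation
pair, `read_gmt()` / `read_edge_table()` load gene sets and regulator
tables, and the same `run_pipeline()` call applies; per-dataset
fold-change thresholds and the correlation cut-off are the two settings
that must be chosen (and are logged) per dataset.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the planted benchmark from the given seed, runs the entire
pipeline (filter → network → communities → cartography → switch calls →
robustness) against the installed package, logs the recovery summary, and
writes the JSON report to `--out`.

See `vignettes/switch-gene-cartography.Rmd` for the model, the generator's
assumptions, parameter rationale and numerical conventions.
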