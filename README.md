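# oamethyl

Integrative DNA-methylation analysis for osteoarthritis (OA) gene
discovery.

OA is a degenerative joint disease with no reliable early molecular
diagnostics. Aberrant DNA methylation at CpG sites — measured as beta
values β ∈ [0,1] on Illumina 450K arrays — carries disease signal, but
single sites are weak markers. `oamethyl` implements an integrative
framework that screens, selects and fuses CpG methylation features into a
diagnostic biomarker panel and traces the panel back to candidate effector
genes. It is aimed at computational epigenomics researchers who work with
case/control beta-value matrices.

The framework has five stages:

1. **Dual-strategy screening.** A statistical pool (*T-pool*): per-CpG
   Welch *t*-tests case vs control with Benjamini–Hochberg FDR adjustment
   and the group mean difference Δβ = mean(case) − mean(control); probes
   ranked by (adj. *p*, |Δβ|), top *k* retained. An annotation pool
   (*G-pool*): probes within ±2000 bp of a transcription start site of a
   known OA effector gene.
2. **Consensus machine-learning selection.** SVM-RFE (recursive
   elimination by linear max-margin weights) and random-forest impurity
   importance each rank a pool; 5-fold cross-validation picks each
   ranker's optimal subset size (highest mean ACC, ties by AUC); the
   intersection of the two selections gives *T-sites* / *G-sites*, and
   their union the integrated *U-sites*.
3. **Gated Trans-CNN diagnosis.** Each sample's beta vector is embedded
   one token per CpG and processed in parallel by a Transformer encoder
   (global dependencies) and a 1-D CNN (local methylation patterns). The
   pooled branch projections p<sub>a</sub>, p<sub>β</sub> are blended per
   dimension by a learned gating vector:

       Z     = [p_a ; p_β]
       g     = σ(W₂ · ReLU(W₁ · Z + b₁) + b₂)
       fused = g ⊙ p_a + (1 − g) ⊙ p_β

   followed by a 2-logit softmax classifier (ACC / F1 / AUC reporting,
   class-weighted loss for imbalanced cohorts). The whole network,
   including backpropagation and the Adam optimizer, is implemented in
   base R and verified against finite-difference gradients in the test
   suite.
4. **Gradient-saliency panel selection.** U-site probes are ranked by the
   mean absolute gradient of the positive-class logit with respect to the
   input beta value; nested prefix subsets over a size grid are retrained
   and the best mean validation ACC wins (ties to the smaller panel).
5. **Gene-level interpretation.** Panel CpGs map to genes via the
   annotation; genes are classified as validated / database-reported /
   novel; hypergeometric over-representation analysis against supplied
   gene sets (GMT) with BH FDR; and interaction-network hub scoring by a
   composite of min–max-standardized degree and betweenness centrality
   (edges kept at combined score ≥ 500).

A synthetic 450K-like cohort generator (`generate_cohort()`,
`generate_interaction_network()`, `generate_gene_sets()`) plants known
differential CpGs, effector genes, network hubs and enriched sets so that
every stage is testable end to end without any external download.

## Worked example

```r
library(oamethyl)

cohort <- generate_cohort(sim_config(n_cases = 60, n_controls = 30,
                                     n_cpg = 2000, n_dm = 100,
                                     delta_beta = 0.25, seed = 7))
bm <- harmonize_datasets(cohort$beta, cohort$annotation)
dm <- differential_methylation(bm)

length(significant_sites(dm))          # adj.p < 0.05 and |delta beta| > 0.2
#> [1] 99
pool <- select_t_pool(dm, k = 100)
length(intersect(pool$cpg_ids, cohort$truth$dm_cpg_ids))
#> [1] 100
head(dm[order(dm$adj_p), c("cpg_id", "t_stat", "adj_p", "delta_beta", "direction")], 3)
#>          cpg_id    t_stat        adj_p delta_beta direction
#> 1311 cg00001429 -25.51529 4.462759e-36  -0.270840      hypo
#> 78   cg00000095 -23.64448 1.555483e-35  -0.261855      hypo
#> 1333 cg00001169 -23.13035 1.555483e-35  -0.240315      hypo
```

99 of the 100 planted differential sites pass both significance filters
and all 100 land in the top-100 statistical pool: the screen recovers the
planted Δβ = 0.25 signal essentially perfectly at this effect size.

The full pipeline runs from one config and is deterministic per seed:

```r
report <- run_pipeline(pipeline_config(seed = 5))
print(report)
#> run_report
#>   input:    2000 CpGs x 125 samples
#>   screen:   T-pool 300 / G-pool 114 / significant 100
#>   select:   T 28 / G 46 / U 59
#>   panel:    40 sites (T 27.5% / G 72.5%)
#>   genes:    24 mapped, 22 validated, 2 novel
#>   network:  24 nodes, top GENE0085
#>   elapsed:  25.2 s
report_fingerprint(report)
#> [1] "e53402879f129a6ee6a1e8ed01fcfc9b"
```

Here 100 planted sites survive screening, the consensus selections merge
into 59 U-sites, the gradient sweep keeps a 40-site panel that maps to 24
genes, 22 of which are the cohort's planted effector genes.

A thin CLI wraps the same functions
(`inst/cli/oamethyl simulate|run --out DIR --seed N`).

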