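# rrhosig

Cross-study discovery and validation of prognostic gene-expression
signatures, built around the threshold-free **rank-rank hypergeometric
overlap (RRHO)** comparison and a **weighted gene voting (WGV)** outcome
classifier.

## The problem

Survival-associated gene signatures reported from independent tumor
expression studies rarely agree: platforms differ in probe content, and the
conventional recipe — call genes at a fold-change/p-value cutoff in each
study, then intersect — throws away genes with small but reproducible
changes and typically returns an empty intersection. `rrhosig` implements
the threshold-free alternative for two-class (favorable outcome *FO* vs
poor outcome *PO*) cohorts:

1. **Ranking.** Each cohort is reduced to a signed ranked profile: per gene,
   `score = sign(mean_FO − mean_PO) · (−log10 p)` with `p` from the
   two-sample Student t-test, so rank 1 is the most significantly
   FO-overexpressed gene.
2. **RRHO.** For two ranked lists over a common universe of `N` genes and
   every rank-threshold pair `(i, j)` on a step grid, the overlap
   `k = |top_i ∩ top_j|` is scored by the hypergeometric upper tail
   `P(X ≥ k)`, `X ~ Hypergeom(N, i, j)`, computed in log space. The maximum
   of `−log10 p` inside the FO-concordant quadrant identifies the most
   significant overlapping gene set — no arbitrary cutoff.
3. **Signature.** Pairwise overlap sets from all study pairs are intersected
   into a conserved favorable-outcome signature, optionally profiled against
   a cell-type enrichment-score table (counting signature probes with score
   > 700 per cell type).
4. **Classification.** A WGV classifier votes per signature gene with the
   signal-to-noise weight `W = (μ_alive − μ_dead)/(σ_alive + σ_dead)`:
   `vote = W · (S − (μ_alive + μ_dead)/2)` for sample value `S`, class
   statistics computed leave-one-out. The vote-sum sign predicts the class;
   evaluation covers confusion metrics, ROC AUC (Mann–Whitney), and a
   Kaplan–Meier log-rank split of predicted classes.

Two practical tools complete the pipeline: a **lymph-node contamination
filter** (exclude FO samples exceeding the PO-group expression range on ≥3
of 6 lymph-node classifier genes) and a fully seeded **multi-platform
synthetic data generator** (planted signature, contaminated samples,
class-dependent survival) so every stage is testable offline.

## Worked example

```r
library(rrhosig)

cfg <- sim_config(genes_per_platform = 2000, n_signature_genes = 100,
                  effect_size = 2, n_contaminated_fo = 2, seed = 42)
study <- generate_study(cfg)
disc  <- run_discovery(study$datasets, lymph_genes = study$truth$lymph_genes)
disc$report$pairs
#>                  pair universe_size i_star j_star neglog_p_max overlap_size
#> 1 platform1~platform2          1000    110    100     95.24912           90
#> 2 platform1~platform3          1000    110    110     93.98497           93
#> 3 platform2~platform3          1000    100    110    100.52869           92

length(disc$signature$genes)
#> [1] 88
mean(study$truth$signature_genes %in% disc$signature$genes)  # sensitivity
#> [1] 0.88
mean(disc$signature$genes %in% study$truth$signature_genes)  # precision
#> [1] 1
```

Each study pair's RRHO map peaks near rank ~100 — the planted 100-gene
signature — with overlap p-values around 10^−95; intersecting the three
overlap sets leaves 88 genes, all of them planted. The contamination filter
caught exactly the two planted lymph-contaminated FO samples per platform
(each exceeding the PO range on all 6 classifiers):

```r
disc$excluded_samples$platform1
#>                        sample votes                                           genes
#> platform1_FO01 platform1_FO01     6 GC00402,GC00091,GC00781,GC00181,GC00054,GC00851
#> platform1_FO02 platform1_FO02     6 GC00402,GC00091,GC00781,GC00181,GC00054,GC00851

val <- run_validation(disc$signature, lapply(study$datasets, collapse_probes))
val$platform2
#> <evaluation_summary 'platform2'> 20/20 correct (accuracy 1.000)
#>   PPV 1.000 | NPV 1.000 | sensitivity 1.000 | specificity 1.000 | AUC 1.000
#>   log-rank split: chi-square 2.786, p 0.09507
```

The leave-one-out WGV classifier separates this (deliberately strong,
2-SD-effect) cohort perfectly; the log-rank split is underpowered at
10+10 samples with 20% censoring, which is expected — the survival-power
guarantees hold at 35+35 (see the test suite).

## Command line

```sh
Rscript inst/scripts/rrhosig-cli.R run-all  --out out --seed 5 --genes 2000 \
        --signature-size 100 --effect 2 --contaminated 2
Rscript inst/scripts/rrhosig-cli.R simulate --out sim --seed 5
Rscript inst/scripts/rrhosig-cli.R discover --inputs sim/platform1.tsv,sim/platform2.tsv,sim/platform3.tsv --out disc
Rscript inst/scripts/rrhosig-cli.R classify --signature disc/signature.txt --inputs sim/platform1.tsv --out val
```

Expression inputs are TSV (`probe`, `gene`, then sample columns) with a
`.samples.tsv` annotation sibling (`sample`, `class`, optional
`time`/`event`); see `?write_expr_dataset`.

## Documentation

The methods vignette (`vignettes/signature-discovery.Rmd`) documents the
statistical model, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, numerical and
tie-breaking choices, and known limitations.
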