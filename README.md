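# vascross

Cross-species concordance analysis of vascular aging transcriptomes.

## Why

Drugs against vascular aging are screened in rats or monkeys, but an aging
signaling pathway need not move the same way in every species: a pathway
activated in aged human vessels can be inhibited in an aged monkey's.
`vascross` takes young/old single-cell expression matrices from several
species and answers, per pathway, *does age push it in the same direction
everywhere* — and if not, *which animal model is still informative for a
drug that targets it*. It is aimed at computational biologists comparing
aging (or any two-condition) single-cell studies across species.

## What it computes

For each species, old-vs-young differential expression by the two-sided
Wilcoxon rank-sum test with Bonferroni correction and log2 fold changes on
the log-normalized (CP10k) scale; then pre-ranked GSEA from scratch —
weighted Kolmogorov–Smirnov enrichment score *ES*, gene-label permutation
null, and the signed normalized enrichment score

    NES = ES / mean(|null ES| of the same sign),

whose sign is read as pathway activation (+) or inhibition (−) with age.
Genes and pathways are then aligned across species through a one-to-one
ortholog map and labeled **SM** (same trend in every species) or **DE**
(divergent trend); a model species is recommended for a target pathway
exactly when its NES sign matches the human sign.

Around that core: cell–cell communication probabilities per
(sender cell type, receiver cell type, ligand–receptor pair),

    p = LR/(Kh + LR) · (1 + AG_i/(Kh + AG_i))(1 + AG_j/(Kh + AG_j))
        · Kh/(Kh + AN_i) · Kh/(Kh + AN_j) · n_i n_j / n²,

with group expression summarized by the Tukey trimean
`EM = ½Q₂ + ¼(Q₁ + Q₃)` and ligand/receptor complex activity by geometric
means of subunit trimeans; old-minus-young differential interaction
networks; betweenness-centrality hub genes on a PPI edge list; and
TF→target importance by depth-1-stump gradient boosting with regulon
assembly and two-species TF trend concordance.

A first-class synthetic-study generator (`simulate_study()`) draws
three-species negative-binomial studies with planted SM/DE pathways,
regulons and aging ligand–receptor pairs, and emits the ground truth
needed to score recovery — every statistical claim in the test suite is
checked against structure that was planted on purpose.

## Worked example

Simulate a small three-species study with 3 same-trend and 3 divergent
planted pathways, run the whole pipeline, and ask which animal model to
use for a divergent pathway:

```r
library(vascross)

study <- emit_fixture("small")          # 3 species, ~300 genes, 200 cells each
run   <- run_cross_species(study, n_perm = 500, seed = 1)
run
#> <concordance_run> 3 species; 296 genes aligned; pathways: 5 SM, 5 DE, 0 not shared

dplyr::filter(run$pathway_concordance, grepl("PW0", set)) |>
  dplyr::select(set, dplyr::starts_with("nes_"), label)
#>    set     nes_rat nes_monkey nes_human label
#>  5 DE_PW01  -2.38       2.21     -2.11  DE
#>  6 DE_PW02   2.22      -2.24      2.32  DE
#>  8 SM_PW01   2.47       2.27      2.37  SM
#>  9 SM_PW02  -2.27      -2.83     -2.33  SM
```

The planted divergent pathways come out DE with the monkey NES sign
flipped (that is how they were planted), the same-trend ones come out SM.
For a DE pathway the recommendation is sign-matched to human:

```r
recommend_models(run$pathway_concordance, "DE_PW01")
#>   species   nes sign  recommended rationale
#> 1 rat     -2.38 -     TRUE        rat NES sign '-' vs human '-': concordant…
#> 2 monkey   2.21 +     FALSE       monkey NES sign '+' vs human '-': discordant…

score_pathway_recovery(run$pathway_concordance, study$ground_truth)
#>   n_planted n_correct recovery
#> 1         6         6        1
```

So a drug aimed at `DE_PW01` should be evaluated in the rat: the monkey
moves that pathway in the opposite direction with age and would mislead.
Communication networks and hub genes come from the same study objects:

```r
d   <- study$species$human
net <- build_networks(normalize_log1p_cp10k(d$counts), d$cells, study$lr_db)
net
#> <comm_network> 4 cell types, 3 interactions (Kh = 0.5)
#> old - young total strength: 0.004755

hub_genes(study$ppi_edges, study$ground_truth$pathway_genes$gene, top_k = 3)
#>   gene   betweenness betweenness_norm degree  rank
#> 1 G00073       1488.            0.258      5     1
#> 2 G00068       1163.            0.201      5     2
#> 3 G00036       1024.            0.177      3     3
```

The positive total differential strength reflects the planted
ligand–receptor pairs whose expression rises in old sender/receiver cells.
`autoplot()` methods exist for GSEA results, pathway concordance tables
and communication networks; `tidy()`/`glance()` methods cover the fitted
objects.

Real data enters through plain formats: MatrixMarket or dense TSV
expression (`read_expression()`), an annotation TSV
(`cell_id species cell_type age_group`), GMT gene sets, and TSV
ortholog / ligand–receptor / PPI-edge tables. See the vignette in
`vignettes/cross-species-concordance.Rmd` for the models, conventions and
design decisions.

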