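---
title: "Cross-species pathway concordance for vascular aging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species pathway concordance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascross)
```

## The problem

Anti-aging drug candidates are screened in animal models, but a pathway
that is activated in aged human vessels may be inhibited in the aged
vessels of a candidate model species. `vascross` quantifies, from young/old
single-cell expression in several species, whether each signaling pathway
moves the *same way* with age across species — and therefore which model
species is informative for a drug that targets it.

The pipeline has five statistical stages, each exposed as ordinary
functions over tibbles:

1. **Differential expression** (`call_degs()`): per gene, a two-sided
   Wilcoxon rank-sum test of old versus young cells with Bonferroni
   correction, plus a log2 fold change on the normalized scale.
2. **Pre-ranked GSEA** (`gsea_prerank()`): enrichment scores with a
   permutation null and a signed normalized enrichment score (NES); the
   NES sign is read as pathway activation (+) or inhibition (−) with age.
3. **Cross-species concordance** (`classify_genes()`,
   `classify_pathways()`): genes/pathways whose fold-change/NES signs agree
   in all species are labeled **SM** (same trend); present everywhere but
   with disagreeing signs, **DE** (divergent); otherwise `not_shared`.
   `recommend_models()` then recommends exactly the model species whose
   NES sign matches the reference (human) sign for a target pathway.
4. **Cell–cell communication** (`build_networks()`): a ligand–receptor
   communication probability per (sender type, receiver type, interaction),
   aggregated into per-age-group count/strength networks and an
   old-minus-young differential.
5. **Network and regulatory context**: betweenness-centrality hub genes on
   a PPI graph (`hub_genes()`) and TF→target importance by stump boosting
   (`gbm_importance()`, `build_regulons()`, `tf_concordance()`).

## Models and conventions

### Differential expression

Counts are library-size normalized to 10,000 per cell and `log1p`
transformed before testing (`normalize_log1p_cp10k()`); fold changes are
`log2((mean_old + 1)/(mean_young + 1))` on that scale. The Wilcoxon test
uses the exact Mann–Whitney null when the pooled sample is at most 16 and
tie-free, and otherwise a normal approximation with midranks, tie-corrected
variance and a continuity correction. Genes expressed in neither group are
dropped *before* the Bonferroni denominator is counted.

Two conventions were genuinely open and are exposed as switches with
documented defaults: the DEG p-value cutoff is applied to the
Bonferroni-adjusted p (`p_column = "adj"`) with a non-strict comparator
(`strict = FALSE`) — a multiplicity correction whose output is never
thresholded would be purposeless — and the default scope is all cells of a
species (`scope = "all_cells"`), with `per_cell_type` available because
age effects can be population-specific. Default thresholds are
`|log2fc| >= 0.1` and `p <= 0.05`.

### Pre-ranked GSEA

All tested genes are ranked by `log2fc` (or signed `-log10 p`), descending,
ties broken lexicographically so rankings are reproducible. The enrichment
score is the classic weighted Kolmogorov–Smirnov running sum with exponent
1: hits add `|stat| / sum over hits`, misses subtract `1/(N - n_hits)`;
the ES is the extreme of largest magnitude, the positive extreme winning
exact magnitude ties (a tie can occur and must be broken identically by
any re-implementation). Because a pre-ranked list has no sample labels to
permute, the null is `n_perm = 1000` random same-size member draws from
the ranked universe; `NES = ES / mean(|null ES| of the same sign)` and the
nominal p uses an add-one estimator, so p is never exactly zero. FDR across
sets is deliberately not computed: the concordance logic consumes only NES
signs, and the nominal p is reported for transparency.

### Concordance and model choice

Cross-species comparison goes exclusively through an ortholog map; symbols
are never matched by name. Only one-to-one ortholog records survive
(anything many-to-many is dropped with a message), and overlap percentages
are taken relative to the reference species' own DEG count. A pathway with
missing or exactly zero NES in any species is `not_shared` rather than
guessed. Model recommendation is sign-only — no NES-magnitude weighting —
because the decision the label supports ("will this model reproduce the
direction of the human response?") is a directional one.

### Communication probability

Group-level expression is the Tukey trimean `EM = Q2/2 + (Q1+Q3)/4` with
type-7 (linear interpolation) quartiles — a robust "ensemble average" that
ignores the tails. Ligand and receptor complex activities are geometric
means of subunit trimeans; a silent subunit zeroes the complex (no
pseudocount), which correctly zeroes the probability. Receptor activity is
modulated by `(1 + RA)/(1 + RI)` for co-stimulatory/co-inhibitory receptor
lists, and the probability of interaction `k` from sender `i` to receiver
`j` is

```
p = LR/(Kh + LR)
    * (1 + AG_i/(Kh + AG_i)) * (1 + AG_j/(Kh + AG_j))
    * Kh/(Kh + AN_i) * Kh/(Kh + AN_j)
    * n_i * n_j / n^2
```

with `Kh = 0.5` by default (the conventional half-saturation constant for
this model family; exposed as a parameter). The antagonist (`AN`) factor is
implemented symmetrically to the agonist factor — the model family's
formula carries it even though descriptions usually expand only agonists
and co-stimulatory receptors — so antagonist expression attenuates the
probability toward zero. Useful anchors: `p = 0` whenever `L·R = 0`, and
`p = 0.5` at `L·R = Kh` with unit proportions and no modulators. An
optional within-age-group label-permutation test (`n_perm >= 10`,
add-one p) can filter retained pairs; groups with fewer than 3 cells are
computed but flagged low-confidence.

### Hub genes

Betweenness centrality is exact shortest-path betweenness on the
undirected, unweighted PPI graph (confidence weights are accepted and
ignored — no principled weighting rule exists for mixed-evidence edges).
Both the raw unordered-pair-count convention and the
`2/((n-1)(n-2))`-normalized value are reported, since different network
tools print different conventions; ranking ties break by degree, then id.

### TF→target importance

Eq-style gradient boosting is implemented with depth-1 regression stumps
under squared-error loss: each round fits the current residual, the best
(TF, threshold) split is added with learning rate 0.1, and a TF's
importance is the total training-loss reduction of its splits. Stumps keep
the learner deterministic and desk-scale while preserving what the
downstream analysis consumes — which TFs explain a target and how strongly.
Training loss is non-increasing by construction (each stump is the
least-squares fit of the residual), a property the tests assert round by
round. Motif pruning and activity scoring from the full single-cell
regulatory-network toolchain are out of scope: regulons here are
importance-ranked target lists, which is exactly what the TF-trend
concordance consumes.

## The synthetic-data generator

Real deposited datasets are deliberately not bundled; instead
`simulate_study()` draws studies in which every downstream answer is known.
The default configuration **is** the study design the package is validated
under: 3 species (rat, monkey, human; human the reference), 4 vascular
cell types (FB, SMC, EC, IMM), 50 cells per species × cell type × age
group (200 per species and age group), 2000 genes, negative-binomial
counts (`size = 2`) with log-normal baseline means (`meanlog = log(0.8)`,
`sdlog = 1` — a sparse, low-UMI regime), 10 SM + 10 DE planted pathways of
50 genes shifted by `delta = 0.5` on the log-mean scale in old cells (DE
pathways flip the sign in exactly one species, monkey by default), 4
planted regulons of 10 targets, and 4 planted ligand–receptor pairs.

Design choices worth knowing:

* **Orthology** is simulated as shared symbols: planted genes are always
  present in every species (a planted cross-species label is meaningless
  otherwise); background genes are subsampled per species at
  `ortholog_fraction = 0.85` and 100 private genes are appended, so
  one-to-one filtering is genuinely exercised.
* **Regulons** couple a TF and its targets through a per-cell latent
  activity (sd 0.7 on the log-mean scale): the TF loads on it with weight
  1, targets with weight `beta`. This is the generative reading of "targets
  receive a `beta`-scaled TF-expression contribution" that keeps counts
  integer-valued and means stable.
* **Detectability floors.** Trimeans of genes that are zero in most cells
  are identically zero, and a regression on an almost-always-zero TF
  carries no signal; planted TF/ligand/receptor genes therefore get a
  baseline mean of at least 2 counts and planted pathway genes at least
  0.3. Planted TFs are shifted by `tf_age_effect = 1` in old cells in all
  species: the planted "conserved aging TF" is strongly induced — the
  scenario the TF-concordance stage exists to detect — because a weaker
  shift is not reliably separable from the TF's own latent activity noise
  at this design size. Ligand/receptor genes rise by `lr_effect = 1` in
  old cells of their designated sender/receiver cell types.
* **Determinism.** Every artifact (layout, per-species expression, PPI
  graph, background sets) consumes its own stream seeded at a fixed offset
  from the master seed, so regeneration is byte-identical and adding one
  artifact cannot shift another's draws.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: cell-type marker structure and realistic
type proportions, batch and donor effects, doublets, ambient RNA,
mean-variance trends beyond a single dispersion, and real ortholog
ambiguity beyond symbol subsampling. Recovery results on this simulator
validate the machinery, not the biology of any particular dataset.

## Numerical choices and degenerate inputs

* Wilcoxon: exact only when tie-free and pooled n ≤ 16; variance guarded
  against all-identical pools (p = 1).
* GSEA: sets whose intersection with the ranking falls outside
  `[min_size, max_size] = [5, 500]` are skipped with a reason, not
  errored; an all-zero-weight hit vector falls back to equal weights; the
  add-one p estimator keeps p in (0, 1].
* Fold changes use pseudocount 1 on the normalized scale, so a DEG's sign
  is always well defined.
* Boosting stops early when no split has positive gain (constant target →
  zero importance everywhere, flat loss).
* All-zero cells stay all-zero under normalization; normalizing twice is
  an error rather than a silent re-scale.

## Problem sizes used by the test-suite and acceptance script

Oracle equivalences run on 100 random instances (ranked lists up to 50
genes; graphs up to 7 nodes; all Wilcoxon group splits with pooled n ≤ 10,
five datasets each). Recovery and calibration run on the default study
design above (one study plus one `delta = 0` null study), with 1000 GSEA
permutations for recovery and 500 for null calibration, 200 random sets
for the GSEA calibration check, and 60 background candidate targets for
regulon recovery. These sizes make the full validation run in a few
minutes on one CPU while leaving every planted effect comfortably inside
its detectable regime.

## Known limitations

* Bonferroni (the only correction offered, by design) is conservative;
  with many genes the DEG stage trades recall for specificity.
* The permutation NES normalizes by the same-sign null mean; for very
  small rankings the same-sign null can be sparse and the NES unstable
  (it is `NA` when the same-sign null is empty).
* The communication model compares age groups through group trimeans; it
  does not model per-cell heterogeneity within a group, and `Kh` is a
  convention, not a fitted constant.
* Stump boosting attributes importance greedily; strongly correlated TFs
  split credit unpredictably, as in any boosting-based network inference.
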