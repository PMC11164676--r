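# End-to-end convenience wrapper: per-species DEG calling, pre-ranked GSEA,
# ortholog alignment, and SM/DE classification in one call.

#' Run the cross-species concordance pipeline on a study
#'
#' Normalizes each species' counts, calls old-vs-young DEGs, ranks genes,
#' runs pre-ranked GSEA over the study's gene-set collection, aligns the DEG
#' tables onto the reference species and classifies genes and pathways as
#' SM (same trend) or DE (divergent).
#'
#' @param study a [simulate_study()] / [read_study()] shaped list: per
#'   species `counts` + `cells`, plus `gene_sets` and `orthologs`.
#' @param reference reference species (defaults to the study config's, else
#'   the last species).
#' @param statistic ranking statistic, see [rank_genes()].
#' @param n_perm,min_size,max_size GSEA parameters, see [gsea_prerank()].
#' @param fc_threshold,p_threshold,p_column DEG parameters, see
#'   [call_degs()].
#' @param seed seed for the per-species GSEA permutation streams.
#' @return A list (class `concordance_run`) with `degs`, `gsea` (named
#'   per-species lists), `aligned`, `gene_table`, `pathway_concordance`.
#' @export
run_cross_species <- function(study, reference = NULL,
                              statistic = "log2fc", n_perm = 1000,
                              min_size = 5, max_size = 500,
                              fc_threshold = 0.1, p_threshold = 0.05,
                              p_column = "adj", seed = 1) {
  reference <- reference %||% study$config$reference %||%
    utils::tail(names(study$species), 1)
  sp <- names(study$species)
  degs <- lapply(study$species, function(d) {
    call_degs(normalize_log1p_cp10k(d$counts), d$cells,
              fc_threshold = fc_threshold, p_threshold = p_threshold,
              p_column = p_column)
  })
  gsea <- lapply(seq_along(sp), function(i) {
    gsea_prerank(rank_genes(degs[[sp[i]]], statistic), study$gene_sets,
                 n_perm = n_perm, min_size = min_size, max_size = max_size,
                 seed = seed + i)
  })
  names(gsea) <- sp
  aligned <- map_to_reference(degs, study$orthologs, reference)
  structure(
    list(
      degs = degs,
      gsea = gsea,
      aligned = aligned,
      gene_table = classify_genes(aligned),
      pathway_concordance = classify_pathways(gsea, reference)
    ),
    class = "concordance_run"
  )
}

#' @export
print.concordance_run <- function(x, ...) {
  pc <- x$pathway_concordance
  cat(sprintf(
    "<concordance_run> %d species; %d genes aligned; pathways: %d SM, %d DE, %d not shared\n",
    length(x$degs), length(unique(x$aligned$ref_gene)),
    sum(pc$label == "SM"), sum(pc$label == "DE"),
    sum(pc$label == "not_shared")
  ))
  invisible(x)
}

#' Score pathway-label recovery against a planted ground truth
#'
#' @param pc a [classify_pathways()] result.
#' @param ground_truth the `ground_truth` element of a simulated study.
#' @return A one-row tibble: `n_planted`, `n_correct`, `recovery` (fraction
#'   of planted pathways receiving their planted SM/DE label).
#' @export
score_pathway_recovery <- function(pc, ground_truth) {
  truth <- ground_truth$pathways
  merged <- inner_join(
    as_tibble(pc)[c("set", "label")],
    truth[c("set", "label")],
    by = "set", suffix = c("_called", "_true")
  )
  tibble(
    n_planted = nrow(truth),
    n_correct = sum(merged$label_called == merged$label_true),
    recovery = sum(merged$label_called == merged$label_true) / nrow(truth)
  )
}
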