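# Cross-species concordance: ortholog-mediated alignment of per-species DEG
# tables to a reference species, Venn-style overlap counts, SM/DE gene and
# pathway classification from fold-change and NES signs, and animal-model
# recommendation. "SM" marks a gene/pathway moving the same way with age in
# every compared species; "DE" marks a divergent one.

#' Align per-species DEG tables onto a reference species
#'
#' Joins each non-reference species' DEG table to the reference through an
#' ortholog map. Only one-to-one orthologs are retained: any gene
#' participating in more than one record for a species pair is dropped (a
#' message reports how many). Rows are keyed by the reference gene id; a
#' reference gene untested in some species carries `NA` there.
#'
#' @param degs_by_species named list of [call_degs()] tibbles; names are
#'   species and must include `reference`.
#' @param orthologs an ortholog map tibble (see [read_ortholog_map()]).
#' @param reference reference species name (the human column in the study
#'   design).
#' @return A long tibble (class `aligned_degs`) with columns `ref_gene,
#'   species, gene, log2fc, p_adj, is_deg` and a `reference` attribute.
#' @export
map_to_reference <- function(degs_by_species, orthologs, reference) {
  if (!reference %in% names(degs_by_species)) {
    abort(sprintf("Reference species '%s' is absent from the input.", reference))
  }
  ref_tab <- degs_by_species[[reference]]
  others <- setdiff(names(degs_by_species), reference)

  pick <- c("gene", "log2fc", "p_adj", "is_deg")
  rows <- list(
    ref_tab |>
      select(all_of(pick)) |>
      mutate(ref_gene = .data$gene, species = reference, .before = 1)
  )
  for (sp in others) {
    pairs <- ortholog_pairs_1to1(orthologs, reference, sp)
    tab <- degs_by_species[[sp]] |>
      select(all_of(pick)) |>
      inner_join(pairs, by = c(gene = "other_gene"))
    rows[[sp]] <- tab |>
      mutate(species = sp) |>
      select("ref_gene", "species", all_of(pick))
  }
  out <- list_rbind(rows) |>
    filter(.data$ref_gene %in% ref_tab$gene) |>
    arrange(.data$ref_gene, .data$species)
  structure(out, reference = reference,
            species = names(degs_by_species),
            class = c("aligned_degs", class(out)))
}

# one-to-one ortholog pairs between two species, direction-free input
ortholog_pairs_1to1 <- function(orthologs, ref, other) {
  fwd <- orthologs |>
    filter(.data$species_a == ref, .data$species_b == other) |>
    transmute(ref_gene = .data$gene_a, other_gene = .data$gene_b)
  rev <- orthologs |>
    filter(.data$species_a == other, .data$species_b == ref) |>
    transmute(ref_gene = .data$gene_b, other_gene = .data$gene_a)
  pairs <- distinct(bind_rows(fwd, rev))
  if (nrow(pairs) == 0) {
    abort(sprintf("Ortholog map has no records for the pair (%s, %s).",
                  ref, other))
  }
  keep <- pairs |>
    add_count(.data$ref_gene, name = "n_ref") |>
    add_count(.data$other_gene, name = "n_other") |>
    filter(.data$n_ref == 1, .data$n_other == 1) |>
    select(-"n_ref", -"n_other")
  dropped <- nrow(pairs) - nrow(keep)
  if (dropped > 0) {
    inform(sprintf("Dropped %d non-one-to-one ortholog record(s) for (%s, %s).",
                   dropped, ref, other))
  }
  keep
}

#' Venn-style DEG overlap counts across species
#'
#' For every non-empty subset of species, counts reference genes that are
#' differentially expressed in each species of the subset, plus the
#' percentage relative to the reference species' own DEG count.
#'
#' @param aligned a [map_to_reference()] result.
#' @return A tibble `species_set, n_species, n, pct_of_reference`.
#' @export
overlap_counts <- function(aligned) {
  reference <- attr(aligned, "reference")
  wide <- aligned |>
    mutate(is_deg = coalesce(.data$is_deg, FALSE)) |>
    select("ref_gene", "species", "is_deg") |>
    pivot_wider(names_from = "species", values_from = "is_deg",
                values_fill = FALSE)
  sp <- setdiff(names(wide), "ref_gene")
  ref_total <- sum(wide[[reference]])
  subsets <- unlist(
    lapply(seq_along(sp), function(k) combn(sp, k, simplify = FALSE)),
    recursive = FALSE
  )
  purrr::map(subsets, function(ss) {
    in_all <- Reduce(`&`, wide[ss])
    tibble(
      species_set = paste(sort(ss), collapse = "&"),
      n_species = length(ss),
      n = sum(in_all),
      pct_of_reference = if (ref_total > 0) 100 * sum(in_all) / ref_total
                         else NA_real_
    )
  }) |> list_rbind()
}

#' Classify shared genes as SM (same trend) or DE (divergent)
#'
#' A reference gene is `SM` when it is a DEG in every compared species and
#' its old-vs-young fold-change signs all agree; `DE` when it is a DEG
#' everywhere but the signs disagree; otherwise `not_shared`.
#'
#' @param aligned a [map_to_reference()] result.
#' @return A wide tibble: `ref_gene`, per-species `sign_<species>` and
#'   `deg_<species>` columns, and `label`.
#' @export
classify_genes <- function(aligned) {
  sp <- attr(aligned, "species")
  wide <- aligned |>
    mutate(
      sign = sign(.data$log2fc),
      is_deg = coalesce(.data$is_deg, FALSE)
    ) |>
    select("ref_gene", "species", "sign", "is_deg") |>
    pivot_wider(names_from = "species", values_from = c("sign", "is_deg"))
  deg_cols <- paste0("is_deg_", sp)
  sign_cols <- paste0("sign_", sp)
  deg_all <- Reduce(`&`, wide[deg_cols])
  signs <- as.matrix(wide[sign_cols])
  same <- apply(signs, 1, function(s) length(unique(s[!is.na(s)])) == 1)
  wide |>
    mutate(label = case_when(
      deg_all & same ~ "SM",
      deg_all & !same ~ "DE",
      .default = "not_shared"
    )) |>
    arrange(.data$ref_gene)
}

#' Classify pathways as SM or DE from per-species NES signs
#'
#' A gene set is `SM` when it passed size filters in every species and the
#' NES signs all agree, `DE` when present everywhere with disagreeing signs,
#' and `not_shared` when skipped (or NES missing/zero) in any species.
#'
#' @param gsea_by_species named list of [gsea_prerank()] results computed
#'   over the same collection; names are species and must include
#'   `reference`.
#' @param reference reference species.
#' @return A tibble (class `pathway_concordance`): `set`, per-species
#'   `nes_<species>` and `sign_<species>`, and `label`.
#' @export
classify_pathways <- function(gsea_by_species, reference) {
  if (!reference %in% names(gsea_by_species)) {
    abort(sprintf("Reference species '%s' is absent from the input.", reference))
  }
  universes <- purrr::map(gsea_by_species, ~ sort(.x$set))
  if (length(unique(universes)) != 1) {
    abort("Per-species GSEA results cover different gene-set collections.")
  }
  sp <- names(gsea_by_species)
  long <- purrr::imap(gsea_by_species, function(g, nm) {
    tibble(set = g$set, species = nm, nes = g$nes, skipped = g$skipped)
  }) |> list_rbind()
  wide <- long |>
    mutate(nes = ifelse(.data$skipped | is.na(.data$nes) | .data$nes == 0,
                        NA_real_, .data$nes)) |>
    select(-"skipped") |>
    pivot_wider(names_from = "species", values_from = "nes",
                names_prefix = "nes_")
  nes_mat <- as.matrix(wide[paste0("nes_", sp)])
  present <- rowSums(is.na(nes_mat)) == 0
  same <- apply(sign(nes_mat), 1, function(s) {
    s <- s[!is.na(s)]
    length(s) > 0 && length(unique(s)) == 1
  })
  out <- wide |>
    mutate(label = case_when(
      present & same ~ "SM",
      present & !same ~ "DE",
      .default = "not_shared"
    ))
  for (s in sp) {
    out[[paste0("sign_", s)]] <-
      ifelse(is.na(out[[paste0("nes_", s)]]), NA_character_,
             ifelse(out[[paste0("nes_", s)]] > 0, "+", "-"))
  }
  out <- arrange(out, .data$set)
  structure(out, reference = reference, species = sp,
            class = c("pathway_concordance", class(out)))
}

#' Recommend animal models for a target pathway
#'
#' A model species is recommended exactly when its NES sign for the target
#' pathway equals the reference (human) sign — pathway activation/inhibition
#' must point the same way. For an SM pathway every model species is
#' therefore recommended; for a DE pathway only the concordant ones.
#'
#' @param pc a [classify_pathways()] result.
#' @param target_pathway gene-set name to advise on.
#' @return A tibble `species, nes, sign, recommended, rationale` for the
#'   non-reference species (warning if none is concordant).
#' @export
recommend_models <- function(pc, target_pathway) {
  row <- pc[pc$set == target_pathway, ]
  if (nrow(row) == 0) {
    near <- utils::head(pc$set[agrepl(target_pathway, pc$set,
                                      max.distance = 0.3)], 5)
    abort(paste0(
      sprintf("Pathway '%s' not found.", target_pathway),
      if (length(near) > 0) {
        paste0(" Near matches: ", paste(near, collapse = ", "))
      } else ""
    ))
  }
  reference <- attr(pc, "reference")
  sp <- setdiff(attr(pc, "species"), reference)
  ref_sign <- row[[paste0("sign_", reference)]]
  out <- purrr::map(sp, function(s) {
    s_sign <- row[[paste0("sign_", s)]]
    rec <- !is.na(s_sign) && !is.na(ref_sign) && s_sign == ref_sign
    tibble(
      species = s,
      nes = row[[paste0("nes_", s)]],
      sign = s_sign,
      recommended = rec,
      rationale = sprintf(
        "%s NES sign '%s' vs %s '%s': %s",
        s, s_sign %||% "NA", reference, ref_sign %||% "NA",
        if (rec) "concordant direction, suitable model"
        else "discordant direction, model would mislead"
      )
    )
  }) |> list_rbind()
  if (!any(out$recommended)) {
    warn(sprintf(
      "No model species matches the %s NES sign for '%s'.",
      reference, target_pathway
    ))
  }
  arrange(out, desc(.data$recommended), .data$species)
}

#' Summarize a full concordance analysis
#'
#' Bundles overlap counts, SM/DE gene counts, the pathway table and any
#' model recommendations; optionally writes JSON and Markdown twins carrying
#' identical numbers.
#'
#' @param aligned a [map_to_reference()] result.
#' @param gene_table a [classify_genes()] result.
#' @param pc a [classify_pathways()] result.
#' @param recommendations optional [recommend_models()] result.
#' @param path optional output stem; writes `<path>.json` and `<path>.md`.
#' @return A list (class `concordance_report`) with elements `venn`,
#'   `gene_counts`, `pathways`, `recommendations`.
#' @export
concordance_report <- function(aligned, gene_table, pc,
                               recommendations = NULL, path = NULL) {
  venn <- overlap_counts(aligned)
  gene_counts <- gene_table |> count(.data$label, name = "n_genes")
  pathway_counts <- pc |> count(.data$label, name = "n_sets")
  report <- list(
    reference = attr(aligned, "reference"),
    venn = venn,
    gene_counts = gene_counts,
    pathway_counts = pathway_counts,
    pathways = as_tibble(pc),
    recommendations = recommendations
  )
  class(report) <- "concordance_report"
  if (!is.null(path)) {
    jsonlite::write_json(
      purrr::map(report, ~ if (is.data.frame(.x)) as.data.frame(.x) else .x),
      paste0(path, ".json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null"
    )
    writeLines(format_report_md(report), paste0(path, ".md"))
  }
  report
}

format_report_md <- function(report) {
  md_tbl <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("(none)")
    df <- as.data.frame(df)
    df[] <- lapply(df, function(col) {
      if (is.list(col)) vapply(col, paste, character(1), collapse = ";")
      else as.character(col)
    })
    c(
      paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    )
  }
  c(
    "# Cross-species concordance report",
    sprintf("Reference species: %s", report$reference),
    "", "## DEG overlaps", md_tbl(report$venn),
    "", "## Gene labels", md_tbl(report$gene_counts),
    "", "## Pathway labels", md_tbl(report$pathway_counts),
    "", "## Pathways", md_tbl(report$pathways),
    "", "## Model recommendations", md_tbl(report$recommendations)
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}

#' Tile plot of per-species pathway direction
#'
#' @param object a `pathway_concordance` tibble.
#' @param ... unused.
#' @return A ggplot object: pathways x species, tiles coloured by NES.
#' @method autoplot pathway_concordance
#' @export
autoplot.pathway_concordance <- function(object, ...) {
  sp <- attr(object, "species")
  long <- as_tibble(object) |>
    select("set", "label", starts_with("nes_")) |>
    pivot_longer(starts_with("nes_"), names_to = "species",
                 names_prefix = "nes_", values_to = "nes")
  ggplot2::ggplot(long, ggplot2::aes(.data$species, .data$set,
                                     fill = .data$nes)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$label), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "NES") +
    ggplot2::theme_minimal()
}
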