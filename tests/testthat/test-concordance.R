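# Cross-species alignment, SM/DE classification, model recommendation.

mk_degs <- function(genes, lfc, deg) {
  tibble::tibble(
    gene = genes, log2fc = lfc, p_raw = 0.01, p_adj = 0.01,
    n_old = 10L, n_young = 10L, mean_old = 1, mean_young = 1, is_deg = deg
  )
}

identity_orth <- function(genes, species) {
  tidyr::crossing(species_a = species, species_b = species) |>
    dplyr::filter(species_a < species_b) |>
    tidyr::crossing(gene = genes) |>
    dplyr::transmute(species_a, gene_a = gene, species_b, gene_b = gene)
}

test_that("identity ortholog map reproduces the input tables", {
  genes <- c("A", "B", "C")
  degs <- list(
    human = mk_degs(genes, c(1, -1, 0.5), c(TRUE, TRUE, FALSE)),
    rat = mk_degs(genes, c(0.8, -0.2, 0.1), c(TRUE, FALSE, FALSE))
  )
  aligned <- map_to_reference(degs, identity_orth(genes, names(degs)), "human")
  rat_rows <- dplyr::filter(aligned, species == "rat") |> dplyr::arrange(gene)
  expect_identical(rat_rows$log2fc, degs$rat$log2fc)
  expect_identical(rat_rows$ref_gene, rat_rows$gene)
  expect_error(map_to_reference(degs, identity_orth(genes, names(degs)), "dog"),
               "absent")
})

test_that("many-to-many ortholog records are dropped", {
  degs <- list(
    human = mk_degs(c("A", "B"), c(1, 1), c(TRUE, TRUE)),
    rat = mk_degs(c("a1", "a2", "b"), c(1, 1, 1), c(TRUE, TRUE, TRUE))
  )
  orth <- tibble::tibble(
    species_a = "human", gene_a = c("A", "A", "B"),
    species_b = "rat", gene_b = c("a1", "a2", "b")
  )
  expect_message(
    aligned <- map_to_reference(degs, orth, "human"),
    "Dropped 2"
  )
  expect_identical(
    dplyr::filter(aligned, species == "rat")$ref_gene, "B"
  )
})

test_that("overlap counts respect subset structure and reference percent", {
  genes <- sprintf("g%d", 1:10)
  degs <- list(
    human = mk_degs(genes, rep(1, 10), rep(c(TRUE, FALSE), c(8, 2))),
    rat = mk_degs(genes, rep(1, 10), rep(c(TRUE, FALSE), c(4, 6))),
    monkey = mk_degs(genes, rep(1, 10), rep(FALSE, 10))
  )
  aligned <- map_to_reference(degs, identity_orth(genes, names(degs)), "human")
  counts <- overlap_counts(aligned)
  lk <- function(ss) counts$n[counts$species_set == ss]
  expect_equal(lk("human"), 8)
  expect_equal(lk("human&rat"), 4)  # rat DEGs are a subset of human's
  expect_equal(lk("human&monkey"), 0)
  expect_equal(lk("human&monkey&rat"), 0)
  expect_equal(counts$pct_of_reference[counts$species_set == "human&rat"],
               100 * 4 / 8)
})

test_that("gene labels follow the SM/DE sign rule", {
  genes <- c("g1", "g2", "g3")
  degs <- list(
    human = mk_degs(genes, c(1, 1, 1), c(TRUE, TRUE, FALSE)),
    rat = mk_degs(genes, c(2, -1, 1), c(TRUE, TRUE, TRUE)),
    monkey = mk_degs(genes, c(0.5, 1, 1), c(TRUE, TRUE, TRUE))
  )
  aligned <- map_to_reference(degs, identity_orth(genes, names(degs)), "human")
  tab <- classify_genes(aligned)
  expect_identical(tab$label[tab$ref_gene == "g1"], "SM")    # (+,+,+)
  expect_identical(tab$label[tab$ref_gene == "g2"], "DE")    # (+,-,+)
  expect_identical(tab$label[tab$ref_gene == "g3"], "not_shared")
})

test_that("pathway labels follow NES sign concordance", {
  mk_gsea <- function(nes) {
    structure(
      tibble::tibble(
        set = names(nes), size = 10L, es = sign(nes) * 0.5, nes = unname(nes),
        p_nominal = 0.01, sign = ifelse(nes >= 0, "+", "-"),
        leading_edge = list(character(0)),
        skipped = is.na(nes), skip_reason = NA_character_
      ),
      class = c("gsea_result", "tbl_df", "tbl", "data.frame")
    )
  }
  gsea <- list(
    rat = mk_gsea(c(ECM = -1.5, LIPID = 1.2, MISS = 1)),
    monkey = mk_gsea(c(ECM = -1.1, LIPID = -1.4, MISS = NA)),
    human = mk_gsea(c(ECM = -2.0, LIPID = 1.6, MISS = 1))
  )
  pc <- classify_pathways(gsea, "human")
  # consistently inhibited across species: same-trend (the ECM pattern)
  expect_identical(pc$label[pc$set == "ECM"], "SM")
  # activated in rat and human, inhibited in monkey: divergent
  expect_identical(pc$label[pc$set == "LIPID"], "DE")
  expect_identical(pc$label[pc$set == "MISS"], "not_shared")

  # identical results in every species => every shared set SM
  same <- classify_pathways(
    list(rat = gsea$rat, monkey = gsea$rat, human = gsea$rat), "human"
  )
  expect_true(all(same$label[!is.na(same$nes_rat)] == "SM"))

  # permuting the non-reference species never changes labels
  perm <- classify_pathways(
    list(monkey = gsea$monkey, rat = gsea$rat, human = gsea$human), "human"
  )
  expect_identical(pc$label[order(pc$set)], perm$label[order(perm$set)])

  bad <- list(rat = gsea$rat[1:2, ], human = gsea$human)
  expect_error(classify_pathways(bad, "human"), "different")
})

test_that("model recommendation is sign-only against the reference", {
  mk_gsea <- function(nes) {
    structure(
      tibble::tibble(
        set = names(nes), size = 10L, es = sign(nes) * 0.5, nes = unname(nes),
        p_nominal = 0.01, sign = ifelse(nes >= 0, "+", "-"),
        leading_edge = list(character(0)), skipped = FALSE,
        skip_reason = NA_character_
      ),
      class = c("gsea_result", "tbl_df", "tbl", "data.frame")
    )
  }
  gsea <- list(
    rat = mk_gsea(c(SMP = 1.0, LIPID = 1.3, LONE = -1)),
    monkey = mk_gsea(c(SMP = 1.1, LIPID = -1.2, LONE = -1)),
    human = mk_gsea(c(SMP = 1.2, LIPID = 1.5, LONE = 1))
  )
  pc <- classify_pathways(gsea, "human")

  sm <- recommend_models(pc, "SMP")
  expect_true(all(sm$recommended))

  de <- recommend_models(pc, "LIPID")
  expect_true(de$recommended[de$species == "rat"])
  expect_false(de$recommended[de$species == "monkey"])

  expect_warning(none <- recommend_models(pc, "LONE"), "No model species")
  expect_false(any(none$recommended))

  expect_error(recommend_models(pc, "LIPIDS"), "Near matches")
})

test_that("report twins agree and planted fixtures show both labels", {
  st <- tiny_study()
  run <- suppressMessages(run_cross_species(st, n_perm = 100, seed = 2))
  dir <- withr::local_tempdir()
  rep <- concordance_report(run$aligned, run$gene_table,
                            run$pathway_concordance,
                            path = file.path(dir, "report"))
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "report.md")))
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$venn$n, rep$venn$n)
  expect_equal(js$pathway_counts$n_sets, rep$pathway_counts$n_sets)
  md <- readLines(file.path(dir, "report.md"))
  expect_true(any(grepl("concordance report", md)))

  labels <- run$pathway_concordance$label[
    run$pathway_concordance$set %in% st$ground_truth$pathways$set
  ]
  expect_true("SM" %in% labels && "DE" %in% labels)
})
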