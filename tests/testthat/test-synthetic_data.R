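# The study generator: determinism, bookkeeping, planted-effect realization.

test_that("configuration invariants are enforced before anything is drawn", {
  expect_error(simulation_config(cells_per_group = 0), "positive")
  expect_error(simulation_config(ortholog_fraction = 0), "0, 1")
  expect_error(simulation_config(ortholog_fraction = 1.2), "0, 1")
  expect_error(simulation_config(delta = Inf), "finite")
  expect_error(simulation_config(reference = "dog"), "one of")
  expect_error(simulation_config(discordant_species = "dog"), "one of")
  expect_error(simulation_config(n_genes = 50), "too small")
})

test_that("the same config reproduces a byte-identical study", {
  cfg <- simulation_config(
    n_genes = 120, n_private_genes = 5, cells_per_group = 8,
    n_sm_pathways = 1, n_de_pathways = 1, genes_per_pathway = 10,
    n_regulons = 1, targets_per_regulon = 3, n_lr_pairs = 1,
    n_background_sets = 1, ppi_background_edges = 30, seed = 77
  )
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  for (sp in names(a$species)) {
    expect_identical(as.matrix(a$species[[sp]]$counts$values),
                     as.matrix(b$species[[sp]]$counts$values))
    expect_identical(a$species[[sp]]$cells, b$species[[sp]]$cells)
  }
  expect_identical(a$ppi_edges, b$ppi_edges)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(unclass(a$gene_sets), unclass(b$gene_sets))
})

test_that("ground truth bookkeeping matches the planted design", {
  st <- small_study()
  cfg <- st$config
  gt <- st$ground_truth
  expect_equal(nrow(gt$pathways), cfg$n_sm_pathways + cfg$n_de_pathways)
  expect_equal(sum(gt$pathways$label == "SM"), cfg$n_sm_pathways)
  expect_equal(sum(gt$pathways$label == "DE"), cfg$n_de_pathways)
  # SM <=> all per-species signs equal
  sign_cols <- paste0("sign_", cfg$species)
  signs <- as.matrix(gt$pathways[sign_cols])
  all_same <- apply(signs, 1, function(s) length(unique(s)) == 1)
  expect_identical(gt$pathways$label == "SM", all_same)
  # DE pathways flip exactly the discordant species
  de <- gt$pathways[gt$pathways$label == "DE", ]
  others <- setdiff(cfg$species, cfg$discordant_species)
  expect_true(all(
    de[[paste0("sign_", cfg$discordant_species)]] ==
      -de[[paste0("sign_", others[1])]]
  ))
  expect_equal(nrow(gt$regulons), cfg$n_regulons * cfg$targets_per_regulon)
  expect_equal(nrow(gt$lr_pairs), cfg$n_lr_pairs)
  # planted sets appear in the emitted collection with their genes
  for (i in seq_len(nrow(gt$pathways))) {
    nm <- gt$pathways$set[i]
    expect_setequal(st$gene_sets[[nm]],
                    gt$pathway_genes$gene[gt$pathway_genes$set == nm])
  }
})

test_that("planted shifts are realized with the planted sign", {
  st <- small_study()
  gt <- st$ground_truth
  ok <- unlist(lapply(st$config$species, function(sp) {
    d <- st$species[[sp]]
    norm <- normalize_log1p_cp10k(d$counts)
    is_old <- d$cells$age_group == "old"
    diff <- Matrix::rowMeans(norm$values[gt$pathway_genes$gene, is_old]) -
      Matrix::rowMeans(norm$values[gt$pathway_genes$gene, !is_old])
    planted_sign <- gt$pathways[[paste0("sign_", sp)]][
      match(gt$pathway_genes$set, gt$pathways$set)
    ]
    sign(diff) == planted_sign
  }))
  expect_gte(mean(ok), 0.9)
})

test_that("fixture presets scale and round-trip through disk", {
  tiny <- tiny_study()
  small <- small_study()
  expect_lt(nrow(tiny$species$rat$counts$values),
            nrow(small$species$rat$counts$values))
  expect_lte(nrow(tiny$species$human$counts$values), 50)
  expect_lte(ncol(tiny$species$human$counts$values), 80)
  expect_gte(nrow(dplyr::filter(tiny$ground_truth$pathways, label == "SM")), 1)
  expect_gte(nrow(dplyr::filter(tiny$ground_truth$pathways, label == "DE")), 1)

  dir <- withr::local_tempdir()
  write_study(tiny, dir)
  back <- read_study(dir)
  expect_setequal(names(back$species), names(tiny$species))
  for (sp in names(tiny$species)) {
    expect_equal(as.matrix(back$species[[sp]]$counts$values),
                 as.matrix(tiny$species[[sp]]$counts$values))
    expect_identical(back$species[[sp]]$cells, tiny$species[[sp]]$cells)
  }
  expect_identical(unclass(back$gene_sets)[names(tiny$gene_sets)],
                   unclass(tiny$gene_sets)[names(tiny$gene_sets)])
  expect_identical(back$lr_db, tiny$lr_db)
  expect_equal(back$ground_truth$pathways, tiny$ground_truth$pathways)
})

test_that("orthology only bridges genes present in both species", {
  st <- tiny_study()
  for (i in seq_len(nrow(st$orthologs))) {
    row <- st$orthologs[i, ]
    expect_true(row$gene_a %in% genes(st$species[[row$species_a]]$counts))
    expect_true(row$gene_b %in% genes(st$species[[row$species_b]]$counts))
  }
  # private genes never appear in the map
  priv <- grep("_P", genes(st$species$rat$counts), value = TRUE)
  expect_false(any(priv %in% c(st$orthologs$gene_a, st$orthologs$gene_b)))
})
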