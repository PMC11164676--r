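# Stump-boosting TF importance, regulon assembly, TF concordance.

sim_tf_matrix <- function(n_cells = 200, n_tfs = 4, seed = 21,
                          target_fun = NULL) {
  set.seed(seed)
  tfs <- matrix(rnorm(n_cells * n_tfs), n_cells, n_tfs)
  target <- if (is.null(target_fun)) rnorm(n_cells) else target_fun(tfs)
  vals <- t(cbind(tfs, target))
  vals <- vals - min(vals)  # expression-like: non-negative
  dimnames(vals) <- list(c(paste0("TF", seq_len(n_tfs)), "TARGET"),
                         paste0("c", seq_len(n_cells)))
  expr_matrix(vals, normalized = TRUE)
}

test_that("a target copying one TF gives that TF nearly all importance", {
  m <- sim_tf_matrix(target_fun = function(tfs) tfs[, 2])
  fit <- gbm_importance(m, paste0("TF", 1:4), "TARGET")
  expect_identical(fit$importance$tf[1], "TF2")
  expect_gte(fit$importance$share[1], 0.99)
})

test_that("training loss never increases across boosting rounds", {
  for (seed in 1:5) {
    m <- sim_tf_matrix(seed = seed,
                       target_fun = function(tfs) tfs[, 1] + 0.5 * tfs[, 3])
    fit <- gbm_importance(m, paste0("TF", 1:4), "TARGET", n_rounds = 60)
    expect_true(all(diff(fit$train_loss) <= 1e-12))
  }
})

test_that("a constant target yields zero importance, flat loss", {
  m <- sim_tf_matrix(target_fun = function(tfs) rep(2, nrow(tfs)))
  fit <- gbm_importance(m, paste0("TF", 1:4), "TARGET")
  expect_true(all(fit$importance$importance == 0))
  expect_true(all(fit$train_loss == fit$train_loss[1]))
})

test_that("a pure-noise target gives no TF a dominant share", {
  shares <- sapply(1:10, function(s) {
    m <- sim_tf_matrix(seed = 100 + s)
    max(gbm_importance(m, paste0("TF", 1:4), "TARGET")$importance$share)
  })
  # uniform would be 0.25; require no systematic dominance
  expect_lt(mean(shares), 3 * 0.25)
})

test_that("importance is invariant to cell order and target shifts", {
  m <- sim_tf_matrix(target_fun = function(tfs) tfs[, 1] - tfs[, 4])
  fit <- gbm_importance(m, paste0("TF", 1:4), "TARGET")

  perm <- sample(ncol(m$values))
  m_perm <- expr_matrix(m$values[, perm], normalized = TRUE)
  fit_perm <- gbm_importance(m_perm, paste0("TF", 1:4), "TARGET")
  expect_equal(fit_perm$importance, fit$importance, tolerance = 1e-9)

  shifted <- as.matrix(m$values)
  shifted["TARGET", ] <- shifted["TARGET", ] + 5
  fit_shift <- gbm_importance(expr_matrix(shifted, normalized = TRUE),
                              paste0("TF", 1:4), "TARGET")
  expect_equal(fit_shift$importance, fit$importance, tolerance = 1e-9)
})

test_that("input contracts are enforced", {
  m <- sim_tf_matrix()
  expect_error(gbm_importance(m, c("TF1", "TARGET"), "TARGET"), "tf_list")
  expect_error(gbm_importance(m, c("TF1", "NOPE"), "TARGET"), "absent")
  tiny <- expr_matrix(matrix(1, 2, 5, dimnames = list(c("TF1", "T2"),
                                                      paste0("c", 1:5))),
                      normalized = TRUE)
  expect_error(gbm_importance(tiny, "TF1", "T2"), "20 cells")
})

test_that("build_regulons ranks targets and respects top_k", {
  imp <- tibble::tibble(
    target = c("t1", "t2", "t3", "t1", "t2"),
    tf = c("TF1", "TF1", "TF1", "TF2", "TF2"),
    importance = c(5, 3, 0, 2, 2),
    share = 1
  )
  reg <- build_regulons(imp, top_k = 2)
  expect_identical(reg$target[reg$tf == "TF1"], c("t1", "t2"))
  # zero-importance link dropped; TF2 tie broken by gene id
  expect_identical(reg$target[reg$tf == "TF2"], c("t1", "t2"))
  expect_equal(nrow(build_regulons(imp, top_k = 0)), 0)
  expect_equal(nrow(build_regulons(imp[0, ], top_k = 5)), 0)
})

test_that("planted regulons are recovered from the small fixture", {
  st <- small_study()
  d <- st$species$human
  norm <- normalize_log1p_cp10k(d$counts)
  gt <- st$ground_truth$regulons
  tfs <- unique(gt$tf)
  set.seed(3)
  candidates <- c(unique(gt$target),
                  sample(setdiff(genes(norm), c(tfs, gt$target)), 30))
  imp <- regulon_importance(norm, tfs, candidates, n_rounds = 40)
  reg <- build_regulons(imp, top_k = 6)
  hits <- sapply(tfs, function(tf) {
    mean(gt$target[gt$tf == tf] %in% reg$target[reg$tf == tf])
  })
  # scaled-down bound (half the cells of the full design, no top-k slack);
  # the full-scale recovery bound lives in the acceptance suite
  expect_gte(mean(hits), 0.7)
})

test_that("regulon recovery does not degrade as beta grows", {
  recov <- sapply(c(0.5, 2), function(beta) {
    hits <- sapply(1:3, function(rep) {
      cfg <- simulation_config(
        n_genes = 150, n_private_genes = 5, cells_per_group = 25,
        n_sm_pathways = 1, n_de_pathways = 1, genes_per_pathway = 10,
        n_regulons = 1, targets_per_regulon = 5, beta = beta,
        n_lr_pairs = 1, n_background_sets = 1, ppi_background_edges = 30,
        seed = 500 + rep
      )
      st <- simulate_study(cfg)
      norm <- normalize_log1p_cp10k(st$species$human$counts)
      gt <- st$ground_truth$regulons
      set.seed(rep)
      cand <- c(gt$target, sample(setdiff(genes(norm), c(gt$tf, gt$target)), 20))
      imp <- regulon_importance(norm, unique(gt$tf), cand, n_rounds = 30)
      reg <- build_regulons(imp, top_k = 5)
      mean(gt$target %in% reg$target)
    })
    mean(hits)
  })
  expect_gte(recov[2], recov[1])
})

test_that("TF concordance labels the planted shared-up factors", {
  st <- small_study()
  run_degs <- function(sp) {
    d <- st$species[[sp]]
    call_degs(normalize_log1p_cp10k(d$counts), d$cells)
  }
  degs <- list(rat = run_degs("rat"), human = run_degs("human"))
  tfs <- st$ground_truth$tfs$tf
  tc <- suppressMessages(tf_concordance(degs, st$orthologs, tfs))
  expect_true(all(tc$label == "shared_up"))

  swapped <- suppressMessages(
    tf_concordance(rev(degs), st$orthologs, tfs)
  )
  expect_identical(swapped$label, tc$label)
  expect_error(tf_concordance(degs, st$orthologs, character(0)), "non-empty")
})

test_that("disjoint DEG TF sets share nothing", {
  mk <- function(genes, deg) {
    tibble::tibble(
      gene = genes, log2fc = 1, p_raw = 0.001, p_adj = 0.001,
      n_old = 10L, n_young = 10L, mean_old = 2, mean_young = 1, is_deg = deg
    )
  }
  degs <- list(
    rat = mk(c("TFA", "TFB"), c(TRUE, FALSE)),
    human = mk(c("TFA", "TFB"), c(FALSE, TRUE))
  )
  orth <- tibble::tibble(
    species_a = "rat", gene_a = c("TFA", "TFB"),
    species_b = "human", gene_b = c("TFA", "TFB")
  )
  tc <- tf_concordance(degs, orth, c("TFA", "TFB"))
  expect_true(all(tc$label == "not_shared"))
})
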