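# Synthetic three-species young/old single-cell studies with planted,
# recoverable structure: negative-binomial counts on a log-link; gene sets
# whose old-vs-young log-mean shift has the same sign in every species (SM)
# or flips in one species (DE); TF regulons coupled through a per-cell
# latent activity; ligand-receptor pairs whose expression rises in old
# sender/receiver cells; and a PPI graph wired more densely inside planted
# pathways than in the background.

#' Configuration of a synthetic cross-species aging study
#'
#' Defaults describe the reference study design: three species, four
#' vascular cell types (fibroblasts, smooth muscle, endothelium, immune),
#' 50 cells per species x cell type x age group (200 per species and age
#' group), 2000 genes, 10 same-trend (SM) and 10 divergent (DE) planted
#' pathways of 50 genes with an old-group log-mean shift of `delta = 0.5`
#' (the divergent species defaults to monkey), four planted regulons and
#' four planted ligand-receptor pairs.
#'
#' @param species species names; first-listed conventions do not matter,
#'   `reference` marks the human-like column.
#' @param reference reference species.
#' @param n_genes shared gene-symbol universe size.
#' @param ortholog_fraction fraction of background shared genes retained per
#'   species (planted genes are always shared); in (0, 1].
#' @param n_private_genes species-private genes appended per species.
#' @param cell_types cell-type labels.
#' @param cells_per_group cells per (species, cell type, age group).
#' @param dispersion negative-binomial size parameter.
#' @param base_meanlog,base_sdlog log-normal parameters of baseline mean
#'   counts.
#' @param n_sm_pathways,n_de_pathways,genes_per_pathway planted pathway
#'   design.
#' @param delta old-group log-mean shift of planted pathway genes.
#' @param discordant_species species whose DE-pathway sign is flipped.
#' @param n_background_sets unplanted random gene sets added to the GMT.
#' @param n_regulons,targets_per_regulon,beta planted regulon design;
#'   `beta` scales how strongly targets load on the TF's latent activity.
#' @param tf_latent_sd standard deviation of the per-cell TF latent
#'   activity on the log-mean scale.
#' @param tf_age_effect old-group log-mean shift of planted TFs (same sign
#'   in all species, so planted TFs are shared-up).
#' @param n_lr_pairs,lr_effect planted ligand-receptor design; `lr_effect`
#'   is the old-group log-mean rise of the ligand in its sender cell type
#'   and the receptor in its receiver cell type.
#' @param planted_base_floor minimum baseline mean count of planted pathway
#'   genes (keeps planted effects detectable rather than drowned in zeros).
#' @param hub_base baseline mean count assigned to TFs and ligand/receptor
#'   genes (group trimeans of near-all-zero genes are identically zero).
#' @param ppi_within_prob within-pathway PPI edge probability.
#' @param ppi_background_edges random background PPI edges.
#' @param seed master seed; all artifacts derive fixed offsets from it.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(
    species = c("rat", "monkey", "human"),
    reference = "human",
    n_genes = 2000,
    ortholog_fraction = 0.85,
    n_private_genes = 100,
    cell_types = c("FB", "SMC", "EC", "IMM"),
    cells_per_group = 50,
    dispersion = 2,
    base_meanlog = log(0.8),
    base_sdlog = 1,
    n_sm_pathways = 10,
    n_de_pathways = 10,
    genes_per_pathway = 50,
    delta = 0.5,
    discordant_species = "monkey",
    n_background_sets = 10,
    n_regulons = 4,
    targets_per_regulon = 10,
    beta = 1,
    tf_latent_sd = 0.7,
    tf_age_effect = 1,
    n_lr_pairs = 4,
    lr_effect = 1,
    planted_base_floor = 0.3,
    hub_base = 2,
    ppi_within_prob = 0.1,
    ppi_background_edges = 1000,
    seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos <- c("n_genes", "n_private_genes", "cells_per_group", "dispersion",
           "genes_per_pathway", "targets_per_regulon", "cells_per_group")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(sprintf("`%s` must be positive.", f))
    }
  }
  nonneg <- c("n_sm_pathways", "n_de_pathways", "n_regulons", "n_lr_pairs",
              "n_background_sets", "ppi_background_edges")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      abort(sprintf("`%s` must be non-negative.", f))
    }
  }
  if (!is.finite(cfg$delta) || !is.finite(cfg$beta)) {
    abort("`delta` and `beta` must be finite.")
  }
  if (cfg$ortholog_fraction <= 0 || cfg$ortholog_fraction > 1) {
    abort("`ortholog_fraction` must be in (0, 1].")
  }
  if (length(cfg$species) < 2) abort("At least two species are required.")
  if (!cfg$reference %in% cfg$species) {
    abort("`reference` must be one of `species`.")
  }
  if (cfg$n_de_pathways > 0 && !cfg$discordant_species %in% cfg$species) {
    abort("`discordant_species` must be one of `species`.")
  }
  n_structural <- (cfg$n_sm_pathways + cfg$n_de_pathways) *
    cfg$genes_per_pathway +
    cfg$n_regulons * (1 + cfg$targets_per_regulon) +
    2 * cfg$n_lr_pairs
  if (cfg$n_genes < n_structural + 10) {
    abort(sprintf(
      "`n_genes` = %d is too small for %d planted genes plus background.",
      cfg$n_genes, n_structural
    ))
  }
  if (cfg$seed < 0 || cfg$seed > 2^31 - 1000) {
    abort("`seed` must lie in [0, 2^31 - 1000].")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a cross-species aging study with known ground truth
#'
#' Draws per-species gene x cell negative-binomial count matrices plus all
#' side tables (annotations, gene sets, ortholog map, ligand-receptor table,
#' PPI edges) and the ground truth needed to score downstream recovery.
#' Identical configurations (including seed) reproduce identical studies;
#' each artifact consumes its own seeded stream, so changing, say, the PPI
#' design does not perturb the expression draws.
#'
#' @param config a [simulation_config()].
#' @return A list (class `sim_study`) with elements `species` (named list of
#'   `counts` = raw [expr_matrix()] and `cells` = annotation tibble),
#'   `gene_sets`, `orthologs`, `lr_db`, `ppi_edges`, `ground_truth`,
#'   `config`.
#' @export
simulate_study <- function(config) {
  config <- validate_sim_config(unclass(config))
  layout <- with_seed_offset(config$seed, 1, sim_layout(config))
  species_data <- lapply(seq_along(config$species), function(i) {
    with_seed_offset(config$seed, 100 + i,
                     sim_species(config, layout, config$species[i]))
  })
  names(species_data) <- config$species
  ppi <- with_seed_offset(config$seed, 200, sim_ppi(config, layout))
  sets <- with_seed_offset(config$seed, 300, sim_gene_sets(config, layout))
  orth <- build_ortholog_map(config, species_data)
  structure(
    list(
      species = species_data,
      gene_sets = sets,
      orthologs = orth,
      lr_db = layout$lr_db,
      ppi_edges = ppi,
      ground_truth = layout$ground_truth,
      config = config
    ),
    class = "sim_study"
  )
}

with_seed_offset <- function(seed, offset, expr) {
  set.seed(seed + offset)
  expr
}

# gene roles, planted pathway membership/signs, base means, regulon and LR
# wiring -- shared across species
sim_layout <- function(cfg) {
  n_pw <- cfg$n_sm_pathways + cfg$n_de_pathways
  pw_genes <- if (n_pw > 0) {
    sprintf("G%05d", seq_len(n_pw * cfg$genes_per_pathway))
  } else {
    character(0)
  }
  tfs <- if (cfg$n_regulons > 0) sprintf("TF%02d", seq_len(cfg$n_regulons))
         else character(0)
  n_tg <- cfg$n_regulons * cfg$targets_per_regulon
  targets <- if (n_tg > 0) sprintf("TG%04d", seq_len(n_tg)) else character(0)
  ligands <- if (cfg$n_lr_pairs > 0) sprintf("LG%02d", seq_len(cfg$n_lr_pairs))
             else character(0)
  receptors <- if (cfg$n_lr_pairs > 0) {
    sprintf("RC%02d", seq_len(cfg$n_lr_pairs))
  } else {
    character(0)
  }
  structural <- c(pw_genes, tfs, targets, ligands, receptors)
  n_bg <- cfg$n_genes - length(structural)
  background <- sprintf("B%05d", seq_len(n_bg))
  universe <- c(structural, background)

  base_mean <- rlnorm(length(universe), cfg$base_meanlog, cfg$base_sdlog)
  names(base_mean) <- universe
  if (length(pw_genes) > 0) {
    base_mean[pw_genes] <- pmax(base_mean[pw_genes], cfg$planted_base_floor)
  }
  base_mean[c(tfs, targets, ligands, receptors)] <-
    pmax(base_mean[c(tfs, targets, ligands, receptors)], cfg$hub_base)

  # planted pathways: overall direction alternates; DE pathways flip the
  # sign in the discordant species
  pw_names <- c(
    if (cfg$n_sm_pathways > 0) sprintf("SM_PW%02d", seq_len(cfg$n_sm_pathways)),
    if (cfg$n_de_pathways > 0) sprintf("DE_PW%02d", seq_len(cfg$n_de_pathways))
  )
  pw_label <- rep(c("SM", "DE"), c(cfg$n_sm_pathways, cfg$n_de_pathways))
  membership <- if (n_pw > 0) {
    tibble(
      set = rep(pw_names, each = cfg$genes_per_pathway),
      gene = pw_genes
    )
  } else {
    tibble(set = character(0), gene = character(0))
  }
  base_sign <- rep_len(c(1, -1), n_pw)
  signs <- matrix(rep(base_sign, length(cfg$species)),
                  nrow = n_pw, ncol = length(cfg$species),
                  dimnames = list(pw_names, cfg$species))
  if (cfg$n_de_pathways > 0) {
    de_rows <- which(pw_label == "DE")
    signs[de_rows, cfg$discordant_species] <-
      -signs[de_rows, cfg$discordant_species]
  }
  pathways <- tibble(set = pw_names, label = pw_label)
  for (sp in cfg$species) pathways[[paste0("sign_", sp)]] <- unname(signs[, sp])

  regulons <- if (n_tg > 0) {
    tibble(
      tf = rep(tfs, each = cfg$targets_per_regulon),
      target = targets
    )
  } else {
    tibble(tf = character(0), target = character(0))
  }

  K <- length(cfg$cell_types)
  lr_pairs <- if (cfg$n_lr_pairs > 0) {
    tibble(
      interaction = sprintf("LRI%02d", seq_len(cfg$n_lr_pairs)),
      ligand = ligands,
      receptor = receptors,
      sender = cfg$cell_types[((seq_len(cfg$n_lr_pairs) - 1) %% K) + 1],
      receiver = cfg$cell_types[(seq_len(cfg$n_lr_pairs) %% K) + 1],
      effect_sign = 1
    )
  } else {
    tibble(interaction = character(0), ligand = character(0),
           receptor = character(0), sender = character(0),
           receiver = character(0), effect_sign = numeric(0))
  }
  lr_db <- tibble(
    interaction = lr_pairs$interaction,
    pathway = paste0("LRP_", lr_pairs$interaction),
    ligand = as.list(lr_pairs$ligand),
    receptor = as.list(lr_pairs$receptor),
    agonist = rep(list(character(0)), nrow(lr_pairs)),
    antagonist = rep(list(character(0)), nrow(lr_pairs)),
    co_stim = rep(list(character(0)), nrow(lr_pairs)),
    co_inhib = rep(list(character(0)), nrow(lr_pairs))
  )

  ground_truth <- list(
    pathways = pathways,
    pathway_genes = left_join(membership, pathways[c("set", "label")],
                              by = "set"),
    regulons = regulons,
    tfs = tibble(tf = tfs,
                 age_sign = rep(sign(cfg$tf_age_effect), length(tfs))),
    lr_pairs = lr_pairs
  )
  list(
    universe = universe, background = background, base_mean = base_mean,
    membership = membership, signs = signs, tfs = tfs, regulons = regulons,
    lr_pairs = lr_pairs, lr_db = lr_db, ground_truth = ground_truth
  )
}

# one species' counts + annotation (runs inside its own seeded stream)
sim_species <- function(cfg, layout, sp) {
  n_bg_keep <- floor(cfg$ortholog_fraction * length(layout$background))
  bg_keep <- sort(sample(layout$background, n_bg_keep))
  private <- if (cfg$n_private_genes > 0) {
    sprintf("%s_P%04d", toupper(sp), seq_len(cfg$n_private_genes))
  } else {
    character(0)
  }
  gene_ids <- c(setdiff(layout$universe, layout$background), bg_keep, private)
  base <- c(
    layout$base_mean[setdiff(layout$universe, layout$background)],
    layout$base_mean[bg_keep],
    setNames(rlnorm(length(private), cfg$base_meanlog, cfg$base_sdlog),
             private)
  )

  grid <- expand.grid(
    cell_type = cfg$cell_types, age_group = AGE_LEVELS,
    idx = seq_len(cfg$cells_per_group),
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$cell_type, grid$age_group, grid$idx), ]
  cells_tbl <- tibble(
    cell_id = sprintf("%s_%s_%s_%03d", sp, grid$cell_type, grid$age_group,
                      grid$idx),
    species = sp,
    cell_type = grid$cell_type,
    age_group = grid$age_group
  )
  n_cells <- nrow(cells_tbl)
  is_old <- cells_tbl$age_group == "old"

  logmu <- matrix(log(base), nrow = length(gene_ids), ncol = n_cells,
                  dimnames = list(gene_ids, cells_tbl$cell_id))

  # planted pathway shifts in old cells
  if (nrow(layout$membership) > 0) {
    for (p in rownames(layout$signs)) {
      pg <- layout$membership$gene[layout$membership$set == p]
      logmu[pg, is_old] <- logmu[pg, is_old] +
        layout$signs[p, sp] * cfg$delta
    }
  }
  # regulons: TF and its targets load on a shared per-cell latent activity
  for (tf in layout$tfs) {
    a <- rnorm(n_cells, 0, cfg$tf_latent_sd)
    logmu[tf, ] <- logmu[tf, ] + a
    logmu[tf, is_old] <- logmu[tf, is_old] + cfg$tf_age_effect
    tg <- layout$regulons$target[layout$regulons$tf == tf]
    if (length(tg) > 0) {
      logmu[tg, ] <- logmu[tg, ] + cfg$beta *
        matrix(a, length(tg), n_cells, byrow = TRUE)
    }
  }
  # ligand-receptor aging effects in their sender/receiver cell types
  if (nrow(layout$lr_pairs) > 0) {
    for (k in seq_len(nrow(layout$lr_pairs))) {
      lp <- layout$lr_pairs[k, ]
      send_old <- is_old & cells_tbl$cell_type == lp$sender
      recv_old <- is_old & cells_tbl$cell_type == lp$receiver
      logmu[lp$ligand, send_old] <- logmu[lp$ligand, send_old] + cfg$lr_effect
      logmu[lp$receptor, recv_old] <- logmu[lp$receptor, recv_old] +
        cfg$lr_effect
    }
  }

  counts <- matrix(
    rnbinom(length(logmu), size = cfg$dispersion, mu = exp(logmu)),
    nrow = nrow(logmu), dimnames = dimnames(logmu)
  )
  list(counts = expr_matrix(counts), cells = cells_tbl)
}

sim_ppi <- function(cfg, layout) {
  edges <- list()
  if (nrow(layout$membership) > 0) {
    for (p in unique(layout$membership$set)) {
      pg <- layout$membership$gene[layout$membership$set == p]
      pairs <- combn(pg, 2)
      keep <- runif(ncol(pairs)) < cfg$ppi_within_prob
      if (any(keep)) {
        edges[[p]] <- tibble(gene_a = pairs[1, keep], gene_b = pairs[2, keep])
      }
    }
  }
  if (cfg$ppi_background_edges > 0) {
    a <- sample(layout$universe, cfg$ppi_background_edges, replace = TRUE)
    b <- sample(layout$universe, cfg$ppi_background_edges, replace = TRUE)
    edges[["background"]] <- tibble(gene_a = a, gene_b = b)
  }
  canonicalize_edges(list_rbind(edges))
}

sim_gene_sets <- function(cfg, layout) {
  sets <- split(layout$membership$gene, layout$membership$set)
  if (cfg$n_background_sets > 0) {
    bg <- lapply(seq_len(cfg$n_background_sets), function(i) {
      sample(layout$universe, cfg$genes_per_pathway)
    })
    names(bg) <- sprintf("BG_PW%02d", seq_len(cfg$n_background_sets))
    sets <- c(sets, bg)
  }
  gene_sets(sets[order(names(sets))])
}

build_ortholog_map <- function(cfg, species_data) {
  sp <- cfg$species
  rows <- list()
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)) {
      if (i >= j) next
      shared <- intersect(genes(species_data[[sp[i]]]$counts),
                          genes(species_data[[sp[j]]]$counts))
      rows[[paste(sp[i], sp[j])]] <- tibble(
        species_a = sp[i], gene_a = shared,
        species_b = sp[j], gene_b = shared
      )
    }
  }
  list_rbind(rows)
}

#' Write / read a simulated study on disk
#'
#' `write_study()` emits every artifact in its interchange format:
#' per-species MatrixMarket triples and annotation TSVs, the GMT collection,
#' ortholog / ligand-receptor / PPI TSVs, and `ground_truth.json`.
#' `read_study()` loads them back (ground truth included) for round-trip
#' checks and external tooling.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `write_study()` the directory, invisibly; `read_study()` a list
#'   shaped like a `sim_study` (without the config).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(study$species)) {
    write_expression_mtx(study$species[[sp]]$counts, dir, prefix = sp)
    write_cell_annotation(study$species[[sp]]$cells,
                          file.path(dir, paste0(sp, "_cells.tsv")))
  }
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_ortholog_map(study$orthologs, file.path(dir, "orthologs.tsv"))
  write_lr_db(study$lr_db, file.path(dir, "lr_db.tsv"))
  write_edge_list(study$ppi_edges, file.path(dir, "ppi_edges.tsv"))
  jsonlite::write_json(
    purrr::map(study$ground_truth, as.data.frame),
    file.path(dir, "ground_truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_study
#' @param species species prefixes to load (defaults to every
#'   `<sp>_cells.tsv` present).
#' @export
read_study <- function(dir, species = NULL) {
  if (is.null(species)) {
    species <- sub("_cells\\.tsv$", "",
                   basename(Sys.glob(file.path(dir, "*_cells.tsv"))))
  }
  species_data <- lapply(species, function(sp) {
    list(
      counts = read_expression(
        file.path(dir, paste0(sp, ".mtx")),
        file.path(dir, paste0(sp, "_genes.tsv")),
        file.path(dir, paste0(sp, "_barcodes.tsv"))
      ),
      cells = read_cell_annotation(file.path(dir, paste0(sp, "_cells.tsv")))
    )
  })
  names(species_data) <- species
  gt_raw <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                simplifyVector = TRUE)
  list(
    species = species_data,
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
    orthologs = read_ortholog_map(file.path(dir, "orthologs.tsv")),
    lr_db = read_lr_db(file.path(dir, "lr_db.tsv")),
    ppi_edges = read_edge_list(file.path(dir, "ppi_edges.tsv")),
    ground_truth = purrr::map(gt_raw, as_tibble)
  )
}

#' Emit a deterministic fixture study
#'
#' Three size presets with fixed seeds: `tiny` (50 genes x 80 cells per
#' species, strong planted effects -- a smoke fixture), `small` (300 genes,
#' 200 cells) and `default` (the full [simulation_config()] design). Larger
#' presets have strictly more genes.
#'
#' @param size preset name.
#' @param dir optional directory; when given the study is also written via
#'   [write_study()].
#' @return The simulated study, invisibly when written to disk.
#' @export
emit_fixture <- function(size = c("tiny", "small", "default"), dir = NULL) {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = simulation_config(
      n_genes = 50, n_private_genes = 2, cells_per_group = 10,
      n_sm_pathways = 1, n_de_pathways = 1, genes_per_pathway = 8,
      delta = 1.5, n_background_sets = 2, n_regulons = 1,
      targets_per_regulon = 4, n_lr_pairs = 2, lr_effect = 1.5,
      ortholog_fraction = 0.9, ppi_background_edges = 40, seed = 101
    ),
    small = simulation_config(
      n_genes = 300, n_private_genes = 20, cells_per_group = 25,
      n_sm_pathways = 3, n_de_pathways = 3, genes_per_pathway = 20,
      n_background_sets = 4, n_regulons = 2, targets_per_regulon = 6,
      n_lr_pairs = 3, ppi_background_edges = 150, seed = 102
    ),
    default = simulation_config(seed = 103)
  )
  study <- simulate_study(cfg)
  if (!is.null(dir)) {
    write_study(study, dir)
    return(invisible(study))
  }
  study
}
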