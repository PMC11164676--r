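# Ligand-receptor communication probability between cell-type groups:
# robust group expression by the Tukey trimean, geometric-mean complex
# activity with co-stimulatory / co-inhibitory modulation, a Hill-saturated
# probability with agonist/antagonist terms and population proportions, and
# old-vs-young differential interaction networks.

#' Tukey trimean
#'
#' `EM = Q2/2 + (Q1 + Q3)/4` with quartiles by linear interpolation
#' (`type = 7`): the robust "ensemble average" expression of a gene in a
#' group of cells.
#'
#' @param values non-empty numeric vector.
#' @return The trimean.
#' @export
#' @examples
#' trimean(c(0, 0, 0, 4)) # 0.25
trimean <- function(values) {
  if (length(values) == 0) abort("`values` must be non-empty.")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  0.5 * q[2] + 0.25 * (q[1] + q[3])
}

#' Group-level trimean expression
#'
#' Trimean expression of each requested gene within each cell group (cell
#' type within one age group), plus group sizes. Genes absent from the
#' matrix get expression 0.
#'
#' @param m a normalized [expr_matrix()].
#' @param group named factor/character: group of every cell of `m` (in
#'   column order).
#' @param gene_ids genes to summarize.
#' @return A list with `em` (genes x groups matrix of trimeans), `sizes`
#'   (named cell counts) and `n` (total cells).
#' @export
group_expression <- function(m, group, gene_ids) {
  stopifnot(inherits(m, "expr_matrix"))
  group <- as.character(group)
  stopifnot(length(group) == ncol(m$values))
  groups <- sort(unique(group))
  present <- intersect(gene_ids, genes(m))
  em <- matrix(0, length(gene_ids), length(groups),
               dimnames = list(gene_ids, groups))
  for (g in groups) {
    sub <- as.matrix(m$values[present, group == g, drop = FALSE])
    em[present, g] <- apply(sub, 1, trimean)
  }
  list(em = em, sizes = table(group)[groups], n = length(group))
}

geo_mean <- function(x) {
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

em_of <- function(em, gs, group) {
  vapply(gs, function(g) if (g %in% rownames(em)) em[g, group] else 0,
         numeric(1))
}

#' Ligand and receptor activity of a multi-subunit complex
#'
#' Ligand activity in sender group `i` is the geometric mean of the subunit
#' trimeans (a missing or silent subunit zeroes the complex). Receptor
#' activity in receiver group `j` is the geometric mean of receptor-subunit
#' trimeans times `(1 + RA_j) / (1 + RI_j)`, where `RA_j` / `RI_j` are mean
#' trimeans of the co-stimulatory / co-inhibitory receptor lists (0 when the
#' list is empty).
#'
#' @param em trimean matrix from [group_expression()].
#' @param subunits character vector of complex subunits.
#' @param group column of `em` to evaluate.
#' @param co_stim,co_inhib modulator gene lists (may be empty).
#' @return Activity (non-negative scalar).
#' @export
ligand_activity <- function(em, subunits, group) {
  geo_mean(em_of(em, subunits, group))
}

#' @rdname ligand_activity
#' @export
receptor_activity <- function(em, subunits, group,
                              co_stim = character(0),
                              co_inhib = character(0)) {
  base <- geo_mean(em_of(em, subunits, group))
  ra <- if (length(co_stim) > 0) mean(em_of(em, co_stim, group)) else 0
  ri <- if (length(co_inhib) > 0) mean(em_of(em, co_inhib, group)) else 0
  base * (1 + ra) / (1 + ri)
}

#' Communication probability of one ligand-receptor pair
#'
#' Hill-saturated probability that sender group `i` signals receiver group
#' `j` through interaction `k`:
#' `p = LR/(Kh + LR) * (1 + AG_i/(Kh + AG_i)) * (1 + AG_j/(Kh + AG_j)) *
#'  Kh/(Kh + AN_i) * Kh/(Kh + AN_j) * n_i n_j / n^2`,
#' where `AG`/`AN` are mean trimeans of the soluble agonist / antagonist
#' lists in each group (their factors collapse to 1 when the list is empty).
#'
#' @param L,R ligand and receptor activities.
#' @param AG_i,AG_j,AN_i,AN_j agonist / antagonist mean expression in sender
#'   and receiver groups.
#' @param n_i,n_j,n sender, receiver and total cell counts.
#' @param Kh Hill constant (> 0; default 0.5).
#' @return The probability contribution (non-negative).
#' @export
communication_probability <- function(L, R, AG_i = 0, AG_j = 0,
                                      AN_i = 0, AN_j = 0,
                                      n_i = 1, n_j = 1, n = 1, Kh = 0.5) {
  if (Kh <= 0) abort("`Kh` must be positive.")
  lr <- L * R
  hill <- lr / (Kh + lr)
  ag <- (1 + AG_i / (Kh + AG_i)) * (1 + AG_j / (Kh + AG_j))
  an <- (Kh / (Kh + AN_i)) * (Kh / (Kh + AN_j))
  hill * ag * an * (n_i * n_j / n^2)
}

#' Old-vs-young cell-cell communication networks
#'
#' For each age group, computes the communication probability of every
#' (sender cell type, receiver cell type, interaction) triple, then
#' aggregates to K x K interaction-count matrices (pairs with `p > 0`, and
#' permutation `p-value <= p_cutoff` when `n_perm > 0`) and summed-strength
#' matrices. The differential network is old minus young, entrywise. Groups
#' with fewer than 3 cells are still computed but flagged low-confidence.
#'
#' @param m a normalized [expr_matrix()].
#' @param ann cell annotation for the cells of `m`.
#' @param lrdb ligand-receptor table (see [read_lr_db()]).
#' @param Kh Hill constant, default 0.5.
#' @param n_perm label permutations per age group for significance filtering
#'   (0 disables the filter).
#' @param p_cutoff permutation p-value cutoff used when `n_perm > 0`.
#' @param seed seed for the permutation stream.
#' @return A `comm_network` object: per age group the probability array
#'   (`K x K x N`), `count` and `strength` matrices; `diff_count` and
#'   `diff_strength`; `low_confidence` group labels.
#' @export
build_networks <- function(m, ann, lrdb, Kh = 0.5, n_perm = 0,
                           p_cutoff = 0.05, seed = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$normalized) abort("`m` must be normalized.")
  ann <- validate_cell_annotation(ann)
  ann <- ann[match(cells(m), ann$cell_id), ]
  types <- sort(unique(ann$cell_type))
  all_genes <- unique(unlist(lrdb[LR_LIST_COLS]))

  per_age <- purrr::map(AGE_LEVELS, function(age) {
    keep <- ann$age_group == age
    sub <- expr_matrix(m$values[, keep, drop = FALSE], normalized = TRUE)
    grp <- ann$cell_type[keep]
    prob <- comm_prob_array(sub, grp, types, lrdb, all_genes, Kh)
    retained <- prob > 0
    if (n_perm > 0) {
      pv <- comm_permutation_test(sub, grp, types, lrdb, all_genes, Kh,
                                  n_perm = n_perm,
                                  seed = seed + match(age, AGE_LEVELS))
      retained <- retained & (pv <= p_cutoff)
    }
    sizes <- table(factor(grp, levels = types))
    list(
      prob = prob,
      count = apply(retained, c(1, 2), sum),
      strength = apply(prob * retained, c(1, 2), sum),
      low_confidence = names(sizes)[sizes < 3]
    )
  })
  names(per_age) <- AGE_LEVELS
  structure(
    list(
      young = per_age$young, old = per_age$old,
      diff_count = per_age$old$count - per_age$young$count,
      diff_strength = per_age$old$strength - per_age$young$strength,
      cell_types = types, interactions = lrdb$interaction, Kh = Kh
    ),
    class = "comm_network"
  )
}

# K x K x N probability array for one age group
comm_prob_array <- function(m, group, types, lrdb, all_genes, Kh) {
  ge <- group_expression(m, group, all_genes)
  em <- ge$em
  sizes <- as.numeric(table(factor(group, levels = types)))
  n <- ge$n
  K <- length(types)
  N <- nrow(lrdb)
  prob <- array(0, c(K, K, N), dimnames = list(types, types, lrdb$interaction))
  mod_mean <- function(gs, grp) {
    if (length(gs) == 0) 0 else mean(em_of(em, gs, grp))
  }
  for (k in seq_len(N)) {
    L <- vapply(types, function(t) ligand_activity(em, lrdb$ligand[[k]], t),
                numeric(1))
    R <- vapply(types, function(t) {
      receptor_activity(em, lrdb$receptor[[k]], t,
                        lrdb$co_stim[[k]], lrdb$co_inhib[[k]])
    }, numeric(1))
    AG <- vapply(types, function(t) mod_mean(lrdb$agonist[[k]], t), numeric(1))
    AN <- vapply(types, function(t) mod_mean(lrdb$antagonist[[k]], t),
                 numeric(1))
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        prob[i, j, k] <- communication_probability(
          L[i], R[j], AG[i], AG[j], AN[i], AN[j],
          sizes[i], sizes[j], n, Kh
        )
      }
    }
  }
  prob
}

#' Permutation test for communication probabilities
#'
#' Null distribution by shuffling cell-type labels within the age group and
#' recomputing the probability array; the p-value of each (sender, receiver,
#' interaction) triple is the add-one fraction of null probabilities at
#' least as large as the observed one.
#'
#' @param m normalized [expr_matrix()] restricted to one age group.
#' @param group cell-type label per cell.
#' @param types cell-type universe (matrix axes).
#' @param lrdb ligand-receptor table.
#' @param all_genes genes to pre-summarize (defaults to all genes named in
#'   `lrdb`).
#' @param Kh Hill constant.
#' @param n_perm number of label shuffles (>= 10).
#' @param seed permutation seed.
#' @return A `K x K x N` array of p-values.
#' @export
comm_permutation_test <- function(m, group, types = sort(unique(group)),
                                  lrdb, all_genes = NULL, Kh = 0.5,
                                  n_perm = 100, seed = 1) {
  if (n_perm < 10) abort("`n_perm` must be at least 10.")
  if (is.null(all_genes)) all_genes <- unique(unlist(lrdb[LR_LIST_COLS]))
  obs <- comm_prob_array(m, group, types, lrdb, all_genes, Kh)
  set.seed(seed)
  exceed <- array(0, dim(obs))
  for (b in seq_len(n_perm)) {
    null <- comm_prob_array(m, sample(group), types, lrdb, all_genes, Kh)
    exceed <- exceed + (null >= obs)
  }
  pv <- (1 + exceed) / (1 + n_perm)
  dimnames(pv) <- dimnames(obs)
  pv
}

#' Aggregate communication probabilities to signaling pathways
#'
#' The communication probability of a pathway is the sum of the
#' probabilities of its member ligand-receptor pairs.
#'
#' @param net a [build_networks()] result.
#' @param lrdb the ligand-receptor table used to build it.
#' @return A tibble `pathway, sender, receiver, strength_young,
#'   strength_old, diff_strength`.
#' @export
aggregate_pathways <- function(net, lrdb) {
  stopifnot(identical(lrdb$interaction, net$interactions))
  purrr::map(unique(lrdb$pathway), function(pw) {
    k <- which(lrdb$pathway == pw)
    young <- apply(net$young$prob[, , k, drop = FALSE], c(1, 2), sum)
    old <- apply(net$old$prob[, , k, drop = FALSE], c(1, 2), sum)
    grid <- expand.grid(sender = net$cell_types, receiver = net$cell_types,
                        stringsAsFactors = FALSE)
    as_tibble(grid) |>
      mutate(
        pathway = pw, .before = 1
      ) |>
      mutate(
        strength_young = as.vector(young),
        strength_old = as.vector(old),
        diff_strength = as.vector(old - young)
      )
  }) |> list_rbind()
}

#' @export
print.comm_network <- function(x, ...) {
  cat(sprintf(
    "<comm_network> %d cell types, %d interactions (Kh = %g)\n",
    length(x$cell_types), length(x$interactions), x$Kh
  ))
  cat("old - young total strength:",
      format(sum(x$diff_strength), digits = 4), "\n")
  invisible(x)
}

#' @method tidy comm_network
#' @export
tidy.comm_network <- function(x, ...) {
  grid <- expand.grid(
    sender = x$cell_types, receiver = x$cell_types,
    stringsAsFactors = FALSE
  )
  as_tibble(grid) |>
    mutate(
      count_young = as.vector(x$young$count),
      count_old = as.vector(x$old$count),
      strength_young = as.vector(x$young$strength),
      strength_old = as.vector(x$old$strength),
      diff_count = as.vector(x$diff_count),
      diff_strength = as.vector(x$diff_strength)
    )
}

#' @method glance comm_network
#' @export
glance.comm_network <- function(x, ...) {
  tibble(
    n_cell_types = length(x$cell_types),
    n_interactions = length(x$interactions),
    total_count_young = sum(x$young$count),
    total_count_old = sum(x$old$count),
    total_strength_young = sum(x$young$strength),
    total_strength_old = sum(x$old$strength)
  )
}

#' Heatmap of the old-minus-young differential interaction strength
#'
#' Red cells mark sender-receiver pairs whose communication strengthens with
#' age; blue cells mark weakened ones.
#'
#' @param object a `comm_network`.
#' @param what `"strength"` (default) or `"count"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot comm_network
#' @export
autoplot.comm_network <- function(object, what = c("strength", "count"), ...) {
  what <- match.arg(what)
  df <- tidy(object)
  df$value <- df[[paste0("diff_", what)]]
  ggplot2::ggplot(df, ggplot2::aes(.data$receiver, .data$sender,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(fill = sprintf("old - young %s", what)) +
    ggplot2::theme_minimal()
}
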