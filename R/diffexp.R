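# Old-vs-young differential expression: two-sided Wilcoxon rank-sum per gene
# with Bonferroni correction and a log2 fold-change filter on the normalized
# scale.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution of the Mann-Whitney U statistic when the pooled
#' sample is small (`n_x + n_y <= 16`) and tie-free; otherwise the normal
#' approximation with midranks, tie-corrected variance and a continuity
#' correction. The two-sided exact p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_max pooled-size cutoff for the exact path (default 16).
#' @return A list with `statistic` (U for `x`) and `p.value` in (0, 1].
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p.value # 1/3
wilcoxon_rank_sum <- function(x, y, exact_max = 16L) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0 || ny == 0) abort("Both groups must be non-empty.")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && (nx + ny) <= exact_max) {
    p <- 2 * min(pwilcox(u, nx, ny), pwilcox(u - 1, nx, ny, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    n <- nx + ny
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
  }
  list(statistic = unname(u), p.value = p)
}

#' Log2 fold change with pseudocount
#'
#' `log2((mean_old + pseudocount) / (mean_young + pseudocount))`, vectorized.
#'
#' @param mean_old,mean_young non-negative group means (normalized scale).
#' @param pseudocount positive stabilizer, default 1.
#' @return Numeric vector of log2 fold changes (old over young).
#' @export
log2_fold_change <- function(mean_old, mean_young, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  if (any(mean_old < 0) || any(mean_young < 0)) {
    abort("Group means must be non-negative.")
  }
  log2((mean_old + pseudocount) / (mean_young + pseudocount))
}

#' Call differentially expressed genes between age groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test of old versus young cells with
#' Bonferroni correction over the genes actually tested; genes expressed in
#' neither group are dropped before testing (and before the correction
#' denominator is counted). A gene is flagged `is_deg` when
#' `|log2fc| >= fc_threshold` and its p-value (column and comparator are
#' configurable; default Bonferroni-adjusted, `<=`) passes `p_threshold`.
#'
#' @param m a normalized [expr_matrix()].
#' @param ann cell annotation covering all cells of `m` (see
#'   [read_cell_annotation()]).
#' @param fc_threshold absolute log2 fold-change cutoff (default 0.1).
#' @param p_threshold p-value cutoff (default 0.05).
#' @param scope `"all_cells"` (one table) or `"per_cell_type"` (stacked
#'   tables with a `cell_type` column).
#' @param p_column which p-value the DEG flag uses: `"adj"` (Bonferroni,
#'   default) or `"raw"`.
#' @param strict if `TRUE` use `<` rather than `<=` for the p cutoff.
#' @param pseudocount passed to [log2_fold_change()].
#' @return A tibble with columns `gene, log2fc, p_raw, p_adj, n_old, n_young,
#'   mean_old, mean_young, is_deg` (plus `cell_type` for the per-type scope).
#' @export
call_degs <- function(m, ann, fc_threshold = 0.1, p_threshold = 0.05,
                      scope = c("all_cells", "per_cell_type"),
                      p_column = c("adj", "raw"), strict = FALSE,
                      pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$normalized) abort("`m` must be normalized before DEG calling.")
  scope <- match.arg(scope)
  p_column <- match.arg(p_column)
  ann <- validate_cell_annotation(ann)
  missing_cells <- setdiff(cells(m), ann$cell_id)
  if (length(missing_cells) > 0) {
    abort(sprintf("%d cells of the matrix are missing from the annotation.",
                  length(missing_cells)))
  }
  ann <- ann[match(cells(m), ann$cell_id), ]

  run_scope <- function(keep, label) {
    age <- ann$age_group[keep]
    if (!all(AGE_LEVELS %in% age)) {
      abort(sprintf("Scope '%s' does not contain both age groups.", label))
    }
    sub <- m$values[, keep, drop = FALSE]
    deg_table_one(sub, age == "old", fc_threshold, p_threshold,
                  p_column, strict, pseudocount)
  }

  if (scope == "all_cells") {
    run_scope(rep(TRUE, ncol(m$values)), "all_cells")
  } else {
    types <- sort(unique(ann$cell_type))
    purrr::map(types, function(ct) {
      run_scope(ann$cell_type == ct, ct) |> mutate(cell_type = ct, .before = 1)
    }) |> list_rbind()
  }
}

deg_table_one <- function(values, is_old, fc_threshold, p_threshold,
                          p_column, strict, pseudocount) {
  old <- values[, is_old, drop = FALSE]
  young <- values[, !is_old, drop = FALSE]
  expressed <- (Matrix::rowSums(old) + Matrix::rowSums(young)) > 0
  old <- old[expressed, , drop = FALSE]
  young <- young[expressed, , drop = FALSE]
  m_tested <- sum(expressed)
  if (m_tested == 0) {
    return(tibble(
      gene = character(0), log2fc = numeric(0), p_raw = numeric(0),
      p_adj = numeric(0), n_old = integer(0), n_young = integer(0),
      mean_old = numeric(0), mean_young = numeric(0), is_deg = logical(0)
    ))
  }
  old_d <- as.matrix(old)
  young_d <- as.matrix(young)
  p_raw <- vapply(seq_len(m_tested), function(i) {
    wilcoxon_rank_sum(old_d[i, ], young_d[i, ])$p.value
  }, numeric(1))
  mean_old <- rowMeans(old_d)
  mean_young <- rowMeans(young_d)
  lfc <- log2_fold_change(mean_old, mean_young, pseudocount)
  p_adj <- pmin(1, m_tested * p_raw)
  p_use <- if (p_column == "adj") p_adj else p_raw
  pass_p <- if (strict) p_use < p_threshold else p_use <= p_threshold
  tibble(
    gene = rownames(old_d),
    log2fc = lfc,
    p_raw = p_raw,
    p_adj = p_adj,
    n_old = ncol(old_d),
    n_young = ncol(young_d),
    mean_old = mean_old,
    mean_young = mean_young,
    is_deg = abs(lfc) >= fc_threshold & pass_p
  )
}

#' Volcano plot of a DEG table
#'
#' @param degs a tibble from [call_degs()].
#' @param fc_threshold,p_threshold guide lines matching the calling
#'   thresholds.
#' @return A ggplot object.
#' @export
plot_volcano <- function(degs, fc_threshold = 0.1, p_threshold = 0.05) {
  ggplot2::ggplot(degs, ggplot2::aes(.data$log2fc, -log10(.data$p_adj),
                                     colour = .data$is_deg)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * fc_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (old / young)",
                  y = "-log10 adjusted p", colour = "DEG") +
    ggplot2::theme_minimal()
}
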