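# Transcription-factor to target importance by least-squares gradient
# boosting with depth-1 regression stumps over TF expression, regulon
# assembly from importance rankings, and the two-species TF trend
# concordance used to nominate conserved aging regulators (the AP-1 family
# pattern: FOS/JUN/JUNB/ATF3 up in both species).

#' TF-to-target importance by stump boosting
#'
#' Fits the target gene's expression as a sum of depth-1 regression stumps
#' over candidate transcription-factor expressions: each round greedily
#' picks the (TF, threshold) split minimizing the squared-error loss of the
#' current residual and adds it with step `learning_rate`. The importance of
#' a TF is the total training-loss reduction of the splits made on it.
#' Boosting on training residuals makes the training loss non-increasing by
#' construction; a constant target yields zero importance everywhere.
#'
#' @param m a normalized [expr_matrix()] containing the TFs and the target.
#' @param tf_list candidate transcription factors (must not contain
#'   `target`).
#' @param target target gene id.
#' @param n_rounds boosting rounds (default 50).
#' @param learning_rate shrinkage per round (default 0.1).
#' @param subsample fraction of cells drawn (without replacement, seeded)
#'   per round; 1 disables subsampling and the fit is fully deterministic.
#' @param seed seed for subsampling.
#' @return A `gbm_fit` object: `importance` tibble (`tf, importance,
#'   share`), `train_loss` (mean squared error per round, index 1 = before
#'   boosting), and the call parameters.
#' @export
gbm_importance <- function(m, tf_list, target, n_rounds = 50,
                           learning_rate = 0.1, subsample = 1, seed = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (target %in% tf_list) abort("`target` must not be in `tf_list`.")
  missing_genes <- setdiff(c(tf_list, target), genes(m))
  if (length(missing_genes) > 0) {
    abort(paste0("Genes absent from the matrix: ",
                 paste(missing_genes, collapse = ", ")))
  }
  n_cells <- ncol(m$values)
  if (n_cells < 20) abort("At least 20 cells are required.")
  X <- t(as.matrix(m$values[tf_list, , drop = FALSE]))
  y <- as.numeric(m$values[target, ])
  if (subsample < 1) set.seed(seed)

  ord <- lapply(seq_along(tf_list), function(j) order(X[, j]))
  fit <- rep(mean(y), n_cells)
  importance <- setNames(numeric(length(tf_list)), tf_list)
  train_loss <- numeric(n_rounds + 1)
  train_loss[1] <- mean((y - fit)^2)

  for (mround in seq_len(n_rounds)) {
    r <- y - fit
    use <- if (subsample < 1) {
      sort(sample.int(n_cells, max(2, floor(subsample * n_cells))))
    } else {
      seq_len(n_cells)
    }
    best <- list(gain = 0, tf = NA_integer_, thr = NA_real_,
                 left = NA_real_, right = NA_real_)
    for (j in seq_along(tf_list)) {
      oj <- ord[[j]][ord[[j]] %in% use]
      xs <- X[oj, j]
      rs <- r[oj]
      nn <- length(rs)
      if (nn < 2) next
      csum <- cumsum(rs)
      tot <- csum[nn]
      k <- seq_len(nn - 1)
      # SSE reduction of splitting after position k (left mean vs right mean)
      gain <- csum[k]^2 / k + (tot - csum[k])^2 / (nn - k) - tot^2 / nn
      valid <- xs[k] < xs[k + 1]
      gain[!valid] <- -Inf
      kb <- which.max(gain)
      if (length(kb) == 1 && is.finite(gain[kb]) && gain[kb] > best$gain) {
        best <- list(
          gain = gain[kb], tf = j, thr = (xs[kb] + xs[kb + 1]) / 2,
          left = csum[kb] / kb, right = (tot - csum[kb]) / (nn - kb)
        )
      }
    }
    if (is.na(best$tf)) {
      train_loss[(mround + 1):(n_rounds + 1)] <- train_loss[mround]
      break
    }
    h <- ifelse(X[, best$tf] <= best$thr, best$left, best$right)
    fit <- fit + learning_rate * h
    loss_before <- mean((y - (fit - learning_rate * h))^2)
    train_loss[mround + 1] <- mean((y - fit)^2)
    importance[best$tf] <- importance[best$tf] +
      n_cells * (loss_before - train_loss[mround + 1])
  }
  total <- sum(importance)
  structure(
    list(
      importance = tibble(
        tf = tf_list,
        importance = unname(importance),
        share = if (total > 0) unname(importance) / total else 0
      ) |> arrange(desc(.data$importance), .data$tf),
      train_loss = train_loss,
      target = target,
      n_rounds = n_rounds,
      learning_rate = learning_rate
    ),
    class = "gbm_fit"
  )
}

#' @export
print.gbm_fit <- function(x, ...) {
  cat(sprintf("<gbm_fit> target %s: %d rounds, final MSE %.4g\n",
              x$target, x$n_rounds, x$train_loss[length(x$train_loss)]))
  print(head(x$importance, 5))
  invisible(x)
}

#' @method tidy gbm_fit
#' @export
tidy.gbm_fit <- function(x, ...) {
  mutate(x$importance, target = x$target, .before = 1)
}

#' @method glance gbm_fit
#' @export
glance.gbm_fit <- function(x, ...) {
  tibble(
    target = x$target,
    n_rounds = x$n_rounds,
    initial_mse = x$train_loss[1],
    final_mse = x$train_loss[length(x$train_loss)],
    top_tf = x$importance$tf[1]
  )
}

#' TF importance over many candidate targets
#'
#' Runs [gbm_importance()] for each target gene and stacks the importances.
#'
#' @inheritParams gbm_importance
#' @param targets candidate target genes (TFs are excluded automatically).
#' @return A tibble `target, tf, importance, share`.
#' @export
regulon_importance <- function(m, tf_list, targets, n_rounds = 50,
                               learning_rate = 0.1, subsample = 1, seed = 1) {
  targets <- setdiff(targets, tf_list)
  purrr::map(targets, function(tg) {
    tidy(gbm_importance(m, tf_list, tg, n_rounds, learning_rate,
                        subsample, seed))
  }) |> list_rbind() |> select("target", "tf", "importance", "share")
}

#' Assemble regulons from an importance table
#'
#' For each TF, its regulon is the `top_k` targets by descending importance
#' (ties broken by gene id); the TF itself is never its own target and
#' zero-importance links are dropped.
#'
#' @param importances tibble from [regulon_importance()].
#' @param top_k targets per regulon (default 10).
#' @return A tibble `tf, target, importance, rank` (class `regulon_table`).
#' @export
build_regulons <- function(importances, top_k = 10) {
  if (nrow(importances) == 0 || top_k == 0) {
    out <- tibble(tf = character(0), target = character(0),
                  importance = numeric(0), rank = integer(0))
  } else {
    out <- importances |>
      filter(.data$importance > 0, .data$tf != .data$target) |>
      group_by(.data$tf) |>
      arrange(desc(.data$importance), .data$target, .by_group = TRUE) |>
      slice_head(n = top_k) |>
      mutate(rank = row_number()) |>
      ungroup() |>
      select("tf", "target", "importance", "rank")
  }
  class(out) <- c("regulon_table", class(out))
  out
}

#' Cross-species TF trend concordance
#'
#' Labels each transcription factor by its old-vs-young behaviour in two
#' species (mapped through one-to-one orthologs): `shared_up` when it is a
#' DEG with positive log2 fold change in both, `shared_down` symmetric,
#' `discordant` when a DEG in both with opposite signs, else `not_shared`.
#' Swapping the two species leaves labels unchanged.
#'
#' @param deg_tables named list of exactly two [call_degs()] tibbles
#'   computed with identical thresholds.
#' @param orthologs ortholog map covering the two species.
#' @param tf_list transcription factors (symbols of the first species).
#' @return A tibble: `tf`, per-species `log2fc_*` and `is_deg_*`, `label`.
#' @export
tf_concordance <- function(deg_tables, orthologs, tf_list) {
  if (length(deg_tables) != 2 || is.null(names(deg_tables))) {
    abort("`deg_tables` must be a named list of exactly two DEG tables.")
  }
  if (length(tf_list) == 0) abort("`tf_list` must be non-empty.")
  sp <- names(deg_tables)
  aligned <- map_to_reference(deg_tables, orthologs, reference = sp[1])
  wide <- aligned |>
    filter(.data$ref_gene %in% tf_list) |>
    mutate(is_deg = coalesce(.data$is_deg, FALSE)) |>
    select("ref_gene", "species", "log2fc", "is_deg") |>
    pivot_wider(names_from = "species", values_from = c("log2fc", "is_deg"))
  lfc <- as.matrix(wide[paste0("log2fc_", sp)])
  deg <- as.matrix(wide[paste0("is_deg_", sp)])
  deg[is.na(deg)] <- FALSE
  both_deg <- deg[, 1] & deg[, 2]
  wide |>
    rename(tf = "ref_gene") |>
    mutate(label = case_when(
      both_deg & lfc[, 1] > 0 & lfc[, 2] > 0 ~ "shared_up",
      both_deg & lfc[, 1] < 0 & lfc[, 2] < 0 ~ "shared_down",
      both_deg ~ "discordant",
      .default = "not_shared"
    )) |>
    arrange(.data$tf)
}
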