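# Containers and on-disk formats for every object the pipeline consumes:
# gene x cell expression (MatrixMarket or dense TSV), cell annotations,
# GMT gene-set collections, ortholog maps, ligand-receptor interaction
# tables, and PPI edge lists.

AGE_LEVELS <- c("young", "old")

# ---- expression matrix -----------------------------------------------------

#' Construct a gene-by-cell expression matrix
#'
#' Wraps a (sparse or dense) numeric matrix of non-negative expression values
#' with gene ids on rows and cell ids on columns, plus a flag recording
#' whether the values are raw counts or normalized expression. This is the
#' one container in the package that is not a tibble: a genes x cells matrix
#' is the natural (and memory-sane) shape for single-cell expression, and
#' every downstream function returns tibbles.
#'
#' @param values numeric matrix or `Matrix::dgCMatrix`, genes in rows, cells
#'   in columns; `dimnames` must carry unique gene and cell ids.
#' @param normalized logical; `TRUE` once values are on the log-normalized
#'   scale (see [normalize_log1p_cp10k()]).
#' @return An object of class `expr_matrix`.
#' @export
#' @examples
#' m <- expr_matrix(matrix(0:3, 2, 2, dimnames = list(c("A", "B"), c("c1", "c2"))))
#' dim(m)
expr_matrix <- function(values, normalized = FALSE) {
  if (is.matrix(values)) {
    storage.mode(values) <- "double"
    values <- Matrix::Matrix(values, sparse = TRUE)
  }
  values <- methods::as(values, "CsparseMatrix")
  if (!is(values, "sparseMatrix")) {
    abort("`values` must be a base matrix or a sparse Matrix.")
  }
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    abort("`values` must have gene ids as rownames and cell ids as colnames.")
  }
  if (anyDuplicated(gene_ids)) abort("Duplicate gene ids are not allowed.")
  if (anyDuplicated(cell_ids)) abort("Duplicate cell ids are not allowed.")
  if (any(values@x < 0)) abort("Expression values must be non-negative.")
  structure(
    list(values = values, normalized = isTRUE(normalized)),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Gene and cell ids of an expression matrix
#' @param m an `expr_matrix`.
#' @return Character vector of ids.
#' @export
genes <- function(m) rownames(m$values)

#' @rdname genes
#' @export
cells <- function(m) colnames(m$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d cells (%s)\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) "normalized" else "raw counts"
  ))
  invisible(x)
}

#' Read an expression matrix
#'
#' Accepts either a MatrixMarket coordinate file (with `genes_path` /
#' `cells_path` sidecars listing one id per line) or a dense TSV whose header
#' row holds cell ids and whose first column holds gene ids. Both readers
#' produce identical in-memory objects for equivalent content.
#'
#' @param matrix_path path to a `.mtx` file or a dense TSV.
#' @param genes_path,cells_path sidecar id files; required for `.mtx` input.
#' @param normalized logical flag recorded on the result.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(matrix_path, genes_path = NULL, cells_path = NULL,
                            normalized = FALSE) {
  if (grepl("\\.mtx$", matrix_path)) {
    if (is.null(genes_path) || is.null(cells_path)) {
      abort("MatrixMarket input needs `genes_path` and `cells_path` sidecars.")
    }
    values <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    if (nrow(values) != length(gene_ids)) {
      abort(sprintf(
        "Matrix has %d rows but %d gene ids were supplied.",
        nrow(values), length(gene_ids)
      ))
    }
    if (ncol(values) != length(cell_ids)) {
      abort(sprintf(
        "Matrix has %d columns but %d cell ids were supplied.",
        ncol(values), length(cell_ids)
      ))
    }
    dimnames(values) <- list(gene_ids, cell_ids)
  } else {
    tab <- utils::read.delim(matrix_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- gene_ids
  }
  if (any(values < 0)) abort("Negative expression values are not allowed.")
  expr_matrix(values, normalized = normalized)
}

#' Write an expression matrix
#'
#' `write_expression_tsv()` writes the dense TSV twin of the reader;
#' `write_expression_mtx()` writes MatrixMarket plus id sidecars into `dir`.
#'
#' @param m an [expr_matrix()].
#' @param path,dir output file / directory.
#' @param prefix file-name prefix for the MatrixMarket triple.
#' @return The written path(s), invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  dense <- as.matrix(m$values)
  tab <- data.frame(gene = rownames(dense), dense, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
write_expression_mtx <- function(m, dir, prefix = "matrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.tsv", "_barcodes.tsv")))
  Matrix::writeMM(m$values, paths[1])
  writeLines(genes(m), paths[2])
  writeLines(cells(m), paths[3])
  invisible(paths)
}

#' Library-size normalize and log-transform counts
#'
#' Scales each cell to 10,000 total counts and applies `log(1 + x)` — the
#' standard preprocessing ahead of log-scale fold changes. All-zero cells are
#' left all-zero.
#'
#' @param m an [expr_matrix()] of raw counts (`normalized = FALSE`).
#' @param scale_factor target library size (default 10,000).
#' @return A normalized [expr_matrix()].
#' @export
normalize_log1p_cp10k <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$normalized) abort("Matrix is already normalized.")
  cs <- Matrix::colSums(m$values)
  fac <- ifelse(cs > 0, scale_factor / cs, 0)
  scaled <- m$values %*% Matrix::Diagonal(x = fac)
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(m$values)
  expr_matrix(methods::as(scaled, "CsparseMatrix"), normalized = TRUE)
}

# ---- cell annotations ------------------------------------------------------

#' Read / write a cell annotation table
#'
#' TSV with header `cell_id  species  cell_type  age_group`; `age_group`
#' must be `young` or `old` and each cell id may appear only once.
#'
#' @param path file path.
#' @return A tibble with those four character columns.
#' @export
read_cell_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cell_annotation(as_tibble(tab))
}

#' @rdname read_cell_annotation
#' @param ann annotation tibble to write.
#' @export
write_cell_annotation <- function(ann, path) {
  validate_cell_annotation(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_cell_annotation <- function(ann) {
  need <- c("cell_id", "species", "cell_type", "age_group")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("Annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(ann$cell_id)) abort("Duplicate cell ids in annotation.")
  bad <- setdiff(unique(ann$age_group), AGE_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("age_group must be one of {young, old}; found: ",
                 paste(bad, collapse = ", ")))
  }
  as_tibble(ann[need])
}

# ---- gene set collections (GMT) -------------------------------------------

#' Read a GMT gene-set collection
#'
#' Each line is `name <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Members are deduplicated preserving first occurrence; descriptions are
#' kept as an attribute but unused by the analysis.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (class `gene_sets`), with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("GMT file '%s' is empty.", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("Malformed GMT line %d in '%s': fewer than 3 fields.",
                  bad[1], path))
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) abort("Duplicate gene set names in GMT file.")
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  gene_sets(sets, descriptions = setNames(desc, nm))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols; members are
#'   deduplicated, empty sets rejected.
#' @param descriptions optional named character vector.
#' @return A `gene_sets` object (named list).
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("Gene sets must have unique names.")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) abort("Gene sets must be non-empty.")
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = c("gene_sets", "list"))
}

#' @rdname read_gmt
#' @param sets a `gene_sets` collection to write.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

# ---- ortholog map ----------------------------------------------------------

#' Read / write an ortholog map
#'
#' TSV with header `species_a  gene_a  species_b  gene_b`; records are
#' direction-free. Cross-species gene comparison in this package goes
#' exclusively through such a map — never through symbol-name matching.
#'
#' @param path file path.
#' @return A tibble with the four columns.
#' @export
read_ortholog_map <- function(path) {
  tab <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("species_a", "gene_a", "species_b", "gene_b")
  if (!all(need %in% names(tab))) {
    abort(paste0("Ortholog map needs columns: ", paste(need, collapse = ", ")))
  }
  tab[need]
}

#' @rdname read_ortholog_map
#' @param orth ortholog tibble to write.
#' @export
write_ortholog_map <- function(orth, path) {
  utils::write.table(orth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- ligand-receptor database ---------------------------------------------

LR_LIST_COLS <- c("ligand", "receptor", "agonist", "antagonist",
                  "co_stim", "co_inhib")

#' Read / write a ligand-receptor interaction table
#'
#' TSV with columns `interaction`, `pathway`, then comma-delimited gene lists
#' `ligand`, `receptor`, `agonist`, `antagonist`, `co_stim`, `co_inhib`.
#' Ligand and receptor subunit lists must be non-empty; the modulator lists
#' (soluble agonists/antagonists, co-stimulatory/co-inhibitory receptors)
#' may be empty.
#'
#' @param path file path.
#' @return A tibble with list-columns for the six gene lists.
#' @export
read_lr_db <- function(path) {
  tab <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                     na.strings = NULL))
  need <- c("interaction", "pathway", LR_LIST_COLS)
  if (!all(need %in% names(tab))) {
    abort(paste0("LR table needs columns: ", paste(need, collapse = ", ")))
  }
  for (col in LR_LIST_COLS) {
    tab[[col]] <- lapply(as.character(tab[[col]]), split_gene_list)
  }
  validate_lr_db(tab[need])
}

split_gene_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  str_trim(strsplit(x, ",", fixed = TRUE)[[1]])
}

validate_lr_db <- function(lrdb) {
  if (any(lengths(lrdb$ligand) == 0) || any(lengths(lrdb$receptor) == 0)) {
    abort("Every interaction needs at least one ligand and one receptor subunit.")
  }
  if (anyDuplicated(lrdb$interaction)) abort("Duplicate interaction ids.")
  lrdb
}

#' @rdname read_lr_db
#' @param lrdb ligand-receptor tibble to write.
#' @export
write_lr_db <- function(lrdb, path) {
  out <- lrdb
  for (col in LR_LIST_COLS) {
    out[[col]] <- vapply(lrdb[[col]], paste, character(1), collapse = ",")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- graph edge list -------------------------------------------------------

#' Read / write a protein-protein interaction edge list
#'
#' TSV with header `gene_a  gene_b` and an optional `weight` column.
#' Self-loops are dropped and duplicate (undirected) edges collapsed,
#' keeping the first weight seen.
#'
#' @param path file path.
#' @return A tibble `gene_a, gene_b, weight` in canonical (sorted-pair) order.
#' @export
read_edge_list <- function(path) {
  tab <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("gene_a", "gene_b") %in% names(tab))) {
    abort("Edge list needs columns gene_a and gene_b.")
  }
  if (!"weight" %in% names(tab)) tab$weight <- 1
  canonicalize_edges(tab)
}

canonicalize_edges <- function(edges) {
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges |>
    mutate(
      a = pmin(.data$gene_a, .data$gene_b),
      b = pmax(.data$gene_a, .data$gene_b)
    ) |>
    filter(.data$a != .data$b) |>
    distinct(.data$a, .data$b, .keep_all = TRUE) |>
    transmute(gene_a = .data$a, gene_b = .data$b, weight = .data$weight) |>
    arrange(.data$gene_a, .data$gene_b)
}

#' @rdname read_edge_list
#' @param edges edge tibble to write.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
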