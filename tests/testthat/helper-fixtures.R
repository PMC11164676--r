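# Shared fixtures, simulated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_study <- function() cached("tiny", emit_fixture("tiny"))

small_study <- function() cached("small", emit_fixture("small"))

# toy expression matrix: deterministic counts, two cell types, two ages
toy_matrix <- function(n_genes = 6, n_cells = 8) {
  set.seed(42)
  vals <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells,
                 dimnames = list(
                   paste0("g", seq_len(n_genes)),
                   paste0("c", seq_len(n_cells))
                 ))
  expr_matrix(vals)
}

toy_annotation <- function(m) {
  n <- length(cells(m))
  tibble::tibble(
    cell_id = cells(m),
    species = "human",
    cell_type = rep(c("FB", "SMC"), length.out = n),
    age_group = rep(c("young", "old"), each = ceiling(n / 2))[seq_len(n)]
  )
}
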