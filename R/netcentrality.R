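# Hub-gene identification on a protein-protein interaction graph by
# shortest-path betweenness centrality (unweighted, undirected; confidence
# weights in the edge list are accepted but ignored).

edges_to_graph <- function(edges) {
  edges <- canonicalize_edges(edges)
  igraph::graph_from_data_frame(edges[c("gene_a", "gene_b")],
                                directed = FALSE)
}

#' Betweenness centrality of every gene in a PPI graph
#'
#' Exact shortest-path betweenness with fractional credit across equal-length
#' paths, in the raw unordered-pair-count convention, alongside the
#' `2 / ((n - 1)(n - 2))` normalized value and the degree. Nodes are ranked
#' by betweenness, ties broken by degree and then gene id.
#'
#' @param edges an edge tibble (see [read_edge_list()]).
#' @return A tibble `gene, betweenness, betweenness_norm, degree, rank`.
#' @export
centrality_table <- function(edges) {
  if (nrow(edges) == 0) {
    return(tibble(gene = character(0), betweenness = numeric(0),
                  betweenness_norm = numeric(0), degree = integer(0),
                  rank = integer(0)))
  }
  g <- edges_to_graph(edges)
  bc <- igraph::betweenness(g, directed = FALSE, weights = NA)
  n <- igraph::vcount(g)
  norm_fac <- if (n > 2) 2 / ((n - 1) * (n - 2)) else 0
  out <- tibble(
    gene = igraph::V(g)$name,
    betweenness = unname(bc),
    betweenness_norm = unname(bc) * norm_fac,
    degree = unname(igraph::degree(g))
  ) |>
    arrange(desc(.data$betweenness), desc(.data$degree), .data$gene) |>
    mutate(rank = row_number())
  out
}

#' Top hub genes within a gene subset of a PPI graph
#'
#' Induces the subgraph on `gene_subset` (for example the cross-species SM
#' genes) and returns the `top_k` nodes by betweenness centrality.
#'
#' @param edges an edge tibble.
#' @param gene_subset genes to induce the subgraph on; edges with an
#'   endpoint outside the subset are dropped.
#' @param top_k how many hubs to return (default 20).
#' @return A [centrality_table()] tibble truncated to `top_k` rows (warns
#'   and returns all when the subgraph is smaller).
#' @export
hub_genes <- function(edges, gene_subset, top_k = 20) {
  if (length(gene_subset) == 0) {
    return(centrality_table(edges[0, ]))
  }
  sub <- edges |>
    filter(.data$gene_a %in% gene_subset, .data$gene_b %in% gene_subset)
  tab <- centrality_table(sub)
  if (top_k > nrow(tab)) {
    warn(sprintf("Requested top %d hubs but the subgraph has %d nodes.",
                 top_k, nrow(tab)))
    top_k <- nrow(tab)
  }
  head(tab, top_k)
}
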