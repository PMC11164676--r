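# Independent oracles, deliberately naive: each re-derives the quantity from
# first principles so agreement with the package is meaningful.

# Exact two-sided Wilcoxon p by enumerating every assignment of ranks to the
# first group (tie-free data only).
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  stopifnot(anyDuplicated(pooled) == 0)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  assignments <- combn(length(pooled), nx)
  u_all <- apply(assignments, 2, function(idx) {
    sum(seq_len(length(pooled))[idx]) - nx * (nx + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force GSEA running sum: literal position-by-position loop.
oracle_es <- function(stats, hit, exponent = 1) {
  n <- length(stats)
  nh <- sum(hit)
  w <- abs(stats)^exponent
  total <- sum(w[hit])
  if (total == 0) {
    w[hit] <- 1
    total <- nh
  }
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) w[i] / total else -1 / (n - nh)
    running[i] <- cur
  }
  hi <- max(running)
  lo <- min(running)
  if (abs(hi) >= abs(lo)) hi else lo  # positive extreme wins exact ties
}

# Brute-force betweenness: enumerate every simple path between every node
# pair with DFS, keep the shortest ones, and award fractional credit to
# interior nodes. Only sane for tiny graphs.
oracle_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- lapply(setNames(nodes, nodes), function(v) {
    sort(unique(c(edges$gene_b[edges$gene_a == v],
                  edges$gene_a[edges$gene_b == v])))
  })
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == to) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (w in setdiff(adj[[v]], path)) walk(c(path, w))
    }
    walk(from)
    out
  }
  bc <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      paths <- all_paths(nodes[i], nodes[j])
      if (length(paths) == 0) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        bc[interior] <- bc[interior] + 1 / length(shortest)
      }
    }
  }
  bc
}

random_edge_list <- function(n_nodes, p_edge = 0.45) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- combn(nodes, 2)
  keep <- runif(ncol(pairs)) < p_edge
  tibble::tibble(gene_a = pairs[1, keep], gene_b = pairs[2, keep])
}
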