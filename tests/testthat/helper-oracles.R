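# Independent brute-force oracles used to check the implementation.
# Each one is deliberately written from first principles (no shared code
# with the package internals).

# Spearman correlation: assign average ranks by hand, then Pearson
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# two-pass mean/SD compactness
oracle_compactness <- function(w) {
  m <- sum(w) / length(w)
  v <- sum((w - m)^2) / (length(w) - 1)
  if (v == 0) Inf else m / sqrt(v)
}

# AUC by exhaustive pairwise counting over all case-control pairs
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]; ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cs) * length(ct))
}

# all-pairs BFS mean shortest path over connected unordered pairs
oracle_cpl <- function(edges_df) {
  nodes <- sort(unique(c(edges_df$gene1, edges_df$gene2)))
  adj <- lapply(nodes, function(v) {
    c(edges_df$gene2[edges_df$gene1 == v], edges_df$gene1[edges_df$gene2 == v])
  })
  names(adj) <- nodes
  dsum <- 0; npairs <- 0
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          queue <- c(queue, u)
        }
      }
    }
    reach <- dist[names(dist) != s & is.finite(dist)]
    dsum <- dsum + sum(reach); npairs <- npairs + length(reach)
  }
  dsum / npairs  # each unordered pair counted twice in both terms
}

# mean local clustering by exhaustive neighbour-pair counting,
# degree < 2 nodes contributing 0
oracle_clustering <- function(edges_df) {
  nodes <- sort(unique(c(edges_df$gene1, edges_df$gene2)))
  key <- paste(pmin(edges_df$gene1, edges_df$gene2),
               pmax(edges_df$gene1, edges_df$gene2))
  local <- vapply(nodes, function(v) {
    nb <- unique(c(edges_df$gene2[edges_df$gene1 == v],
                   edges_df$gene1[edges_df$gene2 == v]))
    if (length(nb) < 2) return(0)
    closed <- 0; total <- 0
    for (i in seq_along(nb)) for (j in seq_along(nb)) {
      if (i < j) {
        total <- total + 1
        if (paste(min(nb[i], nb[j]), max(nb[i], nb[j])) %in% key) {
          closed <- closed + 1
        }
      }
    }
    closed / total
  }, numeric(1))
  mean(local)
}

# step-up BH by hand
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# quick toy network from an edge triple list
toy_network <- function(...) {
  rows <- list(...)
  df <- data.frame(gene1 = vapply(rows, function(r) min(r[[1]], r[[2]]), ""),
                   gene2 = vapply(rows, function(r) max(r[[1]], r[[2]]), ""),
                   rho = vapply(rows, function(r) as.numeric(r[[3]]), 0),
                   stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("gene1\tgene2\trho",
               sprintf("%s\t%s\t%.10g", df$gene1, df$gene2, df$rho)), tf)
  on.exit(unlink(tf))
  read_edge_list(tf)
}

# random expression matrix fixture
random_expr <- function(n_genes, n_samples, seed, labels = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, labels = labels)
}
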