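#' Spearman rank correlation of two vectors
#'
#' Rank correlation with average (fractional) ranks for ties, i.e. the
#' Pearson correlation of the two rank vectors.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  abort_if(length(x) != length(y), "'x' and 'y' must have equal length")
  abort_if(length(x) < 3L, "need at least 3 observations")
  abort_if(!all(is.finite(x)) || !all(is.finite(y)), "inputs must be finite")
  abort_if(stats::sd(x) == 0 || stats::sd(y) == 0,
           "rank correlation is undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

new_coexpression_network <- function(edges, rho_min, nodes = NULL) {
  # edges: data.frame(gene1, gene2, rho), gene1 < gene2 lexicographically
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes %||% sort(unique(c(edges$gene1, edges$gene2)))
  structure(list(edges = edges, nodes = nodes, rho_min = rho_min),
            class = "coexpression_network")
}

#' Build a weighted co-expression network
#'
#' Computes Spearman correlations among all gene pairs of a (filtered)
#' expression matrix and keeps as edges exactly the pairs whose correlation
#' meets the threshold. The threshold is signed by default (`rho >= rho_min`;
#' negative correlations never become edges); set `absolute = TRUE` to
#' threshold `|rho|` instead. Genes left without any qualifying edge are not
#' network members.
#'
#' @param x An [expression_matrix()] with >= 2 genes, none constant.
#' @param rho_min Inclusive correlation threshold, default 0.1.
#' @param absolute Threshold `|rho|` rather than signed `rho`. Default
#'   `FALSE`.
#' @return A `coexpression_network`: list with `edges`
#'   (data.frame `gene1`, `gene2`, `rho`; pairs in lexicographic order),
#'   `nodes`, and `rho_min`. The edge set may be empty.
#' @export
build_network <- function(x, rho_min = 0.1, absolute = FALSE) {
  stopifnot(inherits(x, "expression_matrix"))
  abort_if(nrow(x$values) < 2L, "need at least 2 genes")
  abort_if(any(row_sds(x$values) == 0),
           "constant genes present; apply filter_flat_genes() first")
  rho <- stats::cor(t(x$values), method = "spearman")
  crit <- if (absolute) abs(rho) >= rho_min else rho >= rho_min
  idx <- which(upper.tri(rho) & crit, arr.ind = TRUE)
  genes <- rownames(x$values)
  g1 <- genes[idx[, 1L]]
  g2 <- genes[idx[, 2L]]
  swap <- g1 > g2
  edges <- data.frame(gene1 = ifelse(swap, g2, g1),
                      gene2 = ifelse(swap, g1, g2),
                      rho = rho[idx],
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    warning("no gene pair meets the correlation threshold; empty network")
  }
  new_coexpression_network(edges, rho_min)
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges (rho >= %g)\n",
              length(x$nodes), nrow(x$edges), x$rho_min))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Characteristic path length
#'
#' Mean unweighted shortest-path length over all unordered node pairs. For a
#' disconnected network the mean is taken over connected pairs only, with a
#' warning.
#'
#' @param net A `coexpression_network` with >= 2 nodes.
#' @return Mean geodesic distance.
#' @export
characteristic_path_length <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  abort_if(length(net$nodes) < 2L, "need at least 2 nodes")
  g <- as_igraph(net)
  if (!igraph::is_connected(g)) {
    warning("network is disconnected; averaging over connected pairs only")
  }
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Average clustering coefficient
#'
#' Unweighted Watts-Strogatz mean of local clustering coefficients. By
#' default nodes with degree < 2 contribute 0 to the mean; with
#' `exclude_low_degree = TRUE` they are excluded from it instead.
#'
#' @param net A `coexpression_network` with >= 1 node.
#' @param exclude_low_degree Drop degree < 2 nodes from the average rather
#'   than counting them as 0. Default `FALSE`.
#' @return Mean local clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, exclude_low_degree = FALSE) {
  stopifnot(inherits(net, "coexpression_network"))
  abort_if(length(net$nodes) < 1L, "need at least 1 node")
  g <- as_igraph(net)
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  if (exclude_low_degree) {
    local <- local[igraph::degree(g) >= 2]
    if (length(local) == 0L) return(0)
  }
  mean(local)
}

#' Write a network as a three-column edge list
#'
#' Tab-separated file with header `gene1 gene2 rho`; genes within a pair in
#' lexicographic order, rows sorted by (gene1, gene2), weights printed with
#' enough digits to round-trip through [read_edge_list()].
#'
#' @param net A `coexpression_network`.
#' @param path Output file path.
#' @param header_lines Optional character vector of `#`-prefixed provenance
#'   lines written before the column header.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, header_lines = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  writeLines("gene1\tgene2\trho", con)
  if (nrow(net$edges) > 0L) {
    writeLines(sprintf("%s\t%s\t%.10g", net$edges$gene1, net$edges$gene2,
                       net$edges$rho), con)
  }
  invisible(path)
}

#' Read a three-column edge list written by [write_edge_list()]
#'
#' @param path Input file path.
#' @param rho_min Construction threshold to record on the network object;
#'   defaults to the smallest weight present (or `NA` for an empty file).
#' @return A `coexpression_network`.
#' @export
read_edge_list <- function(path, rho_min = NULL) {
  abort_if(!file.exists(path), "file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  abort_if(!all(c("gene1", "gene2", "rho") %in% colnames(tab)),
           "expected columns gene1, gene2, rho")
  rho_min <- rho_min %||% (if (nrow(tab)) min(tab$rho) else NA_real_)
  new_coexpression_network(
    data.frame(gene1 = as.character(tab$gene1),
               gene2 = as.character(tab$gene2),
               rho = as.numeric(tab$rho), stringsAsFactors = FALSE),
    rho_min)
}
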