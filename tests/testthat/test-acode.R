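test_that("compactness is mean over sample SD with an infinity sentinel", {
  expect_equal(community_compactness(c(0.8, 0.9, 1.0)), 9)
  expect_identical(community_compactness(c(0.7, 0.7, 0.7)), Inf)
  set.seed(2)
  w <- runif(10)
  expect_equal(community_compactness(w), oracle_compactness(w),
               tolerance = 1e-12)
  expect_error(community_compactness(0.5), "at least 2")
})

test_that("compactness is scale-invariant and monotone under mean-value additions", {
  set.seed(8)
  for (i in 1:10) {
    w <- runif(6, 0.2, 0.9)
    expect_equal(community_compactness(3.7 * w), community_compactness(w),
                 tolerance = 1e-9)
    # appending a weight equal to the current mean never decreases it
    expect_gte(community_compactness(c(w, mean(w))) + 1e-12,
               community_compactness(w))
  }
})

test_that("neighborhood edges are exactly the incident outside edges", {
  tri <- toy_network(list("a", "b", 0.9), list("b", "c", 0.5),
                     list("a", "c", 0.4))
  nb <- neighborhood_edges(tri, c("a", "b"))
  expect_setequal(paste(nb$gene1, nb$gene2), c("a c", "b c"))
  # a community covering all edges has an empty neighborhood
  com <- structure(list(genes = c("a", "b", "c"), edges = tri$edges),
                   class = "acode_community")
  expect_equal(nrow(neighborhood_edges(tri, com)), 0L)
})

test_that("neighborhood edges agree with a brute-force scan", {
  net <- generate_null_network(12, 30, rng_seed = 6)
  genes <- net$nodes[1:4]
  nb <- neighborhood_edges(net, genes)
  e <- net$edges
  manual <- e[(e$gene1 %in% genes) | (e$gene2 %in% genes), ]
  expect_equal(paste(nb$gene1, nb$gene2),
               paste(manual$gene1, manual$gene2))
})

test_that("greedy growth follows descending weights with lexicographic ties", {
  # hand-built 7-edge network: seed a-b, neighbour weights strictly
  # decreasing so the admissible growth order is unique
  net <- toy_network(list("a", "b", 0.95),
                     list("b", "c", 0.90), list("a", "d", 0.85),
                     list("c", "d", 0.80), list("d", "e", 0.75),
                     list("c", "e", 0.70), list("e", "f", 0.65))
  com <- grow_community(net, c("a", "b"),
                        acode_params(min_q = 0.99, min_edges = 2,
                                     max_edges = 7, n_perm = 200,
                                     rng_seed = 1))
  expect_false(is.null(com))
  got <- paste(com$edges$gene1, com$edges$gene2)
  expect_equal(got[1:5], c("a b", "b c", "a d", "c d", "d e"))
  expect_equal(com$edges$rho, sort(com$edges$rho, decreasing = TRUE))

  # identical weights: the lexicographically smaller pair enters first
  net2 <- toy_network(list("a", "b", 0.9),
                      list("b", "z", 0.5), list("a", "c", 0.5),
                      list("c", "z", 0.4))
  com2 <- grow_community(net2, c("a", "b"),
                         acode_params(min_q = 0.99, min_edges = 2,
                                      max_edges = 4, n_perm = 200))
  expect_equal(paste(com2$edges$gene1, com2$edges$gene2)[2], "a c")
})

test_that("growth fails when the component cannot reach min_edges", {
  net <- toy_network(list("a", "b", 0.9), list("b", "c", 0.8),
                     list("a", "c", 0.7), list("x", "y", 0.6))
  com <- grow_community(net, c("a", "b"),
                        acode_params(min_edges = 5, max_edges = 20,
                                     n_perm = 10000))
  expect_null(com)
  expect_error(grow_community(net, c("a", "z"), acode_params(n_perm = 1e4)),
               "not an edge")
})

test_that("subset permutation null is deterministic and respects degenerate weights", {
  net <- generate_null_network(8, 12, rng_seed = 3)
  n1 <- permutation_null(net, k = 4, n_perm = 500, rng_seed = 11)
  n2 <- permutation_null(net, k = 4, n_perm = 500, rng_seed = 11)
  expect_identical(n1$values, n2$values)
  n3 <- permutation_null(net, k = 4, n_perm = 500, rng_seed = 12)
  expect_false(identical(n1$values, n3$values))
  # all-equal weights: every null draw hits the zero-SD sentinel
  flat <- toy_network(list("a", "b", 0.7), list("b", "c", 0.7),
                      list("c", "d", 0.7), list("a", "d", 0.7))
  nf <- permutation_null(flat, k = 3, n_perm = 50, rng_seed = 1)
  expect_true(all(is.infinite(nf$values)))
})

test_that("q-values count exceedances by linear scan semantics", {
  net <- generate_null_network(8, 12, rng_seed = 3)
  null <- permutation_null(net, k = 3, n_perm = 999, rng_seed = 5)
  expect_equal(q_value(null, max(null$values) + 1)$q, 0)
  expect_equal(q_value(null, min(null$values))$q, 1)
  obs <- stats::median(null$values)  # odd n_perm: an attained value
  qv <- q_value(null, obs)
  expect_equal(qv$exceedance_count, sum(null$values >= obs))
  expect_equal(qv$q, sum(null$values >= obs) / 999)
})

test_that("q is non-increasing in the observed compactness", {
  net <- generate_null_network(10, 25, rng_seed = 9)
  null <- permutation_null(net, k = 5, n_perm = 2000, rng_seed = 2)
  obs <- seq(0, 30, length.out = 40)
  qs <- vapply(obs, function(o) q_value(null, o)$q, numeric(1))
  expect_true(all(diff(qs) <= 0))
  expect_equal(q_value(null, Inf)$q, mean(is.infinite(null$values)))
})

test_that("detect_communities evaluates one trajectory per edge and can return none", {
  net <- toy_network(list("a", "b", 0.9), list("b", "c", 0.8),
                     list("a", "c", 0.7))
  res <- detect_communities(net, acode_params(min_edges = 5, max_edges = 20,
                                              n_perm = 10000))
  expect_length(res$communities, 0L)
  expect_equal(res$n_seeds, 3L)
  expect_equal(nrow(res$summary), 0L)
})

test_that("detected communities satisfy their structural invariants", {
  net <- generate_null_network(15, 40, rng_seed = 17)
  params <- acode_params(min_q = 0.05, min_edges = 3, max_edges = 6,
                         n_perm = 500, rng_seed = 1)
  res <- detect_communities(net, params)
  expect_gt(length(res$communities), 0L)
  for (com in res$communities) {
    k <- nrow(com$edges)
    expect_true(k >= 3 && k <= 6)
    # compactness recomputable from stored weights
    expect_equal(com$compactness, oracle_compactness(com$edges$rho),
                 tolerance = 1e-9)
    # q from stored exceedance count
    expect_equal(com$q, com$exceedance_count / params$n_perm)
    expect_lte(com$q, params$min_q)
    # edges form a connected subgraph containing the seed
    sub <- igraph::graph_from_data_frame(com$edges[, 1:2], directed = FALSE)
    expect_true(igraph::is_connected(sub))
    expect_true(paste(com$seed_edge, collapse = " ") %in%
                  paste(com$edges$gene1, com$edges$gene2))
  }
  # ranking: q ascending, compactness descending within q ties
  s <- res$summary
  expect_true(all(diff(s$q) >= 0))
  for (qq in unique(s$q)) {
    block <- s$compactness[s$q == qq]
    expect_true(all(diff(block) <= 0))
  }
})

test_that("community detection is invariant to node relabeling", {
  net <- generate_null_network(12, 26, rng_seed = 23)
  params <- acode_params(min_q = 0.05, min_edges = 3, max_edges = 5,
                         n_perm = 400, rng_seed = 3)
  res1 <- detect_communities(net, params)
  # relabel nodes in a way that preserves lexicographic order, so even
  # tie-breaking is unaffected
  relabel <- function(g) sub("^N", "Q", g)
  net2 <- net
  net2$edges$gene1 <- relabel(net2$edges$gene1)
  net2$edges$gene2 <- relabel(net2$edges$gene2)
  net2$nodes <- relabel(net2$nodes)
  res2 <- detect_communities(net2, params)
  expect_equal(length(res1$communities), length(res2$communities))
  expect_equal(lapply(res2$communities, function(c) c$genes),
               lapply(res1$communities, function(c) relabel(c$genes)))
})

test_that("growth-replay null is deterministic and calibrated on its own terms", {
  net <- generate_null_network(12, 30, rng_seed = 31)
  g1 <- permutation_null(net, k = 4, n_perm = 300, rng_seed = 7,
                         scheme = "growth")
  g2 <- permutation_null(net, k = 4, n_perm = 300, rng_seed = 7,
                         scheme = "growth")
  expect_identical(g1$values, g2$values)
  expect_equal(g1$scheme, "growth")
  # growth nulls dominate subset nulls in location: the greedy replay
  # picks large weights, so its typical compactness is higher
  s <- permutation_null(net, k = 4, n_perm = 300, rng_seed = 7)
  expect_gt(stats::median(g1$values, na.rm = TRUE),
            stats::median(s$values))
})

test_that("community reports are written with q-text annotation and sidecar", {
  net <- generate_null_network(15, 40, rng_seed = 17)
  res <- detect_communities(net, acode_params(min_q = 0.05, min_edges = 3,
                                              max_edges = 6, n_perm = 500,
                                              rng_seed = 1))
  tf <- tempfile(fileext = ".tsv")
  write_communities(res, tf)
  tab <- utils::read.delim(tf, comment.char = "#")
  expect_equal(nrow(tab), length(res$communities))
  expect_true(all(c("rank", "q", "compactness", "genes", "q_text") %in%
                    colnames(tab)))
  expect_true(file.exists(paste0(tf, ".edges.txt")))
  zeroq <- tab$exceedance_count == 0
  if (any(zeroq)) expect_true(all(grepl("^<", tab$q_text[zeroq])))
})

test_that("seed-closure merging consolidates a planted module without absorbing run-ins", {
  cfg <- synthetic_config(n_background_genes = 60, rng_seed = 5)
  ds <- generate_dataset(cfg)
  net <- build_network(filter_flat_genes(ds$expression))
  res <- detect_communities(net, acode_params(n_perm = 2000, min_q = 5e-4,
                                              rng_seed = 2))
  mods <- merge_communities(res)
  expect_gt(nrow(mods), 0L)
  truth <- ds$ground_truth$modules[[1]]
  top_genes <- strsplit(mods$genes[1], ";")[[1]]
  # the top module is pure: every gene it claims is a planted module gene
  expect_true(all(top_genes %in% truth))
  expect_gte(length(top_genes) / length(truth), 0.8)
})

test_that("parameter validation enforces the q-resolution constraint", {
  expect_error(acode_params(min_q = 1e-4, n_perm = 100), "resolvable")
  expect_error(acode_params(min_q = 0), "min_q")
  expect_error(acode_params(min_edges = 1), "min_edges")
  p <- acode_params()
  expect_equal(p$min_q, 1e-4)
  expect_equal(p$min_edges, 5L)
  expect_equal(p$max_edges, 20L)
  expect_equal(p$n_perm, 10000L)
})
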