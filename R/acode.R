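#' Parameters for A-CODE community detection
#'
#' Defaults are the reference operating point of the method: communities of
#' 5 to 20 edges, a q cutoff of 1e-4 resolved by 10000 permutations (so a
#' community is kept only when at most one permutation reaches its
#' compactness).
#'
#' @param min_q Acceptance cutoff on the permutation q-value, in (0, 1).
#' @param min_edges,max_edges Community size bounds in edges,
#'   `2 <= min_edges <= max_edges`.
#' @param n_perm Number of permutations per community size; must be at
#'   least `1/min_q` so the cutoff is resolvable.
#' @param rng_seed Integer seed governing all permutation draws; per-size
#'   substreams are derived deterministically from it.
#' @param null_scheme `"subset"` (default): null compactness values are
#'   computed from k edge weights sampled without replacement from the
#'   network's edge-weight multiset. `"growth"`: each permutation replays
#'   the greedy growth itself from a random seed edge on a weight-permuted
#'   network and records its compactness at every size; this null is
#'   calibrated against the greedy selection but has far lower detection
#'   power (see the package vignette).
#' @return An `acode_params` list.
#' @export
acode_params <- function(min_q = 1e-4, min_edges = 5L, max_edges = 20L,
                         n_perm = 10000L, rng_seed = 1L,
                         null_scheme = c("subset", "growth")) {
  null_scheme <- match.arg(null_scheme)
  abort_if(min_q <= 0 || min_q >= 1, "'min_q' must be in (0, 1)")
  abort_if(min_edges < 2L || max_edges < min_edges,
           "need 2 <= min_edges <= max_edges")
  abort_if(n_perm < 1 / min_q,
           "'n_perm' must be >= 1/min_q so that min_q is resolvable")
  structure(list(min_q = min_q, min_edges = as.integer(min_edges),
                 max_edges = as.integer(max_edges),
                 n_perm = as.integer(n_perm),
                 rng_seed = as.integer(rng_seed),
                 null_scheme = null_scheme),
            class = "acode_params")
}

#' Co-expression compactness of a community
#'
#' Mean of the community's edge weights divided by their sample standard
#' deviation. Dividing by the spread penalizes communities whose strength
#' rests on a few highly variable co-expression values. A community with
#' identical weights has zero spread and is assigned `+Inf`, which orders
#' above every finite compactness.
#'
#' @param weights Numeric vector of >= 2 edge weights.
#' @return Compactness (possibly `Inf`).
#' @examples
#' community_compactness(c(0.8, 0.9, 1.0))  # 9
#' @export
community_compactness <- function(weights) {
  abort_if(length(weights) < 2L, "need at least 2 weights")
  abort_if(!all(is.finite(weights)), "weights must be finite")
  m <- mean(weights)
  s <- stats::sd(weights)
  # relative guard: spreads at floating-point cancellation level count as 0
  if (s <= abs(m) * 1e-12) Inf else m / s
}

# ---- internal indexed representation ---------------------------------------

# integer-indexed view of a network for the growth loops; edge indices are
# in lexicographic (gene1, gene2) order, which backs all tie-breaking
net_index <- function(net) {
  genes <- net$nodes
  e1 <- match(net$edges$gene1, genes)
  e2 <- match(net$edges$gene2, genes)
  m <- length(e1)
  inc <- vector("list", length(genes))
  inc_idx <- split(rep(seq_len(m), 2L), c(e1, e2))
  inc[as.integer(names(inc_idx))] <- inc_idx
  list(genes = genes, e1 = e1, e2 = e2, w = net$edges$rho, m = m, inc = inc)
}

# greedy trajectory from a seed edge: at each step add the neighbourhood
# edge of maximal weight (ties: smallest edge index = lexicographically
# smallest gene pair). Returns edge indices in growth order and the running
# compactness at each size (NA at size 1).
grow_trajectory <- function(idx, seed_edge, max_edges, w = idx$w) {
  edges_in <- integer(max_edges)
  edges_in[1L] <- seed_edge
  in_comm <- rep(FALSE, idx$m)
  in_comm[seed_edge] <- TRUE
  gene_in <- rep(FALSE, length(idx$genes))
  g <- c(idx$e1[seed_edge], idx$e2[seed_edge])
  gene_in[g] <- TRUE
  cand <- setdiff(c(idx$inc[[g[1L]]], idx$inc[[g[2L]]]), seed_edge)
  s1 <- w[seed_edge]
  s2 <- w[seed_edge]^2
  cmp <- rep(NA_real_, max_edges)
  k <- 1L
  while (k < max_edges && length(cand) > 0L) {
    wc <- w[cand]
    mx <- max(wc)
    best <- min(cand[wc == mx])
    k <- k + 1L
    edges_in[k] <- best
    in_comm[best] <- TRUE
    s1 <- s1 + w[best]
    s2 <- s2 + w[best]^2
    # v is the sample variance; cancellation noise (relative to the mean
    # square) is treated as an exactly-zero spread
    v <- (s2 - s1^2 / k) / (k - 1L)
    cmp[k] <- if (v <= s2 / k * 1e-13) Inf else (s1 / k) / sqrt(v)
    for (gnew in c(idx$e1[best], idx$e2[best])) {
      if (!gene_in[gnew]) {
        gene_in[gnew] <- TRUE
        cand <- c(cand, idx$inc[[gnew]])
      }
    }
    cand <- cand[!in_comm[cand]]
  }
  list(edges = edges_in[seq_len(k)], compactness = cmp[seq_len(k)])
}

# ---- permutation nulls ------------------------------------------------------

#' Permutation null distribution of compactness
#'
#' Draws `n_perm` null compactness values for communities of `k` edges.
#' Under the default `"subset"` scheme each draw is the compactness of `k`
#' edge weights sampled uniformly without replacement from the network's
#' full edge-weight multiset. Under `"growth"` each draw replays the greedy
#' growth from a uniformly chosen seed edge on a network whose weights have
#' been randomly permuted over the topology, recording the compactness at
#' size `k` (`NA` when the component is exhausted before reaching `k`).
#'
#' @param net A `coexpression_network` with at least `k` edges.
#' @param k Community size in edges, >= 2.
#' @param n_perm Number of draws.
#' @param rng_seed Integer seed; draws are reproducible from
#'   (network, k, scheme, seed).
#' @param scheme `"subset"` or `"growth"`.
#' @return A `permutation_null` object with elements `values`, `k`,
#'   `n_perm`, `rng_seed`, `scheme`.
#' @export
permutation_null <- function(net, k, n_perm = 10000L, rng_seed = 1L,
                             scheme = c("subset", "growth")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(net, "coexpression_network"))
  k <- as.integer(k)
  abort_if(k < 2L, "'k' must be >= 2")
  abort_if(k > nrow(net$edges), "'k' exceeds the network's edge count")
  params <- acode_params(min_edges = k, max_edges = k, n_perm = n_perm,
                         rng_seed = rng_seed, null_scheme = scheme,
                         min_q = max(1 / n_perm, 1e-12))
  bank <- null_bank(net_index(net), params)
  structure(list(values = bank$values[[as.character(k)]], k = k,
                 n_perm = as.integer(n_perm),
                 rng_seed = as.integer(rng_seed), scheme = scheme),
            class = "permutation_null")
}

# build null compactness banks for every size in [min_edges, max_edges];
# values are per-k vectors of length n_perm, sorted copies cached for the
# fast exceedance lookup used by detect_communities()
null_bank <- function(idx, params) {
  ks <- params$min_edges:params$max_edges
  w <- idx$w
  m <- idx$m
  values <- vector("list", length(ks))
  names(values) <- as.character(ks)
  if (params$null_scheme == "subset") {
    for (k in ks) {
      # per-size substream: seed + k (deterministic, shared across seeds)
      values[[as.character(k)]] <- with_seed(params$rng_seed + k, {
        draws <- vapply(seq_len(params$n_perm),
                        function(i) sample.int(m, k), integer(k))
        s1 <- colSums(matrix(w[draws], nrow = k))
        s2 <- colSums(matrix(w[draws]^2, nrow = k))
        v <- (s2 - s1^2 / k) / (k - 1L)
        ifelse(v <= s2 / k * 1e-13, Inf, (s1 / k) / sqrt(pmax(v, 1e-300)))
      })
    }
  } else {
    kmax <- params$max_edges
    traj <- with_seed(params$rng_seed, {
      seeds <- sample.int(m, params$n_perm, replace = TRUE)
      lapply(seq_len(params$n_perm), function(i) {
        grow_trajectory(idx, seeds[i], kmax, w = sample(w))$compactness
      })
    })
    for (k in ks) {
      values[[as.character(k)]] <-
        vapply(traj, function(tr) if (length(tr) >= k) tr[k] else NA_real_,
               numeric(1))
    }
  }
  sorted <- lapply(values, function(v) sort(v[!is.na(v)]))
  list(values = values, sorted = sorted, n_perm = params$n_perm)
}

# exceedances of `observed` in a sorted null vector (ties count as
# exceedances); NA draws never exceed
count_exceed <- function(sorted_vals, observed) {
  length(sorted_vals) - findInterval(observed, sorted_vals, left.open = TRUE)
}

#' Empirical q-value of an observed compactness
#'
#' `q = #{null values >= observed} / n_perm`, the empirical exceedance rate
#' of the observed compactness under the permutation null. A q of 0 means
#' no permutation reached the observed value and is reported as
#' `< 1/n_perm` in text output.
#'
#' @param null A [permutation_null()].
#' @param observed Observed compactness (may be `Inf`).
#' @return List with `q` and `exceedance_count`.
#' @export
q_value <- function(null, observed) {
  stopifnot(inherits(null, "permutation_null"))
  exceed <- sum(null$values >= observed, na.rm = TRUE)
  list(q = exceed / null$n_perm, exceedance_count = as.integer(exceed))
}

# ---- community growth -------------------------------------------------------

new_community <- function(idx, edge_ids, seed_edge, compactness, q, exceed,
                          params) {
  genes <- sort(unique(idx$genes[c(idx$e1[edge_ids], idx$e2[edge_ids])]))
  edges <- data.frame(gene1 = pmin(idx$genes[idx$e1[edge_ids]],
                                   idx$genes[idx$e2[edge_ids]]),
                      gene2 = pmax(idx$genes[idx$e1[edge_ids]],
                                   idx$genes[idx$e2[edge_ids]]),
                      rho = idx$w[edge_ids],
                      stringsAsFactors = FALSE)
  structure(list(seed_edge = c(edges$gene1[1L], edges$gene2[1L]),
                 edges = edges, genes = genes,
                 compactness = compactness, q = q,
                 exceedance_count = as.integer(exceed),
                 params = params),
            class = "acode_community")
}

#' @export
print.acode_community <- function(x, ...) {
  qtxt <- if (x$exceedance_count == 0L)
    sprintf("< %g", 1 / x$params$n_perm) else format(x$q)
  cat(sprintf("acode_community: %d edges, %d genes | compactness %.4g | q %s\n",
              nrow(x$edges), length(x$genes), x$compactness, qtxt))
  cat("seed:", paste(x$seed_edge, collapse = " -- "), "\n")
  invisible(x)
}

#' Neighborhood edges of a community
#'
#' All network edges outside the community that touch at least one of its
#' genes — the candidate pool the greedy growth selects from.
#'
#' @param net A `coexpression_network`.
#' @param community An `acode_community`, or a character vector of gene IDs.
#'   A two-gene vector that is a network edge is treated as the seed
#'   community containing just that edge.
#' @return Edge data.frame (`gene1`, `gene2`, `rho`) in lexicographic order.
#' @export
neighborhood_edges <- function(net, community) {
  stopifnot(inherits(net, "coexpression_network"))
  if (inherits(community, "acode_community")) {
    genes <- community$genes
    key_in <- paste(community$edges$gene1, community$edges$gene2)
  } else {
    genes <- as.character(community)
    key_in <- character(0)
    if (length(genes) == 2L) {
      g <- sort(genes)
      if (any(net$edges$gene1 == g[1L] & net$edges$gene2 == g[2L])) {
        key_in <- paste(g[1L], g[2L])
      }
    }
  }
  e <- net$edges
  touch <- (e$gene1 %in% genes) | (e$gene2 %in% genes)
  out <- e[touch & !(paste(e$gene1, e$gene2) %in% key_in), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# core growth + acceptance rule, shared by grow_community/detect_communities.
# Returns NULL or list(edge_ids, compactness, q, exceed).
grow_accept <- function(idx, seed_edge, bank, params) {
  tr <- grow_trajectory(idx, seed_edge, params$max_edges)
  len <- length(tr$edges)
  if (len < params$min_edges) return(NULL)
  ks <- params$min_edges:len
  qs <- vapply(ks, function(k) {
    count_exceed(bank$sorted[[as.character(k)]], tr$compactness[k]) /
      bank$n_perm
  }, numeric(1))
  ok <- qs <= params$min_q
  if (!any(ok)) return(NULL)
  first <- which(ok)[1L]
  # extend greedily from the first accepted size while q stays at or below
  # min_q; growth stops just before the first size where q would exceed it
  run_end <- first
  while (run_end < length(ks) && ok[run_end + 1L]) run_end <- run_end + 1L
  k_final <- ks[run_end]
  exceed <- count_exceed(bank$sorted[[as.character(k_final)]],
                         tr$compactness[k_final])
  list(edge_ids = tr$edges[seq_len(k_final)],
       compactness = community_compactness(idx$w[tr$edges[seq_len(k_final)]]),
       q = qs[run_end], exceed = exceed)
}

#' Grow a candidate community from a seed edge
#'
#' Starting from the seed edge, repeatedly adds the neighborhood edge with
#' the highest co-expression value (ties broken towards the
#' lexicographically smallest gene pair). The permutation q-value is
#' evaluated at every size from `min_edges` up; the returned community is
#' the greedy prefix at the first accepted size, extended while q remains
#' at or below `min_q` and the size cap is not exceeded. Returns `NULL`
#' when no size in range reaches `min_q` or the component is exhausted
#' before `min_edges`.
#'
#' @param net A `coexpression_network`.
#' @param seed Character vector of the two seed genes (must be a network
#'   edge).
#' @param params An [acode_params()].
#' @param null_bank Optional pre-computed null bank (internal; built from
#'   `params` when missing).
#' @return An `acode_community` or `NULL`.
#' @export
grow_community <- function(net, seed, params = acode_params(),
                           null_bank = NULL) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(params, "acode_params"))
  abort_if(length(seed) != 2L, "'seed' must be two gene IDs")
  seed <- sort(as.character(seed))
  idx <- net_index(net)
  eid <- which(net$edges$gene1 == seed[1L] & net$edges$gene2 == seed[2L])
  abort_if(length(eid) != 1L, "seed is not an edge of the network: ",
           paste(seed, collapse = " -- "))
  if (nrow(net$edges) < params$min_edges) return(NULL)
  bank <- null_bank %||% null_bank_for(net, idx, params)
  res <- grow_accept(idx, eid, bank, params)
  if (is.null(res)) return(NULL)
  new_community(idx, res$edge_ids, eid, res$compactness, res$q, res$exceed,
                params)
}

null_bank_for <- function(net, idx, params) {
  abort_if(nrow(net$edges) < params$min_edges,
           "network has fewer edges than 'min_edges'")
  params2 <- params
  params2$max_edges <- min(params$max_edges, nrow(net$edges))
  null_bank(idx, params2)
}

#' Detect communities around every network edge
#'
#' Runs the A-CODE search: every edge seeds one greedy candidate community
#' ([grow_community()]); accepted candidates (permutation q at or below
#' `min_q`) with identical edge sets are merged into a single community
#' whose seed list records all originating edges. Null compactness
#' distributions are computed once per community size and shared across
#' seeds. Communities are ranked by q ascending, then compactness
#' descending, then lexicographically smallest gene set.
#'
#' @param net A non-empty `coexpression_network`.
#' @param params An [acode_params()].
#' @return An `acode_communities` object: list with `communities` (list of
#'   `acode_community`, ranked), `summary` (one row per community: `rank`,
#'   `q`, `exceedance_count`, `compactness`, `n_edges`, `n_genes`,
#'   `seed_edges`, `genes`), `params`, and `n_seeds` (candidate
#'   trajectories evaluated, one per edge). An empty community list is a
#'   valid result.
#' @export
detect_communities <- function(net, params = acode_params()) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(params, "acode_params"))
  m <- nrow(net$edges)
  abort_if(m == 0L, "empty network")
  idx <- net_index(net)
  empty <- structure(list(communities = list(),
                          summary = community_summary(list()),
                          params = params, n_seeds = m),
                     class = "acode_communities")
  if (m < params$min_edges) return(empty)
  bank <- null_bank_for(net, idx, params)
  hits <- vector("list", m)
  keys <- character(m)
  for (s in seq_len(m)) {
    res <- grow_accept(idx, s, bank, params)
    if (!is.null(res)) {
      hits[[s]] <- res
      keys[s] <- paste(sort(res$edge_ids), collapse = ",")
    }
  }
  found <- which(nzchar(keys))
  if (length(found) == 0L) return(empty)
  # deduplicate identical edge sets, retaining every originating seed
  groups <- split(found, keys[found])
  comms <- lapply(groups, function(seeds) {
    res <- hits[[seeds[1L]]]
    com <- new_community(idx, res$edge_ids, seeds[1L], res$compactness,
                         res$q, res$exceed, params)
    com$seed_edges <- data.frame(
      gene1 = pmin(idx$genes[idx$e1[seeds]], idx$genes[idx$e2[seeds]]),
      gene2 = pmax(idx$genes[idx$e1[seeds]], idx$genes[idx$e2[seeds]]),
      stringsAsFactors = FALSE)
    com
  })
  ord <- order(vapply(comms, `[[`, numeric(1), "q"),
               -vapply(comms, function(c) min(c$compactness, .Machine$double.xmax),
                       numeric(1)),
               vapply(comms, function(c) paste(c$genes, collapse = ";"),
                      character(1)))
  comms <- comms[ord]
  names(comms) <- NULL
  structure(list(communities = comms, summary = community_summary(comms),
                 params = params, n_seeds = m),
            class = "acode_communities")
}

community_summary <- function(comms) {
  if (length(comms) == 0L) {
    return(data.frame(rank = integer(0), q = numeric(0),
                      exceedance_count = integer(0), compactness = numeric(0),
                      n_edges = integer(0), n_genes = integer(0),
                      seed_edges = character(0), genes = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    rank = seq_along(comms),
    q = vapply(comms, `[[`, numeric(1), "q"),
    exceedance_count = vapply(comms, `[[`, integer(1), "exceedance_count"),
    compactness = vapply(comms, `[[`, numeric(1), "compactness"),
    n_edges = vapply(comms, function(c) nrow(c$edges), integer(1)),
    n_genes = vapply(comms, function(c) length(c$genes), integer(1)),
    seed_edges = vapply(comms, function(c) {
      se <- c$seed_edges %||%
        data.frame(gene1 = c$seed_edge[1L], gene2 = c$seed_edge[2L])
      paste(paste0(se$gene1, "--", se$gene2), collapse = ";")
    }, character(1)),
    genes = vapply(comms, function(c) paste(c$genes, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.acode_communities <- function(x, ...) {
  cat(sprintf("acode_communities: %d accepted of %d seed edges (min_q = %g, %s null)\n",
              length(x$communities), x$n_seeds, x$params$min_q,
              x$params$null_scheme))
  if (nrow(x$summary) > 0L) {
    print(utils::head(x$summary[, c("rank", "q", "exceedance_count",
                                    "compactness", "n_edges", "n_genes")],
                      10L))
  }
  invisible(x)
}

#' Consolidate communities into modules by seed closure
#'
#' Edge-seeded detection intentionally yields overlapping communities: each
#' seed edge views the same strongly co-expressed region from a different
#' vantage point, and a single community is capped at `max_edges` edges so
#' it can only span part of a larger co-expressed module. Consolidation is
#' by seed closure: starting from the highest-ranked unassigned community,
#' a module repeatedly absorbs every unassigned community at least one of
#' whose seed edges has both endpoints inside the module's current gene
#' set — or one endpoint inside it and a seed weight no weaker than the
#' module's weakest member edge — until a fixed point. A community thus
#' joins a module only when it is seeded on what is effectively one of the
#' module's own edges; candidates seeded on weak edges elsewhere, whose
#' greedy growth merely wandered into the strong region, stay out. The
#' rule has no tuning parameter: the strength condition is taken from the
#' module's own observed weight range, and membership uses only the seed
#' bookkeeping that deduplication retains.
#'
#' @param x An `acode_communities` object.
#' @return Data.frame with one row per module in discovery (rank) order:
#'   `module`, `n_genes`, `n_communities`, `best_q`, `best_compactness`,
#'   `genes` (semicolon-separated).
#' @export
merge_communities <- function(x) {
  stopifnot(inherits(x, "acode_communities"))
  comms <- x$communities
  n <- length(comms)
  if (n == 0L) {
    return(data.frame(module = integer(0), n_genes = integer(0),
                      n_communities = integer(0), best_q = numeric(0),
                      best_compactness = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE))
  }
  gene_sets <- lapply(comms, `[[`, "genes")
  seed_sets <- lapply(comms, function(c) {
    se <- c$seed_edges %||%
      data.frame(gene1 = c$seed_edge[1L], gene2 = c$seed_edge[2L])
    # seed weights, looked up in the community's own edge list
    key <- paste(c$edges$gene1, c$edges$gene2)
    se$rho <- c$edges$rho[match(paste(se$gene1, se$gene2), key)]
    se
  })
  min_edge_rho <- vapply(comms, function(c) min(c$edges$rho), numeric(1))
  assigned <- rep(FALSE, n)
  rows <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    members <- i
    assigned[i] <- TRUE
    mod_genes <- gene_sets[[i]]
    mod_min_rho <- min_edge_rho[i]
    repeat {
      cand <- which(vapply(seq_len(n), function(j) {
        if (assigned[j]) return(FALSE)
        se <- seed_sets[[j]]
        in1 <- se$gene1 %in% mod_genes
        in2 <- se$gene2 %in% mod_genes
        any(in1 & in2) || any((in1 | in2) & se$rho >= mod_min_rho)
      }, logical(1)))
      if (length(cand) == 0L) break
      assigned[cand] <- TRUE
      members <- c(members, cand)
      mod_genes <- sort(unique(c(mod_genes, unlist(gene_sets[cand]))))
      mod_min_rho <- min(mod_min_rho, min_edge_rho[cand])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      n_genes = length(mod_genes), n_communities = length(members),
      best_q = min(vapply(comms[members], `[[`, numeric(1), "q")),
      best_compactness = max(vapply(comms[members], `[[`, numeric(1),
                                    "compactness")),
      genes = paste(mod_genes, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- cbind(module = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write a community report
#'
#' Writes the ranked community table as TSV (q of 0 additionally annotated
#' as `< 1/n_perm` in a `q_text` column) and, alongside it, a structured
#' sidecar `<path>.edges.txt` listing parameters and every community's edge
#' list in growth order.
#'
#' @param x An `acode_communities` object.
#' @param path Output TSV path.
#' @param header_lines Optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_communities <- function(x, path, header_lines = NULL) {
  stopifnot(inherits(x, "acode_communities"))
  s <- x$summary
  s$q_text <- ifelse(s$exceedance_count == 0L,
                     sprintf("< %g", 1 / x$params$n_perm),
                     format(s$q, digits = 10))
  con <- file(path, "w")
  if (!is.null(header_lines)) writeLines(header_lines, con)
  suppressWarnings(utils::write.table(s, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  side <- paste0(path, ".edges.txt")
  con <- file(side, "w")
  p <- x$params
  writeLines(c(sprintf("# min_q=%g min_edges=%d max_edges=%d n_perm=%d rng_seed=%d null_scheme=%s",
                       p$min_q, p$min_edges, p$max_edges, p$n_perm,
                       p$rng_seed, p$null_scheme),
               sprintf("# %d communities from %d seed edges",
                       length(x$communities), x$n_seeds)), con)
  for (i in seq_along(x$communities)) {
    com <- x$communities[[i]]
    writeLines(sprintf("community %d", i), con)
    writeLines(sprintf("  %s\t%s\t%.10g", com$edges$gene1, com$edges$gene2,
                       com$edges$rho), con)
  }
  close(con)
  invisible(path)
}
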