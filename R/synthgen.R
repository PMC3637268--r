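#' Configuration for the synthetic expression generator
#'
#' The generator emulates the structure of a case/control cardiac
#' transcriptome study: a handful of strongly co-expressed gene modules
#' driven by latent factors, a background of uncorrelated noise genes, and
#' optional disease marker genes whose case samples are shifted by a
#' standardized effect size. Defaults mirror the reference study design:
#' 36 case vs 23 control samples, one 18-gene module with loadings in
#' 0.85-0.95 (giving within-module correlations near 0.9), and a noise SD
#' of 0.3 on a log-like expression scale.
#'
#' @param n_background_genes Number of pure-noise genes. Default 150.
#' @param modules List of module descriptors `list(size =, loading_range =
#'   c(lo, hi))`; sizes >= 2, loadings in (0, 1).
#' @param n_case,n_control Class sizes, each >= 2. Defaults 36 / 23.
#' @param marker_genes Optional list of `list(gene =, d =)` entries: gene
#'   ID (must exist in the generated matrix) and case-vs-control shift `d`
#'   in units of the within-class SD. A marker with effect `d` has
#'   theoretical AUC `pnorm(d / sqrt(2))`.
#' @param noise_sd Residual noise SD, > 0. Default 0.3.
#' @param rng_seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_background_genes = 150L,
                             modules = list(list(size = 18L,
                                                 loading_range = c(0.85, 0.95))),
                             n_case = 36L, n_control = 23L,
                             marker_genes = list(),
                             noise_sd = 0.3, rng_seed = 1L) {
  abort_if(n_background_genes < 0, "'n_background_genes' must be >= 0")
  abort_if(n_case < 2L || n_control < 2L, "class counts must be >= 2")
  abort_if(noise_sd <= 0, "'noise_sd' must be > 0")
  for (m in modules) {
    abort_if(is.null(m$size) || m$size < 2L, "module sizes must be >= 2")
    lr <- m$loading_range
    abort_if(length(lr) != 2L || any(lr <= 0) || any(lr >= 1) || lr[1] > lr[2],
             "loading_range must be c(lo, hi) within (0, 1)")
  }
  structure(list(n_background_genes = as.integer(n_background_genes),
                 modules = modules, n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 marker_genes = marker_genes, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' Generate a synthetic case/control expression dataset
#'
#' For gene g in module m, `value(g, s) = a_g * F_m(s) + eps(g, s)` with
#' `F_m` a standard-normal latent factor per sample, loading `a_g` drawn
#' uniformly from the module's loading range, and
#' `eps ~ N(0, noise_sd^2)`. Background genes are pure noise. Marker genes
#' are additionally shifted in case samples by `d` times their realized
#' pooled within-class SD.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `expression` (an [expression_matrix()] with labels)
#'   and `ground_truth` (list with `modules` — gene ID vectors —,
#'   `module_loadings`, and `markers` data.frame).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_case + cfg$n_control
  mod_sizes <- vapply(cfg$modules, function(m) as.integer(m$size), integer(1))
  n_mod_genes <- sum(mod_sizes)
  gene_ids <- c(unlist(lapply(seq_along(mod_sizes), function(i) {
    sprintf("M%d_G%02d", i, seq_len(mod_sizes[i]))
  })), if (cfg$n_background_genes > 0)
    sprintf("BG_G%03d", seq_len(cfg$n_background_genes)))
  sample_ids <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
                  sprintf("ctrl_%02d", seq_len(cfg$n_control)))
  labels <- stats::setNames(rep(c("case", "control"),
                                c(cfg$n_case, cfg$n_control)), sample_ids)
  out <- with_seed(cfg$rng_seed, {
    vals <- matrix(stats::rnorm(length(gene_ids) * n, 0, cfg$noise_sd),
                   nrow = length(gene_ids),
                   dimnames = list(gene_ids, sample_ids))
    loadings <- vector("list", length(cfg$modules))
    row0 <- 0L
    for (i in seq_along(cfg$modules)) {
      lr <- cfg$modules[[i]]$loading_range
      a <- stats::runif(mod_sizes[i], lr[1], lr[2])
      f <- stats::rnorm(n)
      vals[row0 + seq_len(mod_sizes[i]), ] <-
        vals[row0 + seq_len(mod_sizes[i]), , drop = FALSE] + outer(a, f)
      loadings[[i]] <- stats::setNames(a, gene_ids[row0 + seq_len(mod_sizes[i])])
      row0 <- row0 + mod_sizes[i]
    }
    list(vals = vals, loadings = loadings)
  })
  vals <- out$vals
  markers <- data.frame(gene = character(0), d = numeric(0),
                        stringsAsFactors = FALSE)
  for (mk in cfg$marker_genes) {
    abort_if(!(mk$gene %in% gene_ids), "marker gene not in matrix: ", mk$gene)
    row <- vals[mk$gene, ]
    is_case <- labels == "case"
    sd_within <- sqrt(((cfg$n_case - 1) * stats::var(row[is_case]) +
                         (cfg$n_control - 1) * stats::var(row[!is_case])) /
                        (n - 2))
    vals[mk$gene, is_case] <- row[is_case] + mk$d * sd_within
    markers <- rbind(markers, data.frame(gene = mk$gene, d = mk$d,
                                         stringsAsFactors = FALSE))
  }
  list(expression = expression_matrix(vals, labels = labels),
       ground_truth = list(
         modules = lapply(out$loadings, names),
         module_loadings = out$loadings,
         markers = markers))
}

#' Generate a random network with i.i.d. edge weights
#'
#' Simple undirected random graph (edges drawn uniformly without
#' replacement from all node pairs) with independent uniformly distributed
#' weights — a pure-noise network for null calibration of the community
#' search.
#'
#' @param n_nodes Number of nodes (IDs `N001`, ...).
#' @param n_edges Number of edges, at most `choose(n_nodes, 2)`.
#' @param weight_range `c(lo, hi)` of the uniform weight distribution.
#'   Default `c(0.1, 0.9)`.
#' @param rng_seed Integer seed.
#' @return A `coexpression_network`; isolated nodes (possible when
#'   `n_edges` is small) are not members.
#' @export
generate_null_network <- function(n_nodes, n_edges,
                                  weight_range = c(0.1, 0.9),
                                  rng_seed = 1L) {
  abort_if(n_nodes < 2L, "'n_nodes' must be >= 2")
  abort_if(n_edges < 1L || n_edges > choose(n_nodes, 2),
           "'n_edges' must be in [1, choose(n_nodes, 2)]")
  abort_if(length(weight_range) != 2L || weight_range[1] > weight_range[2],
           "'weight_range' must be c(lo, hi)")
  ids <- sprintf("N%03d", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2L))
  with_seed(rng_seed, {
    take <- sample.int(nrow(pairs), n_edges)
    w <- stats::runif(n_edges, weight_range[1], weight_range[2])
    new_coexpression_network(
      data.frame(gene1 = ids[pairs[take, 1L]], gene2 = ids[pairs[take, 2L]],
                 rho = w, stringsAsFactors = FALSE),
      rho_min = weight_range[1])
  })
}

#' Write a generated dataset to disk
#'
#' Emits the expression TSV, the two-column labels TSV and a ground-truth
#' file (module memberships and marker effects) usable as pipeline inputs.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix. Default `"synthetic"`.
#' @return Named character vector of the written paths.
#' @export
write_dataset <- function(dataset, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- dataset$expression
  expr_path <- file.path(dir, paste0(prefix, "_expression.tsv"))
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  labels_path <- file.path(dir, paste0(prefix, "_labels.tsv"))
  utils::write.table(data.frame(sample_id = names(x$labels),
                                group = unname(x$labels)),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth_path <- file.path(dir, paste0(prefix, "_ground_truth.txt"))
  con <- file(truth_path, "w")
  gt <- dataset$ground_truth
  for (i in seq_along(gt$modules)) {
    writeLines(sprintf("module %d\t%s", i,
                       paste(gt$modules[[i]], collapse = ";")), con)
  }
  if (nrow(gt$markers) > 0) {
    writeLines(sprintf("marker\t%s\t%g", gt$markers$gene, gt$markers$d), con)
  }
  close(con)
  c(expression = expr_path, labels = labels_path, ground_truth = truth_path)
}
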