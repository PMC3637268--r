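#' Pipeline run configuration
#'
#' Collects every stage parameter at its reference default: SD filter 0.1,
#' correlation threshold 0.1, community q cutoff 1e-4 with 5-20 edges and
#' 10000 permutations, ridge 1e-8, 10000 AUC label permutations. Any
#' override is echoed into the run log and all artifact headers.
#'
#' @param expr Path to the expression table.
#' @param labels Optional path to the labels TSV (required for the
#'   differential-expression and classification stages).
#' @param out_dir Output directory for artifacts.
#' @param format Expression input format, see [read_expression_table()].
#' @param sd_threshold,rho_min,min_q,min_edges,max_edges,n_perm Stage
#'   parameters, see [filter_flat_genes()], [build_network()],
#'   [acode_params()].
#' @param null_scheme Permutation null scheme, see [acode_params()].
#' @param ridge,n_perm_auc Classifier parameters, see
#'   [fit_ridge_logistic()] and [auc_pvalue()].
#' @param feature_gene Optional gene ID; when given, the classification
#'   stage trains a single-gene model on it.
#' @param run_diffexp Run the differential-expression stage (needs labels).
#' @param rng_seed Integer seed for every stochastic stage.
#' @return A validated `run_config` list.
#' @export
run_config <- function(expr, labels = NULL, out_dir = "acode_out",
                       format = c("tsv", "geo_series_matrix"),
                       sd_threshold = 0.1, rho_min = 0.1, min_q = 1e-4,
                       min_edges = 5L, max_edges = 20L, n_perm = 10000L,
                       null_scheme = c("subset", "growth"),
                       ridge = 1e-8, n_perm_auc = 10000L,
                       feature_gene = NULL, run_diffexp = FALSE,
                       rng_seed = 1L) {
  format <- match.arg(format)
  null_scheme <- match.arg(null_scheme)
  abort_if(!is.numeric(rho_min) || rho_min < -1 || rho_min > 1,
           "'rho_min' must be in [-1, 1]")
  abort_if(sd_threshold < 0, "'sd_threshold' must be >= 0")
  # validates min_q / sizes / n_perm
  acode_params(min_q, min_edges, max_edges, n_perm, rng_seed, null_scheme)
  structure(list(expr = expr, labels = labels, out_dir = out_dir,
                 format = format, sd_threshold = sd_threshold,
                 rho_min = rho_min, min_q = min_q,
                 min_edges = as.integer(min_edges),
                 max_edges = as.integer(max_edges),
                 n_perm = as.integer(n_perm), null_scheme = null_scheme,
                 ridge = ridge, n_perm_auc = as.integer(n_perm_auc),
                 feature_gene = feature_gene, run_diffexp = run_diffexp,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys match the arguments of [run_config()]; `overrides` (e.g. parsed
#' command-line flags) take precedence over file values.
#'
#' @param path YAML config file.
#' @param overrides Named list of overriding values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

provenance_header <- function(cfg, inputs) {
  sums <- vapply(inputs, function(p)
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else "NA",
    character(1))
  c(sprintf("# acode %s", as.character(utils::packageVersion("acode"))),
    sprintf("# sd_threshold=%g rho_min=%g min_q=%g min_edges=%d max_edges=%d n_perm=%d null_scheme=%s ridge=%g n_perm_auc=%d rng_seed=%d",
            cfg$sd_threshold, cfg$rho_min, cfg$min_q, cfg$min_edges,
            cfg$max_edges, cfg$n_perm, cfg$null_scheme, cfg$ridge,
            cfg$n_perm_auc, cfg$rng_seed),
    sprintf("# input %s md5=%s", names(sums), sums))
}

#' Run the full analysis pipeline
#'
#' Executes filter, network construction, topology statistics, community
#' detection and (optionally) differential expression and single-gene
#' classification, writing every artifact with a provenance header (tool
#' version, parameters, seed, input checksums). Identical configuration and
#' inputs produce byte-identical artifacts.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`network`,
#'   `topology`, `communities`, and present stages) and `artifacts`, the
#'   named vector of written file paths.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(cfg, list(expr = cfg$expr, labels = cfg$labels))
  artifacts <- c()

  say("stage filter: reading and filtering expression data")
  x <- tryCatch(
    read_expression_table(cfg$expr, format = cfg$format, labels = cfg$labels),
    error = function(e) stop("stage filter failed: ", conditionMessage(e),
                             call. = FALSE))
  xf <- filter_flat_genes(x, cfg$sd_threshold)
  say(sprintf("  %d of %d genes retained", nrow(xf$values), nrow(x$values)))

  say("stage network: building co-expression network")
  net <- build_network(xf, rho_min = cfg$rho_min)
  net_path <- file.path(cfg$out_dir, "network.tsv")
  write_edge_list(net, net_path, header_lines = hdr)
  artifacts["network"] <- net_path

  topo <- list(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
               characteristic_path_length = if (length(net$nodes) >= 2)
                 suppressWarnings(characteristic_path_length(net)) else NA_real_,
               clustering_coefficient = if (length(net$nodes) >= 1)
                 clustering_coefficient(net) else NA_real_)
  topo_path <- file.path(cfg$out_dir, "topology.tsv")
  con <- file(topo_path, "w")
  writeLines(hdr, con)
  writeLines("statistic\tvalue", con)
  writeLines(sprintf("%s\t%.10g", names(topo), unlist(topo)), con)
  close(con)
  artifacts["topology"] <- topo_path

  say("stage acode: detecting communities")
  params <- acode_params(cfg$min_q, cfg$min_edges, cfg$max_edges,
                         cfg$n_perm, cfg$rng_seed, cfg$null_scheme)
  comms <- detect_communities(net, params)
  comm_path <- file.path(cfg$out_dir, "communities.tsv")
  write_communities(comms, comm_path, header_lines = hdr)
  artifacts["communities"] <- comm_path
  say(sprintf("  %d accepted communities", length(comms$communities)))

  de <- NULL
  if (isTRUE(cfg$run_diffexp)) {
    say("stage diffexp: per-gene t-tests")
    abort_if(is.null(x$labels), "stage diffexp failed: labels required")
    de <- t_test_per_gene(x)
    de_path <- file.path(cfg$out_dir, "diffexp.tsv")
    con <- file(de_path, "w")
    writeLines(hdr, con)
    suppressWarnings(utils::write.table(de, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
    artifacts["diffexp"] <- de_path
  }

  model <- NULL; roc <- NULL
  if (!is.null(cfg$feature_gene)) {
    say(sprintf("stage classify: LOOCV model on %s", cfg$feature_gene))
    abort_if(is.null(x$labels), "stage classify failed: labels required")
    abort_if(!(cfg$feature_gene %in% rownames(x$values)),
             "stage classify failed: feature gene not found: ",
             cfg$feature_gene)
    xs <- standardize_features(x)
    feat <- xs$values[cfg$feature_gene, ]
    model <- fit_ridge_logistic(feat, xs$labels, ridge = cfg$ridge,
                                feature_gene = cfg$feature_gene)
    model_path <- file.path(cfg$out_dir, "model.json")
    write_model(model, model_path)
    artifacts["model"] <- model_path
    roc <- loocv_auc(feat, xs$labels, ridge = cfg$ridge)
    roc$p_vs_random <- auc_pvalue(roc$held_out, xs$labels,
                                  n_perm = cfg$n_perm_auc,
                                  rng_seed = cfg$rng_seed)
    roc$method <- "label_permutation"
    roc_path <- file.path(cfg$out_dir, "roc_loocv.tsv")
    write_roc(roc, roc_path, header_lines = hdr)
    artifacts["roc"] <- roc_path
  }

  invisible(list(network = net, topology = topo, communities = comms,
                 diffexp = de, model = model, roc = roc,
                 artifacts = artifacts))
}
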