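#' Construct an expression matrix object
#'
#' An `expression_matrix` wraps a genes x samples numeric matrix together
#' with optional case/control sample labels. It is the common input
#' container for network construction, differential expression and
#' classification.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). Values are used on the scale supplied; for
#'   microarray data a log scale is assumed upstream.
#' @param labels Optional named character vector mapping every sample ID to
#'   `"case"` or `"control"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `labels`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- expression_matrix(m)
#' dim(x)
#' @export
expression_matrix <- function(values, labels = NULL) {
  abort_if(!is.matrix(values) || !is.numeric(values),
           "'values' must be a numeric matrix")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "'values' must have gene rownames and sample colnames")
  abort_if(anyDuplicated(rownames(values)) > 0, "duplicate gene IDs")
  abort_if(anyDuplicated(colnames(values)) > 0, "duplicate sample IDs")
  abort_if(!all(is.finite(values)), "all expression values must be finite")
  if (!is.null(labels)) {
    labels <- validate_labels(labels, colnames(values))
  }
  structure(list(values = values, labels = labels),
            class = "expression_matrix")
}

validate_labels <- function(labels, sample_ids) {
  labels <- vapply(labels, as.character, character(1))
  abort_if(is.null(names(labels)), "labels must be named by sample ID")
  abort_if(!all(sample_ids %in% names(labels)),
           "every sample must have a label")
  labels <- labels[sample_ids]
  bad <- setdiff(unique(labels), c("case", "control"))
  abort_if(length(bad) > 0,
           "labels must be 'case' or 'control', found: ",
           paste(bad, collapse = ", "))
  abort_if(!all(c("case", "control") %in% labels),
           "both classes must be non-empty")
  labels
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("labels: %d case / %d control\n",
                tab[["case"]], tab[["control"]]))
  }
  invisible(x)
}

#' Read an expression table
#'
#' Reads a genes x samples expression matrix from a tab-separated file or
#' from the sample-table block of a GEO series-matrix file. Rows containing
#' any missing or non-numeric entry are dropped (with a message giving the
#' count), and duplicate gene IDs are collapsed by keeping the row with the
#' highest variance.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` (header row of sample IDs, first column gene IDs)
#'   or `"geo_series_matrix"` (only the block between
#'   `!series_matrix_table_begin` and `!series_matrix_table_end` is parsed;
#'   all other metadata lines are ignored).
#' @param labels Optional named label vector passed to
#'   [expression_matrix()], or a path to a two-column TSV read by
#'   [read_labels()].
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, format = c("tsv", "geo_series_matrix"),
                                  labels = NULL) {
  format <- match.arg(format)
  abort_if(!file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    abort_if(length(begin) != 1L || length(end) != 1L || end <= begin + 1L,
             "series-matrix table markers not found in ", path)
    lines <- lines[(begin + 1L):(end - 1L)]
    lines <- gsub("\"", "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  abort_if(length(lines) < 2L, "no data rows in ", path)
  tab <- utils::read.delim(text = lines, header = TRUE, check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE)
  abort_if(ncol(tab) < 2L, "expected gene ID column plus >= 1 sample column")
  gene_ids <- as.character(tab[[1L]])
  sample_ids <- colnames(tab)[-1L]
  abort_if(anyDuplicated(sample_ids) > 0, "duplicate sample IDs in ", path)
  vals <- suppressWarnings(
    vapply(tab[-1L], function(col) as.numeric(col), numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(NULL, sample_ids))

  keep <- rowSums(!is.finite(vals)) == 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("read_expression_table: dropped %d row(s) with missing or non-numeric values",
                    n_dropped))
  }
  vals <- vals[keep, , drop = FALSE]
  gene_ids <- gene_ids[keep]
  abort_if(nrow(vals) == 0L, "zero genes after parsing ", path)

  # collapse duplicate gene IDs: keep the highest-variance row
  if (anyDuplicated(gene_ids) > 0) {
    v <- apply(vals, 1L, stats::var)
    ord <- order(gene_ids, -v)
    first <- !duplicated(gene_ids[ord])
    keep_rows <- sort(ord[first])
    message(sprintf("read_expression_table: collapsed %d duplicate gene ID row(s), keeping highest variance",
                    nrow(vals) - length(keep_rows)))
    vals <- vals[keep_rows, , drop = FALSE]
    gene_ids <- gene_ids[keep_rows]
  }
  rownames(vals) <- gene_ids
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    labels <- read_labels(labels)
  }
  expression_matrix(vals, labels = labels)
}

#' Read a sample-label table
#'
#' @param path Two-column tab-separated file: sample ID, group. Groups must
#'   be `case` or `control`. A header line `sample_id<TAB>group` is allowed.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  abort_if(ncol(tab) < 2L, "labels file must have two columns")
  if (identical(tolower(tab[1L, 1L]), "sample_id")) tab <- tab[-1L, , drop = FALSE]
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Remove flat expression profiles
#'
#' Drops genes whose sample standard deviation is less than or equal to
#' `sd_threshold` (boundary inclusive), keeping only genes that vary enough
#' across samples to carry co-expression signal.
#'
#' @param x An [expression_matrix()].
#' @param sd_threshold Non-negative cutoff; genes with sample SD
#'   (n - 1 denominator) `<= sd_threshold` are removed. Default 0.1.
#' @return A filtered [expression_matrix()].
#' @export
filter_flat_genes <- function(x, sd_threshold = 0.1) {
  stopifnot(inherits(x, "expression_matrix"))
  abort_if(!is.numeric(sd_threshold) || sd_threshold < 0,
           "'sd_threshold' must be >= 0")
  sds <- row_sds(x$values)
  keep <- sds > sd_threshold
  abort_if(!any(keep), "all genes removed by SD filter (threshold ",
           sd_threshold, ")")
  expression_matrix(x$values[keep, , drop = FALSE], labels = x$labels)
}

#' Standardize each gene to mean 0, SD 1
#'
#' Per-row affine transform placing every gene on a common scale, as used
#' before fitting or transferring a classification model across datasets.
#' Each dataset is standardized with its own statistics.
#'
#' @param x An [expression_matrix()].
#' @return An [expression_matrix()] whose rows have mean 0 and sample SD 1.
#' @export
standardize_features <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  sds <- row_sds(x$values)
  flat <- sds == 0
  abort_if(any(flat), "cannot standardize constant gene(s): ",
           paste(utils::head(rownames(x$values)[flat], 5L), collapse = ", "))
  vals <- (x$values - rowMeans(x$values)) / sds
  expression_matrix(vals, labels = x$labels)
}

#' Efficiency-corrected qPCR relative quantity
#'
#' Delta-Cq relative quantification incorporating the amplification
#' efficiency calculated for each primer pair:
#' `R = eff_target^(-cq_target) / eff_reference^(-cq_reference)`.
#' With both efficiencies equal to 2 this reduces to the classic
#' `2^(-delta Cq)` rule (one cycle = one doubling). The reference gene
#' (e.g. GAPDH) normalizes for input amount; no calibrator sample is used.
#'
#' @param cq_target,cq_reference Quantification cycles (positive, finite);
#'   vectors are recycled together.
#' @param eff_target,eff_reference Amplification efficiencies in fold per
#'   cycle, each in (1, 2].
#' @return Strictly positive relative quantity, same length as the inputs.
#' @examples
#' qpcr_relative_quantity(20, 21, 2, 2)  # target one cycle later -> 0.5
#' @export
qpcr_relative_quantity <- function(cq_target, cq_reference,
                                   eff_target = 2, eff_reference = 2) {
  abort_if(!all(is.finite(cq_target)) || !all(is.finite(cq_reference)) ||
             any(cq_target <= 0) || any(cq_reference <= 0),
           "Cq values must be positive and finite")
  abort_if(any(eff_target <= 1) || any(eff_target > 2) ||
             any(eff_reference <= 1) || any(eff_reference > 2),
           "amplification efficiencies must be in (1, 2]")
  # evaluate in log space for numerical range safety at large Cq
  exp(-cq_target * log(eff_target) + cq_reference * log(eff_reference))
}
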