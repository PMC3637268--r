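#' Per-gene differential expression (pooled-variance t-test)
#'
#' Classic two-sided Student's t-test (pooled variance,
#' `df = n_case + n_control - 2`) for every gene, comparing case against
#' control samples, with Benjamini-Hochberg adjustment across genes.
#' Genes with zero pooled variance are reported with `p = 1` and direction
#' `none` (with a message).
#'
#' @param x An [expression_matrix()] with labels and >= 2 samples per class.
#' @return Data.frame with columns `gene`, `t`, `p`, `p_adj`, `direction`
#'   (`up_in_case`, `down_in_case` or `none`), in input gene order.
#' @export
t_test_per_gene <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  abort_if(is.null(x$labels), "labels are required")
  case <- x$values[, x$labels == "case", drop = FALSE]
  ctrl <- x$values[, x$labels == "control", drop = FALSE]
  abort_if(ncol(case) < 2L || ncol(ctrl) < 2L,
           "need >= 2 samples per class")
  genes <- rownames(x$values)
  res <- lapply(seq_along(genes), function(i) {
    a <- case[i, ]
    b <- ctrl[i, ]
    if (stats::var(a) + stats::var(b) == 0) {
      return(list(t = 0, p = 1, direction = "none", degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value,
         direction = if (mean(a) > mean(b)) "up_in_case" else
           if (mean(a) < mean(b)) "down_in_case" else "none",
         degenerate = FALSE)
  })
  n_deg <- sum(vapply(res, `[[`, logical(1), "degenerate"))
  if (n_deg > 0) {
    message(sprintf("t_test_per_gene: %d gene(s) with zero pooled variance set to p = 1",
                    n_deg))
  }
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(gene = genes,
             t = vapply(res, `[[`, numeric(1), "t"),
             p = p,
             p_adj = bh_adjust(p),
             direction = vapply(res, `[[`, character(1), "direction"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output is in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  abort_if(!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1),
           "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
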