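#' Fit a single-gene ridge-penalised logistic classifier
#'
#' Logistic regression of class (case = 1) on one standardized expression
#' feature, maximising the binomial log-likelihood minus
#' `ridge * coefficient^2` (the intercept is not penalised) by
#' iteratively reweighted least squares. The tiny default penalty matches
#' a ridge estimation value of 1e-8: numerically immaterial away from
#' separation, but it guarantees a finite maximiser on separable data.
#'
#' @param x Numeric vector of standardized expression values (mean ~0,
#'   SD ~1; a warning is given otherwise).
#' @param labels Character vector of `"case"`/`"control"`, same length.
#' @param ridge Penalty on the squared slope, > 0. Default `1e-8`.
#' @param feature_gene Optional gene ID recorded in the model.
#' @return A `ridge_logistic` model: list with `intercept`, `coefficient`,
#'   `ridge`, `feature_gene`, `n_case`, `n_control`, `converged`,
#'   `iterations`. The model is frozen: applying it never modifies it.
#' @export
fit_ridge_logistic <- function(x, labels, ridge = 1e-8,
                               feature_gene = NA_character_) {
  y <- as_binary_labels(labels)
  abort_if(length(x) != length(y), "'x' and 'labels' lengths differ")
  abort_if(!all(is.finite(x)), "'x' must be finite")
  abort_if(ridge <= 0, "'ridge' must be > 0")
  if (abs(mean(x)) > 0.1 || abs(stats::sd(x) - 1) > 0.25) {
    warning("input does not look standardized (mean ~0, SD ~1)")
  }
  beta <- c(0, 0)  # (intercept, slope)
  it <- 0L
  converged <- FALSE
  while (it < 100L) {
    it <- it + 1L
    eta <- beta[1L] + beta[2L] * x
    mu <- stats::plogis(eta)
    wgt <- pmax(mu * (1 - mu), 1e-12)
    # penalised Newton step: H = X'WX + diag(0, 2*ridge), g = X'(y-mu) - (0, 2*ridge*b1)
    h11 <- sum(wgt); h12 <- sum(wgt * x); h22 <- sum(wgt * x^2) + 2 * ridge
    g1 <- sum(y - mu); g2 <- sum((y - mu) * x) - 2 * ridge * beta[2L]
    det <- h11 * h22 - h12^2
    step <- c(h22 * g1 - h12 * g2, h11 * g2 - h12 * g1) / det
    beta <- beta + step
    if (max(abs(step)) < 1e-10) { converged <- TRUE; break }
  }
  structure(list(intercept = beta[1L], coefficient = beta[2L], ridge = ridge,
                 feature_gene = feature_gene,
                 n_case = sum(y == 1), n_control = sum(y == 0),
                 converged = converged, iterations = it),
            class = "ridge_logistic")
}

#' @export
print.ridge_logistic <- function(x, ...) {
  cat(sprintf("ridge_logistic (%s): intercept %.6g, coefficient %.6g (ridge %g)\n",
              x$feature_gene, x$intercept, x$coefficient, x$ridge))
  cat(sprintf("trained on %d case / %d control\n", x$n_case, x$n_control))
  invisible(x)
}

as_binary_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("case", "control"))
  abort_if(length(bad) > 0, "labels must be 'case'/'control'")
  abort_if(!all(c("case", "control") %in% labels),
           "both classes must be present")
  as.integer(labels == "case")
}

#' ROC curve and AUC
#'
#' `AUC = (concordant case/control pairs + 0.5 * tied pairs) /
#' (n_case * n_control)` — the normalised Mann-Whitney U statistic — with a
#' ROC curve built by thresholding at every distinct score (ties grouped,
#' so the trapezoidal area of the curve equals the AUC).
#'
#' @param scores Numeric classifier scores, higher = more case-like.
#' @param labels `"case"`/`"control"` vector, both classes present.
#' @return A `roc_result`: list with `auc`, `curve` (data.frame `fpr`,
#'   `tpr` from (0,0) to (1,1)), `n_case`, `n_control`, and (when computed)
#'   `p_vs_random` and `method`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  abort_if(length(scores) != length(y), "'scores' and 'labels' lengths differ")
  abort_if(!all(is.finite(scores)), "'scores' must be finite")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)  # average ranks handle ties with half credit
  a <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # curve: sweep thresholds over distinct scores, highest first
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_end <- which(!duplicated(ss, fromLast = TRUE))  # last index of each tied group
  tp <- cumsum(ys)[grp_end] / n1
  fp <- cumsum(1 - ys)[grp_end] / n0
  curve <- data.frame(fpr = c(0, fp), tpr = c(0, tp))
  structure(list(auc = a, curve = curve, n_case = n1, n_control = n0,
                 p_vs_random = NULL, method = NULL),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d case / %d control)\n",
              x$auc, x$n_case, x$n_control))
  if (!is.null(x$p_vs_random)) {
    cat(sprintf("P vs random model = %.4g (%s)\n", x$p_vs_random, x$method))
  }
  invisible(x)
}

#' Leave-one-out cross-validated AUC
#'
#' For each sample, fits the ridge-logistic model on the remaining n - 1
#' samples and records the held-out predicted probability; the n pooled
#' held-out probabilities form one ROC/AUC. A fold that would lose an
#' entire class is skipped with a warning.
#'
#' @param x Standardized expression vector (n >= 4).
#' @param labels `"case"`/`"control"` vector, >= 2 samples per class.
#' @param ridge Slope penalty, as in [fit_ridge_logistic()].
#' @return A `roc_result` with an extra element `held_out` (the pooled
#'   predictions).
#' @export
loocv_auc <- function(x, labels, ridge = 1e-8) {
  y <- as_binary_labels(labels)
  n <- length(x)
  abort_if(n < 4L, "need n >= 4")
  abort_if(sum(y == 1) < 2L || sum(y == 0) < 2L,
           "need >= 2 samples per class")
  preds <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L) {
      warning(sprintf("fold %d skipped: training split lost a class", i))
      next
    }
    fit <- suppressWarnings(
      fit_ridge_logistic(x[-i], ifelse(yi == 1, "case", "control"),
                         ridge = ridge))
    preds[i] <- stats::plogis(fit$intercept + fit$coefficient * x[i])
  }
  keep <- !is.na(preds)
  out <- auc(preds[keep], ifelse(y[keep] == 1, "case", "control"))
  out$held_out <- preds
  out
}

#' Permutation p-value of an AUC against a random model
#'
#' Default method permutes the class labels `n_perm` times and reports
#' `p = (1 + #\{permuted AUC >= observed\}) / (1 + n_perm)` (add-one
#' corrected, so p can never be 0). `method = "rank_approximation"` instead
#' uses the one-sided normal approximation to the Mann-Whitney U statistic
#' (tie-corrected).
#'
#' @param scores,labels As in [auc()].
#' @param n_perm Number of label permutations. Default 10000.
#' @param rng_seed Integer seed; the result is deterministic given it.
#' @param method `"label_permutation"` (default) or `"rank_approximation"`.
#' @return P-value in (0, 1].
#' @export
auc_pvalue <- function(scores, labels, n_perm = 10000L, rng_seed = 1L,
                       method = c("label_permutation", "rank_approximation")) {
  method <- match.arg(method)
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0); n <- n1 + n0
  r <- rank(scores)
  obs <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (method == "rank_approximation") {
    u <- obs * n1 * n0
    ties <- table(scores)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    vu <- n1 * n0 / 12 * (n + 1 - tie_term)
    if (vu <= 0) return(1)
    return(stats::pnorm((u - n1 * n0 / 2) / sqrt(vu), lower.tail = FALSE))
  }
  # permuted AUC depends on labels only through which ranks fall in the
  # case class, so each permutation reduces to a rank-sum of a random
  # n_case-subset
  exceed <- with_seed(rng_seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      (sum(r[sample.int(n, n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0) >=
        obs - 1e-12
    }, logical(1)))
  })
  (1 + exceed) / (1 + n_perm)
}

#' Apply a frozen model to a new standardized dataset
#'
#' Scores `x_new` with the trained model
#' (`sigmoid(intercept + coefficient * x)`) and evaluates ROC/AUC plus the
#' permutation p-value against a random model. The model is not modified;
#' `x_new` is expected to be standardized within its own dataset, which
#' places both datasets on the same scale.
#'
#' @param model A `ridge_logistic` model.
#' @param x_new Standardized expression vector of the validation cohort.
#' @param labels_new `"case"`/`"control"` vector for the cohort.
#' @param n_perm,rng_seed,method Passed to [auc_pvalue()].
#' @return A `roc_result` with `p_vs_random`, `method` and `scores`.
#' @export
apply_model <- function(model, x_new, labels_new, n_perm = 10000L,
                        rng_seed = 1L,
                        method = c("label_permutation", "rank_approximation")) {
  stopifnot(inherits(model, "ridge_logistic"))
  method <- match.arg(method)
  scores <- stats::plogis(model$intercept + model$coefficient * x_new)
  out <- auc(scores, labels_new)
  out$p_vs_random <- auc_pvalue(scores, labels_new, n_perm = n_perm,
                                rng_seed = rng_seed, method = method)
  out$method <- method
  out$scores <- scores
  out
}

#' Serialize / load a fitted model as structured text
#'
#' @param model A `ridge_logistic` model.
#' @param path JSON file path.
#' @return `path` invisibly; [read_model()] returns the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ridge_logistic"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "ridge_logistic")
}

#' Write a ROC report
#'
#' Summary comment lines (AUC, p-value, method, class sizes) followed by the
#' tab-separated curve points.
#'
#' @param roc A `roc_result`.
#' @param path Output path.
#' @param header_lines Optional extra `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path, header_lines = NULL) {
  stopifnot(inherits(roc, "roc_result"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  writeLines(sprintf("# auc=%.10g n_case=%d n_control=%d", roc$auc,
                     roc$n_case, roc$n_control), con)
  if (!is.null(roc$p_vs_random)) {
    writeLines(sprintf("# p_vs_random=%.10g method=%s", roc$p_vs_random,
                       roc$method), con)
  }
  writeLines("fpr\ttpr", con)
  writeLines(sprintf("%.10g\t%.10g", roc$curve$fpr, roc$curve$tpr), con)
  invisible(path)
}
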