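std <- function(v) (v - mean(v)) / sd(v)
lab <- function(y) ifelse(y == 1, "case", "control")

test_that("ridge-logistic fit recovers closed-form degenerate cases", {
  # class-symmetric feature: no signal, intercept = log odds of class sizes
  x <- rep(std(c(-1, 0, 1)), 3)
  y <- c(1, 1, 1, 1, 1, 1, 0, 0, 0)
  fit <- suppressWarnings(fit_ridge_logistic(x[1:9], lab(y)))
  expect_lt(abs(fit$coefficient), 1e-5)
  expect_equal(fit$intercept, log(6 / 3), tolerance = 1e-6)
  # well-separated classes: in-sample ranking is perfect
  set.seed(1)
  x2 <- std(c(rnorm(20, 3), rnorm(20, -3)))
  y2 <- rep(c(1, 0), each = 20)
  fit2 <- fit_ridge_logistic(x2, lab(y2))
  scores <- plogis(fit2$intercept + fit2$coefficient * x2)
  expect_equal(auc(scores, lab(y2))$auc, 1)
  expect_true(is.finite(fit2$coefficient))  # penalty bounds separation
  expect_error(fit_ridge_logistic(x2, rep("case", 40)), "both classes")
})

test_that("penalized likelihood optimum matches a grid-search oracle", {
  # non-separable 6-point fixture
  x <- std(c(-1.2, 0.3, 1.1, -0.8, 0.2, 1.4))
  y <- c(0, 1, 0, 0, 1, 1)
  ridge <- 0.05  # large enough that the penalty matters
  fit <- fit_ridge_logistic(x, lab(y), ridge = ridge)
  objective <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log(1 + exp(eta))) - ridge * b1^2
  }
  b0s <- seq(fit$intercept - 0.3, fit$intercept + 0.3, length.out = 121)
  b1s <- seq(fit$coefficient - 0.3, fit$coefficient + 0.3, length.out = 121)
  grid <- outer(b0s, b1s, Vectorize(objective))
  best <- arrayInd(which.max(grid), dim(grid))
  expect_equal(b0s[best[1]], fit$intercept, tolerance = 1e-2)
  expect_equal(b1s[best[2]], fit$coefficient, tolerance = 1e-2)
  # and the fitted point is a stationary maximum: no grid point beats it
  expect_gte(objective(fit$intercept, fit$coefficient) + 1e-10, max(grid))
})

test_that("ridge-logistic agrees with glm when the penalty is negligible", {
  set.seed(3)
  x <- std(rnorm(60))
  y <- rbinom(60, 1, plogis(0.4 + 0.9 * x))
  if (length(unique(y)) == 2) {
    fit <- fit_ridge_logistic(x, lab(y), ridge = 1e-8)
    ref <- glm(y ~ x, family = binomial())
    expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
    expect_equal(fit$coefficient, unname(coef(ref)[2]), tolerance = 1e-6)
  }
})

test_that("AUC equals exhaustive pairwise counting, including ties", {
  expect_equal(auc(c(3, 4, 5, 1, 2), lab(c(1, 1, 1, 0, 0)))$auc, 1)
  expect_equal(auc(rep(1, 8), lab(rep(c(1, 0), 4)))$auc, 0.5)
  set.seed(4)
  for (i in 1:10) {
    n <- 30
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(scores, lab(y))$auc, oracle_auc(scores, lab(y)),
                 tolerance = 1e-12)
  }
})

test_that("the ROC curve is a valid staircase whose area equals the AUC", {
  set.seed(5)
  for (i in 1:5) {
    scores <- round(runif(40), 1)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- auc(scores, lab(y))
    cv <- r$curve
    expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
    expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
    expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-9)
  }
})

test_that("AUC agrees with pROC and respects its symmetries", {
  set.seed(6)
  scores <- rnorm(50)
  y <- rbinom(50, 1, 0.5)
  a <- auc(scores, lab(y))$auc
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                                 direction = "<"))))
  expect_equal(auc(-scores, lab(y))$auc, 1 - a, tolerance = 1e-12)
  expect_equal(auc(exp(scores), lab(y))$auc, a, tolerance = 1e-12)
})

test_that("LOOCV pools one held-out prediction per sample", {
  set.seed(7)
  x <- std(c(rnorm(10, 1), rnorm(10)))
  y <- rep(c(1, 0), each = 10)
  r <- loocv_auc(x, lab(y))
  expect_length(r$held_out, 20)
  expect_true(all(is.finite(r$held_out)))
  expect_true(r$auc >= 0 && r$auc <= 1)
})

test_that("LOOCV AUC tracks the closed-form normal-shift AUC", {
  # marker with a d-SD case shift: theoretical AUC = pnorm(d / sqrt(2))
  set.seed(8)
  n <- 150
  d <- 2
  x <- std(c(rnorm(n, d), rnorm(n, 0)))
  y <- rep(c(1, 0), each = n)
  r <- loocv_auc(x, lab(y))
  expect_lt(abs(r$auc - pnorm(d / sqrt(2))), 0.04)
  # pure noise marker: pooled-LOOCV AUC never shows optimistic signal
  # (it is downward-biased at the null, since each fold's training class
  # balance depends on the held-out label; see the methods vignette)
  x0 <- std(rnorm(2 * n))
  r0 <- loocv_auc(x0, lab(y))
  expect_lt(r0$auc, 0.62)
})

test_that("LOOCV AUC depends on the feature only through ranks on separable data", {
  set.seed(9)
  x <- std(c(rnorm(12, 3), rnorm(12, -3)))
  y <- rep(c(1, 0), each = 12)
  r1 <- loocv_auc(x, lab(y))
  # strictly increasing transform preserves ranks; re-standardize after
  r2 <- loocv_auc(std(x^3), lab(y))
  expect_equal(r1$auc, r2$auc)
})

test_that("permutation p-value hits its floor on perfectly separated data", {
  scores <- c(1:10, 21:30) / 30
  y <- rep(c(0, 1), each = 10)
  p <- auc_pvalue(scores, lab(y), n_perm = 10000, rng_seed = 1)
  expect_equal(p, 1 / 10001)
  expect_equal(auc_pvalue(scores, lab(y), n_perm = 10000, rng_seed = 1), p)
  # rank approximation agrees on order of magnitude
  pr <- auc_pvalue(scores, lab(y), method = "rank_approximation")
  expect_lt(pr, 1e-3)
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(10)
  ps <- replicate(60, {
    scores <- rnorm(24)
    y <- rep(c(1, 0), each = 12)
    auc_pvalue(scores, lab(y), n_perm = 200, rng_seed = sample.int(1e6, 1))
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(min(ps), 0)
})

test_that("frozen models transfer without mutation and obey ROC symmetry", {
  set.seed(11)
  x <- std(c(rnorm(20, 1.5), rnorm(20)))
  y <- rep(c(1, 0), each = 20)
  fit <- fit_ridge_logistic(x, lab(y), feature_gene = "markerX")
  snapshot <- unclass(fit)
  in_sample <- auc(plogis(fit$intercept + fit$coefficient * x), lab(y))$auc
  r_same <- apply_model(fit, x, lab(y), n_perm = 200, rng_seed = 1)
  expect_equal(r_same$auc, in_sample)
  # flipping the class structure mirrors the AUC
  r_flip <- apply_model(fit, x, lab(1 - y), n_perm = 200, rng_seed = 1)
  expect_equal(r_flip$auc, 1 - in_sample, tolerance = 1e-12)
  expect_identical(unclass(fit), snapshot)
})

test_that("models serialize to JSON and back", {
  set.seed(12)
  x <- std(rnorm(30))
  y <- rep(c(1, 0), 15)
  fit <- suppressWarnings(fit_ridge_logistic(x, lab(y), feature_gene = "g7"))
  tf <- tempfile(fileext = ".json")
  write_model(fit, tf)
  back <- read_model(tf)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$coefficient, fit$coefficient)
  expect_equal(back$feature_gene, "g7")
  roc <- apply_model(back, x, lab(y), n_perm = 100, rng_seed = 2)
  tf2 <- tempfile(fileext = ".tsv")
  write_roc(roc, tf2)
  lines <- readLines(tf2)
  expect_true(any(grepl("^# auc=", lines)))
  expect_true(any(grepl("^# p_vs_random=", lines)))
})
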