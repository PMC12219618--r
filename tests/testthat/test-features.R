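# Splitting, standardization, LASSO selection and ridge weights.

test_that("split_cohort is stratified, disjoint, exhaustive, reproducible", {
  cls <- factor(rep(c("no-decrease", "decrease"), c(60, 171)))
  sp <- split_cohort(cls, c(0.70, 0.15, 0.15), seed = 17)
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), 1:231)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_true(abs(length(sp$train) - 162) <= 1)
  expect_true(abs(length(sp$validation) - 35) <= 1)
  expect_true(abs(length(sp$test) - 34) <= 1)
  # stratification: class proportions are preserved in every split
  for (part in sp) {
    expect_equal(mean(cls[part] == "decrease"), 171 / 231, tolerance = 0.05)
  }
  expect_identical(sp, split_cohort(cls, c(0.70, 0.15, 0.15), seed = 17))
  expect_false(identical(sp, split_cohort(cls, c(0.70, 0.15, 0.15), seed = 18)))

  all_train <- split_cohort(cls, c(1, 0, 0), seed = 1)
  expect_equal(all_train$train, 1:231)
  expect_error(split_cohort(factor(rep(c("a", "b"), c(229, 2))),
                            c(0.7, 0.15, 0.15), seed = 1), "stratum")
})

test_that("standardization uses training statistics only", {
  set.seed(3)
  x <- cbind(a = rnorm(100, 5, 2), b = rnorm(100, -1, 0.5),
             bin = rbinom(100, 1, 0.4))
  tr <- 1:60
  xs <- standardize_features(x, tr)
  expect_lt(max(abs(colMeans(xs[tr, c("a", "b")]))), 1e-8)
  expect_lt(max(abs(apply(xs[tr, c("a", "b")], 2, sd) - 1)), 1e-8)
  expect_identical(attr(xs, "provenance"), "train")
  # binary column untouched
  expect_equal(xs[, "bin"], x[, "bin"])
  # test rows use the training stats, not their own
  expect_false(abs(mean(xs[61:100, "a"])) < 1e-8 &&
                 abs(sd(xs[61:100, "a"]) - 1) < 1e-8)
  expect_equal(xs[61:100, "a"],
               (x[61:100, "a"] - mean(x[tr, "a"])) / sd(x[tr, "a"]))
})

test_that("auc_score agrees with a trapezoid ROC oracle and pROC", {
  set.seed(7)
  for (i in 1:20) {
    y <- rbinom(80, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(80) + y
    expect_equal(auc_score(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    y <- rbinom(200, 1, 0.4); s <- rnorm(200) + 0.8 * y
    expect_equal(auc_score(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

make_planted_regression <- function(n = 200, p = 100, n_true = 5, snr = 2,
                                    beta = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", 1:p)))
  true_idx <- seq_len(n_true)
  lp <- x[, true_idx, drop = FALSE] %*% rep(beta, n_true)
  noise_sd <- sqrt(sum(rep(beta, n_true)^2)) / snr
  y <- as.vector(lp + rnorm(n, 0, noise_sd))
  list(x = x, y = y, class = as.integer(y > median(y)),
       true = colnames(x)[true_idx])
}

test_that("the selected-feature count is non-increasing in the shrinkage", {
  d <- make_planted_regression(seed = 5)
  sel <- lasso_select(d$x, d$y, d$class, seed = 5)
  curve <- sel$curve[order(curve_alpha <- sel$curve$alpha, decreasing = TRUE), ]
  expect_true(all(diff(curve$n_selected) >= 0))
  expect_true(length(sel$selected_features) > 0)
})

test_that("LASSO recovers planted predictors at SNR 2", {
  hits <- 0L
  for (s in 1:5) {
    d <- make_planted_regression(seed = s)
    sel <- lasso_select(d$x, d$y, d$class, seed = s)
    hits <- hits + as.integer(all(d$true %in% sel$selected_features))
  }
  expect_gte(hits, 4L)
})

test_that("full-shrinkage and no-shrinkage limits behave as expected", {
  d <- make_planted_regression(seed = 2)
  expect_error(lasso_select(d$x, d$y, d$class, alpha_grid = c(1e6, 1e5),
                            seed = 1), "zeroed")
  sel <- lasso_select(d$x, d$y, d$class,
                      alpha_grid = 10^seq(0, -4, length.out = 20), seed = 1)
  tiny <- sel$curve$n_selected[which.min(sel$curve$alpha)]
  expect_gt(tiny, 50)  # selection approaches the full feature set
})

test_that("ridge weights normalize to max 1 and respect planted ratios", {
  # single feature: weight 1 by construction
  set.seed(4)
  x1 <- matrix(rnorm(100), dimnames = list(NULL, "only"))
  w1 <- ridge_weights(x1, rnorm(100))
  expect_equal(unname(w1$weights), 1)

  # planted coefficients 3 and 1 on independent standardized features
  ratios <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 500
    x <- scale(matrix(rnorm(n * 2), n, 2)); colnames(x) <- c("big", "small")
    y <- 3 * x[, 1] + 1 * x[, 2] + rnorm(n, 0, 0.3)
    w <- ridge_weights(x, y, seed = s)
    unname(w$weights["small"] / w$weights["big"])
  })
  expect_lt(abs(mean(ratios) - 1 / 3), 0.1)

  # duplicated features share the effect nearly equally
  set.seed(9)
  n <- 300
  z <- rnorm(n)
  x <- cbind(a = z, b = z + rnorm(n, 0, 1e-6), c = rnorm(n))
  y <- 2 * z + rnorm(n, 0, 0.5)
  w <- ridge_weights(scale(x), y, seed = 9)$weights
  expect_lt(abs(w["a"] / w["b"] - 1), 0.1)

  expect_error(ridge_weights(cbind(k = rep(1, 50), j = rnorm(50)), rnorm(50)),
               "zero-variance")
})
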