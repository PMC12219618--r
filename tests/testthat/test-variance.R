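# Nested OLS variance decomposition and the FD x target interaction.

test_that("fit_nested matches the brute-force RSS/F/p oracle to 1e-8", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(30:80, 1)
    p1 <- sample(1:3, 1); p2 <- sample(1:4, 1)
    x <- matrix(rnorm(n * (p1 + p2)), n,
                dimnames = list(NULL, c(sprintf("c%d", seq_len(p1)),
                                        sprintf("f%d", seq_len(p2)))))
    y <- rnorm(n)
    res <- fit_nested(x, y, sprintf("c%d", seq_len(p1)),
                      sprintf("f%d", seq_len(p2)))
    x1 <- cbind(1, x[, seq_len(p1), drop = FALSE])
    x2 <- cbind(x1, x[, p1 + seq_len(p2), drop = FALSE])
    oracle <- brute_nested_f(x1, x2, y)
    expect_equal(res$rss1, oracle$rss1, tolerance = 1e-8)
    expect_equal(res$rss2, oracle$rss2, tolerance = 1e-8)
    expect_equal(res$f_statistic, oracle$f, tolerance = 1e-8)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-8)
    expect_gte(res$r2_2, res$r2_1)   # adding columns cannot raise RSS
  }
})

test_that("fit_nested rejects degenerate nestings", {
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- rnorm(50)
  expect_error(fit_nested(x, y, c("a", "b"), character(0)), "empty")
  expect_error(fit_nested(x, y, c("a", "b"), c("b", "c")), "disjoint")
  xs <- cbind(x, e = x[, "a"])
  expect_error(fit_nested(xs, y, c("a", "b"), c("c", "e")), "singular")
})

test_that("nested F has the nominal type-I error under the null", {
  set.seed(31)
  n <- 200
  rejections <- replicate(1000, {
    x <- matrix(rnorm(n * 13), n,
                dimnames = list(NULL, c("c1", "c2", "c3",
                                        sprintf("f%02d", 1:10))))
    y <- 0.5 * x[, "c1"] + rnorm(n)   # the 10 added features are pure noise
    fit_nested(x, y, c("c1", "c2", "c3"),
               sprintf("f%02d", 1:10))$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("null F statistics follow the reference distribution", {
  set.seed(41)
  n <- 100
  fs <- replicate(1000, {
    x <- matrix(rnorm(n * 6), n,
                dimnames = list(NULL, c("c1", "c2", sprintf("f%d", 1:4))))
    fit_nested(x, rnorm(n), c("c1", "c2"), sprintf("f%d", 1:4))$f_statistic
  })
  ks <- suppressWarnings(ks.test(fs, function(q) pf(q, 4, n - 7)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted delta-R2 of 0.15 is recovered on average", {
  # population: clinical block explains 25% of variance, FD block adds 15%
  deltas <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 200
    clin <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("c1", "c2", "c3")))
    fd <- matrix(rnorm(n * 5), n, dimnames = list(NULL, sprintf("f%d", 1:5)))
    b_c <- sqrt(0.25 / 3); b_f <- sqrt(0.15 / 5)
    y <- clin %*% rep(b_c, 3) + fd %*% rep(b_f, 5) + rnorm(n, 0, sqrt(0.60))
    res <- fit_nested(cbind(clin, fd), as.vector(y),
                      c("c1", "c2", "c3"), sprintf("f%d", 1:5))
    res$r2_2 - res$r2_1
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 0.15), 0.05)
})

make_interaction_cohort <- function(n, slope_stn, slope_gpi, noise_sd,
                                    seed) {
  set.seed(seed)
  target <- sample(c("STN", "GPi"), n, replace = TRUE)
  fd <- rnorm(n, 2.4, 0.08)
  d <- data.frame(
    target = target, sex = sample(c("male", "female"), n, TRUE),
    laterality = sample(c("bilateral", "unilateral"), n, TRUE, c(0.8, 0.2)),
    age = rnorm(n, 65, 9), motor_improvement_pct = rnorm(n, 53, 16),
    region_001 = fd)
  slope <- ifelse(target == "STN", slope_stn, slope_gpi)
  d$delta_ledd_pct <- 23 + slope * (fd - 2.4) + rnorm(n, 0, noise_sd)
  names(d)[names(d) == "age"] <- "age"
  d$age <- d$age  # keep the column name expected downstream
  d
}

test_that("interaction analysis recovers opposite-sign target slopes", {
  flagged <- 0L; signs_ok <- 0L
  for (s in 1:10) {
    d <- make_interaction_cohort(200, slope_stn = 20 / 0.08,
                                 slope_gpi = -20 / 0.08,
                                 noise_sd = 5, seed = s)
    row <- interaction_analysis(d, "region_001")
    flagged <- flagged + as.integer(row$interaction_p < 0.05)
    signs_ok <- signs_ok + as.integer(row$slope_stn > 0 && row$slope_gpi < 0)
  }
  expect_gte(flagged, 9L)
  expect_gte(signs_ok, 9L)
})

test_that("interaction p-values are calibrated under equal slopes", {
  rej <- vapply(1:200, function(s) {
    d <- make_interaction_cohort(120, slope_stn = 50, slope_gpi = 50,
                                 noise_sd = 20, seed = 500 + s)
    interaction_analysis(d, "region_001")$interaction_p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.09)
  expect_gte(mean(rej), 0.01)
})

test_that("interaction analysis rejects degenerate inputs", {
  d <- make_interaction_cohort(60, 10, 10, 10, seed = 3)
  d$target <- "STN"
  expect_error(interaction_analysis(d, "region_001"), "both DBS targets")
  d2 <- make_interaction_cohort(60, 10, 10, 10, seed = 4)
  d2$region_001 <- 2.4
  expect_error(interaction_analysis(d2, "region_001"), "constant")
})
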