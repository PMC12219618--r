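# Biomarker-validation statistics: normality, group tests with FDR
# control and effect sizes, severity regressions.

test_that("Anderson-Darling check has nominal size and power", {
  reject_normal <- 0L; reject_exp <- 0L
  for (s in 1:50) {
    set.seed(s)
    if (normality_check(rnorm(500))$p_value < 0.05) {
      reject_normal <- reject_normal + 1L
    }
    if (normality_check(rexp(500))$p_value < 0.05) reject_exp <- reject_exp + 1L
  }
  expect_lte(reject_normal, 5L)   # non-rejection in >= 90% of seeds
  expect_gte(reject_exp, 48L)     # rejection in >= 95% of seeds
  expect_error(normality_check(rep(1, 20)), "constant")
  expect_error(normality_check(rnorm(5)), "n >= 8")
})

test_that("QQ points sit on the identity line for normal quantile input", {
  x <- qnorm(ppoints(60))            # exactly normal quantiles
  qq <- normality_check(x)$qq
  expect_lt(max(abs(qq$theoretical - qq$sample)), 0.05)
})

test_that("group_compare is null-correct on identical groups", {
  fdm <- data.frame(subject_id = rep(sprintf("s%02d", 1:20), each = 3),
                    region = rep(c("r1", "r2", "r3"), 20),
                    fd = rep(c(2.3, 2.4, 2.2), 20))
  groups <- setNames(rep(c("PD", "HC"), each = 10), sprintf("s%02d", 1:20))
  res <- group_compare(fdm, groups)
  expect_equal(res$t_statistic, rep(0, 3))
  expect_equal(res$cohens_d, rep(0, 3))
  expect_equal(res$p_raw, rep(1, 3))
})

test_that("Cohen's d is antisymmetric and t-test p group-swap invariant", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(15, 2.4, 0.1); y <- rnorm(18, 2.3, 0.12)
    expect_equal(cohens_d(x, y), -cohens_d(y, x))
    expect_equal(t.test(x, y)$p.value, t.test(y, x)$p.value)
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(99)
  for (i in 1:1000) {
    m <- sample(3:120, 1)
    p <- runif(m)^sample(c(1, 2, 0.5), 1)
    expect_equal(p.adjust(p, method = "BH"), brute_bh_adjust(p))
  }
})

test_that("planted group shifts at d = 1, n = 70/70 are recovered", {
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    co <- make_cohort(cohort_spec(
      n_subjects = 140L, pd_fraction = 0.5,
      effect_regions = c(3L, 8L, 19L, 23L, 30L, 54L, 70L, 74L, 75L),
      effect_size_d = 1, seed = 1000L + s))
    res <- group_compare(co$fd_table, co$group)
    flagged <- res$region[res$significant]
    planted <- sprintf("region_%03d", co$truth$effect_regions)
    hits <- hits + as.integer(all(planted %in% flagged))
    total <- total + 1L
  }
  expect_gte(hits / total, 0.95)
})

test_that("label permutation keeps the BH discovery proportion near nominal", {
  co <- make_cohort(cohort_spec(n_subjects = 60L, pd_fraction = 0.5,
                                n_regions = 40L, seed = 5L))
  set.seed(5)
  prop <- replicate(200, {
    g <- setNames(sample(co$group), names(co$group))
    res <- group_compare(co$fd_table, g)
    mean(res$significant)
  })
  expect_lte(mean(prop), 0.05)
})

test_that("severity regression recovers a planted FD association", {
  recovered <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 231
    ids <- sprintf("p%03d", 1:n)
    fd <- rnorm(n, 2.4, 0.08)
    age <- rnorm(n, 65, 9)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    score <- 5 * scale(fd)[, 1] + 0.05 * age + rnorm(n, 0, 5)
    fd_table <- data.frame(subject_id = ids, region = "region_001", fd = fd)
    scores <- data.frame(subject_id = ids, state = "OFF", score = score)
    cov <- data.frame(subject_id = ids, age = age, sex = sex)
    row <- severity_regression(fd_table, scores, cov)
    recovered <- recovered + as.integer(row$r > 0 && row$ci_lo > 0)
  }
  expect_gte(recovered, 9L)
})

test_that("zero-noise planted severity model hits the perfect-fit bound", {
  set.seed(2)
  n <- 50
  ids <- sprintf("p%02d", 1:n)
  fd <- rnorm(n, 2.4, 0.08)
  fd_table <- data.frame(subject_id = ids, region = "region_001", fd = fd)
  scores <- data.frame(subject_id = ids, state = "OFF", score = 10 * fd)
  cov <- data.frame(subject_id = ids, age = rnorm(n, 65, 9),
                    sex = sample(c("male", "female"), n, replace = TRUE))
  row <- suppressWarnings(severity_regression(fd_table, scores, cov))
  expect_equal(row$r, 1, tolerance = 1e-6)
})

test_that("permuted FD yields few adjusted-significant severity models", {
  co <- make_cohort(cohort_spec(n_subjects = 120L, n_regions = 30L, seed = 9L))
  set.seed(9)
  subj <- co$subjects
  scores <- rbind(
    data.frame(subject_id = subj$subject_id, state = "OFF",
               score = rnorm(120, 40, 10)),
    data.frame(subject_id = subj$subject_id, state = "ON",
               score = rnorm(120, 25, 8)))
  cov <- data.frame(subject_id = subj$subject_id, age = subj$age_at_mri,
                    sex = subj$sex)
  perm <- co$fd_table
  for (r in unique(perm$region)) {
    sel <- perm$region == r
    perm$fd[sel] <- sample(perm$fd[sel])
  }
  res <- severity_regression(perm, scores, cov)
  expect_lte(mean(res$significant), 0.05)
})

test_that("rank-deficient severity designs fail loudly", {
  n <- 30
  ids <- sprintf("p%02d", 1:n)
  fd_table <- data.frame(subject_id = ids, region = "r1", fd = rep(2.4, n))
  scores <- data.frame(subject_id = ids, state = "OFF", score = rnorm(n))
  cov <- data.frame(subject_id = ids, age = rnorm(n, 65, 9),
                    sex = sample(c("male", "female"), n, replace = TRUE))
  expect_error(severity_regression(fd_table, scores, cov), "collinear")
})
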