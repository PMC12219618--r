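# Validation statistics for regional FD as a disease biomarker: normality
# diagnostics, case-control group tests with FDR control and effect sizes,
# and covariate-adjusted regressions of motor severity on regional FD.

#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric vectors for the two groups.
#' @return Standardized mean difference `(mean(x) - mean(y)) / sd_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("need >= 2 observations per group")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Anderson-Darling normality check with QQ data
#'
#' Tests the composite normal hypothesis (mean and SD estimated) with the
#' Anderson-Darling statistic and returns theoretical/sample quantile pairs
#' for a QQ plot.
#'
#' @param values numeric vector, n >= 8, non-constant.
#' @return List: `statistic` (A^2), `p_value`, `qq` (data frame with
#'   `theoretical` and `sample` quantiles on the observed scale).
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8L) stop("need n >= 8 for the Anderson-Darling test")
  if (stats::sd(values) == 0) stop("constant input: normality test undefined")
  ad <- nortest::ad.test(values)
  n <- length(values)
  qq <- data.frame(
    theoretical = stats::qnorm(stats::ppoints(n), mean(values),
                               stats::sd(values)),
    sample = sort(values)
  )
  list(statistic = unname(ad$statistic), p_value = ad$p.value, qq = qq)
}

#' Per-region case-control comparison of regional FD
#'
#' Two-sided t-test per region (Welch by default), Benjamini-Hochberg
#' adjustment across all tested regions, and Cohen's d with pooled SD.
#' `direction` is `"higher-in-PD"` when the case-group mean exceeds the
#' control mean. Regions with fewer than two subjects in either group are
#' excluded with a message.
#'
#' @param fd_table long data frame `subject_id`, `region`, `fd` (as from
#'   [extract_cohort_fd()] or [make_cohort()]).
#' @param groups named vector (names = subject ids) with two levels; the
#'   first level of `case_level` is treated as the case (PD) group.
#' @param case_level value of `groups` identifying cases; default `"PD"`.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param alpha significance level on the adjusted p-values.
#' @return Data frame: `region`, `t_statistic`, `p_raw`, `p_adjusted`,
#'   `cohens_d`, `direction`, `significant`.
#' @export
group_compare <- function(fd_table, groups, case_level = "PD",
                          var_equal = FALSE, alpha = 0.05) {
  g <- groups[match(fd_table$subject_id, names(groups))]
  if (anyNA(g)) stop("some subjects in fd_table have no group label")
  is_case <- g == case_level
  regions <- unique(fd_table$region)
  rows <- list(); skipped <- character(0)
  for (r in regions) {
    sel <- fd_table$region == r & is.finite(fd_table$fd)
    x <- fd_table$fd[sel & is_case]      # cases
    y <- fd_table$fd[sel & !is_case]     # controls
    if (length(x) < 2L || length(y) < 2L) {
      skipped <- c(skipped, r)
      next
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      # degenerate but well-defined: identical constant groups
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    d <- cohens_d(x, y)
    rows[[r]] <- data.frame(
      region = r, t_statistic = unname(tt$statistic),
      p_raw = tt$p.value, cohens_d = d,
      direction = if (mean(x) >= mean(y)) "higher-in-PD" else "lower-in-PD")
  }
  if (length(skipped)) {
    message("excluded ", length(skipped), " region(s) with < 2 subjects ",
            "in a group: ", paste(utils::head(skipped, 5), collapse = ", "))
  }
  if (!length(rows)) stop("no region could be tested")
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out[, c("region", "t_statistic", "p_raw", "p_adjusted", "cohens_d",
          "direction", "significant")]
}

#' Covariate-adjusted regressions of motor severity on regional FD
#'
#' For each region and medication state, fits an ordinary least squares
#' model of the motor score on FD plus age and sex, and reports the FD
#' association on the partial-correlation scale: `r = sign(beta) *
#' sqrt(t^2 / (t^2 + df))` with a Fisher-z 95% confidence interval.
#' P-values are Benjamini-Hochberg adjusted jointly across all fitted
#' models (regions x states).
#'
#' @param fd_table long data frame `subject_id`, `region`, `fd`.
#' @param scores data frame `subject_id`, `state` (`"ON"`/`"OFF"`),
#'   `score` (e.g. MDS-UPDRS III total, item-masked upstream if needed).
#' @param covariates data frame `subject_id`, `age`, `sex`.
#' @param alpha significance level on adjusted p-values.
#' @return Data frame: `region`, `state`, `r`, `ci_lo`, `ci_hi`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
severity_regression <- function(fd_table, scores, covariates, alpha = 0.05) {
  covariates$sex_num <- as.numeric(factor(covariates$sex)) - 1
  rows <- list()
  for (st in unique(scores$state)) {
    sc <- scores[scores$state == st, , drop = FALSE]
    for (r in unique(fd_table$region)) {
      fd <- fd_table[fd_table$region == r, c("subject_id", "fd")]
      df <- merge(merge(fd, sc, by = "subject_id"), covariates,
                  by = "subject_id")
      df <- df[stats::complete.cases(df[, c("fd", "score", "age", "sex_num")]), ]
      if (nrow(df) < 10L) stop("fewer than 10 complete cases for region ", r)
      X <- cbind(1, df$fd, df$age, df$sex_num)
      colnames(X) <- c("(Intercept)", "fd", "age", "sex")
      qx <- qr(X)
      if (qx$rank < ncol(X)) {
        bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
        stop("rank-deficient design for region ", r, ": collinear column(s) ",
             paste(bad, collapse = ", "))
      }
      fit <- stats::lm(df$score ~ df$fd + df$age + df$sex_num)
      sm <- summary(fit)$coefficients
      tval <- sm["df$fd", "t value"]
      dfres <- fit$df.residual
      pr <- sign(tval) * sqrt(tval^2 / (tval^2 + dfres))
      # Fisher z interval; 2 covariates controlled
      se_z <- 1 / sqrt(nrow(df) - 3 - 2)
      ci <- tanh(atanh(pr) + c(-1, 1) * stats::qnorm(0.975) * se_z)
      rows[[paste(st, r)]] <- data.frame(
        region = r, state = st, r = pr, ci_lo = ci[1], ci_hi = ci[2],
        p_raw = sm["df$fd", "Pr(>|t|)"])
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
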