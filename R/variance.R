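# Nested-model variance decomposition: how much variance in the percent
# LEDD change is explained by clinical covariates alone versus clinical
# covariates plus regional FD, with the standard F-test for nested OLS
# models, plus the per-region FD x DBS-target interaction analysis.

#' Nested OLS comparison of clinical vs clinical + FD models
#'
#' Fits two ordinary least squares models on identical rows: model 1 on
#' `clinical_set`, model 2 on `clinical_set` plus `fd_set`. The F statistic
#' for the added block is
#' `F = ((RSS1 - RSS2) / q) / (RSS2 / df2)` with `q` the number of added
#' parameters and `df2` the residual degrees of freedom of the larger
#' model; the p-value comes from the F(q, df2) distribution.
#'
#' @param x numeric feature matrix with named columns.
#' @param y outcome vector.
#' @param clinical_set column names of the reduced (clinical) model.
#' @param fd_set column names added in the full model; must be non-empty
#'   and disjoint from `clinical_set`.
#' @return A `nested_comparison`: `rss1`, `rss2`, `df1`, `df2`, `r2_1`,
#'   `r2_2`, `f_statistic`, `p_value`, `n`.
#' @export
fit_nested <- function(x, y, clinical_set, fd_set) {
  x <- as.matrix(x)
  if (length(fd_set) == 0L) {
    stop("fd_set is empty: zero added parameters, nested F undefined")
  }
  if (any(fd_set %in% clinical_set)) {
    stop("fd_set and clinical_set must be disjoint (models must nest)")
  }
  miss <- setdiff(c(clinical_set, fd_set), colnames(x))
  if (length(miss)) stop("columns not in x: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(cbind(x[, c(clinical_set, fd_set)], y))
  if (sum(!keep)) message("dropping ", sum(!keep), " incomplete row(s)")
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  x1 <- cbind(`(Intercept)` = 1, x[, clinical_set, drop = FALSE])
  x2 <- cbind(x1, x[, fd_set, drop = FALSE])
  if (nrow(x2) <= ncol(x2)) stop("need n > number of model-2 parameters")
  if (qr(x2)$rank < ncol(x2)) stop("singular design in the combined model")
  f1 <- stats::lm.fit(x1, y)
  f2 <- stats::lm.fit(x2, y)
  rss1 <- sum(f1$residuals^2); rss2 <- sum(f2$residuals^2)
  df1 <- nrow(x1) - ncol(x1); df2 <- nrow(x2) - ncol(x2)
  tss <- sum((y - mean(y))^2)
  q <- df1 - df2
  fstat <- ((rss1 - rss2) / q) / (rss2 / df2)
  structure(list(rss1 = rss1, rss2 = rss2, df1 = df1, df2 = df2,
                 r2_1 = 1 - rss1 / tss, r2_2 = 1 - rss2 / tss,
                 f_statistic = fstat,
                 p_value = stats::pf(fstat, q, df2, lower.tail = FALSE),
                 n = length(y)),
            class = "nested_comparison")
}

#' @export
print.nested_comparison <- function(x, ...) {
  cat(sprintf(paste0("<nested_comparison> R2 %.3f -> %.3f ",
                     "(F = %.3f on %d and %d df, p = %.4g, n = %d)\n"),
              x$r2_1, x$r2_2, x$f_statistic, x$df1 - x$df2, x$df2,
              x$p_value, x$n))
  invisible(x)
}

#' Per-region FD x DBS-target interaction analysis
#'
#' For each selected region, fits OLS of the percent LEDD change on the
#' region's FD, the covariates, the binary DBS target, and an FD x target
#' interaction. The within-target slopes are derived from the FD main
#' effect (GPi, the reference level) and the interaction coefficient
#' (STN = GPi slope + interaction).
#'
#' @param data data frame with columns `delta_ledd_pct`, `target` (coded
#'   STN = 1 / GPi = 0 or the strings), `age`, `sex`, `laterality`,
#'   `motor_improvement_pct`, and one column per FD region.
#' @param regions character vector of FD column names to analyse.
#' @return Data frame: `region`, `slope_stn`, `slope_gpi`,
#'   `interaction_p`.
#' @export
interaction_analysis <- function(data, regions) {
  d <- encode_clinical(data)
  if (!"age" %in% names(d) && "age_at_mri" %in% names(d)) {
    d$age <- d$age_at_mri
  }
  if (length(unique(d$target)) < 2L) {
    stop("both DBS targets must be represented")
  }
  rows <- lapply(regions, function(r) {
    if (!r %in% names(d)) stop("region column missing: ", r)
    fd <- d[[r]]
    if (stats::sd(fd) == 0) stop("FD column is constant: ", r)
    fit <- stats::lm(delta_ledd_pct ~ fd * target + age + sex + laterality +
                       motor_improvement_pct, data = cbind(d, fd = fd))
    sm <- summary(fit)$coefficients
    b_fd <- sm["fd", "Estimate"]
    b_int <- sm["fd:target", "Estimate"]
    data.frame(region = r,
               slope_stn = b_fd + b_int,
               slope_gpi = b_fd,
               interaction_p = sm["fd:target", "Pr(>|t|)"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
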