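# Feature standardization, train/validation/test splitting, LASSO feature
# selection with the shrinkage factor chosen by cross-validated
# classification AUC, and ridge-regression importance weights.

#' Stratified train/validation/test split
#'
#' Disjoint, exhaustive, stratified by outcome class, reproducible given
#' the seed. Within each stratum the requested fractions are realized by
#' largest-remainder rounding.
#'
#' @param outcome_class factor (or vector) of class labels, length n.
#' @param fractions length-3 non-negative fractions (train, validation,
#'   test) summing to 1.
#' @param seed integer RNG seed.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
split_cohort <- function(outcome_class, fractions = c(0.70, 0.15, 0.15),
                         seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    stop("fractions must be non-negative and sum to 1")
  }
  n <- length(outcome_class)
  if (n < 20L) stop("need n >= 20 subjects to split")
  n_splits <- sum(fractions > 0)
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(seed)
  for (lev in unique(as.character(outcome_class))) {
    idx <- which(as.character(outcome_class) == lev)
    if (length(idx) < n_splits) {
      stop("stratum '", lev, "' has ", length(idx),
           " subjects, fewer than the ", n_splits, " requested splits")
    }
    idx <- sample(idx)
    target <- fractions * length(idx)
    sizes <- floor(target)
    rem <- target - sizes
    short <- length(idx) - sum(sizes)
    if (short > 0) {
      give <- order(rem, decreasing = TRUE)[seq_len(short)]
      sizes[give] <- sizes[give] + 1L
    }
    cut1 <- sizes[1]; cut2 <- sizes[1] + sizes[2]
    out$train <- c(out$train, idx[seq_len(cut1)])
    if (sizes[2] > 0) out$validation <- c(out$validation, idx[(cut1 + 1):cut2])
    if (sizes[3] > 0) out$test <- c(out$test, idx[(cut2 + 1):length(idx)])
  }
  lapply(out, sort)
}

#' Encode clinical covariates to numeric with documented reference levels
#'
#' Coding: `sex` female = 1 / male = 0; `target` STN = 1 / GPi = 0;
#' `laterality` bilateral = 1 / unilateral = 0. Other columns pass through.
#'
#' @param df data frame of clinical covariates.
#' @return Numeric data frame with the same rows.
#' @export
encode_clinical <- function(df) {
  out <- df
  if ("sex" %in% names(df)) out$sex <- as.numeric(df$sex == "female")
  if ("target" %in% names(df)) out$target <- as.numeric(df$target == "STN")
  if ("laterality" %in% names(df)) {
    out$laterality <- as.numeric(df$laterality == "bilateral")
  }
  out
}

#' Standardize features using training-split statistics only
#'
#' Continuous columns are centred and scaled to the mean and SD computed on
#' the training rows alone; the same statistics are then applied to every
#' row, so validation/test data never leak into the standardization.
#' Binary 0/1 columns are left unscaled.
#'
#' @param x numeric matrix or data frame (subjects x features).
#' @param train_idx integer indices of the training rows.
#' @return A `feature_matrix`: the standardized matrix with attributes
#'   `center`, `scale`, `scaled_cols` and `provenance = "train"`.
#' @export
standardize_features <- function(x, train_idx) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric; encode categoricals first")
  is_binary <- apply(x, 2L, function(v) all(v %in% c(0, 1)))
  centre <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  names(centre) <- names(scl) <- colnames(x)
  tr <- x[train_idx, , drop = FALSE]
  for (j in which(!is_binary)) {
    centre[j] <- mean(tr[, j])
    s <- stats::sd(tr[, j])
    if (!is.finite(s) || s == 0) {
      stop("zero-variance continuous feature on the training split: ",
           colnames(x)[j])
    }
    scl[j] <- s
  }
  out <- sweep(sweep(x, 2L, centre, "-"), 2L, scl, "/")
  structure(out, center = centre, scale = scl, scaled_cols = !is_binary,
            provenance = "train", train_idx = train_idx,
            class = c("feature_matrix", class(out)))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC of `scores` for predicting the positive class, with
#' midrank tie handling.
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 vector; `TRUE`/1 is the positive class.
#' @return AUC in `[0, 1]`; `NA` if a class is absent.
#' @export
auc_score <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment, seeded.
make_folds <- function(labels, k, seed) {
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(labels))
  for (lev in unique(labels)) {
    idx <- sample(which(labels == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Mean cross-validated AUC of a logistic classifier on the given columns.
cv_logistic_auc <- function(x, class01, cols, nfolds, seed) {
  fold <- make_folds(class01, nfolds, seed)
  scores <- rep(NA_real_, length(class01))
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    dtr <- data.frame(y = class01[tr], x[tr, cols, drop = FALSE])
    dte <- data.frame(x[!tr, cols, drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = dtr,
                                       family = stats::binomial()))
    scores[!tr] <- suppressWarnings(
      stats::predict(fit, newdata = dte, type = "response"))
  }
  auc_score(scores, class01)
}

#' LASSO feature selection with CV-AUC-chosen shrinkage
#'
#' Fits a linear LASSO of the continuous outcome (percent LEDD change) on
#' the standardized training features over a grid of shrinkage factors.
#' For each shrinkage value the nonzero-coefficient feature set is
#' extracted and scored by the 5-fold cross-validated AUC of a logistic
#' classifier, restricted to that set, predicting the binary outcome
#' class. The shrinkage maximizing mean CV AUC is returned (ties resolved
#' toward the sparser model). Set `logistic = TRUE` to run the LASSO
#' itself on the binary class instead.
#'
#' @param x standardized training feature matrix (see
#'   [standardize_features()]).
#' @param y continuous outcome (percent LEDD change) for the same rows.
#' @param class binary outcome class for the same rows (factor or 0/1);
#'   the second factor level / 1 is the positive class.
#' @param alpha_grid decreasing grid of shrinkage factors; default: 40
#'   log-spaced values from the smallest shrinkage that zeroes every
#'   coefficient down to 1/1000 of it.
#' @param nfolds folds for the classification CV (default 5).
#' @param logistic run a logistic (binomial) LASSO on `class` instead of a
#'   linear LASSO on `y`.
#' @param seed RNG seed for fold assignment.
#' @return A `selection_result` list: `alpha` (chosen shrinkage),
#'   `selected_features`, `curve` (data frame alpha / n_selected /
#'   cv_auc), `path` (the glmnet fit).
#' @export
lasso_select <- function(x, y, class, alpha_grid = NULL, nfolds = 5L,
                         logistic = FALSE, seed = 1L) {
  x <- as.matrix(x)
  class01 <- if (is.factor(class)) as.integer(class) - 1L else as.integer(class)
  if (!all(class01 %in% c(0L, 1L))) stop("`class` must be binary")
  if (!is.null(alpha_grid) && any(alpha_grid <= 0)) {
    stop("alpha_grid must be positive")
  }
  fam <- if (logistic) "binomial" else "gaussian"
  resp <- if (logistic) class01 else y
  if (is.null(alpha_grid)) {
    path0 <- glmnet::glmnet(x, resp, family = fam, standardize = FALSE,
                            nlambda = 40)
    lmax <- max(path0$lambda)
    alpha_grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 40))
  }
  alpha_grid <- sort(alpha_grid, decreasing = TRUE)
  path <- glmnet::glmnet(x, resp, family = fam, standardize = FALSE,
                         lambda = alpha_grid)
  beta <- as.matrix(path$beta)
  curve <- data.frame(alpha = path$lambda,
                      n_selected = colSums(beta != 0),
                      cv_auc = NA_real_)
  sets <- lapply(seq_len(ncol(beta)),
                 function(j) rownames(beta)[beta[, j] != 0])
  for (j in seq_along(sets)) {
    if (length(sets[[j]]) == 0L) next
    curve$cv_auc[j] <- cv_logistic_auc(x, class01, sets[[j]], nfolds, seed)
  }
  if (all(is.na(curve$cv_auc))) {
    stop("every shrinkage value zeroed all coefficients; extend alpha_grid ",
         "toward smaller values")
  }
  best <- which(curve$cv_auc == max(curve$cv_auc, na.rm = TRUE))[1L]
  structure(list(alpha = curve$alpha[best],
                 selected_features = sets[[best]],
                 curve = curve, path = path, family = fam),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> shrinkage = %.4g, %d features selected\n",
              x$alpha, length(x$selected_features)))
  invisible(x)
}

#' Normalized ridge-regression importance weights
#'
#' Ridge fit (penalty chosen by 5-fold cross-validation) of the outcome on
#' the selected features; weights are absolute coefficients scaled so the
#' largest equals 1, and serve as per-feature hyperedge weights downstream.
#'
#' @param x standardized feature matrix restricted to >= 1 selected column.
#' @param y outcome vector.
#' @param nfolds CV folds for the ridge penalty.
#' @param seed RNG seed.
#' @return Named list: `coefficients` (signed ridge coefficients) and
#'   `weights` (normalized magnitudes in (0, 1]).
#' @export
ridge_weights <- function(x, y, nfolds = 5L, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("need >= 1 selected feature")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance selected feature: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(seed)
  if (ncol(x) == 1L) {
    # cv.glmnet needs >= 2 columns; a single feature gets weight 1 by
    # construction
    fit <- stats::lm(y ~ x)
    co <- stats::coef(fit)[-1]
    names(co) <- colnames(x)
    return(list(coefficients = co, weights = stats::setNames(1, colnames(x))))
  }
  cvfit <- glmnet::cv.glmnet(x, y, alpha = 0, nfolds = nfolds,
                             standardize = FALSE)
  co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, 1]
  w <- abs(co) / max(abs(co))
  list(coefficients = co, weights = w)
}
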