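# End-to-end orchestration: FD extraction or synthesis -> outcome
# labelling -> biomarker validation -> feature selection -> variance
# decomposition -> hypergraph classification, with a manifest that makes
# the run reproducible (config hash, derived seeds, per-stage row counts).

#' Pipeline configuration
#'
#' @param out_dir run directory (created if absent).
#' @param fd_table optional precomputed long FD table (data frame or TSV
#'   path); when `NULL` and `volumes` is `NULL`, a synthetic cohort is
#'   generated from `cohort` and `validation_cohort`.
#' @param volumes optional named list of [label_volume()] objects to run
#'   [extract_cohort_fd()] on.
#' @param cohort a [cohort_spec()] for the patient (DBS) cohort when
#'   synthesizing.
#' @param validation_cohort a [cohort_spec()] for the PD-vs-HC validation
#'   cohort, or `NULL` to skip the group-comparison stage.
#' @param fd_mode `"mask"` or `"boundary"` for FD extraction.
#' @param split_fractions train/validation/test fractions.
#' @param k hyperedge size for the classifier; ignored when `scan_k_grid`
#'   is given.
#' @param scan_k_grid optional integer grid to scan for the best k.
#' @param hgnn an [hgnn_config()] used as the base classifier config.
#' @param seed master seed; each stage derives its own child seed from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("fractaldbs_run_"),
                            fd_table = NULL, volumes = NULL,
                            cohort = cohort_spec(),
                            validation_cohort = cohort_spec(
                              n_subjects = 140L, pd_fraction = 0.5,
                              effect_regions = c(3L, 8L, 19L, 23L, 30L,
                                                 54L, 70L, 74L, 75L),
                              effect_size_d = 1, seed = 2L),
                            fd_mode = c("mask", "boundary"),
                            split_fractions = c(0.70, 0.15, 0.15),
                            k = 12L, scan_k_grid = NULL,
                            hgnn = hgnn_config(),
                            seed = 1L) {
  fd_mode <- match.arg(fd_mode)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Derive a reproducible child seed for a named stage
#'
#' All randomness in [run_pipeline()] flows through one master seed; each
#' stage uses `child_seed(master, stage_name)` so stages are independent
#' yet reproducible.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% (2^31 - 1))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writes per-stage outputs (TSV/JSON) under
#' `config$out_dir`, and returns a manifest. A failing stage halts the run
#' with an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  counts <- list()
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  # --- stage 1: regional FD ------------------------------------------------
  synthetic <- is.null(config$fd_table) && is.null(config$volumes)
  dat <- stage("fd_extraction", function() {
    if (!is.null(config$volumes)) {
      ft <- extract_cohort_fd(config$volumes, mode = config$fd_mode)
      list(fd_table = ft, subjects = NULL, group = NULL)
    } else if (!is.null(config$fd_table)) {
      ft <- if (is.character(config$fd_table)) read_fd_table(config$fd_table)
            else config$fd_table
      list(fd_table = ft, subjects = NULL, group = NULL)
    } else {
      spec <- config$cohort
      spec$seed <- child_seed(config$seed, "cohort")
      make_cohort(spec)
    }
  })
  if (is.null(dat$subjects)) {
    stop("pipeline stage 'medication_outcomes' failed: no subject table; ",
         "supply clinical data alongside a precomputed FD table",
         call. = FALSE)
  }
  write_fd_table(dat$fd_table, file.path(config$out_dir, "fd_table.tsv"))
  counts$fd_rows <- nrow(dat$fd_table)

  # --- stage 2: outcomes ---------------------------------------------------
  subjects <- stage("medication_outcomes", function() {
    s <- dat$subjects
    pd <- !is.na(s$delta_ledd_pct)
    s$outcome_class[pd] <- classify_outcome(s$delta_ledd_pct[pd])
    s
  })
  utils::write.table(subjects, file.path(config$out_dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$subjects <- nrow(subjects)

  # --- stage 3: biomarker validation --------------------------------------
  validation <- stage("biomarker_validation", function() {
    if (is.null(config$validation_cohort)) return(NULL)
    vspec <- config$validation_cohort
    vspec$seed <- child_seed(config$seed, "validation_cohort")
    vc <- make_cohort(vspec)
    gc <- group_compare(vc$fd_table, vc$group)
    utils::write.table(gc, file.path(config$out_dir, "group_compare.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(group_compare = gc, planted = vc$truth$effect_regions)
  })
  if (!is.null(validation)) {
    counts$validation_regions <- nrow(validation$group_compare)
  }

  # --- stage 4: feature selection -----------------------------------------
  feat <- stage("feature_pipeline", function() {
    pd <- subjects[!is.na(subjects$delta_ledd_pct), ]
    fdm <- fd_wide(dat$fd_table)[pd$subject_id, , drop = FALSE]
    clin <- encode_clinical(pd[, c("sex", "target", "laterality")])
    xraw <- cbind(clin, age_at_mri = pd$age_at_mri,
                  motor_improvement_pct = pd$motor_improvement_pct, fdm)
    split <- split_cohort(pd$outcome_class, config$split_fractions,
                          seed = child_seed(config$seed, "split"))
    xs <- standardize_features(xraw, split$train)
    sel <- lasso_select(xs[split$train, , drop = FALSE],
                        pd$delta_ledd_pct[split$train],
                        pd$outcome_class[split$train],
                        seed = child_seed(config$seed, "lasso"))
    rw <- ridge_weights(xs[split$train, sel$selected_features, drop = FALSE],
                        pd$delta_ledd_pct[split$train],
                        seed = child_seed(config$seed, "ridge"))
    jsonlite::write_json(
      list(alpha = sel$alpha, features = sel$selected_features,
           weights = as.list(rw$weights)),
      file.path(config$out_dir, "selection.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.table(sel$curve,
                       file.path(config$out_dir, "lasso_auc_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(pd = pd, x = xs, split = split, selection = sel, ridge = rw)
  })
  counts$selected_features <- length(feat$selection$selected_features)

  # --- stage 5: variance models -------------------------------------------
  variance <- stage("variance_models", function() {
    clinical_set <- c("target", "laterality", "age_at_mri", "sex",
                      "motor_improvement_pct")
    fd_set <- setdiff(feat$selection$selected_features, clinical_set)
    fd_set <- intersect(fd_set, colnames(feat$x))
    if (!length(fd_set)) return(NULL)
    nested_train <- fit_nested(feat$x[feat$split$train, , drop = FALSE],
                               feat$pd$delta_ledd_pct[feat$split$train],
                               clinical_set, fd_set)
    nested_all <- fit_nested(feat$x, feat$pd$delta_ledd_pct,
                             clinical_set, fd_set)
    inter <- interaction_analysis(
      cbind(feat$pd, fd_wide(dat$fd_table)[feat$pd$subject_id, , drop = FALSE]),
      intersect(fd_set, unique(dat$fd_table$region)))
    jsonlite::write_json(
      list(train = unclass(nested_train), all = unclass(nested_all)),
      file.path(config$out_dir, "variance.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.table(inter, file.path(config$out_dir, "interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(train = nested_train, all = nested_all, interactions = inter)
  })

  # --- stage 6: hypergraph classification ---------------------------------
  hyper <- stage("hypergraph_learning", function() {
    clin_names <- c("sex", "target", "laterality")
    sel <- feat$selection$selected_features
    categorical <- intersect(sel, clin_names)
    continuous <- setdiff(sel, clin_names)
    clinical_set <- c(categorical,
                      intersect(continuous,
                                c("age_at_mri", "motor_improvement_pct")))
    if (!length(clinical_set)) clinical_set <- clin_names[1:2]
    featdf <- feat$pd
    featdf[continuous] <- feat$x[, continuous, drop = FALSE]
    weights <- feat$ridge$weights
    cfg <- config$hgnn
    cfg$seed <- child_seed(config$seed, "hgnn")
    labels <- feat$pd$outcome_class
    build_and_train <- function(cat_f, cont_f, kk) {
      hg <- build_multifeature_hypergraph(featdf, cont_f, cat_f,
                                          weights, k = kk)
      node_x <- as.matrix(feat$x[, c(cat_f, cont_f), drop = FALSE])
      ccfg <- cfg; ccfg$k <- as.integer(kk)
      hgnn_train_eval(hg, node_x, labels, feat$split, ccfg)
    }
    k_use <- config$k
    scan <- NULL
    if (!is.null(config$scan_k_grid)) {
      scan <- scan_k(featdf, continuous, categorical, weights,
                     as.matrix(feat$x[, sel, drop = FALSE]), labels,
                     feat$split, cfg, k_grid = config$scan_k_grid)
      k_use <- scan$k_best
    }
    combined <- build_and_train(categorical, continuous, k_use)
    clin_cat <- intersect(clinical_set, clin_names)
    clin_cont <- setdiff(clinical_set, clin_names)
    clinical <- build_and_train(clin_cat, clin_cont, k_use)
    jsonlite::write_json(
      list(k = k_use,
           combined = list(auc = combined$auc,
                           sensitivity = combined$sensitivity,
                           specificity = combined$specificity),
           clinical = list(auc = clinical$auc,
                           sensitivity = clinical$sensitivity,
                           specificity = clinical$specificity)),
      file.path(config$out_dir, "classification.json"), auto_unbox = TRUE,
      digits = NA)
    list(k = k_use, combined = combined, clinical = clinical, scan = scan)
  })

  # --- manifest ------------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_repr <- config
  cfg_repr$volumes <- if (is.null(config$volumes)) NULL else names(config$volumes)
  cfg_repr$fd_table <- if (is.character(config$fd_table)) config$fd_table
                       else if (!is.null(config$fd_table)) "inline" else NULL
  cfg_repr$out_dir <- NULL  # the hash must not depend on the scratch path
  jsonlite::write_json(lapply(cfg_repr, function(z)
    if (inherits(z, "cohort_spec") || inherits(z, "hgnn_config"))
      unclass(z) else z),
    cfg_path, auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("fractaldbs")),
    config_hash = unname(tools::md5sum(cfg_path)),
    master_seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(c("cohort", "validation_cohort", "split", "lasso", "ridge",
               "hgnn"), function(s) child_seed(config$seed, s)),
      c("cohort", "validation_cohort", "split", "lasso", "ridge", "hgnn")),
    stages_completed = stages,
    counts = counts,
    synthetic = synthetic,
    selected_alpha = feat$selection$alpha,
    k = hyper$k,
    combined_auc = hyper$combined$auc,
    clinical_auc = hyper$clinical$auc,
    n_significant_regions = if (!is.null(validation))
      sum(validation$group_compare$significant) else NA,
    r2_clinical = if (!is.null(variance)) variance$all$r2_1 else NA,
    r2_combined = if (!is.null(variance)) variance$all$r2_2 else NA,
    f_statistic = if (!is.null(variance)) variance$all$f_statistic else NA
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
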