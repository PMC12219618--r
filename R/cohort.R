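# Synthetic cohort generator: regional FD tables with planted group-level
# shifts, clinical covariates matching the target marginals of a DBS
# cohort, and a percent-LEDD-change outcome generated from a known linear
# model plus Gaussian noise. Everything downstream of image processing can
# be exercised on these cohorts with full knowledge of the ground truth.

#' Specification of a synthetic cohort
#'
#' Defaults emulate the clinical marginals of a DBS surgical cohort: age
#' 65 +/- 9 years, 33% female, 58% GPi target, 80% bilateral implants,
#' preoperative motor improvement 53 +/- 16%, and a percent LEDD change of
#' 23 +/- 36. Regional FD values are drawn around a cortical baseline of
#' 2.4 and a subcortical baseline of 2.2 (SD 0.08) with optional
#' exchangeable correlation, and a Cohen's-d shift is planted in
#' `effect_regions` for the PD group when healthy controls are present.
#'
#' @param n_subjects cohort size.
#' @param n_regions number of FD regions (default 90; the last 12 use the
#'   subcortical baseline).
#' @param pd_fraction fraction of subjects labelled PD (1 = a pure patient
#'   cohort; < 1 adds healthy controls who carry no clinical outcome).
#' @param effect_regions integer region indices given a PD-vs-HC shift.
#' @param effect_size_d planted standardized shift (Cohen's d).
#' @param age_mean,age_sd,female_fraction,gpi_fraction,bilateral_fraction,motor_mean,motor_sd
#'   clinical marginals.
#' @param delta_mean,delta_sd target mean and SD of the percent LEDD
#'   change.
#' @param outcome_coefficients named numeric vector of linear-model
#'   coefficients on standardized features (names among `target`,
#'   `laterality`, `age_at_mri`, `motor_improvement_pct`, `sex`, and
#'   `region_###`). `NULL` gives a default model with effects of the DBS
#'   target, laterality, age, motor improvement and 16 FD regions.
#' @param fd_baseline_cortical,fd_baseline_subcortical,fd_sd regional FD
#'   distribution parameters.
#' @param rho exchangeable correlation among regional FD values.
#' @param seed RNG seed; the generator is fully reproducible.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 231L, n_regions = 90L,
                        pd_fraction = 1, effect_regions = integer(0),
                        effect_size_d = 1,
                        age_mean = 65, age_sd = 9, female_fraction = 0.33,
                        gpi_fraction = 0.58, bilateral_fraction = 0.80,
                        motor_mean = 53, motor_sd = 16,
                        delta_mean = 23, delta_sd = 36,
                        outcome_coefficients = NULL,
                        fd_baseline_cortical = 2.4,
                        fd_baseline_subcortical = 2.2,
                        fd_sd = 0.08, rho = 0.2, seed = 1L) {
  if (any(effect_regions > n_regions)) {
    stop("effect region index exceeds n_regions")
  }
  stopifnot(pd_fraction >= 0, pd_fraction <= 1, female_fraction >= 0,
            female_fraction <= 1, gpi_fraction >= 0, gpi_fraction <= 1,
            bilateral_fraction >= 0, bilateral_fraction <= 1,
            delta_sd > 0, fd_sd > 0, rho >= 0, rho < 1)
  if (is.null(outcome_coefficients)) {
    fd_regions <- seq(5L, by = 5L, length.out = 16L)
    fd_regions <- fd_regions[fd_regions <= n_regions]
    co <- c(target = 12, laterality = 5, age_at_mri = -3,
            motor_improvement_pct = 5,
            stats::setNames(rep(c(4, -4), length.out = length(fd_regions)),
                            sprintf("region_%03d", fd_regions)))
    outcome_coefficients <- co
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws regional FD, clinical covariates and the planted linear outcome
#' described by a [cohort_spec()]. The outcome noise SD is solved from the
#' requested marginal SD of the percent LEDD change given the realized
#' variance of the linear predictor, and values are capped at 100 (a
#' post-operative dose cannot be negative). LEDD pre/post doses consistent
#' with the generated percent change are back-filled.
#'
#' @param spec a [cohort_spec()].
#' @return List: `fd_table` (long data frame `subject_id`, `region`,
#'   `fd`), `subjects` (one row per subject with clinical covariates,
#'   `ledd_pre`, `ledd_post`, `delta_ledd_pct`, `outcome_class`), `group`
#'   (named PD/HC vector), `truth` (planted coefficients, effect regions,
#'   noise SD).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_subjects
  p <- spec$n_regions
  ids <- sprintf("sub_%03d", seq_len(n))
  n_pd <- round(spec$pd_fraction * n)
  group <- stats::setNames(rep(c("PD", "HC"), c(n_pd, n - n_pd)), ids)

  # regional FD: baseline + exchangeable correlation + planted PD shift
  n_subcort <- min(12L, p)
  baseline <- c(rep(spec$fd_baseline_cortical, p - n_subcort),
                rep(spec$fd_baseline_subcortical, n_subcort))
  u <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * p), n, p)
  z <- sqrt(spec$rho) * u + sqrt(1 - spec$rho) * eps
  fd <- sweep(z * spec$fd_sd, 2L, baseline, "+")
  if (length(spec$effect_regions) && n_pd > 0 && n_pd < n) {
    shift <- spec$effect_size_d * spec$fd_sd
    fd[group == "PD", spec$effect_regions] <-
      fd[group == "PD", spec$effect_regions] + shift
  }
  region_names <- sprintf("region_%03d", seq_len(p))
  colnames(fd) <- region_names

  # clinical covariates
  subjects <- data.frame(
    subject_id = ids,
    age_at_mri = stats::rnorm(n, spec$age_mean, spec$age_sd),
    sex = ifelse(stats::runif(n) < spec$female_fraction, "female", "male"),
    target = ifelse(stats::runif(n) < spec$gpi_fraction, "GPi", "STN"),
    laterality = ifelse(stats::runif(n) < spec$bilateral_fraction,
                        "bilateral", "unilateral"),
    motor_improvement_pct = stats::rnorm(n, spec$motor_mean, spec$motor_sd),
    stringsAsFactors = FALSE
  )

  # outcome: linear model on standardized features + noise, PD only
  feats <- cbind(encode_clinical(subjects[, c("sex", "target", "laterality")]),
                 age_at_mri = subjects$age_at_mri,
                 motor_improvement_pct = subjects$motor_improvement_pct,
                 fd)
  fm <- as.matrix(feats)
  fs <- scale(fm)
  fs[, attr(fs, "scaled:scale") == 0] <- 0  # degenerate marginals at tiny n
  co <- spec$outcome_coefficients
  missing_co <- setdiff(names(co), colnames(fs))
  if (length(missing_co)) stop("unknown outcome coefficient(s): ",
                               paste(missing_co, collapse = ", "))
  lp <- as.vector(fs[, names(co), drop = FALSE] %*% co)
  var_lp <- stats::var(lp)
  noise_sd <- sqrt(max(spec$delta_sd^2 - var_lp, (0.1 * spec$delta_sd)^2))
  delta <- spec$delta_mean + lp + stats::rnorm(n, 0, noise_sd)
  delta <- pmin(delta, 100)
  is_pd <- group == "PD"
  subjects$delta_ledd_pct <- ifelse(is_pd, delta, NA_real_)
  subjects$ledd_pre <- ifelse(is_pd, round(stats::rlnorm(n, log(1100), 0.35)), NA)
  subjects$ledd_post <- ifelse(
    is_pd, subjects$ledd_pre * (1 - subjects$delta_ledd_pct / 100), NA)
  subjects$outcome_class <- factor(NA, levels = c("no-decrease", "decrease"))
  subjects$outcome_class[is_pd] <- classify_outcome(delta[is_pd])
  subjects[!is_pd, c("target", "laterality", "motor_improvement_pct")] <- NA

  fd_table <- data.frame(
    subject_id = rep(ids, each = p),
    region = rep(region_names, times = n),
    fd = as.vector(t(fd)),
    stringsAsFactors = FALSE
  )
  list(fd_table = fd_table, subjects = subjects, group = group,
       truth = list(coefficients = co, effect_regions = spec$effect_regions,
                    effect_size_d = spec$effect_size_d,
                    noise_sd = noise_sd, spec = spec))
}

#' Wide subjects x regions FD matrix from a long FD table
#'
#' @param fd_table long data frame `subject_id`, `region`, `fd`.
#' @return Numeric matrix, rownames subject ids, colnames regions.
#' @export
fd_wide <- function(fd_table) {
  if (anyDuplicated(fd_table[, c("subject_id", "region")])) {
    stop("duplicate (subject, region) pairs")
  }
  ids <- unique(fd_table$subject_id)
  regions <- unique(fd_table$region)
  m <- matrix(NA_real_, length(ids), length(regions),
              dimnames = list(ids, regions))
  m[cbind(match(fd_table$subject_id, ids),
          match(fd_table$region, regions))] <- fd_table$fd
  m
}
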