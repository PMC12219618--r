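# Levodopa equivalent daily dose (LEDD) accounting and the percent-change
# outcome used to label DBS response: a positive delta means the patient
# reduced dopaminergic medication after surgery.

#' Built-in levodopa-equivalence conversion factors
#'
#' Literature-style conversion factors for common antiparkinsonian drugs.
#' These are defaults, fully overridable via the `factors` argument of
#' [compute_ledd()] or a two-column TSV (`drug_name`, `conversion_factor`).
#' Entacapone is handled specially: it contributes 0.33 times the
#' concomitant immediate-release levodopa dose rather than its own dose.
#'
#' @return Data frame with columns `drug_name`, `conversion_factor`.
#' @export
ledd_conversion_factors <- function() {
  data.frame(
    drug_name = c("levodopa", "levodopa_cr", "pramipexole", "ropinirole",
                  "rotigotine", "rasagiline", "selegiline", "amantadine",
                  "entacapone"),
    conversion_factor = c(1.0, 0.75, 100, 20, 30, 100, 10, 1.0, 0.33),
    stringsAsFactors = FALSE
  )
}

#' Read a conversion-factor table from TSV
#' @param path two-column TSV (`drug_name`, `conversion_factor`).
#' @return Data frame usable as `factors` in [compute_ledd()].
#' @export
read_conversion_factors <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug_name", "conversion_factor") %in% names(tab))) {
    stop("factor table needs columns drug_name, conversion_factor")
  }
  if (any(tab$conversion_factor <= 0)) stop("conversion factors must be > 0")
  tab
}

#' Total levodopa equivalent daily dose for one medication schedule
#'
#' Sums `daily_dose * conversion_factor` over all entries. Entries may
#' carry their own `conversion_factor`; otherwise it is looked up by
#' `drug_name` in `factors`. Entacapone contributes
#' `0.33 * (total immediate-release levodopa daily dose)` irrespective of
#' its own tablet dose, following the usual adjunct rule.
#'
#' @param entries data frame with columns `drug_name`, `daily_dose` (mg/day)
#'   and optionally `conversion_factor`. An empty schedule gives 0.
#' @param factors conversion table, default [ledd_conversion_factors()].
#' @return LEDD in mg levodopa-equivalent per day.
#' @export
compute_ledd <- function(entries, factors = ledd_conversion_factors()) {
  if (is.null(entries) || nrow(entries) == 0L) return(0)
  if (any(!is.finite(entries$daily_dose)) || any(entries$daily_dose < 0)) {
    stop("daily_dose must be finite and >= 0")
  }
  if (!"conversion_factor" %in% names(entries)) {
    entries$conversion_factor <- NA_real_
  }
  need <- is.na(entries$conversion_factor)
  if (any(need)) {
    m <- match(tolower(entries$drug_name[need]), tolower(factors$drug_name))
    if (anyNA(m)) {
      stop("no conversion factor for: ",
           paste(unique(entries$drug_name[need][is.na(m)]), collapse = ", "))
    }
    entries$conversion_factor[need] <- factors$conversion_factor[m]
  }
  if (any(entries$conversion_factor <= 0)) stop("conversion factors must be > 0")
  is_enta <- tolower(entries$drug_name) == "entacapone"
  ld <- sum(entries$daily_dose[tolower(entries$drug_name) == "levodopa"])
  base <- sum(entries$daily_dose[!is_enta] * entries$conversion_factor[!is_enta])
  enta <- if (any(is_enta)) 0.33 * ld else 0
  base + enta
}

#' Percent pre-to-post change in LEDD
#'
#' `100 * (ledd_pre - ledd_post) / ledd_pre`; positive values mean the
#' daily medication dose decreased after DBS. The value is bounded above
#' by 100 (post dose cannot be negative) and is scale-invariant in the
#' common dose unit.
#'
#' @param ledd_pre pre-surgery LEDD, mg/day, must be > 0.
#' @param ledd_post post-surgery LEDD, mg/day, >= 0.
#' @return Percent change (vectorized).
#' @export
delta_ledd <- function(ledd_pre, ledd_post) {
  if (any(!is.finite(ledd_pre)) || any(ledd_pre <= 0)) {
    stop("ledd_pre must be finite and > 0 (ratio undefined otherwise)")
  }
  if (any(!is.finite(ledd_post)) || any(ledd_post < 0)) {
    stop("ledd_post must be finite and >= 0")
  }
  100 * (ledd_pre - ledd_post) / ledd_pre
}

#' Binary DBS outcome class from percent LEDD change
#'
#' Patients with a change less than or equal to 0 (medication unchanged or
#' increased) form the `"no-decrease"` group; those with a positive change
#' form the `"decrease"` group.
#'
#' @param delta_ledd_pct percent change from [delta_ledd()] (vectorized).
#' @return Factor with levels `no-decrease`, `decrease`.
#' @export
classify_outcome <- function(delta_ledd_pct) {
  if (any(!is.finite(delta_ledd_pct))) {
    stop("delta_ledd_pct must be finite")
  }
  factor(ifelse(delta_ledd_pct > 0, "decrease", "no-decrease"),
         levels = c("no-decrease", "decrease"))
}

#' Select the pre- and post-DBS LEDD visits for each subject
#'
#' The pre visit is the latest visit strictly before the surgery date; the
#' post visit is the one nearest to 6 months after surgery, ties resolved
#' toward the later visit.
#'
#' @param visits data frame: `subject_id`, `visit_date` (Date or
#'   parseable), `ledd` (mg/day).
#' @param surgery_dates data frame: `subject_id`, `surgery_date`.
#' @return Data frame: `subject_id`, `ledd_pre`, `ledd_post`,
#'   `delta_ledd_pct`, `outcome_class`; subjects lacking a usable pre or
#'   post visit are returned with `NA` and reported via a message.
#' @export
select_ledd_visits <- function(visits, surgery_dates) {
  visits$visit_date <- as.Date(visits$visit_date)
  surgery_dates$surgery_date <- as.Date(surgery_dates$surgery_date)
  out <- lapply(seq_len(nrow(surgery_dates)), function(i) {
    sid <- surgery_dates$subject_id[i]
    sd <- surgery_dates$surgery_date[i]
    v <- visits[visits$subject_id == sid, , drop = FALSE]
    pre <- v[v$visit_date < sd, , drop = FALSE]
    post <- v[v$visit_date >= sd, , drop = FALSE]
    ledd_pre <- if (nrow(pre)) pre$ledd[which.max(as.numeric(pre$visit_date))] else NA_real_
    ledd_post <- if (nrow(post)) {
      months <- as.numeric(post$visit_date - sd) / 30.44
      gap <- abs(months - 6)
      # ties toward the later visit
      best <- which(gap == min(gap))
      post$ledd[best[which.max(as.numeric(post$visit_date[best]))]]
    } else NA_real_
    data.frame(subject_id = sid, ledd_pre = ledd_pre, ledd_post = ledd_post)
  })
  out <- do.call(rbind, out)
  ok <- !is.na(out$ledd_pre) & !is.na(out$ledd_post) & out$ledd_pre > 0
  out$delta_ledd_pct <- NA_real_
  out$delta_ledd_pct[ok] <- delta_ledd(out$ledd_pre[ok], out$ledd_post[ok])
  out$outcome_class <- factor(NA, levels = c("no-decrease", "decrease"))
  out$outcome_class[ok] <- classify_outcome(out$delta_ledd_pct[ok])
  if (any(!ok)) {
    message(sum(!ok), " subject(s) lack a usable pre or post visit")
  }
  out
}
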