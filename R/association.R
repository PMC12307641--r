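Z95 <- 1.959964

assoc_row <- function(model, stratum = NA_character_, estimate = NA_real_,
                      se = NA_real_, p = NA_real_, n = NA_integer_,
                      n_events = NA_integer_, flags = "") {
  data.frame(
    model = model, stratum = stratum,
    estimate = estimate, se = se,
    or = exp(estimate),
    ci_low = exp(estimate - Z95 * se),
    ci_high = exp(estimate + Z95 * se),
    p = p, n = n, n_events = n_events, flags = flags,
    stringsAsFactors = FALSE
  )
}

#' Crude odds ratio from a 2 x 2 table
#'
#' Computes `OR = ad/bc` with the Wald standard error of the log odds ratio
#' `sqrt(1/a + 1/b + 1/c + 1/d)`, a 95% CI on the OR scale and a two-tailed
#' Wald p-value. If any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe) and the result is flagged `"haldane"`. If a full row
#' or column of the original table is zero the odds ratio is undefined: the
#' estimate is returned as `NA` with `p = 1` and flag `"undefined"`.
#'
#' @param tab 2 x 2 matrix; rows index exposure, columns outcome, so
#'   `tab[1,1]` is exposed cases.
#' @return one-row data.frame: `model, stratum, estimate` (log OR), `se,
#'   or, ci_low, ci_high, p, n, n_events, flags`.
#' @export
or_from_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L, ncol(tab) == 2L, all(tab >= 0))
  n <- sum(tab)
  n_events <- sum(tab[, 1L])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out <- assoc_row("crude_or", estimate = NA_real_, se = NA_real_, p = 1,
                     n = as.integer(n), n_events = as.integer(n_events),
                     flags = "undefined")
    return(out)
  }
  flags <- ""
  if (any(tab == 0)) {
    tab <- tab + 0.5
    flags <- "haldane"
  }
  est <- log(tab[1L, 1L]) + log(tab[2L, 2L]) - log(tab[1L, 2L]) - log(tab[2L, 1L])
  se <- sqrt(sum(1 / tab))
  p <- 2 * stats::pnorm(-abs(est / se))
  assoc_row("crude_or", estimate = est, se = se, p = p,
            n = as.integer(n), n_events = as.integer(n_events), flags = flags)
}

#' Logistic regression with Wald inference and degeneracy flags
#'
#' Fits a binomial-logit model of a binary outcome on a named covariate
#' matrix by maximum likelihood (iteratively reweighted least squares, as
#' implemented in [stats::glm()], tight convergence tolerance, at most 50
#' iterations). Rows with any missing value are dropped (complete-case) and
#' the dropped count is recorded. Non-convergence or fitted probabilities
#' pinned at 0/1 (separation) are flagged rather than silently reported.
#'
#' @param outcome binary (0/1 or logical) response vector.
#' @param design numeric matrix or data.frame of covariates with named
#'   columns; an intercept is added internally.
#' @return data.frame with one row per coefficient (including
#'   `(Intercept)`): `term, estimate` (log OR), `se, or, ci_low, ci_high, p,
#'   n, n_events, flags`, with attribute `n_dropped` (complete-case drops).
#' @export
fit_logistic <- function(outcome, design) {
  design <- as.data.frame(design)
  if (is.null(names(design)) || any(!nzchar(names(design)))) {
    stop("design columns must be named")
  }
  outcome <- as.numeric(outcome)
  stopifnot(length(outcome) == nrow(design), all(outcome %in% c(0, 1, NA)))
  keep <- stats::complete.cases(outcome, design)
  n_dropped <- sum(!keep)
  y <- outcome[keep]
  x <- design[keep, , drop = FALSE]
  if (length(y) <= ncol(x) + 1L) stop("fewer observations than parameters")

  flags <- character(0)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, x), family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        flags <<- union(flags, "separation")
        invokeRestart("muffleWarning")
      } else if (grepl("did not converge", conditionMessage(w))) {
        flags <<- union(flags, "non_convergence")
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) flags <- union(flags, "non_convergence")
  if (length(unique(y)) < 2L) flags <- union(flags, "separation")
  sm <- summary(fit)$coefficients
  flag_str <- paste(flags, collapse = ",")
  out <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    or = exp(sm[, "Estimate"]),
    ci_low = exp(sm[, "Estimate"] - Z95 * sm[, "Std. Error"]),
    ci_high = exp(sm[, "Estimate"] + Z95 * sm[, "Std. Error"]),
    p = 2 * stats::pnorm(-abs(sm[, "Estimate"] / sm[, "Std. Error"])),
    n = length(y),
    n_events = sum(y == 1),
    flags = flag_str,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

merge_calls_pheno <- function(pheno, calls) {
  stopifnot("sample_id" %in% names(pheno), "sample_id" %in% names(calls),
            "call" %in% names(calls))
  m <- merge(pheno, calls[c("sample_id", "call")], by = "sample_id")
  if (nrow(m) == 0L) stop("no overlapping sample ids between phenotypes and calls")
  m
}

#' Adjusted association of each treatment modality with mLOY
#'
#' One logistic model per treatment flag, `call ~ treatment + covariates`
#' (separate models, not one joint fit). For multi-site/multi-cohort input
#' the models are fitted within each cohort-by-site stratum, and sites whose
#' total sample count is at or below `min_site_n` are skipped (recorded in
#' the `skipped` attribute), the usual "sufficient number of patients" rule.
#'
#' @param pheno phenotype data.frame (needs `sample_id`, the treatment
#'   columns and the adjustment covariates; `cohort` and `site` if present
#'   define strata).
#' @param calls data.frame with `sample_id` and logical `call`.
#' @param treatments character vector of binary treatment column names.
#' @param covariates adjustment covariate column names.
#' @param min_site_n minimum per-site sample count (summed over cohorts) for
#'   a site to be analysed; only applied when more than one site is present.
#' @return data.frame of per-treatment rows (`model` = treatment name,
#'   `stratum` = "cohort/site"), with attribute `skipped` naming skipped
#'   sites.
#' @export
treatment_associations <- function(pheno, calls,
                                   treatments = c("rt", "endocrine", "surgery"),
                                   covariates = c("age", "smoking"),
                                   min_site_n = 1000) {
  dat <- merge_calls_pheno(pheno, calls)
  for (tr in treatments) {
    if (!tr %in% names(dat)) stop("treatment column not found: ", tr)
    if (all(is.na(dat[[tr]]))) stop("treatment column is entirely missing: ", tr)
  }
  site <- if ("site" %in% names(dat)) dat$site else "all"
  cohort <- if ("cohort" %in% names(dat)) dat$cohort else "all"
  skipped <- character(0)
  if (length(unique(site)) > 1L) {
    site_n <- table(site)
    small <- names(site_n)[site_n <= min_site_n]
    if (length(small)) {
      skipped <- small
      keep <- !site %in% small
      dat <- dat[keep, , drop = FALSE]
      site <- site[keep]; cohort <- cohort[keep]
    }
  }
  strata <- interaction(cohort, site, sep = "/", drop = TRUE)
  rows <- list()
  for (st in levels(strata)) {
    d <- dat[strata == st, , drop = FALSE]
    for (tr in treatments) {
      fit <- fit_logistic(d$call, d[, c(tr, covariates), drop = FALSE])
      row <- fit[fit$term == tr, , drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(model = tr, stratum = st, row[-1L],
                                         stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    assoc_row("none")[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Time-since-radiotherapy stratified association
#'
#' Fits a single logistic model with two indicators — radiotherapy completed
#' less than `cutoff_years` before sampling, and radiotherapy completed at
#' least `cutoff_years` before — against the never-irradiated reference
#' group, plus the adjustment covariates. A sample exactly at the cutoff
#' falls in the later (">=") stratum. Irradiated samples with missing
#' `years_since_rt` are dropped from this analysis (count in attribute
#' `n_dropped_time`).
#'
#' @inheritParams treatment_associations
#' @param cutoff_years stratum boundary in years.
#' @return data.frame with rows `rt_recent` (< cutoff) and `rt_late`
#'   (>= cutoff); a stratum with no samples yields a flagged `empty_stratum`
#'   row instead of an estimate.
#' @export
time_stratified <- function(pheno, calls, cutoff_years = 1,
                            covariates = c("age", "smoking")) {
  dat <- merge_calls_pheno(pheno, calls)
  stopifnot(all(c("rt", "years_since_rt") %in% names(dat)))
  bad_time <- dat$rt == 1 & is.na(dat$years_since_rt)
  n_dropped_time <- sum(bad_time)
  dat <- dat[!bad_time, , drop = FALSE]
  recent <- as.numeric(dat$rt == 1 & dat$years_since_rt < cutoff_years)
  late <- as.numeric(dat$rt == 1 & dat$years_since_rt >= cutoff_years)
  empty <- c(rt_recent = sum(recent) == 0, rt_late = sum(late) == 0)
  design <- cbind(data.frame(rt_recent = recent, rt_late = late),
                  dat[, covariates, drop = FALSE])
  design <- design[, c(!empty, rep(TRUE, length(covariates))), drop = FALSE]
  rows <- list()
  if (!all(empty)) {
    fit <- fit_logistic(dat$call, design)
    for (term in c("rt_recent", "rt_late")[!empty]) {
      row <- fit[fit$term == term, , drop = FALSE]
      rows[[term]] <- cbind(model = "time_stratified", stratum = term,
                            row[-1L], stringsAsFactors = FALSE)
    }
  }
  for (term in names(empty)[empty]) {
    rows[[term]] <- assoc_row("time_stratified", stratum = term,
                              flags = "empty_stratum")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_dropped_time") <- n_dropped_time
  out[match(c("rt_recent", "rt_late"), out$stratum), , drop = FALSE]
}

#' Per-Gy dose-response within one radiotherapy modality
#'
#' Restricted to samples irradiated with the given modality, fits
#' `call ~ dose_gy + covariates` and reports the exponentiated per-Gy odds
#' ratio. Modalities with fewer than `min_n` samples are refused (the
#' small-cell exclusion rule); zero dose variance is flagged `degenerate`.
#'
#' @inheritParams treatment_associations
#' @param modality value of `pheno$rt_modality` to restrict to.
#' @param min_n minimum number of samples in the modality.
#' @return one-row data.frame (per-Gy log OR scale) or a flagged row.
#' @export
dose_response <- function(pheno, calls, modality,
                          covariates = c("age", "smoking"), min_n = 10) {
  dat <- merge_calls_pheno(pheno, calls)
  stopifnot(all(c("rt", "rt_modality", "dose_gy") %in% names(dat)))
  d <- dat[dat$rt == 1 & !is.na(dat$rt_modality) & dat$rt_modality == modality, ,
           drop = FALSE]
  if (nrow(d) < min_n) {
    message("modality `", modality, "` has n = ", nrow(d), " < ", min_n,
            "; excluded from dose-response analysis")
    return(assoc_row(paste0("dose_response_", modality), stratum = modality,
                     n = nrow(d), flags = "excluded_small_n"))
  }
  if (length(unique(d$dose_gy[!is.na(d$dose_gy)])) < 2L) {
    return(assoc_row(paste0("dose_response_", modality),
                     stratum = modality, flags = "degenerate_dose"))
  }
  fit <- fit_logistic(d$call, d[, c("dose_gy", covariates), drop = FALSE])
  row <- fit[fit$term == "dose_gy", , drop = FALSE]
  out <- cbind(model = paste0("dose_response_", modality), stratum = modality,
               row[-1L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Linear trend of mLRR-Y on age
#'
#' Ordinary least squares of the mLRR-Y signal on age in years, with a
#' two-tailed t-test on the slope. In aging cohorts the slope is expected
#' to be negative: older men carry larger Y-loss clones on average.
#'
#' @param signals data.frame with an `mlrry` column (or a numeric vector).
#' @param ages numeric vector of ages, same length.
#' @return list with `intercept`, `slope` (mLRR-Y per year), `p_slope`.
#' @export
age_trend <- function(signals, ages) {
  y <- if (is.data.frame(signals)) signals$mlrry else signals
  stopifnot(is.numeric(y), is.numeric(ages), length(y) == length(ages))
  keep <- stats::complete.cases(y, ages)
  y <- y[keep]; ages <- ages[keep]
  if (length(y) < 3L) stop("age trend needs at least 3 complete observations")
  if (stats::var(ages) == 0) stop("zero age variance")
  fit <- stats::lm(y ~ ages)
  sm <- summary(fit)$coefficients
  list(intercept = unname(sm[1L, 1L]), slope = unname(sm[2L, 1L]),
       p_slope = unname(sm[2L, 4L]))
}

#' Baseline-characteristic table with Fisher exact p-values
#'
#' Cross-tabulates each categorical characteristic against the mLOY call,
#' dropping samples with a missing category (so columns need not sum to the
#' overall called/uncalled totals), and attaches the exact r x c p-value.
#'
#' @inheritParams treatment_associations
#' @param characteristics character vector of categorical phenotype columns.
#' @return data.frame `characteristic, category, n_mloy, n_non_mloy,
#'   fisher_p` (p repeated across the categories of one characteristic).
#' @export
table1_summary <- function(pheno, calls, characteristics) {
  dat <- merge_calls_pheno(pheno, calls)
  rows <- lapply(characteristics, function(ch) {
    if (!ch %in% names(dat)) stop("characteristic column not found: ", ch)
    d <- dat[!is.na(dat[[ch]]), , drop = FALSE]
    tab <- table(factor(d[[ch]]), factor(d$call, levels = c(TRUE, FALSE)))
    p <- fisher_exact_rxc(unclass(tab))
    data.frame(characteristic = ch, category = rownames(tab),
               n_mloy = as.integer(tab[, 1L]),
               n_non_mloy = as.integer(tab[, 2L]),
               fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
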