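#' Sample-level quality-control filter
#'
#' Excludes samples by two missingness rules applied to the LRR matrix:
#' the MSY rule drops samples missing more than `max_msy_missing` of the
#' probes in the male-specific region of chromosome Y, and the call-rate
#' rule drops samples missing more than `max_overall_missing` of all probes.
#' Both comparisons are strict (`>`), mirroring the usual phrasing "more
#' than 1%" / "exceeding 5%"; a sample at exactly the threshold is kept.
#'
#' @param lrr samples-by-probes numeric matrix, `NA` = missing.
#' @param manifest probe manifest (see [read_manifest()]).
#' @param max_msy_missing maximum tolerated missing fraction over MSY probes.
#' @param max_overall_missing maximum tolerated missing fraction over all
#'   probes.
#' @return list with `lrr` (the retained rows) and `report`, a data.frame
#'   with one row per input sample: `sample_id, msy_missing_fraction,
#'   overall_missing_fraction, passed, reason` (reason `""` when passed;
#'   otherwise `"msy_missing"`, `"overall_missing"` or both,
#'   comma-separated).
#' @export
qc_filter <- function(lrr, manifest, max_msy_missing = 0.01,
                      max_overall_missing = 0.05) {
  if (is.matrix(lrr) && nrow(lrr) == 0L) stop("empty LRR matrix")
  validate_lrr(lrr, manifest)
  stopifnot(max_msy_missing > 0, max_msy_missing <= 1,
            max_overall_missing > 0, max_overall_missing <= 1)
  msy_ids <- manifest$probe_id[manifest$is_msy]
  msy <- lrr[, colnames(lrr) %in% msy_ids, drop = FALSE]
  if (ncol(msy) == 0L) stop("LRR matrix contains no MSY probes")

  msy_frac <- rowMeans(is.na(msy))
  all_frac <- rowMeans(is.na(lrr))
  fail_msy <- msy_frac > max_msy_missing
  fail_all <- all_frac > max_overall_missing
  reason <- character(nrow(lrr))
  reason[fail_msy] <- "msy_missing"
  reason[fail_all] <- ifelse(fail_msy[fail_all], "msy_missing,overall_missing",
                             "overall_missing")
  report <- data.frame(
    sample_id = rownames(lrr),
    msy_missing_fraction = msy_frac,
    overall_missing_fraction = all_frac,
    passed = !(fail_msy | fail_all),
    reason = reason,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(lrr = lrr[report$passed, , drop = FALSE], report = report)
}

#' Compute the median MSY log R ratio (mLRR-Y) per sample
#'
#' For each sample, takes the median of the non-missing log R ratios over
#' MSY probes; even counts use the midpoint of the two central order
#' statistics. Missing entries are ignored, never imputed. Intended to run
#' on QC-passed samples; a sample with zero non-missing MSY values is an
#' error (it should have been excluded by [qc_filter()]).
#'
#' @inheritParams qc_filter
#' @param cohort optional cohort label(s) (length 1 or one per sample)
#'   carried into the output for downstream per-cohort standardization.
#' @return data.frame `sample_id, cohort, mlrry, z` with `z` set to `NA`
#'   until [standardize_within_cohort()] is applied.
#' @export
compute_mlrry <- function(lrr, manifest, cohort = NA_character_) {
  validate_lrr(lrr, manifest)
  if (nrow(lrr) == 0L) stop("empty LRR matrix")
  msy_ids <- manifest$probe_id[manifest$is_msy]
  msy <- lrr[, colnames(lrr) %in% msy_ids, drop = FALSE]
  if (ncol(msy) == 0L) stop("LRR matrix contains no MSY probes")
  n_obs <- rowSums(!is.na(msy))
  if (any(n_obs == 0L)) {
    stop("sample(s) with no non-missing MSY probe (should have failed QC): ",
         paste(rownames(msy)[n_obs == 0L], collapse = ", "))
  }
  med <- if (anyNA(msy)) {
    apply(msy, 1L, function(v) stats::median(v[!is.na(v)]))
  } else {
    apply(msy, 1L, stats::median)
  }
  data.frame(
    sample_id = rownames(lrr),
    cohort = rep_len(cohort, nrow(lrr)),
    mlrry = unname(med),
    z = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Standardize mLRR-Y within each cohort
#'
#' Converts mLRR-Y to a per-cohort z-score, `z = (mlrry - cohort mean) /
#' cohort SD` with the n-1 sample SD, so that signal distributions from
#' different array platforms (which differ by location/scale) become
#' comparable. Each cohort must contain at least two samples and non-zero
#' spread.
#'
#' @param signals data.frame from [compute_mlrry()] (columns `sample_id,
#'   cohort, mlrry`).
#' @return the input with the `z` column filled; within each cohort
#'   `mean(z) == 0` and `sd(z) == 1` to numerical precision.
#' @export
standardize_within_cohort <- function(signals) {
  stopifnot(is.data.frame(signals),
            all(c("sample_id", "cohort", "mlrry") %in% names(signals)))
  signals$z <- NA_real_
  for (ch in unique(signals$cohort)) {
    idx <- which(signals$cohort %in% ch)
    x <- signals$mlrry[idx]
    if (length(x) < 2L) {
      stop("cohort ", ch, " has fewer than 2 samples; cannot standardize")
    }
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("degenerate cohort: ", ch,
                                      " has zero mLRR-Y variance")
    signals$z[idx] <- (x - mean(x)) / s
  }
  signals
}
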