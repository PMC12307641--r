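#' Call mLOY by an absolute mLRR-Y threshold
#'
#' A sample is called as carrying mosaic loss of chromosome Y when its
#' mLRR-Y is at or below the threshold (inclusive `<=`); the conventional
#' cutoff -0.15 corresponds to a Y-loss clone in roughly 10% of cells.
#'
#' @param signals data.frame from [compute_mlrry()] /
#'   [standardize_within_cohort()].
#' @param threshold absolute mLRR-Y cutoff.
#' @return the signals data.frame with logical column `call` and character
#'   column `scheme` added.
#' @export
call_absolute <- function(signals, threshold = -0.15) {
  stopifnot(is.data.frame(signals), "mlrry" %in% names(signals),
            nrow(signals) > 0L, is.numeric(threshold), length(threshold) == 1L)
  signals$call <- signals$mlrry <= threshold
  signals$scheme <- sprintf("absolute(%g)", threshold)
  signals
}

#' Call mLOY by a per-scope percentile threshold
#'
#' Within each scope (by default each cohort, so that platform-specific
#' location differences cannot leak across cohorts), the samples in the
#' bottom `q` tail of the signal distribution (lowest mLRR-Y) are called.
#' The cutoff is the k-th smallest signal with `k = ceiling(q * n)`; all
#' samples at or below the cutoff are called, so ties at the cutoff may
#' push the count above `k`.
#'
#' @inheritParams call_absolute
#' @param q top fraction to call, in `(0, 0.5]`.
#' @param scope `"cohort"` (percentile computed within each cohort) or
#'   `"pooled"` (one percentile over all samples).
#' @param value which signal column the percentile is taken over,
#'   `"mlrry"` or `"z"` (ranks coincide within a cohort; they differ only
#'   for pooled scope).
#' @return signals with logical `call`, numeric `cutoff` (the per-scope
#'   threshold on the chosen value scale) and character `scheme` columns.
#' @export
call_percentile <- function(signals, q = 0.01,
                            scope = c("cohort", "pooled"),
                            value = c("mlrry", "z")) {
  scope <- match.arg(scope)
  value <- match.arg(value)
  stopifnot(is.data.frame(signals), value %in% names(signals),
            is.numeric(q), length(q) == 1L, q > 0, q <= 0.5)
  if (nrow(signals) == 0L) stop("empty signal set")
  v <- signals[[value]]
  if (anyNA(v)) stop("signal column `", value, "` contains missing values")
  groups <- if (scope == "cohort") signals$cohort else rep("all", nrow(signals))
  signals$call <- NA
  signals$cutoff <- NA_real_
  for (g in unique(groups)) {
    idx <- which(groups %in% g)
    n <- length(idx)
    k <- ceiling(q * n)
    cut <- sort(v[idx], partial = k)[k]
    signals$call[idx] <- v[idx] <= cut
    signals$cutoff[idx] <- cut
  }
  signals$scheme <- sprintf("percentile(q=%g,scope=%s,value=%s)", q, scope, value)
  signals
}

#' Threshold sensitivity sweep
#'
#' Re-calls mLOY over a grid of percentile thresholds and, at each, computes
#' the crude 2x2 odds ratio of the call against a binary exposure
#' (typically radiotherapy). Rows where the exposed group contains fewer
#' than `min_exposed_events` called samples are retained in the output but
#' flagged `included = FALSE`, the usual stability rule for tail thresholds.
#'
#' @inheritParams call_percentile
#' @param exposure logical/0-1 vector aligned with `signals` rows.
#' @param q_grid percentile grid to sweep.
#' @param min_exposed_events minimum called-and-exposed count for a row to
#'   be marked included.
#' @return data.frame with one row per `q`: `q, cutoff, n_called,
#'   n_exposed_called, or, ci_low, ci_high, p, included` (`cutoff` is `NA`
#'   when the percentile is computed in more than one scope).
#' @export
sweep_thresholds <- function(signals, exposure,
                             q_grid = seq(0.01, 0.50, by = 0.01),
                             min_exposed_events = 10,
                             scope = c("cohort", "pooled"),
                             value = c("z", "mlrry")) {
  scope <- match.arg(scope)
  value <- match.arg(value)
  stopifnot(length(exposure) == nrow(signals))
  exposure <- as.logical(exposure)
  if (anyNA(exposure)) stop("exposure vector contains missing values")
  rows <- lapply(q_grid, function(q) {
    called <- call_percentile(signals, q = q, scope = scope, value = value)
    tab <- matrix(c(sum(called$call & exposure), sum(!called$call & exposure),
                    sum(called$call & !exposure), sum(!called$call & !exposure)),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(exposure = c("exposed", "unexposed"),
                                  mloy = c("call", "no_call")))
    or <- or_from_2x2(tab)
    data.frame(
      q = q,
      cutoff = if (length(unique(called$cutoff)) == 1L)
        called$cutoff[1L] else NA_real_,
      n_called = sum(called$call),
      n_exposed_called = sum(called$call & exposure),
      or = or$or, ci_low = or$ci_low, ci_high = or$ci_high, p = or$p,
      included = sum(called$call & exposure) >= min_exposed_events,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
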