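#' Reconstruct a log-OR standard error from a reported OR and 95% CI
#'
#' For Wald-type intervals the 95% CI is symmetric on the log scale, so
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`. This lets pooled
#' and subgroup analyses be reproduced from published odds ratios when
#' individual-level data are unavailable; rounding asymmetry in printed CIs
#' is absorbed by using both bounds.
#'
#' @param or_value reported odds ratio.
#' @param ci_low,ci_high reported 95% confidence limits
#'   (`0 < ci_low <= or_value <= ci_high`).
#' @param label optional estimate label.
#' @return one-row data.frame `label, log_or, se, source`
#'   (`source = "reconstructed-from-ci"`).
#' @export
#' @examples
#' se_from_ci(2.45, 1.00, 6.41)
se_from_ci <- function(or_value, ci_low, ci_high, label = NA_character_) {
  stopifnot(is.numeric(or_value), is.numeric(ci_low), is.numeric(ci_high))
  if (any(ci_low <= 0) || any(ci_low > or_value) || any(or_value > ci_high)) {
    stop("require 0 < ci_low <= or <= ci_high")
  }
  data.frame(label = label, log_or = log(or_value),
             se = (log(ci_high) - log(ci_low)) / (2 * Z95),
             source = "reconstructed-from-ci", stringsAsFactors = FALSE)
}

i2_band <- function(i2) {
  ifelse(i2 < 25, "low", ifelse(i2 <= 75, "moderate", "high"))
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools log odds ratios with weights `w_i = 1/se_i^2`:
#' `pooled = sum(w * theta) / sum(w)`, `se = sum(w)^-0.5`. Heterogeneity is
#' summarised by Cochran's `Q = sum(w * (theta - pooled)^2)` on `k - 1`
#' degrees of freedom, `I2 = max(0, (Q - df)/Q) * 100` (0 when `Q = 0`),
#' and the chi-square p-value (`p_het = 1` when `k = 1`). `I2` is reported
#' in percent and classified low / moderate / high at <25 / 25-75 / >75.
#'
#' @param estimates data.frame with columns `log_or` and `se` (e.g. from
#'   [se_from_ci()] or model fits), `se > 0`, `k >= 1` rows.
#' @return one-row data.frame: `k, log_or, se, or, ci_low, ci_high, p, Q,
#'   df, i2, i2_band, p_het`.
#' @export
fixed_effect <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("log_or", "se") %in% names(estimates)))
  k <- nrow(estimates)
  if (k == 0L) stop("no estimates to pool")
  if (any(!is.finite(estimates$se)) || any(estimates$se <= 0)) {
    stop("all standard errors must be finite and positive")
  }
  w <- estimates$se^-2
  pooled <- sum(w * estimates$log_or) / sum(w)
  se <- sum(w)^-0.5
  q <- sum(w * (estimates$log_or - pooled)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  p_het <- if (k == 1L) 1 else stats::pchisq(q, df, lower.tail = FALSE)
  data.frame(
    k = k, log_or = pooled, se = se, or = exp(pooled),
    ci_low = exp(pooled - Z95 * se), ci_high = exp(pooled + Z95 * se),
    p = 2 * stats::pnorm(-abs(pooled / se)),
    Q = q, df = df, i2 = i2, i2_band = i2_band(i2), p_het = p_het,
    stringsAsFactors = FALSE
  )
}

#' Two-level fixed-effect meta-analysis (cohorts within sites)
#'
#' Level 1 pools the cohort estimates within each site; level 2 pools the
#' per-site pooled estimates into the overall effect, whose heterogeneity
#' statistics (`Q`, `df = n_sites - 1`, `I2`, `p_het`) describe
#' between-site consistency. Because inverse-variance weighting is
#' associative, the pooled value and SE are identical to single-level
#' pooling of all cohort estimates; only the heterogeneity partition
#' differs.
#'
#' @param estimates data.frame with columns `site`, `log_or`, `se` (one row
#'   per cohort estimate; a `label` column is carried through if present).
#' @return list with `per_site` (one [fixed_effect()] row per site, with a
#'   `site` column) and `overall` (the level-2 pooled row).
#' @export
two_level_meta <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("site", "log_or", "se") %in% names(estimates)))
  if (nrow(estimates) == 0L) stop("no estimates to pool")
  sites <- unique(estimates$site)
  per_site <- do.call(rbind, lapply(sites, function(s) {
    e <- estimates[estimates$site == s, , drop = FALSE]
    if (nrow(e) == 0L) stop("empty site group: ", s)
    cbind(site = s, fixed_effect(e), stringsAsFactors = FALSE)
  }))
  rownames(per_site) <- NULL
  overall <- fixed_effect(per_site)
  list(per_site = per_site, overall = overall)
}

#' Between-subgroup heterogeneity test for two effect estimates
#'
#' Two-sample z-test on the log-OR scale,
#' `z = (theta1 - theta2) / sqrt(se1^2 + se2^2)`, with a two-tailed normal
#' p-value; algebraically identical to Cochran's Q between two subgroups on
#' one degree of freedom.
#'
#' @param e1,e2 one-row data.frames with `log_or` and `se` (e.g. from
#'   [se_from_ci()]).
#' @return list with `z` and `p`.
#' @export
#' @examples
#' subgroup_heterogeneity(se_from_ci(2.45, 1.00, 6.41),
#'                        se_from_ci(3.11, 0.63, 12.15))
subgroup_heterogeneity <- function(e1, e2) {
  stopifnot(all(c("log_or", "se") %in% names(e1)),
            all(c("log_or", "se") %in% names(e2)),
            e1$se > 0, e2$se > 0)
  z <- (e1$log_or - e2$log_or) / sqrt(e1$se^2 + e2$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
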