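#' Conversion between clonal fraction and expected mLRR-Y
#'
#' Under the single-copy attenuation model, a sample in which a fraction
#' `f` of cells carry zero copies of chromosome Y has expected total-intensity
#' ratio `(1 - f)` at Y probes relative to the two-copy autosomal baseline of
#' one Y copy per male cell, hence an expected log R ratio of `log2(1 - f)`.
#' This makes the conventional absolute call threshold of mLRR-Y <= -0.15
#' interpretable as a clone occupying roughly 10% of sampled cells
#' (`1 - 2^-0.15 = 0.099`).
#'
#' @param f clonal fraction(s), in `[0, 1)`.
#' @return Expected mLRR-Y, `log2(1 - f)`; strictly decreasing in `f`.
#' @seealso [mlrry_to_fraction()] for the inverse.
#' @export
#' @examples
#' fraction_to_mlrry(c(0, 0.1, 0.5))
fraction_to_mlrry <- function(f) {
  if (!is.numeric(f)) stop("`f` must be numeric")
  if (any(is.na(f)) || any(f < 0) || any(f >= 1)) {
    stop("clonal fraction must satisfy 0 <= f < 1")
  }
  log2(1 - f)
}

#' @rdname fraction_to_mlrry
#' @param m mLRR-Y value(s); expected `m <= 0`. Positive values (possible
#'   under probe noise) are clamped to fraction 0 with a warning.
#' @return For `mlrry_to_fraction`, the implied clonal fraction `1 - 2^m`.
#' @export
mlrry_to_fraction <- function(m) {
  if (!is.numeric(m) || any(is.na(m))) stop("`m` must be numeric and non-missing")
  if (any(m > 0)) {
    warning("mLRR-Y above 0 clamped to clonal fraction 0")
    m[m > 0] <- 0
  }
  1 - 2^m
}

#' Simulation parameters for a synthetic mLOY cohort
#'
#' Builds a validated parameter set for [simulate_cohort()]. The defaults are
#' calibrated to the structure of saliva/blood SNP-array cohorts of elderly
#' male cancer patients: a minority of samples carry a detectable Y-loss
#' clone, clone carriage increases with age and with radiotherapy exposure,
#' and probe-level noise plus platform location shifts blur the signal.
#'
#' Clone carriage is Bernoulli on the logit scale,
#' `logit P(carrier) = clone_intercept + clone_beta_age * age +
#' clone_beta_rt * rt (+ optional recency/dose terms)`; carriers draw a cell
#' fraction `f ~ Beta(fraction_shape_a, fraction_shape_b)`, non-carriers have
#' `f = 0`. MSY probe LRRs are `Normal(log2(1 - f) + platform_shift,
#' sigma_probe)`; autosomal probes are `Normal(0, sigma_probe)`.
#'
#' @param n_samples number of samples.
#' @param n_msy_probes number of probes in the male-specific region of Y
#'   (MSY); must be at least 3.
#' @param n_autosomal_probes number of autosomal background probes.
#' @param age_mean,age_sd age distribution (years).
#' @param p_rt probability of radiotherapy exposure.
#' @param clone_intercept,clone_beta_age,clone_beta_rt coefficients on the
#'   logit of carrying a Y-loss clone (intercept; per year of age; for
#'   radiotherapy exposure).
#' @param clone_beta_rt_recent optional replacement for `clone_beta_rt`
#'   applied to samples irradiated less than one year before sampling
#'   (`NA` = no recency effect).
#' @param clone_beta_dose optional additional per-Gy coefficient applied to
#'   the total dose of irradiated samples (default 0).
#' @param fraction_shape_a,fraction_shape_b Beta parameters of the clone cell
#'   fraction given carriage.
#' @param sigma_probe per-probe LRR noise SD.
#' @param platform_shift additive mLRR-Y location offset for the cohort's
#'   platform.
#' @param p_missing per-entry probability of a missing LRR value.
#' @param p_smoking probability of ever-smoking (no effect on clone carriage
#'   by default; provided so adjusted models have their covariate).
#' @param seed integer seed; one RNG stream is derived per cohort from
#'   `seed + cohort_index` so adding a cohort does not perturb existing ones.
#' @return A validated `loy_sim_params` list.
#' @export
sim_params <- function(n_samples = 400L,
                       n_msy_probes = 100L,
                       n_autosomal_probes = 300L,
                       age_mean = 70, age_sd = 8,
                       p_rt = 0.3,
                       clone_intercept = -6.9,
                       clone_beta_age = 0.06,
                       clone_beta_rt = 0.9,
                       clone_beta_rt_recent = NA_real_,
                       clone_beta_dose = 0,
                       fraction_shape_a = 5,
                       fraction_shape_b = 15,
                       sigma_probe = 0.18,
                       platform_shift = 0,
                       p_missing = 0.002,
                       p_smoking = 0.5,
                       seed = 1L) {
  p <- list(
    n_samples = as.integer(n_samples),
    n_msy_probes = as.integer(n_msy_probes),
    n_autosomal_probes = as.integer(n_autosomal_probes),
    age_mean = age_mean, age_sd = age_sd,
    p_rt = p_rt,
    clone_intercept = clone_intercept,
    clone_beta_age = clone_beta_age,
    clone_beta_rt = clone_beta_rt,
    clone_beta_rt_recent = clone_beta_rt_recent,
    clone_beta_dose = clone_beta_dose,
    fraction_shape_a = fraction_shape_a,
    fraction_shape_b = fraction_shape_b,
    sigma_probe = sigma_probe,
    platform_shift = platform_shift,
    p_missing = p_missing,
    p_smoking = p_smoking,
    seed = as.integer(seed)
  )
  stopifnot(
    p$n_samples > 0L, p$n_autosomal_probes >= 0L,
    p$age_sd >= 0,
    p$p_rt >= 0, p$p_rt <= 1,
    p$p_missing >= 0, p$p_missing <= 1,
    p$p_smoking >= 0, p$p_smoking <= 1,
    p$sigma_probe >= 0,
    p$fraction_shape_a > 0, p$fraction_shape_b > 0
  )
  if (p$n_msy_probes < 3L) {
    stop("n_msy_probes must be >= 3: with fewer MSY probes the per-sample ",
         "MSY missing fraction used by QC is degenerate")
  }
  class(p) <- "loy_sim_params"
  p
}

#' Simulate one synthetic cohort of array intensities and phenotypes
#'
#' Generates a probe manifest, a sample-by-probe log R ratio matrix, a
#' phenotype table and the simulation ground truth for a single cohort.
#' Deterministic given `params$seed` and `cohort_index`.
#'
#' @param params a [sim_params()] object.
#' @param cohort_label cohort name written into the phenotype table.
#' @param cohort_index non-negative integer; the cohort's RNG stream is
#'   seeded with `params$seed + cohort_index`.
#' @param site cancer-site label written into the phenotype table.
#' @return A list of class `loy_cohort` with elements
#'   \describe{
#'     \item{manifest}{data.frame `probe_id, chrom, pos, is_msy`.}
#'     \item{lrr}{numeric matrix, samples x probes, `NA` = missing.}
#'     \item{pheno}{data.frame of per-sample covariates (cohort, site, age,
#'       smoking, surgery, endocrine, rt, rt_modality, dose_gy,
#'       years_since_rt).}
#'     \item{truth}{data.frame `sample_id, carrier, true_fraction,
#'       expected_mlrry` where `expected_mlrry = log2(1 - f) +
#'       platform_shift`.}
#'   }
#' @export
simulate_cohort <- function(params, cohort_label = "cohort1",
                            cohort_index = 0L, site = "prostate") {
  stopifnot(inherits(params, "loy_sim_params"), cohort_index >= 0)
  set.seed(params$seed + as.integer(cohort_index))
  n <- params$n_samples

  sample_id <- sprintf("%s_S%04d", cohort_label, seq_len(n))
  age <- stats::rnorm(n, params$age_mean, params$age_sd)
  smoking <- stats::rbinom(n, 1L, params$p_smoking)
  rt <- stats::rbinom(n, 1L, params$p_rt)
  surgery <- stats::rbinom(n, 1L, 0.5)
  endocrine <- stats::rbinom(n, 1L, 0.4)

  rt_modality <- rep(NA_character_, n)
  dose_gy <- rep(NA_real_, n)
  years_since_rt <- rep(NA_real_, n)
  n_rt <- sum(rt)
  if (n_rt > 0L) {
    rt_modality[rt == 1L] <- sample(c("imrt", "brachytherapy", "proton"),
                                    n_rt, replace = TRUE,
                                    prob = c(0.75, 0.22, 0.03))
    mod <- rt_modality[rt == 1L]
    d <- numeric(n_rt)
    d[mod == "imrt"] <- stats::rnorm(sum(mod == "imrt"), 72, 2)
    d[mod == "brachytherapy"] <- stats::rnorm(sum(mod == "brachytherapy"), 158, 15)
    d[mod == "proton"] <- stats::rnorm(sum(mod == "proton"), 70, 2)
    dose_gy[rt == 1L] <- pmax(d, 1)
    years_since_rt[rt == 1L] <- stats::rexp(n_rt, rate = 0.5)
  }

  beta_rt <- rep(params$clone_beta_rt, n)
  if (!is.na(params$clone_beta_rt_recent)) {
    recent <- rt == 1L & !is.na(years_since_rt) & years_since_rt < 1
    beta_rt[recent] <- params$clone_beta_rt_recent
  }
  eta <- params$clone_intercept + params$clone_beta_age * age +
    beta_rt * rt +
    params$clone_beta_dose * ifelse(rt == 1L, dose_gy, 0)
  carrier <- stats::rbinom(n, 1L, stats::plogis(eta))
  f <- numeric(n)
  if (any(carrier == 1L)) {
    f[carrier == 1L] <- stats::rbeta(sum(carrier), params$fraction_shape_a,
                                     params$fraction_shape_b)
  }

  manifest <- data.frame(
    probe_id = c(sprintf("msy%04d", seq_len(params$n_msy_probes)),
                 if (params$n_autosomal_probes > 0L)
                   sprintf("auto%05d", seq_len(params$n_autosomal_probes))),
    chrom = c(rep("Y", params$n_msy_probes),
              rep("1", params$n_autosomal_probes)),
    pos = c(seq_len(params$n_msy_probes) * 1000L + 2650000L,
            if (params$n_autosomal_probes > 0L)
              seq_len(params$n_autosomal_probes) * 1000L),
    is_msy = c(rep(TRUE, params$n_msy_probes),
               rep(FALSE, params$n_autosomal_probes)),
    stringsAsFactors = FALSE
  )
  n_probes <- nrow(manifest)

  mu_msy <- log2(1 - f) + params$platform_shift
  lrr <- matrix(stats::rnorm(n * n_probes, sd = params$sigma_probe),
                nrow = n, ncol = n_probes,
                dimnames = list(sample_id, manifest$probe_id))
  lrr[, manifest$is_msy] <- lrr[, manifest$is_msy] + mu_msy
  if (params$p_missing > 0) {
    miss <- stats::runif(n * n_probes) < params$p_missing
    lrr[miss] <- NA_real_
  }

  pheno <- data.frame(
    sample_id = sample_id, cohort = cohort_label, site = site,
    age = age, smoking = smoking, surgery = surgery, endocrine = endocrine,
    rt = rt, rt_modality = rt_modality, dose_gy = dose_gy,
    years_since_rt = years_since_rt, stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = sample_id, carrier = carrier, true_fraction = f,
    expected_mlrry = mu_msy, stringsAsFactors = FALSE
  )
  structure(list(manifest = manifest, lrr = lrr, pheno = pheno, truth = truth),
            class = "loy_cohort")
}

#' Simulate a multi-cohort study
#'
#' Convenience wrapper calling [simulate_cohort()] once per cohort with
#' per-cohort platform shifts and independent RNG streams, then binding the
#' phenotype and truth tables. All cohorts share one probe manifest.
#'
#' @param params a [sim_params()] object (shared across cohorts except for
#'   the platform shift).
#' @param cohort_labels character vector of cohort names.
#' @param platform_shifts numeric vector, one additive mLRR-Y offset per
#'   cohort (recycled).
#' @param sites site label per cohort (recycled).
#' @return list with `manifest`, per-cohort `lrr` list, combined `pheno` and
#'   `truth`.
#' @export
simulate_study <- function(params, cohort_labels = c("cohortA", "cohortB"),
                           platform_shifts = 0, sites = "prostate") {
  stopifnot(inherits(params, "loy_sim_params"), length(cohort_labels) >= 1)
  platform_shifts <- rep_len(platform_shifts, length(cohort_labels))
  sites <- rep_len(sites, length(cohort_labels))
  cohorts <- lapply(seq_along(cohort_labels), function(i) {
    p <- params
    p$platform_shift <- platform_shifts[i]
    simulate_cohort(p, cohort_label = cohort_labels[i],
                    cohort_index = i - 1L, site = sites[i])
  })
  names(cohorts) <- cohort_labels
  list(
    manifest = cohorts[[1L]]$manifest,
    lrr = lapply(cohorts, `[[`, "lrr"),
    pheno = do.call(rbind, lapply(cohorts, `[[`, "pheno")),
    truth = do.call(rbind, lapply(cohorts, `[[`, "truth"))
  )
}
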