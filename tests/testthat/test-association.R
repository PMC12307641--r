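test_that("crude 2x2 odds ratios, Haldane correction and degeneracies", {
  expect_equal(or_from_2x2(matrix(c(7, 7, 13, 13), 2))$or, 1)
  r <- or_from_2x2(matrix(c(10, 90, 5, 95), 2, byrow = TRUE))
  expect_equal(r$or, (10 * 95) / (90 * 5), tolerance = 1e-12)
  expect_equal(r$se, sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95), tolerance = 1e-12)
  expect_true(r$ci_low < r$or & r$or < r$ci_high)

  h <- or_from_2x2(matrix(c(0, 10, 5, 5), 2, byrow = TRUE))
  expect_equal(h$flags, "haldane")
  expect_equal(h$or, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_equal(round(h$or, 4), 0.0476)

  u <- or_from_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))
  expect_equal(u$flags, "undefined")
  expect_true(is.na(u$estimate))
  expect_equal(u$p, 1)
})

test_that("odds ratio is antisymmetric under row or column swap", {
  set.seed(17)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    a <- or_from_2x2(tab)$estimate
    expect_equal(or_from_2x2(tab[2:1, ])$estimate, -a, tolerance = 1e-12)
    expect_equal(or_from_2x2(tab[, 2:1])$estimate, -a, tolerance = 1e-12)
  }
})

test_that("logistic fit with one binary covariate equals the crude log OR", {
  set.seed(23)
  for (i in 1:10) {
    x <- rbinom(300, 1, 0.4)
    y <- rbinom(300, 1, plogis(-1.5 + 0.8 * x))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(y, data.frame(x = x))
    tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)),
                  2, byrow = TRUE)
    expect_equal(fit$estimate[fit$term == "x"], or_from_2x2(tab)$estimate,
                 tolerance = 1e-6)
  }
})

test_that("logistic degeneracies are flagged, not silently estimated", {
  y <- rep(0, 50)
  expect_match(fit_logistic(y, data.frame(x = rnorm(50)))$flags[1], "separation")
  # perfect separation on a binary covariate
  x <- rep(c(0, 1), each = 25)
  expect_match(fit_logistic(x, data.frame(x = x))$flags[1], "separation")
  # complete-case accounting
  x2 <- rnorm(80); x2[1:7] <- NA
  fit <- fit_logistic(rbinom(80, 1, 0.5), data.frame(x = x2))
  expect_equal(attr(fit, "n_dropped"), 7L)
  expect_equal(fit$n[1], 73L)
})

test_that("age trend recovers an exact linear relationship and flags degeneracy", {
  age <- seq(50, 90, by = 2)
  tr <- suppressWarnings(age_trend(1 - 0.01 * age, age))  # exact fit warns
  expect_equal(tr$slope, -0.01, tolerance = 1e-12)
  expect_equal(tr$intercept, 1, tolerance = 1e-10)
  expect_error(age_trend(rnorm(10), rep(60, 10)), "zero age variance")
  expect_error(age_trend(c(1, 2), c(50, 60)), "at least 3")
})

test_that("age trend p-values are near-uniform under permuted pairing", {
  set.seed(61)
  age <- rnorm(120, 70, 8)
  y <- -0.004 * age + rnorm(120, 0, 0.1)
  ps <- replicate(200, age_trend(y, sample(age))$p_slope)
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("treatment models isolate a simulated radiotherapy effect", {
  p <- sim_params(n_samples = 3000L, n_msy_probes = 40L,
                  n_autosomal_probes = 40L, seed = 77)
  co <- simulate_cohort(p)
  qc <- qc_filter(co$lrr, co$manifest)
  sig <- compute_mlrry(qc$lrr, co$manifest, cohort = "c1")
  calls <- call_absolute(sig)
  res <- treatment_associations(co$pheno, calls)
  rt <- res[res$model == "rt", ]
  expect_gt(rt$or, 1); expect_lt(rt$p, 0.05)
  # null treatments: log OR within 3.5 SE of zero
  for (null_tr in c("endocrine", "surgery")) {
    row <- res[res$model == null_tr, ]
    expect_lt(abs(row$estimate), 3.5 * row$se)
  }
})

test_that("sites at or below the minimum n are skipped, smaller thresholds keep them", {
  p <- fast_params(seed = 55, p_missing = 0)
  study <- simulate_study(p, cohort_labels = "A",
                          sites = "prostate")
  co2 <- simulate_cohort(p, cohort_label = "A2", cohort_index = 5L,
                         site = "lung")
  pheno <- rbind(study$pheno, co2$pheno)
  pheno$cohort <- "A"  # one cohort, two sites: prostate n=300, lung n=300
  sig <- rbind(
    standardize_within_cohort(compute_mlrry(
      qc_filter(study$lrr$A, study$manifest)$lrr, study$manifest, "A")),
    standardize_within_cohort(compute_mlrry(
      qc_filter(co2$lrr, co2$manifest)$lrr, co2$manifest, "A")))
  calls <- call_absolute(sig)
  res <- treatment_associations(pheno, calls, treatments = "rt",
                                min_site_n = 300)
  expect_setequal(attr(res, "skipped"), c("prostate", "lung"))
  res2 <- treatment_associations(pheno, calls, treatments = "rt",
                                 min_site_n = 299)
  expect_length(attr(res2, "skipped"), 0)
  expect_equal(sort(res2$stratum), c("A/lung", "A/prostate"))
  expect_error(treatment_associations(pheno, calls, treatments = "nope"),
               "nope")
})

test_that("time-since-RT strata follow the >= boundary and flag empty strata", {
  p <- fast_params(seed = 91)
  co <- simulate_cohort(p)
  sig <- compute_mlrry(qc_filter(co$lrr, co$manifest)$lrr, co$manifest)
  calls <- call_absolute(sig)

  # everyone irradiated exactly 1.0 years ago lands in the late stratum
  ph <- co$pheno
  ph$years_since_rt[ph$rt == 1] <- 1.0
  res <- time_stratified(ph, calls)
  expect_equal(res$flags[res$stratum == "rt_recent"], "empty_stratum")
  expect_false(is.na(res$estimate[res$stratum == "rt_late"]))

  # no radiotherapy at all -> both strata flagged
  ph0 <- co$pheno; ph0$rt <- 0L; ph0$years_since_rt <- NA_real_
  res0 <- time_stratified(ph0, calls)
  expect_equal(res0$flags, c("empty_stratum", "empty_stratum"))

  # irradiated samples with unknown timing are dropped and counted
  ph2 <- co$pheno
  drop_idx <- which(ph2$rt == 1)[1:3]
  ph2$years_since_rt[drop_idx] <- NA_real_
  res2 <- time_stratified(ph2, calls)
  expect_equal(attr(res2, "n_dropped_time"), 3L)
})

test_that("dose-response enforces the modality minimum and flags constant dose", {
  p <- fast_params(seed = 101)
  co <- simulate_cohort(p)
  sig <- compute_mlrry(qc_filter(co$lrr, co$manifest)$lrr, co$manifest)
  calls <- call_absolute(sig)
  ph <- co$pheno

  # shrink a modality to n = 4: excluded by the >= 10 rule
  idx <- which(ph$rt_modality == "imrt")
  ph4 <- ph
  ph4$rt_modality[idx[-(1:4)]] <- "brachytherapy"
  expect_message(res4 <- dose_response(ph4, calls, "imrt"), "excluded")
  expect_equal(res4$flags, "excluded_small_n")

  # constant dose is degenerate
  phc <- ph
  phc$dose_gy[phc$rt == 1] <- 70
  resc <- dose_response(phc, calls, "imrt")
  expect_equal(resc$flags, "degenerate_dose")

  # a simulated linear-in-dose log-odds effect is recovered; clone_beta_rt
  # recentres the logit so the within-IMRT prevalence stays realistic
  # (logit = intercept + 0.06*age + 0.05*(dose - 72))
  pdose <- sim_params(n_samples = 6000L, n_msy_probes = 40L,
                      n_autosomal_probes = 0L, clone_beta_rt = -3.6,
                      clone_beta_dose = 0.05, p_rt = 0.5, seed = 303)
  cod <- simulate_cohort(pdose)
  sigd <- compute_mlrry(qc_filter(cod$lrr, cod$manifest)$lrr, cod$manifest)
  calld <- call_absolute(sigd)
  resd <- dose_response(cod$pheno, calld, "imrt")
  expect_lt(abs(resd$estimate - 0.05), 3.5 * resd$se)
})

test_that("baseline characteristic tables drop missing categories per characteristic", {
  pheno <- data.frame(
    sample_id = sprintf("s%02d", 1:60),
    grade = c(rep(c("low", "mid", "high"), 19), NA, NA, NA),
    stringsAsFactors = FALSE
  )
  calls <- data.frame(sample_id = pheno$sample_id,
                      call = rep(c(TRUE, FALSE, FALSE), 20))
  t1 <- table1_summary(pheno, calls, "grade")
  expect_equal(sum(t1$n_mloy) + sum(t1$n_non_mloy), 57L)
  expect_equal(length(unique(t1$fisher_p)), 1L)
  expect_error(table1_summary(pheno, calls, "absent"), "absent")
})
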