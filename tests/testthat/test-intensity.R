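test_that("manifest and LRR tables round-trip through TSV including missingness", {
  man <- toy_manifest()
  lrr <- toy_lrr(c(0.1, -0.2, 0.3, NA, 0.05,
                   -0.4, NA, 0.0, 0.2, -0.1), man)
  tmp_m <- tempfile(fileext = ".tsv")
  tmp_l <- tempfile(fileext = ".tsv")
  write_manifest(man, tmp_m)
  write_lrr(lrr, tmp_l)
  man2 <- read_manifest(tmp_m)
  lrr2 <- read_lrr(tmp_l, man2)
  expect_equal(man2, man)
  expect_identical(is.na(lrr2), is.na(lrr))
  expect_equal(lrr2, lrr, tolerance = 1e-12)
})

test_that("matrix validation names offending probes and samples", {
  man <- toy_manifest()
  lrr <- toy_lrr(rep(0, 5), man)
  colnames(lrr)[2] <- "rogue_probe"
  tmp <- tempfile(fileext = ".tsv")
  write_lrr(lrr, tmp)
  expect_error(read_lrr(tmp, man), "rogue_probe")

  lrr2 <- toy_lrr(rep(0, 10), man, sample_ids = c("dup", "dup"))
  tmp2 <- tempfile(fileext = ".tsv")
  write_lrr(lrr2, tmp2)
  expect_error(read_lrr(tmp2, man), "dup")

  expect_error(validate_manifest(data.frame(probe_id = c("a", "a"),
                                            chrom = "Y", pos = 1:2,
                                            is_msy = TRUE)), "duplicated")
  expect_error(validate_manifest(data.frame(probe_id = c("a", "b"),
                                            chrom = "1", pos = 1:2,
                                            is_msy = FALSE)), "no MSY")
})

test_that("QC exclusion uses strict thresholds on MSY and overall missingness", {
  man <- toy_manifest(n_msy = 100L, n_auto = 100L)
  base <- rep(0, 200)
  two_missing <- base; two_missing[1:2] <- NA          # 2% MSY missing
  one_missing <- base; one_missing[1] <- NA            # exactly 1% MSY missing
  eleven_all <- base; eleven_all[101:111] <- NA        # 5.5% overall, 0% MSY
  ten_all <- base; ten_all[101:110] <- NA              # exactly 5% overall
  lrr <- toy_lrr(c(two_missing, one_missing, eleven_all, ten_all, base), man)

  out <- qc_filter(lrr, man)
  expect_equal(out$report$passed, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$report$reason[1], "msy_missing")
  expect_equal(out$report$reason[3], "overall_missing")
  expect_equal(rownames(out$lrr), c("s2", "s4", "s5"))
  expect_equal(nrow(out$report), 5L)

  clean <- qc_filter(toy_lrr(rep(0.1, 10), toy_manifest()), toy_manifest())
  expect_true(all(clean$report$passed))

  expect_error(qc_filter(lrr[0, , drop = FALSE], man), "empty")
})

test_that("mLRR-Y is the median over non-missing MSY probes", {
  man <- toy_manifest(n_msy = 3L, n_auto = 2L)
  lrr <- toy_lrr(c(0, 0, 0, 9, 9,
                   -0.3, -0.1, -0.2, 9, 9,
                   -0.3, NA, -0.1, 9, 9), man)
  sig <- compute_mlrry(lrr, man)
  expect_equal(sig$mlrry, c(0, -0.2, -0.2))  # autosomal 9s never leak in

  # even count -> midpoint of the two central order statistics
  man4 <- toy_manifest(n_msy = 4L, n_auto = 0L)
  sig4 <- compute_mlrry(toy_lrr(c(-0.4, -0.1, -0.2, -0.3), man4), man4)
  expect_equal(sig4$mlrry, -0.25)

  # a sample whose MSY values are all the expected signal of f = 0.1
  manf <- toy_manifest(n_msy = 5L, n_auto = 0L)
  sigf <- compute_mlrry(toy_lrr(rep(fraction_to_mlrry(0.1), 5), manf), manf)
  expect_equal(sigf$mlrry, log2(0.9))
  expect_equal(round(sigf$mlrry, 3), -0.152)

  all_na <- toy_lrr(c(NA, NA, NA, 0, 0), man)
  expect_error(compute_mlrry(all_na, man), "failed QC")
})

test_that("within-cohort standardization centres and scales with the n-1 SD", {
  sig <- data.frame(sample_id = c("a", "b"), cohort = "c1",
                    mlrry = c(-1, 1), z = NA_real_)
  out <- standardize_within_cohort(sig)
  expect_equal(out$z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(round(out$z, 4), c(-0.7071, 0.7071))

  big <- data.frame(sample_id = sprintf("s%d", 1:50), cohort = "c1",
                    mlrry = rnorm(50, -0.05, 0.1), z = NA_real_)
  z1 <- standardize_within_cohort(big)$z
  expect_equal(mean(z1), 0, tolerance = 1e-9)
  expect_equal(sd(z1), 1, tolerance = 1e-9)
  # location invariance
  shifted <- big; shifted$mlrry <- shifted$mlrry + 0.3
  expect_equal(standardize_within_cohort(shifted)$z, z1, tolerance = 1e-9)

  flat <- data.frame(sample_id = c("a", "b", "c"), cohort = "c1",
                     mlrry = rep(-0.1, 3), z = NA_real_)
  expect_error(standardize_within_cohort(flat), "degenerate")
  expect_error(standardize_within_cohort(sig[1, ]), "fewer than 2")
})

test_that("standardization removes a simulated platform shift", {
  p <- sim_params(n_samples = 1500L, n_msy_probes = 40L,
                  n_autosomal_probes = 0L, p_missing = 0, seed = 31)
  study <- simulate_study(p, cohort_labels = c("A", "B"),
                          platform_shifts = c(0, -0.3))
  sigs <- lapply(names(study$lrr), function(ch) {
    compute_mlrry(study$lrr[[ch]], study$manifest, cohort = ch)
  })
  sig <- standardize_within_cohort(do.call(rbind, sigs))
  zA <- sig$z[sig$cohort == "A"]; zB <- sig$z[sig$cohort == "B"]
  # raw signals are clearly separated by the shift; z-scores are not
  mA <- sig$mlrry[sig$cohort == "A"]; mB <- sig$mlrry[sig$cohort == "B"]
  expect_gt(abs(mean(mA) - mean(mB)), 0.25)
  ks_z <- suppressWarnings(ks.test(zA, zB))
  expect_gt(ks_z$p.value, 0.01)
})
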