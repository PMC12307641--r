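# Small simulated fixtures shared across tests.

# Reduced probe counts: keeps the median estimate reasonably tight while
# making matrix generation cheap for repeated simulation.
fast_params <- function(...) {
  sim_params(n_samples = 300L, n_msy_probes = 30L, n_autosomal_probes = 60L,
             ...)
}

# Run the core pipeline on one simulated cohort and return the adjusted
# logistic row for the radiotherapy term (absolute-threshold calls).
rt_fit_one <- function(params, cohort_index = 0L) {
  co <- simulate_cohort(params, cohort_index = cohort_index)
  qc <- qc_filter(co$lrr, co$manifest)
  sig <- compute_mlrry(qc$lrr, co$manifest)
  calls <- call_absolute(sig)
  d <- co$pheno[match(calls$sample_id, co$pheno$sample_id), ]
  fit <- fit_logistic(calls$call, d[, c("rt", "age", "smoking")])
  fit[fit$term == "rt", ]
}

# Tiny hand-writable manifest/matrix pair.
toy_manifest <- function(n_msy = 3L, n_auto = 2L) {
  data.frame(
    probe_id = c(sprintf("msy%d", seq_len(n_msy)),
                 if (n_auto > 0) sprintf("a%d", seq_len(n_auto))),
    chrom = c(rep("Y", n_msy), rep("1", n_auto)),
    pos = seq_len(n_msy + n_auto),
    is_msy = c(rep(TRUE, n_msy), rep(FALSE, n_auto)),
    stringsAsFactors = FALSE
  )
}

toy_lrr <- function(values, manifest, sample_ids = NULL) {
  m <- matrix(values, ncol = nrow(manifest), byrow = TRUE)
  rownames(m) <- sample_ids %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- manifest$probe_id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expand a count summary into sample-level call/phenotype tables, so that
# published table arithmetic can be recomputed through the same code path
# as individual-level data.
counts_to_samples <- function(n, n_mloy, n_rt, n_both, cohort = "c", site = "s") {
  id <- sprintf("%s%05d", cohort, seq_len(n))
  call <- c(rep(TRUE, n_mloy), rep(FALSE, n - n_mloy))
  rt <- integer(n)
  rt[seq_len(n_both)] <- 1L                                 # mLOY & RT
  rt[n_mloy + seq_len(n_rt - n_both)] <- 1L                 # RT only
  list(calls = data.frame(sample_id = id, call = call),
       pheno = data.frame(sample_id = id, cohort = cohort, site = site,
                          rt = rt, stringsAsFactors = FALSE))
}
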