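#' Prevalence and exposure-share summary
#'
#' For each group (by default cohort x site), reports the four count/percent
#' summaries a study table needs: mLOY prevalence among all samples,
#' exposure prevalence among all samples, the exposure share among mLOY
#' cases (`n_mloy_rt / n_mloy`, the arithmetic behind "mLOY in RT (%)"
#' rows), and mLOY prevalence within the exposed (`n_mloy_rt / n_rt`). The
#' two latter summaries answer different questions and are deliberately
#' reported side by side. Percentages with a zero denominator are `NA`
#' (undefined), never 0.
#'
#' @param calls data.frame with `sample_id` and logical `call`.
#' @param pheno phenotype data.frame with `sample_id`, the exposure column
#'   and the grouping columns.
#' @param by character vector of grouping columns present in `pheno`
#'   (empty for a single overall row).
#' @param exposure name of the binary exposure column (default `"rt"`).
#' @return data.frame with one row per group: the grouping columns, `n,
#'   n_mloy, pct_mloy, n_rt, pct_rt, n_mloy_rt, pct_rt_share_of_mloy,
#'   pct_mloy_in_rt`.
#' @export
summarize_prevalence <- function(calls, pheno, by = c("cohort", "site"),
                                 exposure = "rt") {
  dat <- merge_calls_pheno(pheno, calls)
  missing_cols <- setdiff(c(by, exposure), names(dat))
  if (length(missing_cols)) {
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  }
  groups <- if (length(by)) {
    split(dat, dat[by], drop = TRUE)
  } else {
    list(all = dat)
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    n <- nrow(d)
    n_mloy <- sum(d$call)
    n_rt <- sum(d[[exposure]] == 1, na.rm = TRUE)
    n_both <- sum(d$call & d[[exposure]] == 1, na.rm = TRUE)
    key <- if (length(by)) d[1L, by, drop = FALSE] else data.frame(group = "all")
    cbind(key, data.frame(
      n = n, n_mloy = n_mloy, pct_mloy = pct(n_mloy, n),
      n_rt = n_rt, pct_rt = pct(n_rt, n),
      n_mloy_rt = n_both,
      pct_rt_share_of_mloy = pct(n_both, n_mloy),
      pct_mloy_in_rt = pct(n_both, n_rt)
    ), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble and validate a study configuration
#'
#' A study runs either on simulated cohorts (`simulate` block) or on files
#' (`inputs` block with `manifest`, per-cohort `lrr` paths and
#' `phenotypes`). All analysis settings have the conventional defaults.
#'
#' @param simulate `NULL`, or a list with `params` (arguments for
#'   [sim_params()]), `cohorts` (character labels) and optional
#'   `platform_shifts`, `sites`.
#' @param inputs `NULL`, or a list with file paths `manifest`, `lrr` (named
#'   character vector, one path per cohort) and `phenotypes`.
#' @param qc,calling,association,sweep,meta analysis settings; see defaults
#'   in the function signature.
#' @param seed integer seed overriding the simulation seed.
#' @param out_dir optional output directory for [write_report()].
#' @return validated config list of class `loy_config`.
#' @export
study_config <- function(simulate = NULL, inputs = NULL,
                         qc = list(max_msy_missing = 0.01,
                                   max_overall_missing = 0.05),
                         calling = list(absolute_threshold = -0.15,
                                        percentile_q = 0.01),
                         association = list(
                           treatments = c("rt", "endocrine", "surgery"),
                           covariates = c("age", "smoking"),
                           min_site_n = 1000),
                         sweep = list(q_grid = seq(0.01, 0.5, by = 0.01),
                                      min_exposed_events = 10),
                         meta = list(two_level = TRUE),
                         seed = NULL, out_dir = NULL) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of `simulate` or `inputs` must be given")
  }
  if (!is.null(inputs)) {
    for (f in c(inputs$manifest, unlist(inputs$lrr), inputs$phenotypes)) {
      if (!file.exists(f)) stop("input file does not exist: ", f)
    }
    if (is.null(names(inputs$lrr)) || any(!nzchar(names(inputs$lrr)))) {
      stop("`inputs$lrr` must be a named vector: cohort label -> path")
    }
  }
  cfg <- list(simulate = simulate, inputs = inputs, qc = qc, calling = calling,
              association = association, sweep = sweep, meta = meta,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "loy_config"
  cfg
}

#' Read a study configuration from YAML or JSON
#'
#' @param path path to a YAML or JSON file whose top-level keys match the
#'   arguments of [study_config()].
#' @return validated config list of class `loy_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- formals(study_config)
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  do.call(study_config, raw)
}

log_stage <- function(...) message("[loyscan] ", ...)

#' Run the full mLOY study pipeline
#'
#' Executes every stage on a config: load or simulate the cohorts, apply
#' sample QC, compute mLRR-Y, standardize within cohort, call mLOY under
#' both the absolute and percentile schemes, summarise prevalence, fit the
#' age trend per cohort, fit adjusted per-treatment logistic models per
#' cohort-by-site stratum, pool the radiotherapy estimates by a two-level
#' fixed-effect meta-analysis (cohorts within sites, then across sites),
#' run the time-since-RT stratified model, per-modality dose-response
#' models, and the percentile-threshold sensitivity sweep. Deterministic
#' given the config (and its seed, for simulated inputs). Stage progress
#' and every exclusion are logged to standard error.
#'
#' @param config a `loy_config` from [study_config()] / [read_config()].
#' @return a `loy_report` list with elements `qc`, `signals`, `calls`
#'   (absolute and percentile), `prevalence`, `age_trend`, `associations`,
#'   `meta`, `time_stratified`, `dose_response`, `sweep`, and `provenance`.
#'   If `config$out_dir` is set the report is also written there via
#'   [write_report()].
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "loy_config"))

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    pars <- do.call(sim_params, c(sim$params,
                                  if (!is.null(config$seed)) list(seed = config$seed)))
    labels <- if (is.null(sim$cohorts)) c("cohortA", "cohortB") else sim$cohorts
    log_stage("simulating ", length(labels), " cohort(s), n = ",
              pars$n_samples, " each")
    study <- simulate_study(pars,
                            cohort_labels = labels,
                            platform_shifts = sim$platform_shifts %||% 0,
                            sites = sim$sites %||% "prostate")
    manifest <- study$manifest
    lrr_list <- study$lrr
    pheno <- study$pheno
  } else {
    manifest <- read_manifest(config$inputs$manifest)
    lrr_list <- lapply(config$inputs$lrr, read_lrr, manifest = manifest)
    pheno <- read_phenotypes(config$inputs$phenotypes)
    log_stage("loaded ", length(lrr_list), " cohort matrices, ",
              nrow(pheno), " phenotype rows")
  }

  qc_reports <- list()
  signals <- list()
  for (ch in names(lrr_list)) {
    qc <- qc_filter(lrr_list[[ch]], manifest,
                    max_msy_missing = config$qc$max_msy_missing,
                    max_overall_missing = config$qc$max_overall_missing)
    log_stage("QC cohort ", ch, ": ", sum(!qc$report$passed), " of ",
              nrow(qc$report), " samples excluded")
    qc_reports[[ch]] <- cbind(cohort = ch, qc$report, stringsAsFactors = FALSE)
    signals[[ch]] <- compute_mlrry(qc$lrr, manifest, cohort = ch)
  }
  qc_report <- do.call(rbind, qc_reports); rownames(qc_report) <- NULL
  signals <- do.call(rbind, signals); rownames(signals) <- NULL
  signals <- standardize_within_cohort(signals)

  calls_abs <- call_absolute(signals, config$calling$absolute_threshold)
  calls_pct <- call_percentile(signals, q = config$calling$percentile_q,
                               scope = "cohort", value = "mlrry")
  log_stage("calls: absolute ", sum(calls_abs$call), ", percentile ",
            sum(calls_pct$call), " of ", nrow(signals))

  pheno_kept <- pheno[pheno$sample_id %in% signals$sample_id, , drop = FALSE]
  prevalence <- list(
    absolute = summarize_prevalence(calls_abs, pheno_kept),
    percentile = summarize_prevalence(calls_pct, pheno_kept)
  )

  trend <- lapply(split(signals, signals$cohort), function(s) {
    ages <- pheno_kept$age[match(s$sample_id, pheno_kept$sample_id)]
    age_trend(s, ages)
  })

  assoc <- list()
  meta_res <- list()
  for (scheme in c("absolute", "percentile")) {
    calls <- if (scheme == "absolute") calls_abs else calls_pct
    a <- treatment_associations(pheno_kept, calls,
                                treatments = config$association$treatments,
                                covariates = config$association$covariates,
                                min_site_n = config$association$min_site_n)
    if (length(attr(a, "skipped"))) {
      log_stage("sites skipped (n <= ", config$association$min_site_n, "): ",
                paste(attr(a, "skipped"), collapse = ", "))
    }
    assoc[[scheme]] <- a
    rt_rows <- a[a$model == "rt" & !nzchar(a$flags), , drop = FALSE]
    if (nrow(rt_rows) >= 1L) {
      est <- data.frame(
        site = sub("^[^/]*/", "", rt_rows$stratum),
        label = rt_rows$stratum,
        log_or = rt_rows$estimate, se = rt_rows$se,
        stringsAsFactors = FALSE
      )
      meta_res[[scheme]] <- if (isTRUE(config$meta$two_level)) {
        two_level_meta(est)
      } else {
        list(per_site = NULL, overall = fixed_effect(est))
      }
    }
  }

  time_strat <- time_stratified(pheno_kept, calls_abs,
                                covariates = config$association$covariates)
  dose <- lapply(c("imrt", "brachytherapy"), function(m) {
    tryCatch(dose_response(pheno_kept, calls_abs, m,
                           covariates = config$association$covariates),
             error = function(e) {
               log_stage("dose-response ", m, " skipped: ", conditionMessage(e))
               NULL
             })
  })
  dose <- do.call(rbind, dose)

  exposure <- pheno_kept$rt[match(signals$sample_id, pheno_kept$sample_id)]
  sweep <- sweep_thresholds(signals, exposure,
                            q_grid = config$sweep$q_grid,
                            min_exposed_events = config$sweep$min_exposed_events)

  report <- list(
    qc = qc_report, signals = signals,
    calls = list(absolute = calls_abs, percentile = calls_pct),
    prevalence = prevalence, age_trend = trend,
    associations = assoc, meta = meta_res,
    time_stratified = time_strat, dose_response = dose, sweep = sweep,
    provenance = list(
      config = unclass(config),
      seed = config$seed,
      package = as.character(utils::packageVersion("loyscan")),
      r_version = as.character(getRversion())
    )
  )
  class(report) <- "loy_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study report to disk
#'
#' Emits the tabular sections as TSV files (`qc_report.tsv`, `mlrry.tsv`,
#' `calls_absolute.tsv`, `calls_percentile.tsv`, `prevalence_*.tsv`,
#' `assoc_*.tsv`, `meta_*.tsv`, `time_stratified.tsv`, `dose_response.tsv`,
#' `sweep.tsv`) plus a single `report.json` containing every section and
#' the provenance block.
#'
#' @param report a `loy_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "loy_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    if (!is.null(x)) {
      utils::write.table(x, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  tsv(report$qc, "qc_report.tsv")
  tsv(report$signals, "mlrry.tsv")
  tsv(report$calls$absolute, "calls_absolute.tsv")
  tsv(report$calls$percentile, "calls_percentile.tsv")
  for (s in names(report$prevalence)) {
    tsv(report$prevalence[[s]], paste0("prevalence_", s, ".tsv"))
  }
  for (s in names(report$associations)) {
    tsv(report$associations[[s]], paste0("assoc_", s, ".tsv"))
  }
  for (s in names(report$meta)) {
    tsv(report$meta[[s]]$per_site, paste0("meta_per_site_", s, ".tsv"))
    tsv(report$meta[[s]]$overall, paste0("meta_overall_", s, ".tsv"))
  }
  tsv(report$time_stratified, "time_stratified.tsv")
  tsv(report$dose_response, "dose_response.tsv")
  tsv(report$sweep, "sweep.tsv")
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(dir)
}
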