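#' Read and write array-data tables
#'
#' Plain-TSV interchange for the three inputs of the pipeline: a probe
#' manifest (`probe_id, chrom, pos, is_msy`), a sample-by-probe log R ratio
#' matrix (first column `sample_id`, remaining columns probe ids, missing
#' values written as `NA`), and a phenotype table. Reading is validated
#' against the manifest; `read_lrr(write_lrr(x))` round-trips exactly,
#' including the missing mask.
#'
#' @param path file path of a tab-separated table with header.
#' @return `read_manifest`: a data.frame with columns
#'   `probe_id, chrom, pos, is_msy`.
#' @name loy_io
NULL

#' @rdname loy_io
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(probe_id = "character",
                                        chrom = "character"))
  required <- c("probe_id", "chrom", "pos", "is_msy")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- m[required]
  m$pos <- as.integer(m$pos)
  m$is_msy <- as.logical(as.integer(m$is_msy))
  validate_manifest(m)
  m
}

#' @rdname loy_io
#' @param manifest a probe manifest data.frame, used to validate the matrix
#'   columns (written with `is_msy` as 0/1).
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  out <- manifest
  out$is_msy <- as.integer(out$is_msy)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("probe_id", "chrom", "pos", "is_msy") %in% names(manifest)))
  if (anyDuplicated(manifest$probe_id)) {
    stop("duplicated probe ids in manifest: ",
         paste(unique(manifest$probe_id[duplicated(manifest$probe_id)]),
               collapse = ", "))
  }
  if (!any(manifest$is_msy)) stop("manifest contains no MSY probe")
  invisible(manifest)
}

#' @rdname loy_io
#' @return `read_lrr`: a numeric matrix (samples x probes, `NA` = missing)
#'   with sample ids as row names and probe ids as column names.
#' @export
read_lrr <- function(path, manifest) {
  validate_manifest(manifest)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1L] != "sample_id") stop("first column must be `sample_id`")
  ids <- tab$sample_id
  if (anyDuplicated(ids)) {
    stop("duplicated sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  probes <- names(tab)[-1L]
  unknown <- setdiff(probes, manifest$probe_id)
  if (length(unknown)) {
    stop("probe ids absent from manifest: ", paste(unknown, collapse = ", "))
  }
  x <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  validate_lrr(x, manifest)
  x
}

#' @rdname loy_io
#' @param lrr a samples-by-probes numeric matrix with dimnames.
#' @export
write_lrr <- function(lrr, path) {
  stopifnot(is.matrix(lrr), !is.null(rownames(lrr)), !is.null(colnames(lrr)))
  tab <- data.frame(sample_id = rownames(lrr), lrr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_lrr <- function(lrr, manifest) {
  stopifnot(is.matrix(lrr), is.numeric(lrr))
  if (is.null(rownames(lrr)) || is.null(colnames(lrr))) {
    stop("LRR matrix needs sample ids as rownames and probe ids as colnames")
  }
  unknown <- setdiff(colnames(lrr), manifest$probe_id)
  if (length(unknown)) {
    stop("probe ids absent from manifest: ", paste(unknown, collapse = ", "))
  }
  invisible(lrr)
}

#' @rdname loy_io
#' @return `read_phenotypes`: a data.frame of per-sample covariates.
#' @export
read_phenotypes <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(p)) stop("phenotype table lacks `sample_id`")
  if (anyDuplicated(p$sample_id)) stop("duplicated sample ids in phenotypes")
  p
}

#' @rdname loy_io
#' @param pheno a phenotype data.frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
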