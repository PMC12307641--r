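#' Fisher's exact test for an r x c contingency table
#'
#' Exact two-sided p-value under the multivariate hypergeometric null with
#' both margins fixed (the Freeman-Halton extension for tables larger than
#' 2 x 2): the p-value is the sum of the probabilities of every table with
#' the observed margins whose probability does not exceed that of the
#' observed table, with a relative tolerance of 1e-7 to make the
#' probability-ordering robust to floating-point ties. The 2 x 2 case
#' reduces to a single hypergeometric sum; larger tables are enumerated
#' exhaustively over the free cells, so totals are guarded (<= 10000 for
#' 2 x 2, <= 1000 otherwise).
#'
#' A table with an all-zero row or column carries no information about
#' association; by convention it returns `p = 1` with a warning.
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2.
#' @return the two-sided exact p-value.
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2))
fisher_exact_rxc <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2 x 2")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain non-negative integer counts")
  }
  storage.mode(tab) <- "double"
  n <- sum(tab)
  if (n == 0) stop("table grand total must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("table has an all-zero margin; returning p = 1")
    return(1)
  }
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    if (n > 10000) stop("2 x 2 table total exceeds 10000; ",
                        "use a chi-square test instead")
    return(fisher_2x2(tab))
  }
  if (n > 1000) stop("r x c table total exceeds 1000 for exact enumeration; ",
                     "use a chi-square test instead")
  fisher_freeman_halton(tab)
}

fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  a <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- stats::dhyper(a, c1, n - c1, r1, log = TRUE)
  obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1, log = TRUE)
  sum(exp(logp[logp <= obs + log1p(1e-7)]))
}

fisher_freeman_halton <- function(tab) {
  r <- nrow(tab); c <- ncol(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  # log probability of a table given margins: sum(lgamma margins) - lgamma(n!)
  # - sum over cells of lgamma(t_ij + 1)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  log_prob <- function(cells) log_const - sum(lgamma(cells + 1))
  log_obs <- log_prob(tab)
  tol <- log1p(1e-7)
  total <- 0
  # depth-first enumeration filling cells in row-major order over the first
  # (r-1) rows and (c-1) columns; remaining row/column cells are determined
  # by the margins.
  cell_mat <- matrix(0, r, c)
  recurse <- function(i, j, row_rem, col_rem) {
    # row_rem: remaining count to place in row i (cols j..c)
    # col_rem: remaining counts per column (rows i..r)
    if (i == r) {
      # last row fully determined by column remainders
      cell_mat[r, ] <<- col_rem
      lp <- log_prob(cell_mat)
      if (lp <= log_obs + tol) total <<- total + exp(lp)
      return(invisible())
    }
    if (j == c) {
      cell_mat[i, c] <<- row_rem
      if (row_rem > col_rem[c]) return(invisible())
      col_rem2 <- col_rem
      col_rem2[c] <- col_rem2[c] - row_rem
      recurse(i + 1L, 1L, rs[i + 1L], col_rem2)
      return(invisible())
    }
    lo <- max(0, row_rem - sum(col_rem[(j + 1L):c]))
    hi <- min(row_rem, col_rem[j])
    if (lo > hi) return(invisible())
    for (t in lo:hi) {
      cell_mat[i, j] <<- t
      col_rem2 <- col_rem
      col_rem2[j] <- col_rem2[j] - t
      recurse(i, j + 1L, row_rem - t, col_rem2)
    }
    invisible()
  }
  recurse(1L, 1L, rs[1L], cs)
  min(1, total)
}
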