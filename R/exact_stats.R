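## Exact statistics for focal-vs-others contingency tables.
##
## All tests condition on both margins. Point probabilities are computed in
## log space (lchoose / lgamma) so that reference cohorts with margins of
## order 1e6 do not overflow.

# internal: coerce and validate a 2xK count table
validate_table <- function(x, what = "table") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (nrow(x) != 2L || ncol(x) < 2L) {
    stop(what, " must be a 2xK matrix with K >= 2", call. = FALSE)
  }
  if (anyNA(x)) stop(what, " contains missing cells", call. = FALSE)
  if (any(x < 0)) stop("negative cell count in ", what, call. = FALSE)
  if (any(x != round(x))) stop("non-integer cell count in ", what, call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# relative tolerance used to pool tables whose point probability ties the
# observed one up to floating-point noise
.tie_tol <- 1e-7

#' Expected focal counts under frequency homogeneity
#'
#' Distributes the focal row total over categories in the proportions
#' observed in the pooled reference ("others") row:
#' `expected_j = sum(focal) * others_j / sum(others)`. These are the counts
#' the focal population would show if its allele (or genotype) frequencies
#' equalled those of the pooled remaining populations. The output always sums
#' exactly to the focal total.
#'
#' @param focal Non-negative integer vector of observed focal counts
#'   (length 2 for REF/ALT alleles, length 3 for genotypes).
#' @param others Non-negative vector of pooled reference counts, same length.
#' @return Numeric vector of expected focal counts.
#' @examples
#' expected_counts(c(298, 44), c(61000, 24500))
#' @export
expected_counts <- function(focal, others) {
  if (length(focal) != length(others)) {
    stop("'focal' and 'others' must have the same length", call. = FALSE)
  }
  if (any(focal < 0) || any(others < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (sum(others) == 0) {
    stop("no reference population: 'others' counts are all zero", call. = FALSE)
  }
  sum(focal) * others / sum(others)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test conditioning on both margins. The p-value is the sum
#' of hypergeometric probabilities of every table with the observed margins
#' whose point probability does not exceed the observed table's (with a
#' relative tie tolerance of 1e-7). Any zero row or column margin makes the
#' table degenerate and returns p = 1.
#'
#' @param x 2x2 matrix of non-negative integer counts
#'   (rows: focal/others; columns: REF/ALT).
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(rbind(c(3, 1), c(1, 3)))
#' @seealso [fisher_exact_2xk()] for 2xK tables.
#' @export
fisher_exact_2x2 <- function(x) {
  x <- validate_table(x, "2x2 table")
  if (ncol(x) != 2L) stop("2x2 table must have exactly 2 columns", call. = FALSE)
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) return(1)
  if (rs[2L] < rs[1L]) x <- x[2:1, , drop = FALSE]  # enumerate the smaller row
  n <- sum(x)
  n1 <- sum(x[1L, ])
  cs <- colSums(x)
  k <- seq.int(max(0, n1 - cs[2L]), min(n1, cs[1L]))
  logp <- lchoose(cs[1L], k) + lchoose(cs[2L], n1 - k) - lchoose(n, n1)
  obs <- logp[match(x[1L, 1L], k)]
  min(1, sum(exp(logp[logp <= obs + log1p(.tie_tol)])))
}

#' Fisher's exact test for a 2xK table (Freeman-Halton extension)
#'
#' Exact conditional test on a 2-row, K-column table, computed by full
#' enumeration of the K-1 free cells of the smaller-total row. The p-value is
#' the sum of multivariate hypergeometric point probabilities not exceeding
#' the observed table's probability (relative tie tolerance 1e-7). For K = 2
#' this reduces exactly to [fisher_exact_2x2()]. A zero row margin, or fewer
#' than two non-empty columns, returns p = 1.
#'
#' With the 2x3 genotype tables this package builds (focal row total a few
#' hundred), at most `(n+1)(n+2)/2` candidate tables are enumerated, so the
#' test stays exact at realistic cohort sizes.
#'
#' @param x 2xK matrix of non-negative integer counts, K >= 2.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2xk(rbind(c(130, 38, 3), c(30000, 10000, 2750)))
#' @export
fisher_exact_2xk <- function(x) {
  x <- validate_table(x, "2xK table")
  rs <- rowSums(x)
  if (any(rs == 0)) return(1)
  keep <- colSums(x) > 0
  if (sum(keep) < 2L) return(1)
  x <- x[, keep, drop = FALSE]
  if (rs[2L] < rs[1L]) x <- x[2:1, , drop = FALSE]
  n <- sum(x)
  n1 <- sum(x[1L, ])
  cs <- colSums(x)
  K <- ncol(x)

  # grid over the K-1 free cells of row 1; the last cell is forced
  free <- lapply(seq_len(K - 1L), function(j) seq.int(0, min(n1, cs[j])))
  grid <- as.matrix(expand.grid(free, KEEP.OUT.ATTRS = FALSE))
  last <- n1 - rowSums(grid)
  ok <- last >= 0 & last <= cs[K]
  grid <- grid[ok, , drop = FALSE]
  last <- last[ok]

  logp <- -lchoose(n, n1) + lchoose(cs[K], last)
  for (j in seq_len(K - 1L)) logp <- logp + lchoose(cs[j], grid[, j])
  obs <- -lchoose(n, n1) + sum(lchoose(cs, x[1L, ]))
  min(1, sum(exp(logp[logp <= obs + log1p(.tie_tol)])))
}

#' Benjamini-Hochberg step-up multiple-testing decision
#'
#' Applies the step-up false-discovery-rate rule at level `q`: with the
#' p-values sorted ascending, the largest k with `p(k) <= k*q/m` determines
#' the rejection set (hypotheses with the k smallest p-values). Tied p-values
#' share a fate. Implemented via [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q FDR level in (0, 1); default 0.05.
#' @return Logical vector, in the original order: `TRUE` where rejected.
#' @examples
#' benjamini_hochberg(c(0.001, 0.02, 0.04, 0.8), q = 0.05)
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (length(p) == 0L) return(logical(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("'q' must be a single value in (0, 1)", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH") <= q
}

#' Adjusted standardized residuals of a contingency table
#'
#' Haberman's adjusted residuals,
#' `r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - row_i/N) (1 - col_j/N))`,
#' which are approximately standard normal under independence and localise
#' the cells driving a significant test. For a 2x2 table every squared
#' residual equals the Pearson chi-square statistic. Cells whose expected
#' count (or variance term) is zero are returned as `NA`.
#'
#' @param observed 2xK matrix of non-negative counts.
#' @param expected Optional matrix of expected counts derived from the
#'   observed margins; computed as `outer(rowSums, colSums)/N` when omitted.
#' @return Matrix of residuals with the dimensions of `observed`.
#' @examples
#' adjusted_residuals(rbind(c(30, 10), c(10, 30)))
#' @export
adjusted_residuals <- function(observed, expected = NULL) {
  o <- validate_table(observed, "observed table")
  n <- sum(o)
  if (n <= 0) stop("grand total must be positive", call. = FALSE)
  rs <- rowSums(o)
  cs <- colSums(o)
  if (is.null(expected)) {
    e <- outer(rs, cs) / n
  } else {
    e <- as.matrix(expected)
    if (!all(dim(e) == dim(o))) {
      stop("dimension mismatch between observed and expected", call. = FALSE)
    }
  }
  v <- e * outer(1 - rs / n, 1 - cs / n)
  r <- (o - e) / sqrt(v)
  r[e == 0 | v == 0] <- NA_real_
  dimnames(r) <- dimnames(o)
  r
}

#' Allele-frequency spectrum of merged variants
#'
#' Histograms of per-label ALT allele frequencies over the variants with
#' non-absent counts in that label, on `n_bins` equal-width bins of \[0, 1\]
#' (half-open, last bin closed). When `focal` is given, an extra
#' `"others(pooled)"` histogram of the pooled non-focal frequencies is added,
#' so the focal spectrum can be compared against the combined remaining
#' populations.
#'
#' @param x A merged-variants object from [merge_by_key()] (possibly
#'   filtered).
#' @param labels Labels to tabulate; defaults to all labels in `x`.
#' @param n_bins Number of bins (>= 1); default 50.
#' @param focal Optional focal label triggering the pooled-others histogram.
#' @return An object of class `"af_spectrum"`: a list with `bin_edges`
#'   (length `n_bins + 1`) and `counts` (matrix, one row per histogram).
#' @export
allele_frequency_spectrum <- function(x, labels = NULL, n_bins = 50L,
                                      focal = NULL) {
  stopifnot(inherits(x, "merged_variants"), n_bins >= 1)
  if (is.null(labels)) labels <- x$labels
  if (!all(labels %in% x$labels)) stop("unknown label(s)", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  af <- alt_frequency_matrix(x)
  bin_counts <- function(f) {
    f <- f[is.finite(f)]
    tabulate(findInterval(f, edges, rightmost.closed = TRUE), nbins = n_bins)
  }
  counts <- t(vapply(labels, function(l) bin_counts(af[, l]),
                     numeric(n_bins)))
  rownames(counts) <- labels
  if (!is.null(focal)) {
    if (!focal %in% x$labels) stop("unknown focal label", call. = FALSE)
    oth <- setdiff(x$labels, focal)
    alt <- rowSums(2 * x$homalt[, oth, drop = FALSE] +
                     x$het[, oth, drop = FALSE], na.rm = TRUE)
    tot <- rowSums(2 * (x$homref[, oth, drop = FALSE] +
                          x$het[, oth, drop = FALSE] +
                          x$homalt[, oth, drop = FALSE]), na.rm = TRUE)
    counts <- rbind(counts, "others(pooled)" = bin_counts(alt / tot))
  }
  structure(list(bin_edges = edges, counts = counts), class = "af_spectrum")
}

# internal: per-label ALT allele frequency matrix of a merged object
# (NA where absent, NaN where zero alleles were called)
alt_frequency_matrix <- function(x) {
  (2 * x$homalt + x$het) / (2 * (x$homref + x$het + x$homalt))
}
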