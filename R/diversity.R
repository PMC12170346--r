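# Clonal expansion and repertoire diversity summaries: size bins, Shannon
# entropy, D50, and between-group size-distribution tests.

SIZE_BINS <- c("1", "2-5", "6-10", "11-20", "21+")

size_to_bin <- function(sizes) {
  cut(sizes, breaks = c(0, 1, 5, 10, 20, Inf), labels = SIZE_BINS)
}

#' Shannon entropy of a clonotype size distribution
#'
#' `H = -sum p_i log2 p_i` in bits, with `p_i` the fraction of cells in
#' clonotype i. The normalized variant divides by `log2(R)` (number of
#' clonotypes; defined as 0 for a single clonotype).
#'
#' @param sizes Positive integer clonotype sizes (cells per clonotype).
#' @return List with `shannon_bits`, `shannon_normalized`,
#'   `n_clonotypes`, `n_cells`.
#' @export
#' @examples
#' shannon_entropy(c(1, 1, 1, 1))$shannon_bits # 2
shannon_entropy <- function(sizes) {
  if (length(sizes) == 0L) abort("sizes must be non-empty")
  if (any(sizes <= 0) || any(sizes != round(sizes)))
    abort("sizes must be positive integers")
  p <- sizes / sum(sizes)
  h <- -sum(p * log2(p))
  r <- length(sizes)
  list(shannon_bits = h,
       shannon_normalized = if (r == 1L) 0 else h / log2(r),
       n_clonotypes = r, n_cells = sum(sizes))
}

#' D50 repertoire diversity
#'
#' The minimal number of largest clonotypes that together account for at
#' least 50% of cells, and that number as a percentage of all clonotypes.
#'
#' @inheritParams shannon_entropy
#' @return List with `d50_count`, `d50_percent`.
#' @export
#' @examples
#' d50(c(5, 3, 1, 1)) # count 1, percent 25
d50 <- function(sizes) {
  if (length(sizes) == 0L) abort("sizes must be non-empty")
  if (any(sizes <= 0) || any(sizes != round(sizes)))
    abort("sizes must be positive integers")
  s <- sort(sizes, decreasing = TRUE, method = "radix") # stable
  k <- which(cumsum(s) >= 0.5 * sum(s))[1]
  list(d50_count = as.integer(k), d50_percent = 100 * k / length(sizes))
}

#' Full diversity profile of a repertoire
#' @inheritParams shannon_entropy
#' @return List combining [shannon_entropy()] and [d50()] fields.
#' @export
diversity_profile <- function(sizes) {
  c(shannon_entropy(sizes), d50(sizes))
}

#' Bin clonotype sizes into the standard expansion bins
#'
#' Bins: 1, 2-5, 6-10, 11-20, 21+. Proportions are computed over
#' clonotypes (default) or weighted by cells.
#'
#' @param sizes Positive integer clonotype sizes, or a
#'   `clonotype_assignment` (its clonotype sizes are used).
#' @param basis `"clonotypes"` or `"cells"`.
#' @return Tibble with `bin`, `count` (clonotypes or cells per bin) and
#'   `proportion` (sums to 1).
#' @export
bin_clonotype_sizes <- function(sizes, basis = c("clonotypes", "cells")) {
  basis <- match.arg(basis)
  if (inherits(sizes, "clonotype_assignment")) sizes <- sizes$clonotypes$size
  if (length(sizes) == 0L) abort("sizes must be non-empty")
  b <- size_to_bin(sizes)
  w <- if (basis == "cells") sizes else rep(1L, length(sizes))
  count <- vapply(SIZE_BINS, function(lv) sum(w[b == lv]), numeric(1))
  tibble(bin = factor(SIZE_BINS, levels = SIZE_BINS),
         count = unname(count),
         proportion = unname(count) / sum(count))
}

#' Chi-squared comparison of two clonotype size-bin distributions
#'
#' Builds the 2 x 5 count table over the standard bins and applies the
#' Pearson chi-squared independence test; bins empty in both groups are
#' pooled with their left neighbour (the first bin pools rightwards).
#'
#' @param counts_a,counts_b Per-bin counts in the order of `SIZE_BINS`
#'   (vectors of length 5), or tibbles from [bin_clonotype_sizes()].
#' @return A `ct_test_result`.
#' @export
compare_size_distributions <- function(counts_a, counts_b) {
  as_counts <- function(x) {
    if (is.data.frame(x)) x <- x$count
    if (length(x) != length(SIZE_BINS)) abort("expected one count per size bin")
    as.numeric(x)
  }
  a <- as_counts(counts_a); b <- as_counts(counts_b)
  if (sum(a) == 0 || sum(b) == 0) abort("both groups must contain counts")
  m <- rbind(a, b)
  # pool all-empty bins with a neighbour so expected counts exist
  while (ncol(m) > 1 && any(colSums(m) == 0)) {
    k <- which(colSums(m) == 0)[1]
    tgt <- if (k == 1) 2L else k - 1L
    m[, tgt] <- m[, tgt] + m[, k]
    m <- m[, -k, drop = FALSE]
  }
  chi2_independence(m)
}
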