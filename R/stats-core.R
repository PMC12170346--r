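# Statistical primitives used throughout the pipeline: contingency-table
# tests (Pearson chi-squared, exact r x c Fisher by full enumeration),
# two-sample location tests and Benjamini-Hochberg adjustment.

#' Construct a validated contingency table
#'
#' A thin wrapper around a labelled integer matrix with the invariants the
#' downstream tests rely on: non-negative counts, at least 2 rows and 2
#' columns, and a positive grand total.
#'
#' @param counts Matrix (or coercible) of non-negative integer counts,
#'   r rows x c columns with r, c >= 2.
#' @param row_labels,col_labels Optional character labels; defaults are taken
#'   from `dimnames(counts)` or generated.
#' @return An integer matrix of class `contingency_table`.
#' @export
#' @examples
#' contingency_table(rbind(c(6, 1, 0), c(1, 3, 2)),
#'                   row_labels = c("pre", "post"),
#'                   col_labels = c("Treg", "Tcm", "Tem"))
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(counts)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    abort("counts must be non-negative integers")
  if (nrow(m) < 2L || ncol(m) < 2L)
    abort("a contingency table needs at least 2 rows and 2 columns")
  if (sum(m) < 1) abort("grand total must be >= 1")
  storage.mode(m) <- "integer"
  rownames(m) <- row_labels %||% rownames(m) %||% paste0("r", seq_len(nrow(m)))
  colnames(m) <- col_labels %||% colnames(m) %||% paste0("c", seq_len(ncol(m)))
  class(m) <- c("contingency_table", class(m))
  m
}

new_test_result <- function(statistic, df, p, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = min(max(unname(p), .Machine$double.xmin), 1), method = method),
            class = "ct_test_result")
}

#' @export
print.ct_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' Pearson chi-squared test of independence
#'
#' Pearson's X-squared without continuity correction on an r x c count
#' table, with df = (r-1)(c-1) and the p-value from the upper chi-squared
#' tail. Errors if any row or column margin is zero (expected counts would
#' be undefined).
#'
#' @param table A matrix of counts or a [contingency_table()].
#' @return A `ct_test_result` with fields `statistic`, `df`, `p`.
#' @export
#' @examples
#' chi2_independence(rbind(c(6, 2), c(2, 6)))
chi2_independence <- function(table) {
  m <- if (inherits(table, "contingency_table")) table else contingency_table(table)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) abort(sprintf("zero row margin: %s", rownames(m)[which(rs == 0)[1]]))
  if (any(cs == 0)) abort(sprintf("zero column margin: %s", colnames(m)[which(cs == 0)[1]]))
  ht <- suppressWarnings(chisq.test(unclass(m), correct = FALSE))
  res <- new_test_result(ht$statistic, ht$parameter, ht$p.value, "Pearson chi-squared")
  ct_log(sprintf("chi2_independence: X2 = %.4g, df = %d, p = %.4g",
                 res$statistic, as.integer(res$df), res$p))
  res
}

# --- exact r x c Fisher test -------------------------------------------------

# Enumerate all tables with the given margins; return their log-probabilities
# under the multivariate hypergeometric null:
#   P(T) = (prod r_i! prod c_j!) / (N! prod n_ij!)
enumerate_margin_tables <- function(row_sums, col_sums) {
  r <- length(row_sums); k <- length(col_sums)
  n <- sum(row_sums)
  stopifnot(n == sum(col_sums))
  log_const <- sum(lgamma(row_sums + 1)) + sum(lgamma(col_sums + 1)) - lgamma(n + 1)
  # depth-first over rows; within a row, over compositions bounded by the
  # remaining column totals; the last row is forced by the column remainders
  out <- new.env(); out$lp <- numeric(0)
  rec_row <- function(row_idx, col_left, log_fact_acc) {
    if (row_idx == r) {
      if (any(col_left < 0)) return()
      out$lp <- c(out$lp, log_const - log_fact_acc - sum(lgamma(col_left + 1)))
      return()
    }
    target <- row_sums[row_idx]
    comp <- function(j, left, cl, lf) {
      if (j == k) {
        if (left > cl[k]) return()
        cl[k] <- cl[k] - left
        rec_row(row_idx + 1L, cl, lf + lgamma(left + 1))
        return()
      }
      for (v in 0:min(left, cl[j])) {
        cl2 <- cl; cl2[j] <- cl2[j] - v
        comp(j + 1L, left - v, cl2, lf + lgamma(v + 1))
      }
    }
    comp(1L, target, col_left, log_fact_acc)
  }
  rec_row(1L, col_sums, 0)
  out$lp
}

log_table_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

#' Exact Fisher test for an r x c contingency table
#'
#' Exact conditional test by complete enumeration of every table with the
#' observed row and column margins. The two-sided p-value uses
#' probability-mass ordering: the sum of the null probabilities of all
#' tables whose probability does not exceed that of the observed table
#' (relative tie tolerance 1e-9). For 2 x 2 tables this reduces to the
#' classical two-sided hypergeometric test.
#'
#' @param table Count matrix or [contingency_table()]. Empty rows and
#'   columns are dropped; a table with fewer than 2 informative rows or
#'   columns is conditionally degenerate and returns p = 1.
#' @param max_total Enumeration guard on the grand total (default 500);
#'   larger tables raise an error suggesting a Monte Carlo approach, which
#'   this package does not implement.
#' @return The exact two-sided p-value (scalar).
#' @export
#' @examples
#' fisher_exact_rxc(rbind(c(6, 1, 0), c(1, 3, 2))) # 0.0414
fisher_exact_rxc <- function(table, max_total = 500) {
  m <- as.matrix(table)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    abort("counts must be non-negative integers")
  n <- sum(m)
  if (n < 1) abort("grand total must be >= 1")
  if (n > max_total)
    abort(sprintf(paste0("grand total %d exceeds the enumeration guard (%d); ",
                         "an exact enumeration is infeasible - consider a Monte ",
                         "Carlo approximation (not implemented)"), n, max_total))
  # drop empty margins: they carry no information and break the enumeration
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) return(1)
  lp <- enumerate_margin_tables(rowSums(m), colSums(m))
  lp_obs <- log_table_prob(m)
  p <- sum(exp(lp[lp <= lp_obs + log1p(1e-9)]))
  p <- min(p, 1)
  ct_log(sprintf("fisher_exact_rxc: %dx%d table, N = %d, p = %.4g",
                 nrow(m), ncol(m), n, p))
  p
}

#' Two-sided Student t tail probability
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom (> 0; may be fractional, e.g. Welch).
#' @return p = 2 P(T_df >= |t|).
#' @export
#' @examples
#' student_t_two_sided_p(2.824, 42) # 0.0072
student_t_two_sided_p <- function(t, df) {
  if (!is.numeric(df) || any(df <= 0)) abort("df must be > 0")
  2 * pt(-abs(t), df = df)
}

#' Two-sample t test (pooled or Welch)
#'
#' Computes the independent two-sample t statistic directly from the
#' pooled-variance (Student) or Welch formulas, with the p-value from
#' [student_t_two_sided_p()]. When both samples have zero variance the test
#' returns statistic 0 / p 1 if the means are equal and errors otherwise
#' (the statistic would be infinite).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance Student form (`TRUE`, default) or
#'   Welch's unequal-variance form.
#' @return A `ct_test_result`.
#' @export
two_sample_t_test <- function(x, y, pooled = TRUE) {
  if (length(x) < 2L || length(y) < 2L) abort("each sample needs n >= 2")
  if (anyNA(x) || anyNA(y)) abort("missing values not supported")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  dm <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (dm == 0) return(new_test_result(0, nx + ny - 2, 1, "two-sample t (degenerate)"))
    abort("both samples have zero variance but different means: t undefined")
  }
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- dm / se
  res <- new_test_result(tstat, df, student_t_two_sided_p(tstat, df),
                         if (pooled) "two-sample t (pooled)" else "Welch t")
  ct_log(sprintf("two_sample_t_test: t = %.4g, df = %.4g, p = %.4g",
                 res$statistic, res$df, res$p))
  res
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks are used for ties. With `mode = "auto"` the exact two-sided
#' p-value is computed when the combined sample size is <= 12 and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A `ct_test_result`; `statistic` is the Mann-Whitney U for `x`,
#'   `df` is `NA`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) < 1L || length(y) < 1L) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
    auto = (length(x) + length(y)) <= 12L && !ties,
    exact = TRUE,
    normal = FALSE)
  if (exact && ties)
    abort("exact mode is unavailable with ties; use mode = 'normal'")
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  res <- new_test_result(ht$statistic, NA_real_, ht$p.value,
                         if (exact) "Wilcoxon rank-sum (exact)"
                         else "Wilcoxon rank-sum (normal approx.)")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_i = min_{j >= i} m p_(j) / j`, mapped back to
#' the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
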