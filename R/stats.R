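# Inferential machinery: Pearson/Spearman correlation tests with t-based
# two-tailed p values, partial rank correlations, least-squares
# residualization, Benjamini-Hochberg FDR, and the Fisher-z comparison of
# two correlations.

new_correlation_result <- function(method, estimate, n, k = 0L,
                                   statistic, p) {
  structure(
    list(method = method, estimate = estimate, n = n,
         df = n - 2L - k, statistic = statistic,
         p = p, p_fdr = NA_real_),
    class = "correlation_result"
  )
}

#' Two-tailed p value for a correlation estimate
#'
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k` referred to the
#' Student-t distribution; the t approximation is also used for Spearman's
#' rho. Useful for reproducing a test from a printed `(r, n)` pair.
#'
#' @param estimate Correlation estimate in (-1, 1) (p is 0 at the bounds).
#' @param n Sample size.
#' @param k Number of covariates partialled out (default 0).
#' @return Two-tailed p value.
#' @export
correlation_pvalue <- function(estimate, n, k = 0L) {
  df <- n - 2L - k
  if (df < 1L) stop("need n > k + 2")
  if (abs(estimate) >= 1) return(0)
  tt <- estimate * sqrt(df / (1 - estimate^2))
  2 * stats::pt(-abs(tt), df)
}

#' Correlation test (Pearson or Spearman, t-based p)
#'
#' Spearman's rho is computed as the Pearson correlation of average ranks;
#' both methods use the t approximation
#' `t = est * sqrt((n - 2)/(1 - est^2))` with `n - 2` df for the two-tailed
#' p value.
#'
#' @param x,y Paired numeric vectors without missing values, `n >= 4`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `correlation_result` with fields `method`, `estimate`, `n`,
#'   `df`, `statistic`, `p`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  r <- stats::cor(x, y)
  if (1 - r^2 < .Machine$double.eps) {
    return(new_correlation_result(method, r, n,
                                  statistic = sign(r) * Inf, p = 0))
  }
  tt <- r * sqrt((n - 2L) / (1 - r^2))
  new_correlation_result(method, r, n, statistic = tt,
                         p = 2 * stats::pt(-abs(tt), n - 2L))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: est = %.4f, n = %d, df = %d, p = %.4g\n",
              x$method, x$estimate, x$n, x$df, x$p))
  invisible(x)
}

#' Least-squares residualization
#'
#' Residuals of `y` regressed on an intercept plus the covariates; zero
#' mean and orthogonal to every covariate column.
#'
#' @param y Numeric response.
#' @param covariates Numeric matrix/data.frame of covariate columns (may
#'   have zero columns).
#' @return Residual vector.
#' @export
residualize <- function(y, covariates) {
  X <- as.matrix(covariates)
  if (nrow(X) == 0L || is.null(dim(X))) stop("invalid covariates")
  if (nrow(X) != length(y)) stop("covariate rows must match length(y)")
  design <- cbind(intercept = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("rank-deficient covariate design")
  }
  as.numeric(qr.resid(qrd, y))
}

#' Partial rank correlation
#'
#' Rank-transforms all variables (average ranks for ties), residualizes `x`
#' and `y` on the covariates plus an intercept, and correlates the
#' residuals; two-tailed p from the t approximation with `n - 2 - k` df.
#' With `method = "pearson"` the rank transform is skipped.
#'
#' @param x,y Paired numeric vectors.
#' @param covariates Matrix/data.frame of covariate columns.
#' @param method `"spearman"` (default, rank-based) or `"pearson"`.
#' @return A `correlation_result` (method `partial_spearman` or
#'   `partial_pearson`).
#' @export
partial_rank_correlation <- function(x, y, covariates,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  Z <- as.matrix(covariates)
  if (is.null(ncol(Z))) Z <- matrix(Z, ncol = 1L)
  k <- ncol(Z)
  n <- length(x)
  if (length(y) != n || (k > 0L && nrow(Z) != n)) {
    stop("x, y and covariates must share the sample size")
  }
  if (n <= k + 3L) stop("need n > k + 3")
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
    if (k > 0L) Z <- apply(Z, 2L, rank)
  }
  if (k == 0L) {
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    rx <- residualize(x, Z)
    ry <- residualize(y, Z)
  }
  label <- paste0("partial_", method)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    # no residual variance left to explain (e.g. a covariate duplicates y)
    return(new_correlation_result(label, 0, n, k, statistic = 0, p = 1))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  if (1 - r^2 < .Machine$double.eps) {
    return(new_correlation_result(label, r, n, k,
                                  statistic = sign(r) * Inf, p = 0))
  }
  tt <- r * sqrt(df / (1 - r^2))
  new_correlation_result(label, r, n, k, statistic = tt,
                         p = 2 * stats::pt(-abs(tt), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values: `adj_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1 and order-preserving.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @return Adjusted p values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Compare two correlation coefficients (independent-samples Fisher z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-tailed standard-normal p. The independent-samples formula is used
#' even when the two correlations share subjects, reproducing the common
#' reporting convention for comparing a network's BGC and within-network
#' correlations in the same sample; a dependent-correlations test would
#' additionally need the correlation between the two measures.
#'
#' @param r1,r2 Correlation estimates with `|r| < 1`.
#' @param n1,n2 Sample sizes (each > 3).
#' @return List with signed `z` and two-tailed `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Per-unit association table between a connectivity measure and a symptom
#'
#' Runs one [correlation_test()] per unit (network or region) and, when
#' `fdr = TRUE`, adjusts across the family of all units in the table with
#' [bh_fdr()].
#'
#' @param measures Unit x subject numeric matrix with unit labels as
#'   rownames.
#' @param symptom Per-subject symptom values aligned to the columns.
#' @param method `"pearson"` or `"spearman"`.
#' @param fdr Adjust across the table's family (default `TRUE`).
#' @return Data frame with columns `unit`, `estimate`, `statistic`, `p`,
#'   `p_fdr`, and attribute `family_size`.
#' @export
association_table <- function(measures, symptom,
                              method = c("pearson", "spearman"),
                              fdr = TRUE) {
  method <- match.arg(method)
  measures <- as.matrix(measures)
  if (ncol(measures) != length(symptom)) {
    stop("subjects in measures and symptom must align")
  }
  if (ncol(measures) < 4L) stop("need at least 4 subjects")
  units <- rownames(measures)
  if (is.null(units)) units <- sprintf("unit_%03d", seq_len(nrow(measures)))
  tests <- lapply(seq_len(nrow(measures)), function(i) {
    correlation_test(measures[i, ], symptom, method)
  })
  out <- data.frame(
    unit = units,
    estimate = vapply(tests, `[[`, numeric(1), "estimate"),
    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$p_fdr <- if (fdr) bh_fdr(out$p) else NA_real_
  attr(out, "family_size") <- nrow(out)
  out
}
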