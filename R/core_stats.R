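#' Construct a test result
#'
#' Light container for an observed statistic together with its p-value and
#' the provenance of the null distribution (analytic or resampled).
#'
#' @param statistic observed test statistic.
#' @param p_value p-value in (0, 1].
#' @param null_size number of resamples behind an empirical p-value; 0 for
#'   analytic tests.
#' @param tail one of `"lower"`, `"upper"`, `"two_sided"`.
#' @param method label describing the test.
#' @return An object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, null_size = 0L,
                        tail = "two_sided", method = "") {
  tail <- match.arg(tail, c("lower", "upper", "two_sided"))
  stopifnot(is.numeric(p_value), length(p_value) == 1L,
            p_value > 0, p_value <= 1)
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         null_size = as.integer(null_size), tail = tail, method = method),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s\n", x$method))
  cat(sprintf("  statistic = %.6g, p = %.4g (%s tail)\n",
              x$statistic, x$p_value, x$tail))
  if (x$null_size > 0)
    cat(sprintf("  empirical null: %d resamples\n", x$null_size))
  invisible(x)
}

#' Rank expression within each sample
#'
#' Replaces every column of a gene-by-sample matrix with within-sample ranks
#' (1 = lowest expression, ties get average ranks). This is the global
#' preprocessing applied to every dataset before any correlation is computed:
#' it removes cross-sample scale and batch differences while preserving the
#' within-sample ordering of genes.
#'
#' @param mat numeric gene-by-sample matrix with no missing values.
#' @return Matrix of the same dimensions and dimnames holding average ranks;
#'   every column sums to G(G+1)/2 for G genes.
#' @export
rank_within_sample <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 genes to rank")
  if (anyNA(mat)) stop("missing values must be handled before ranking")
  if (!is.numeric(mat)) stop("expression matrix must be numeric")
  const <- apply(mat, 2L, function(x) diff(range(x)) == 0)
  if (any(const))
    warning(sprintf("%d constant sample column(s); all ranks set to (G+1)/2",
                    sum(const)))
  ranked <- apply(mat, 2L, rank, ties.method = "average")
  dimnames(ranked) <- dimnames(mat)
  ranked
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors of equal length (n >= 2); neither may be
#'   constant.
#' @return Spearman's rho in \[-1, 1\], with average-rank tie handling.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("undefined correlation: need n >= 2")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("undefined correlation: constant input")
  stats::cor(x, y, method = "spearman")
}

#' Empirical p-value against a resampled null
#'
#' Uses the add-one rule p = (b + 1) / (n + 1), where b counts null values at
#' least as extreme as the observed statistic in the stated tail; the p-value
#' can therefore never be zero, and equals 1/(n+1) when the observation beats
#' every resample. The two-sided p is 2 * min(lower, upper), capped at 1.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of resampled null statistics (length
#'   >= 1).
#' @param tail `"lower"`, `"upper"` or `"two_sided"`.
#' @param method label recorded in the result.
#' @return A [test_result].
#' @export
empirical_p <- function(observed, null_values,
                        tail = c("two_sided", "lower", "upper"),
                        method = "empirical permutation") {
  tail <- match.arg(tail)
  null_values <- null_values[!is.na(null_values)]
  n <- length(null_values)
  if (n < 1L) stop("empty null distribution")
  p_lower <- (sum(null_values <= observed) + 1) / (n + 1)
  p_upper <- (sum(null_values >= observed) + 1) / (n + 1)
  p <- switch(tail,
    lower = p_lower,
    upper = p_upper,
    two_sided = min(1, 2 * min(p_lower, p_upper))
  )
  test_result(observed, p, null_size = n, tail = tail, method = method)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on elementwise differences. Zero differences
#' are dropped (the standard convention); if every difference is zero the
#' test is degenerate and p = 1 is returned with a warning. Exact p-values
#' are used when the difference vector is tie-free and small; otherwise the
#' normal approximation with continuity correction applies. The statistic is
#' V, the sum of the (average) ranks of positive differences.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return A [test_result] with statistic V.
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero; returning p = 1")
    return(test_result(0, 1, tail = "two_sided",
                       method = "paired Wilcoxon signed-rank (degenerate)"))
  }
  if (length(nz) < 5L)
    warning("fewer than 5 non-zero differences; signed-rank p is coarse")
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  test_result(unname(wt$statistic), max(wt$p.value, .Machine$double.xmin),
              tail = "two_sided", method = "paired Wilcoxon signed-rank")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' @param a,b numeric vectors (each of length >= 2), not paired.
#' @return A two-sided [test_result] with the Mann-Whitney U statistic.
#' @export
ranksum_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (diff(range(c(a, b))) == 0) {
    warning("all observations tied; rank-sum test degenerate, p = 1")
    return(test_result(length(a) * length(b) / 2, 1, tail = "two_sided",
                       method = "Wilcoxon rank-sum (degenerate)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  test_result(unname(wt$statistic), wt$p.value,
              tail = "two_sided", method = "Wilcoxon rank-sum")
}

#' Combine p-values across studies
#'
#' `method = "fisher"` combines k p-values through the chi-square statistic
#' -2 * sum(log p) on 2k degrees of freedom. `method = "fisher_trend"` is the
#' direction-aware variant used for meta-analysis of two-sided per-study
#' tests: each two-sided p is first folded to a one-sided value (p/2 when the
#' study's effect direction agrees with the consensus direction, 1 - p/2 when
#' it opposes it), and the folded values are then Fisher-combined. The
#' consensus direction is the sign of the sum of the per-study direction
#' signs; a perfect tie is an error because no trend is defined.
#'
#' Zero p-values are clamped to the smallest positive double with a warning,
#' so permutation p-values produced outside the add-one convention do not
#' break the logarithm.
#'
#' @param ps numeric vector of p-values in (0, 1\].
#' @param directions numeric vector of per-study effect directions (any
#'   nonzero values; only the signs are used). Required for
#'   `"fisher_trend"`.
#' @param method `"fisher"` or `"fisher_trend"`.
#' @return A [test_result]; the statistic is the chi-square value, `p_value`
#'   its upper-tail probability on 2k df.
#' @export
combine_pvalues <- function(ps, directions = NULL,
                            method = c("fisher", "fisher_trend")) {
  method <- match.arg(method)
  if (length(ps) < 1L) stop("no p-values to combine")
  if (any(is.na(ps)) || any(ps < 0) || any(ps > 1))
    stop("p-values must lie in (0, 1]")
  if (any(ps == 0)) {
    warning("p-value of 0 clamped to the smallest positive double")
    ps[ps == 0] <- .Machine$double.xmin
  }
  if (method == "fisher_trend") {
    if (is.null(directions) || length(directions) != length(ps))
      stop("fisher_trend requires one direction per p-value")
    sgn <- sign(directions)
    if (any(sgn == 0)) stop("directions must be nonzero")
    consensus <- sign(sum(sgn))
    if (consensus == 0)
      stop("no consensus direction: direction signs are perfectly tied")
    ps <- ifelse(sgn == consensus, ps / 2, 1 - ps / 2)
  }
  k <- length(ps)
  chisq <- -2 * sum(log(ps))
  p <- stats::pchisq(chisq, df = 2 * k, lower.tail = FALSE)
  test_result(chisq, max(p, .Machine$double.xmin), tail = "upper",
              method = sprintf("%s combination of %d p-values", method, k))
}
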