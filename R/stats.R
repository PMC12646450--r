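# Nonparametric group comparisons shared by every analysis stage.
# All tests are two-sided; normality testing is diagnostic only and never
# switches the rank tests off.

test_result <- function(statistic, p_value, method, n_used, paired,
                        degenerate = FALSE) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         method = method, n_used = n_used, paired = paired,
         degenerate = degenerate),
    class = "sleepeeg_test"
  )
}

#' @export
print.sleepeeg_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d%s)\n", x$method,
              x$statistic, x$p_value, x$n_used,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired Wilcoxon. Incomplete pairs (NA in either member) are
#' dropped, then zero differences are dropped (Wilcoxon's original rule).
#' The exact distribution is used for n <= 25 without ties; otherwise the
#' tie-corrected normal approximation. If every difference is zero the
#' result is flagged degenerate with p = 1.
#'
#' @param x,y Paired per-subject values (equal length).
#' @return A test result with `statistic` (V), `p_value`, `method`,
#'   `n_used` (pairs after dropping), `paired`, `degenerate`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  d <- x - y
  nz <- d != 0
  if (sum(keep) < 2) stop("need at least 2 complete pairs")
  if (!any(nz)) {
    return(test_result(0, 1, "Wilcoxon signed-rank (degenerate)",
                       length(d), TRUE, degenerate = TRUE))
  }
  dd <- d[nz]
  n <- length(dd)
  r <- rank(abs(dd))
  v <- sum(r[dd > 0])
  if (n <= 25) {
    p <- signed_rank_exact_p(r, v)
    return(test_result(v, p, "Wilcoxon signed-rank (exact)", n, TRUE))
  }
  wt <- suppressWarnings(
    wilcox.test(dd, alternative = "two.sided", mu = 0, exact = FALSE,
                correct = TRUE)
  )
  test_result(wt$statistic, wt$p.value, "Wilcoxon signed-rank", n, TRUE)
}

# Exact two-sided signed-rank p-value, valid under tied absolute
# differences: the null distribution of V (sum of positive mid-ranks) is
# built by the shift algorithm — a generating-function convolution over
# the 2^n equiprobable sign assignments. Ranks are doubled so that
# mid-ranks (x.5) stay integral.
signed_rank_exact_p <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (ri in r2) {
    g <- f / 2
    g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)] / 2
    f <- g
  }
  v2 <- as.integer(round(2 * v))
  lower <- sum(f[seq_len(v2 + 1)])
  upper <- sum(f[(v2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Mann-Whitney U test (unpaired Wilcoxon rank-sum)
#'
#' Two-sided. Exact for small samples without ties, tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Group values (each of length >= 2 after removing NA).
#' @return A test result; `statistic` is the Mann-Whitney U of `x`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values")
  }
  exact <- length(x) + length(y) <= 50 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)
  )
  test_result(wt$statistic, wt$p.value, "Mann-Whitney U",
              length(x) + length(y), FALSE)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS against a normal with the sample's mean and SD. Reported
#' as a diagnostic only; analyses in this package are rank-based
#' regardless of its outcome. (With estimated parameters the test is
#' anti-conservative; treat p as descriptive.)
#'
#' @param x Numeric values, n >= 3, non-constant.
#' @return A test result.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 values")
  s <- sd(x)
  if (s == 0) stop("constant input: SD is zero, KS test undefined")
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), s))
  test_result(kt$statistic, kt$p.value, "Kolmogorov-Smirnov normality",
              length(x), FALSE)
}

#' Kruskal-Wallis omnibus with Dunn post-hoc pairwise tests
#'
#' Tie-corrected Kruskal-Wallis H across groups, followed by Dunn's
#' pairwise z-tests on mean ranks with multiplicity adjustment over the
#' pairwise family (Holm by default; `"bonferroni"` and `"none"` are also
#' accepted).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @param p_adjust Adjustment method for the pairwise family.
#' @return List with `omnibus` (test result), `pairwise` (symmetric matrix
#'   of adjusted p-values), `z` (pairwise z statistics), and
#'   `pairwise_raw` (unadjusted p-values).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = c("holm", "bonferroni",
                                                      "none")) {
  p_adjust <- match.arg(p_adjust)
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 values")
  kw <- kruskal.test(values, factor(groups))
  omnibus <- test_result(kw$statistic, kw$p.value,
                         "Kruskal-Wallis", length(values), FALSE)

  # Dunn (1964) z statistics on mean ranks, with the tie correction.
  r <- rank(values)
  N <- length(values)
  gl <- names(tab)
  mean_rank <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  k <- length(gl)
  z <- matrix(NA_real_, k, k, dimnames = list(gl, gl))
  praw <- z
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) *
                   (1 / tab[[gl[i]]] + 1 / tab[[gl[j]]]))
      zij <- (mean_rank[[gl[i]]] - mean_rank[[gl[j]]]) / se
      z[i, j] <- z[j, i] <- zij
      praw[i, j] <- praw[j, i] <- 2 * pnorm(-abs(zij))
    }
  }
  upper <- praw[upper.tri(praw)]
  adj <- p.adjust(upper, method = p_adjust)
  padj <- praw
  padj[upper.tri(padj)] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(omnibus = omnibus, pairwise = padj, z = z, pairwise_raw = praw)
}
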