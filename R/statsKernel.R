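# Unequal-variance t-tests and correlation measures used by the
# group-comparison and concordance analyses.

#' Welch's unequal-variance t-test
#'
#' Two-sample t-test without the equal-variance assumption:
#' `t = (meanA - meanB) / sqrt(sA^2/nA + sB^2/nB)` with
#' Welch-Satterthwaite degrees of freedom. One-sided alternatives are
#' named explicitly: `"a_greater"` tests mean(a) > mean(b),
#' `"b_greater"` the reverse.
#'
#' When both groups have zero variance the standard error vanishes;
#' rather than fail, the test is flagged `degenerate` and reports
#' `t = +/-Inf` with p = 0 or 1 by direction (or `t = 0`, p = 1 when
#' the means also coincide), so that tiny constant groups behave
#' deterministically.
#'
#' @param a,b numeric vectors with at least 2 finite values each.
#' @param alternative `"two_sided"` (default), `"a_greater"` or
#'   `"b_greater"`.
#' @return a one-row data.frame: `nA`, `nB`, `meanA`, `meanB`, `t`,
#'   `df`, `p`, `alternative`, `degenerate`.
#' @examples
#' welchTTest(c(1, 2, 3), c(4, 5, 6))   # t = -3.674, df = 4, p ~ 0.021
#' @export
welchTTest <- function(a, b, alternative = c("two_sided", "a_greater",
                                             "b_greater")) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 finite values (got ",
         length(a), " and ", length(b), ")", call. = FALSE)
  nA <- length(a); nB <- length(b)
  mA <- mean(a); mB <- mean(b)
  vA <- var(a); vB <- var(b)
  seA2 <- vA / nA; seB2 <- vB / nB
  se2 <- seA2 + seB2
  if (se2 == 0) {
    delta <- mA - mB
    t <- if (delta == 0) 0 else sign(delta) * Inf
    p <- switch(alternative,
      two_sided = if (delta == 0) 1 else 0,
      a_greater = if (delta == 0) 0.5 else if (delta > 0) 0 else 1,
      b_greater = if (delta == 0) 0.5 else if (delta < 0) 0 else 1)
    return(data.frame(nA = nA, nB = nB, meanA = mA, meanB = mB,
                      t = t, df = NA_real_, p = p,
                      alternative = alternative, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / (seA2^2 / (nA - 1) + seB2^2 / (nB - 1))
  p <- switch(alternative,
              two_sided = 2 * pt(-abs(t), df),
              a_greater = pt(t, df, lower.tail = FALSE),
              b_greater = pt(t, df, lower.tail = TRUE))
  data.frame(nA = nA, nB = nB, meanA = mA, meanB = mB, t = t, df = df,
             p = p, alternative = alternative, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Paired t-test
#'
#' One-sample t-test on the paired differences `a - b`; provided for
#' completeness alongside [welchTTest()] (paired designs arise in
#' validation assays, not in the profiling pipeline itself).
#'
#' @inheritParams welchTTest
#' @return a one-row data.frame as in [welchTTest()] with `n` in
#'   place of `nA`/`nB`.
#' @export
pairedTTest <- function(a, b, alternative = c("two_sided", "a_greater",
                                              "b_greater")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  d <- a - b
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L)
    stop("need at least 2 finite pairs", call. = FALSE)
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- switch(alternative,
      two_sided = if (m == 0) 1 else 0,
      a_greater = if (m == 0) 0.5 else if (m > 0) 0 else 1,
      b_greater = if (m == 0) 0.5 else if (m < 0) 0 else 1)
    return(data.frame(n = n, meanDiff = m, t = t, df = NA_real_, p = p,
                      alternative = alternative, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  t <- m / (s / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
              two_sided = 2 * pt(-abs(t), df),
              a_greater = pt(t, df, lower.tail = FALSE),
              b_greater = pt(t, df, lower.tail = TRUE))
  data.frame(n = n, meanDiff = m, t = t, df = df, p = p,
             alternative = alternative, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

checkCorInput <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Pearson correlation
#'
#' @param x,y numeric vectors of equal length (>= 2), finite, each
#'   with nonzero variance.
#' @return the correlation coefficient in `[-1, 1]`.
#' @examples
#' pearsonCorrelation(1:5, 2 * (1:5) + 1)   # 1
#' @export
pearsonCorrelation <- function(x, y) {
  checkCorInput(x, y)
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  cor(x, y, method = "pearson")
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks, with average ranks for ties.
#'
#' @inheritParams pearsonCorrelation
#' @return the rank correlation coefficient in `[-1, 1]`.
#' @examples
#' spearmanCorrelation(c(1, 2, 3, 4), c(1, 2, 4, 3))   # 0.8
#' @export
spearmanCorrelation <- function(x, y) {
  checkCorInput(x, y)
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    stop("correlation undefined: zero rank variance", call. = FALSE)
  cor(x, y, method = "spearman")
}
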