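# Rank-based hypothesis tests, written from the standard formulas.
# Exact small-sample p-values come from full enumeration; large samples use
# the normal approximation with tie and continuity corrections.

#' Mann-Whitney U test (unpaired two-group comparison)
#'
#' U is computed from midranks. When `min(n_x, n_y) <= 8` and there are no
#' ties, the two-sided p-value is exact, by enumeration of all
#' `choose(n_x + n_y, n_x)` group labelings; otherwise a normal approximation
#' with tie correction and continuity correction is used. Two-sided extremity
#' is measured as distance of U from its null mean `n_x n_y / 2`.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return A one-row tibble with columns `effect` (rank-biserial-free U
#'   statistic is in `stat`; `effect` is the difference of group means),
#'   `stat` (U for `x`), `p`, `n1`, `n2`, `stars`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- midrank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  mu <- n1 * n2 / 2
  if (min(n1, n2) <= 8L && !ties && choose(n, n1) <= 2e5) {
    # exact null distribution of U over all labelings
    combs <- utils::combn(n, n1)
    rs <- colSums(matrix(r[combs], nrow = n1))
    u_null <- rs - n1 * (n1 + 1) / 2
    p <- mean(abs(u_null - mu) >= abs(u - mu) - 1e-12)
  } else {
    tab <- table(c(x, y))
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (abs(u - mu) - 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
  }
  new_test_result(mean(x) - mean(y), u, p, n1, n2, "mann_whitney")
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped; W+ is the sum of midranks of `|d|` over
#' positive differences. With `n <= 12` nonzero differences and no tied
#' `|d|`, the p-value is exact over all `2^n` sign patterns; otherwise a
#' normal approximation with tie correction is used.
#'
#' @param d Numeric vector of paired differences (e.g. tumor - normal).
#' @return One-row tibble; `stat` is W+, `effect` is the mean difference,
#'   `n1` the number of nonzero differences.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))
wilcoxon_signed_rank <- function(d) {
  d <- as.numeric(d)
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) < 2L) {
    stop("need at least 2 nonzero differences (degenerate pairing)",
         call. = FALSE)
  }
  n <- length(nz)
  r <- midrank(abs(nz))
  w <- sum(r[nz > 0])
  mu <- n * (n + 1) / 4
  ties <- any(duplicated(abs(nz)))
  if (n <= 12L && !ties) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_null <- as.vector(signs %*% r)
    p <- mean(abs(w_null - mu) >= abs(w - mu) - 1e-12)
  } else {
    tab <- table(abs(nz))
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- (abs(w - mu) - 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
  }
  new_test_result(mean(d), w, p, n, NA_integer_, "wilcoxon_signed_rank")
}

#' Correlation test (Pearson or Spearman)
#'
#' Spearman is Pearson on midranks. The two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, nonconstant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble; `effect` is r, `stat` the t statistic.
#' @export
#' @examples
#' correlation_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  if (method == "spearman") {
    x <- midrank(x); y <- midrank(y)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    tstat <- Inf * sign(r); p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  new_test_result(r, tstat, p, n, NA_integer_, paste0("correlation_", method))
}

#' Kruskal-Wallis test for three or more groups
#'
#' H with tie correction, referred to a chi-square distribution on k - 1
#' degrees of freedom.
#'
#' @param groups A list of numeric vectors (>= 3 groups, each >= 2 values).
#' @return One-row tibble; `stat` is H, `n1` the total sample size, `n2` the
#'   number of groups; `effect` is `NA` (no scalar effect size is defined).
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  groups <- purrr::map(groups, ~ as.numeric(.x)[!is.na(.x)])
  if (length(groups) < 3L) {
    stop("need >= 3 groups; use mann_whitney() for two groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  all_v <- unlist(groups, use.names = FALSE)
  n <- length(all_v)
  r <- midrank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  rsum <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
  tab <- table(all_v)
  corr <- 1 - sum(tab^3 - tab) / (n^3 - n)
  h <- if (corr > 0) h / corr else 0
  p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  new_test_result(NA_real_, h, p, n, length(groups), "kruskal_wallis")
}
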