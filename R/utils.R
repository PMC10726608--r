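#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. Input order is preserved: the
#' i-th q-value corresponds to the i-th p-value.
#'
#' @param p Numeric vector of p-values, all in \[0, 1\]. `NA`s are kept as
#'   `NA` and do not count toward the number of tests.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
benjamini_hochberg <- function(p) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  # step-up: running minimum of m * p_(i) / i from the largest p down
  q[ok] <- pmin(1, cummin(m / seq(m, 1L) * pv[o]))[ro]
  q
}

#' Significance stars for a p-value
#'
#' Maps p-values to the conventional star labels used to annotate group
#' comparisons on boxplots and radar axes: `ns` for p >= 0.05, then `*`,
#' `**`, `***`, `****` at the strict thresholds 0.05, 0.01, 0.001, 0.0001.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of labels.
#' @export
#' @examples
#' significance_stars(c(0.2, 0.03, 0.004, 5e-4, 1e-5))
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  dplyr::case_when(
    is.na(p)    ~ NA_character_,
    p < 0.0001  ~ "****",
    p < 0.001   ~ "***",
    p < 0.01    ~ "**",
    p < 0.05    ~ "*",
    TRUE        ~ "ns"
  )
}

# midranks (average ranks for ties)
midrank <- function(x) rank(x, ties.method = "average")

# one-row result tibble shared by the hypothesis tests
new_test_result <- function(effect, stat, p, n1, n2 = NA_integer_, method) {
  tibble::tibble(
    effect = as.numeric(effect),
    stat = as.numeric(stat),
    p = as.numeric(p),
    n1 = as.integer(n1),
    n2 = as.integer(n2),
    stars = significance_stars(p),
    method = method
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
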