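# Survival primitives: Cox proportional hazards (Efron ties, Newton-Raphson),
# the Kaplan-Meier product-limit estimator, and the two-group log-rank test.

# Efron partial log-likelihood, gradient and Hessian for covariate matrix x.
cox_loglik <- function(beta, time, event, x) {
  eta <- drop(x %*% beta)
  w <- exp(eta)
  p <- ncol(x)
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  for (t in sort(unique(time[event == 1]))) {
    dset <- which(time == t & event == 1)
    rset <- which(time >= t)
    d <- length(dset)
    s_r <- sum(w[rset]);  s_d <- sum(w[dset])
    z_r <- colSums(w[rset] * x[rset, , drop = FALSE])
    z_d <- colSums(w[dset] * x[dset, , drop = FALSE])
    q_r <- crossprod(x[rset, , drop = FALSE], w[rset] * x[rset, , drop = FALSE])
    q_d <- crossprod(x[dset, , drop = FALSE], w[dset] * x[dset, , drop = FALSE])
    ll <- ll + sum(eta[dset])
    for (l in seq_len(d) - 1L) {
      f <- l / d
      denom <- s_r - f * s_d
      num <- z_r - f * z_d
      qq <- q_r - f * q_d
      ll <- ll - log(denom)
      grad <- grad - num / denom
      hess <- hess - (qq / denom - tcrossprod(num) / denom^2)
    }
    grad <- grad + colSums(x[dset, , drop = FALSE])
  }
  list(ll = ll, grad = grad, hess = hess)
}

#' Cox proportional-hazards fit for a single gene, optionally age-adjusted
#'
#' Maximizes the Efron partial likelihood by Newton-Raphson (convergence when
#' the log-likelihood change is below 1e-9, at most 50 iterations). The
#' reported hazard ratio is always the gene covariate's, with a Wald 95%
#' confidence interval; with `age` supplied, age enters as a second
#' continuous covariate.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator (1 = death, 0 = censored).
#' @param x Numeric covariate of interest (e.g. gene expression).
#' @param age Optional second continuous covariate.
#' @return An object of class `pc_cox`: a one-row tibble with columns `hr`,
#'   `ci_low`, `ci_high`, `p`, `n`, `n_events`, `converged`,
#'   `adjusted_for_age`, plus attributes `coef` and `loglik`.
#' @export
cox_fit <- function(time, event, x, age = NULL) {
  keep <- stats::complete.cases(time, event, x) &
    (if (is.null(age)) TRUE else !is.na(age))
  time <- as.numeric(time)[keep]; event <- as.numeric(event)[keep]
  x <- as.numeric(x)[keep]
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  if (stats::sd(x) == 0) stop("covariate is constant (non-identifiable)", call. = FALSE)
  xm <- cbind(gene = x)
  if (!is.null(age)) xm <- cbind(xm, age = as.numeric(age)[keep])
  xm <- scale(xm, scale = FALSE)  # centering stabilizes exp(eta)
  p <- ncol(xm)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(50L)) {
    fit <- cox_loglik(beta, time, event, xm)
    if (!is.finite(fit$ll)) stop("Cox likelihood diverged", call. = FALSE)
    info <- -fit$hess
    step <- tryCatch(solve(info, fit$grad), error = function(e) NULL)
    if (is.null(step)) stop("singular information matrix in Cox fit", call. = FALSE)
    # halve the step until the likelihood does not decrease
    for (h in 0:5) {
      cand <- beta + step / 2^h
      ll_new <- cox_loglik(cand, time, event, xm)$ll
      if (is.finite(ll_new) && ll_new >= fit$ll - 1e-12) break
    }
    beta <- cand
    if (abs(ll_new - fit$ll) < 1e-9 && it > 1L) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  if (any(abs(beta) > 15)) {
    stop("monotone likelihood (perfect separation) in Cox fit", call. = FALSE)
  }
  final <- cox_loglik(beta, time, event, xm)
  se <- sqrt(diag(solve(-final$hess)))
  b <- unname(beta[1]); s <- unname(se[1])
  z <- b / s
  res <- tibble::tibble(
    hr = exp(b),
    ci_low = exp(b - 1.96 * s),
    ci_high = exp(b + 1.96 * s),
    p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    n = length(time),
    n_events = as.integer(sum(event)),
    converged = converged,
    adjusted_for_age = !is.null(age)
  )
  attr(res, "coef") <- stats::setNames(beta, colnames(xm))
  attr(res, "se") <- stats::setNames(se, colnames(xm))
  attr(res, "loglik") <- final$ll
  class(res) <- c("pc_cox", class(res))
  res
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return An object of class `pc_km`: a tibble with one row per distinct
#'   observed time, columns `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#'   `surv` starts from S(0) = 1 (implicit) and is non-increasing; with only
#'   censored observations it stays at 1.
#' @export
km_estimate <- function(time, event) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time)
  n <- length(time)
  d <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  c_ <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  surv <- cumprod(1 - d / n_risk)
  res <- tibble::tibble(
    time = ut, n_risk = as.integer(n_risk),
    n_event = as.integer(d), n_censor = as.integer(c_), surv = surv
  )
  class(res) <- c("pc_km", class(res))
  res
}

#' Two-group log-rank test
#'
#' Observed-minus-expected chi-square on 1 degree of freedom, with the
#' hypergeometric variance accumulated at each distinct event time.
#'
#' @param time,event As in [km_estimate()].
#' @param group A two-level grouping vector.
#' @return One-row tibble (see [mann_whitney()] for the schema); `stat` is
#'   the chi-square statistic, `n1`/`n2` the group sizes.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("log-rank test needs exactly 2 groups", call. = FALSE)
  time <- as.numeric(time); event <- as.numeric(event)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  g1 <- group == levels(group)[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  new_test_result(o_minus_e, chisq, p, sum(g1), sum(!g1), "logrank")
}
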