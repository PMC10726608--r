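# Independent brute-force oracles, kept free of the implementation paths
# they check.

# exact two-sided Mann-Whitney p by enumeration of all group labelings
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * length(y) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(n, n1)
  u_all <- apply(labelings, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# exact two-sided signed-rank p over all 2^n sign patterns
oracle_wsr_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(grid, 1L, function(s) sum(r[s]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Kruskal-Wallis H from the textbook rank formula (with tie correction)
oracle_kw_h <- function(groups) {
  v <- unlist(groups); n <- length(v); r <- rank(v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  tab <- table(v)
  h / (1 - sum(tab^3 - tab) / (n^3 - n))
}

# Kaplan-Meier product-limit computed row by row
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  out <- numeric(0)
  for (t in ut) {
    d <- sum(time == t & event == 1)
    n_r <- sum(time >= t)
    s <- s * (1 - d / n_r)
    out <- c(out, s)
  }
  tibble::tibble(time = ut, surv = out)
}

# Efron partial log-likelihood for a single covariate (independent of the
# package's implementation: written directly from the tie-handling formula)
oracle_efron_ll <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dset <- which(time == t & event == 1)
    rset <- which(time >= t)
    d <- length(dset)
    ll <- ll + sum(eta[dset])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(exp(eta[rset])) - (l / d) * sum(exp(eta[dset])))
    }
  }
  ll
}

oracle_cox_grid <- function(time, event, x, step = 1e-4, lim = 5) {
  grid <- seq(-lim, lim, by = step)
  ll <- vapply(grid, oracle_efron_ll, numeric(1), time = time, event = event,
               x = x)
  grid[which.max(ll)]
}

# midrank AUC identity: U / (n1 * n0)
oracle_auc_rank <- function(scores, pos) {
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ssGSEA score recomputed by literal running-sum walk (independent loop)
oracle_ssgsea <- function(values, set, alpha = 0.25) {
  o <- order(-values, names(values), method = "radix")
  nm <- names(values)[o]
  n <- length(nm)
  hit <- nm %in% set
  w <- (n - seq_len(n) + 1)^alpha
  run <- 0; total <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) w[i] / sum(w[hit]) else -1 / sum(!hit)
    total <- total + run
  }
  total
}
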