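test_that("generation is deterministic: same spec, same seed, same bundle", {
  spec <- cohort_spec(
    cancers = tibble::tibble(code = "TST", n_tumor = 30L, n_normal = 25L,
                             n_paired = 10L),
    n_genes = 40, seed = 99)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_identical(g1$cohort$expression, g2$cohort$expression)
  expect_identical(g1$truth, g2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(g1$cohort, d1, seed = 99)
  write_cohort(g2$cohort, d2, seed = 99)
  for (f in setdiff(list.files(d1, recursive = TRUE), "manifest.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("requested per-cancer sample counts are honored", {
  spec <- cohort_spec(
    cancers = tibble::tibble(code = c("A1", "B2", "C3"),
                             n_tumor = c(30L, 30L, 30L),
                             n_normal = c(25L, 25L, 25L),
                             n_paired = c(5L, 10L, 25L)),
    n_genes = 25, seed = 3)
  lc <- list_cancers(generate_cohort(spec)$cohort)
  expect_equal(nrow(lc), 3)
  expect_equal(lc$n_tumor, rep(30L, 3))
  expect_equal(lc$n_normal, rep(25L, 3))
  expect_equal(lc$n_pairs, c(5L, 10L, 25L))
})

test_that("infeasible pairing and missing seed are rejected", {
  expect_error(cohort_spec(
    cancers = tibble::tibble(code = "X", n_tumor = 5L, n_normal = 3L,
                             n_paired = 4L),
    n_genes = 10, seed = 1), "infeasible")
  expect_error(cohort_spec(
    cancers = tibble::tibble(code = "X", n_tumor = 5L, n_normal = 3L,
                             n_paired = 1L), n_genes = 10), "seed")
  expect_error(cohort_spec(
    cancers = tibble::tibble(code = "X", n_tumor = 5L, n_normal = 5L,
                             n_paired = 2L), n_genes = 10,
    planted_metric_corr = tibble::tibble(gene = "SG0001", cancer = "X",
                                         metric = "TMB", target_r = 1),
    seed = 1), "target_r")
})

test_that("a planted log2 fold change lands near its target at n = 50/50", {
  spec <- cohort_spec(
    cancers = tibble::tibble(code = "DE", n_tumor = 50L, n_normal = 50L,
                             n_paired = 50L),
    n_genes = 30,
    planted_de = tibble::tibble(gene = "SG0001", cancer = "DE", log2fc = 2),
    seed = 17)
  g <- generate_cohort(spec)
  expect_equal(g$truth$realized[g$truth$kind == "de"], 2, tolerance = 0.25)
  co <- g$cohort
  s <- co$samples
  diff <- mean(co$expression[s$sample_id[s$group == "tumor"], "SG0001"]) -
    mean(co$expression[s$sample_id[s$group == "normal"], "SG0001"])
  expect_lt(abs(diff - 2), 0.5)  # CLT bound at unit noise SD
})

test_that("null metric couplings stay near zero across seeds", {
  # target_r = 0 plants give |r| < 0.2 at n >= 100 in at least 95% of seeds
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    z <- stats::rnorm(100)
    tmb <- pmax(0, 10 + 3 * stats::rnorm(100))  # the generator's null draw
    abs(stats::cor(z, tmb)) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the reference fixture satisfies its advertised structure", {
  fx <- reference_fixture()
  co <- fx$cohort
  lc <- list_cancers(co)
  expect_equal(nrow(lc), 4)
  expect_equal(sum(lc$pair_eligible), 2)
  expect_equal(ncol(co$expression), 500)
  expect_length(co$families, 5)
  expect_length(co$catalogs, 2)
  expect_identical(co$immune_score$ESTIMATE,
                   co$immune_score$Stromal + co$immune_score$Immune)
  # one truth record per planted effect
  expect_equal(nrow(fx$truth), 17)
  # every layer passes the cohort invariants
  expect_silent(validate_cohort(co))
  # survival times nonnegative, events 0/1
  expect_true(all(co$clinical$os_time >= 0, na.rm = TRUE))
  expect_true(all(co$clinical$os_event %in% c(0L, 1L)))
})

test_that("censoring lands near the requested administrative rate", {
  spec <- cohort_spec(
    cancers = tibble::tibble(code = "CR", n_tumor = 400L, n_normal = 0L,
                             n_paired = 0L),
    n_genes = 10, censoring_rate = 0.3, seed = 23)
  cl <- generate_cohort(spec)$cohort$clinical
  expect_lt(abs(mean(cl$os_event == 0) - 0.3), 0.06)
})

test_that("null survival generation gives nominal Cox CI coverage", {
  # log_hr = 0: the 95% CI covers HR = 1 in at least 90 of 100 seeds
  cover <- vapply(1:100, function(s) {
    set.seed(5000 + s)
    n <- 80
    x <- stats::rnorm(n)
    lambda0 <- log(2) / 730
    t_true <- stats::rexp(n, rate = lambda0)
    u <- stats::uniroot(function(u) (1 - exp(-u)) / u - 0.3, c(1e-8, 1e6))$root
    cens <- stats::runif(n, 0, u / lambda0)
    fit <- cox_fit(pmin(t_true, cens), as.integer(t_true <= cens), x)
    fit$ci_low <= 1 && 1 <= fit$ci_high
  }, logical(1))
  expect_gte(sum(cover), 90)
})
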