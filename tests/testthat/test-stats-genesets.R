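test_that("gene_set_expression is the member mean and tracks absences", {
  expr <- matrix(c(1, 3, 2, 4), nrow = 2,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
  s <- gene_set_expression(expr, c("A", "B", "MISSING"))
  expect_equal(as.numeric(s), c(1.5, 3.5))
  expect_equal(attr(s, "absent"), "MISSING")
  expect_equal(as.numeric(gene_set_expression(expr, "A")), c(1, 3))
  expect_error(gene_set_expression(expr, "ZZZ"), "no gene-set member")
})

test_that("top- and bottom-ranked sets attain the extreme ssGSEA scores", {
  # G = 12 genes; exhaustive over all placements of |S| in {2, 3}
  v <- stats::setNames(seq(12, 1), sprintf("g%02d", 1:12))
  for (k in 2:3) {
    placements <- utils::combn(12, k)
    scores <- apply(placements, 2L, function(idx) {
      ssgsea_score(v, names(v)[idx])
    })
    top <- ssgsea_score(v, names(v)[seq_len(k)])
    bottom <- ssgsea_score(v, names(v)[seq(13 - k, 12)])
    expect_equal(top, max(scores))
    expect_equal(bottom, min(scores))
  }
})

test_that("ssGSEA matches the literal running-sum oracle and is rank-invariant", {
  set.seed(111)
  v <- stats::setNames(stats::rnorm(40, 5, 2), sprintf("g%02d", 1:40))
  set <- sample(names(v), 6)
  expect_equal(ssgsea_score(v, set), oracle_ssgsea(v, set), tolerance = 1e-12)
  # strictly monotone transform leaves the score unchanged, exactly
  expect_identical(ssgsea_score(v, set), ssgsea_score(v^3 + 1, set))
  expect_identical(ssgsea_score(v, set), ssgsea_score(exp(v / 2), set))
  expect_error(ssgsea_score(v, "absent_gene"), "intersect")
})

test_that("ESTIMATE is exactly Stromal + Immune and order-invariant", {
  set.seed(112)
  expr <- matrix(stats::rexp(30 * 6, 0.3), nrow = 6,
                 dimnames = list(sprintf("s%d", 1:6), sprintf("g%02d", 1:30)))
  sc <- estimate_scores(expr, sprintf("g%02d", 1:5), sprintf("g%02d", 11:15))
  expect_identical(sc$ESTIMATE, sc$Stromal + sc$Immune)
  perm <- sample(30)
  sc2 <- estimate_scores(expr[, perm], sprintf("g%02d", 1:5),
                         sprintf("g%02d", 11:15))
  expect_equal(sc2$Immune, sc$Immune)
  # raising immune-signature genes in one sample strictly raises its score
  expr2 <- expr
  expr2["s3", sprintf("g%02d", 11:15)] <- expr2["s3", sprintf("g%02d", 11:15)] + 5
  sc3 <- estimate_scores(expr2, sprintf("g%02d", 1:5), sprintf("g%02d", 11:15))
  expect_gt(sc3$Immune[3], sc$Immune[3])
})

test_that("preranked GSEA finds a planted top set and is deterministic", {
  set.seed(113)
  ranking <- stats::setNames(sort(stats::rnorm(200), decreasing = TRUE),
                             sprintf("g%03d", 1:200))
  catalog <- list(TOP = names(ranking)[1:10],
                  RANDOM = sample(names(ranking), 15))
  r1 <- preranked_gsea(ranking, catalog, n_perm = 999, seed = 7)
  expect_gt(r1$es[r1$set == "TOP"], 0)
  expect_lte(r1$p[r1$set == "TOP"], 0.02)
  expect_equal(sign(r1$nes), sign(r1$es))
  r2 <- preranked_gsea(ranking, catalog, n_perm = 999, seed = 7)
  expect_identical(r1, r2)
  # leading edge of the top set lies inside the set
  expect_true(all(r1$leading_edge[r1$set == "TOP"][[1]] %in% catalog$TOP))
})

test_that("equal metric values reduce the ES to the unweighted KS statistic", {
  genes <- sprintf("g%03d", 1:100)
  ranking <- stats::setNames(rep(1, 100), genes)
  set <- genes[c(5, 20, 21, 40, 40 + 1:4)]
  r <- suppressWarnings(preranked_gsea(ranking, list(S = set),
                                       n_perm = 99, seed = 1))
  # unweighted oracle: running +1/|S| on hits, -1/(G-|S|) off hits
  hit <- genes %in% set
  run <- cumsum(ifelse(hit, 1 / sum(hit), -1 / sum(!hit)))
  es_unweighted <- run[which.max(abs(run))]
  expect_equal(r$es, es_unweighted, tolerance = 1e-12)
})

test_that("GSEA direction agrees with fgsea on a shared ranking", {
  skip_if_not_installed("fgsea")
  set.seed(114)
  ranking <- stats::setNames(stats::rnorm(300), sprintf("g%03d", 1:300))
  ranking[1:12] <- ranking[1:12] + 3
  catalog <- list(UP = names(ranking)[1:12],
                  NULLSET = sample(names(ranking)[50:300], 20))
  mine <- preranked_gsea(ranking, catalog, n_perm = 500, seed = 3)
  ref <- suppressWarnings(fgsea::fgsea(catalog, ranking, nperm = 500))
  expect_equal(sign(mine$es[mine$set == "UP"]),
               sign(ref$ES[ref$pathway == "UP"]))
  expect_lt(mine$p[mine$set == "UP"], 0.05)
})

test_that("undersized and oversized sets are skipped with a warning", {
  ranking <- stats::setNames(stats::rnorm(20), letters[1:20])
  expect_warning(expect_warning(
    r <- preranked_gsea(ranking, list(ONE = "a", BIG = letters[1:15]),
                        n_perm = 49, seed = 1),
    "skipped"), "skipped")
  expect_equal(nrow(r), 0)
})

test_that("hypergeometric ORA matches closed-form tails", {
  bg <- sprintf("g%02d", 1:20)
  catalog <- list(TERM = bg[1:5], OTHER = bg[11:14])
  r <- hypergeometric_ora(bg[1:5], catalog, bg)
  # all 5 query genes inside a 5-gene term: p = 1 / C(20,5)
  expect_equal(r$p[r$set == "TERM"], 1 / choose(20, 5), tolerance = 1e-12)
  # disjoint query
  r2 <- hypergeometric_ora(bg[6:10], list(TERM = bg[1:5]), bg)
  expect_equal(r2$p, 1.0)
  # query = background forces every overlap
  r3 <- hypergeometric_ora(bg, catalog, bg)
  expect_equal(r3$p, c(1, 1))
  expect_error(hypergeometric_ora("zz", catalog, bg), "empty")
})

test_that("ORA p equals the dhyper sum on random draws", {
  set.seed(115)
  bg <- sprintf("g%03d", 1:100)
  for (i in 1:10) {
    term <- sample(bg, 18)
    query <- sample(bg, 25)
    k <- length(intersect(term, query))
    p_oracle <- sum(stats::dhyper(k:18, 18, 82, 25))
    r <- hypergeometric_ora(query, list(T1 = term), bg)
    expect_equal(r$p, p_oracle, tolerance = 1e-12)
  }
})

test_that("median-split DEG screen: constants are null, ties go low", {
  set.seed(116)
  n <- 40
  idx <- stats::rnorm(n)
  expr <- cbind(FLAT = rep(2, n),
                UP = 3 + 2 * (idx > stats::median(idx)) + stats::rnorm(n, 0, 0.2),
                NOISE = stats::rnorm(n, 5))
  rownames(expr) <- sprintf("s%02d", 1:n)
  deg <- deg_high_low(expr, idx)
  expect_equal(deg$log2fc[deg$gene == "FLAT"], 0)
  expect_equal(deg$p[deg$gene == "FLAT"], 1)
  expect_gt(deg$log2fc[deg$gene == "UP"], 1)
  expect_lt(deg$q[deg$gene == "UP"], 0.05)
  groups <- attr(deg, "groups")
  expect_equal(unname(groups[idx == stats::median(idx)]),
               rep("low", sum(idx == stats::median(idx))))
  # excluded index gene never appears
  deg2 <- deg_high_low(expr, expr[, "UP"], exclude = "UP")
  expect_false("UP" %in% deg2$gene)
})
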