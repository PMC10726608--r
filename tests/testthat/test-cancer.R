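test_that("tumor/normal grouping recovers the planted effect", {
  co <- fixture_cohort()
  ge <- grouped_expression(co, "SYNA", "KLF7", "tumor_normal")
  expect_gt(ge$test$effect, 0)
  expect_false(ge$test$stars == "ns")
  expect_equal(nrow(ge$data), 430)
  # paired grouping honors the strict pair rule
  expect_error(grouped_expression(co, "SYNC", "KLF7", "paired"),
               "more than 20")
  gp <- grouped_expression(co, "SYNB", "KLF7", "paired")
  expect_equal(gp$test$method, "wilcoxon_signed_rank")
})

test_that("age tertiles are balanced and clinical groupings pick the right test", {
  co <- fixture_cohort()
  g3 <- grouped_expression(co, "SYNA", "KLF7", "age3")
  sizes <- table(g3$data$label)
  expect_equal(length(sizes), 3L)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(g3$test$method, "kruskal_wallis")
  # 99 samples -> exactly 33/33/33 (rank-based tertiles)
  expect_equal(as.integer(table(pancankit:::tertile_labels(stats::rnorm(99)))),
               rep(33L, 3))
  g2 <- grouped_expression(co, "SYNA", "KLF7", "age2")
  expect_equal(g2$test$method, "mann_whitney")
  expect_setequal(unique(g2$data$label), c("<65", ">=65"))
  gg <- grouped_expression(co, "SYNA", "KLF7", "gender")
  expect_equal(gg$test$method, "mann_whitney")
  gs <- grouped_expression(co, "SYNA", "KLF7", "stage")
  expect_equal(gs$test$method, "kruskal_wallis")
})

test_that("stage labels normalize by collapsing sub-stages", {
  expect_equal(pancankit:::normalize_stage(
    c("Stage IIA", "Stage IIB", "Stage I", "IV", "stage iiic", "Stage X")),
    c("II", "II", "I", "IV", "III", NA))
  co <- fixture_cohort()
  co$clinical$stage[co$clinical$stage == "II"] <- "Stage IIA"
  gs <- grouped_expression(co, "SYNA", "KLF7", "stage")
  expect_true("II" %in% gs$data$label)
  expect_false(any(grepl("IIA", gs$data$label)))
})

test_that("gene-set and gene variants produce identical result structure", {
  co <- fixture_cohort()
  a <- grouped_expression(co, "SYNA", "KLF7", "tumor_normal")
  b <- grouped_expression(co, "SYNA", "KEGGSYN_APOPTOSIS", "tumor_normal")
  expect_identical(names(a), names(b))
  expect_identical(names(a$data), names(b$data))
  expect_identical(names(a$test), names(b$test))
  expect_identical(names(tidy(a)), names(tidy(b)))
})

test_that("diagnostic ROC separates the planted gene and stays null otherwise", {
  co <- fixture_cohort()
  r <- diagnostic_roc(co, "SYNA", "KLF7")
  expect_gte(attr(r, "auc"), 0.9)
  r0 <- diagnostic_roc(co, "SYNA", "SG0050")
  expect_gt(attr(r0, "auc"), 0.3)
  expect_lt(attr(r0, "auc"), 0.7)
  expect_error(diagnostic_roc(co, "SYND", "KLF7"), "lacks tumor or normal")
})

test_that("DEG + GSEA flags the co-expression module set", {
  co <- fixture_cohort()
  res <- deg_and_gsea(co, "SYNA", "KLF7", "gosyn", n_perm = 499, seed = 11)
  expect_false("KLF7" %in% res$deg$gene)
  # partners planted on the index gene surface with positive sign and low q
  partners <- c("KLF4", sprintf("CO%02d", 1:10))
  sub <- res$deg[res$deg$gene %in% partners, ]
  expect_true(all(sub$log2fc > 0))
  expect_true(all(sub$q < 0.05))
  mod <- res$gsea[res$gsea$set == "GOSYN_KLF7_MODULE", ]
  expect_gt(mod$nes, 0)
  expect_lt(mod$fdr, 0.25)
  # determinism under a fixed seed
  res2 <- deg_and_gsea(co, "SYNA", "KLF7", "gosyn", n_perm = 499, seed = 11)
  expect_identical(res$gsea, res2$gsea)
  expect_error(deg_and_gsea(co, "SYNA", "KLF7", "reactome", seed = 1),
               "not loaded")
})

test_that("gene-gene correlation: identity, density flag, planted pair", {
  co <- fixture_cohort()
  self <- gene_gene_correlation(co, "SYNA", "KLF7", "KLF7")
  expect_equal(self$test$effect, 1)
  a <- gene_gene_correlation(co, "SYNA", "KLF4", "KLF7", density = FALSE)
  b <- gene_gene_correlation(co, "SYNA", "KLF4", "KLF7", density = TRUE)
  expect_equal(a$test$effect, b$test$effect)
  expect_equal(a$test$p, b$test$p)
  expect_equal(a$test$effect, 0.7, tolerance = 0.1)
})

test_that("methylation correlation recovers the planted anticorrelation", {
  co <- fixture_cohort()
  m <- gene_methylation_correlation(co, "SYNA", "KLF7")
  expect_lt(m$test$effect, 0)
  expect_false(m$test$stars == "ns")
  co2 <- co
  co2$methylation <- co2$methylation[rownames(co2$methylation) != "SG0400", ]
  expect_error(gene_methylation_correlation(co2, "SYNA", "SG0400"),
               "no promoter methylation row")
  # overlap below 5 samples errors
  co3 <- co
  co3$methylation <- co3$methylation[, 1:3]
  expect_error(gene_methylation_correlation(co3, "SYNA", "KLF7"),
               "fewer than 5")
})

test_that("co-expression panel finds the planted module and honest background", {
  co <- fixture_cohort()
  cp <- coexpression_panel(co, "SYNA", "KLF7", catalog_name = "gosyn")
  partners <- c("KLF4", sprintf("CO%02d", 1:10))
  expect_true(all(partners %in% cp$positive))
  expect_false("KLF7" %in% cp$correlations$gene)
  # ORA background is the tested genes, not a genome
  expect_equal(max(cp$ora$n_set), max(lengths(co$catalogs$gosyn)))
  expect_lt(cp$ora$q[cp$ora$set == "GOSYN_KLF7_MODULE"], 0.05)
  expect_equal(nrow(cp$correlations), ncol(co$expression) - 1)
})

test_that("survival split is deterministic and finds the planted hazard", {
  co <- fixture_cohort()
  km <- survival_by_level(co, "SYNA", "KLF7")
  expect_false(km$test$stars == "ns")
  sizes <- table(km$levels)
  expect_lte(abs(sizes[["high"]] - sizes[["low"]]), 1)
  km2 <- survival_by_level(co, "SYNA", "KLF7")
  expect_identical(km$levels, km2$levels)
  # methylation layer runs through the identical split/test path
  kmm <- survival_by_level(co, "SYNA", "KLF7", layer = "methylation")
  expect_identical(names(kmm), names(km))
  expect_equal(unique(kmm$curves$level), unique(km$curves$level))
  # curves are valid survival functions
  for (lv in c("high", "low")) {
    s <- km$curves$surv[km$curves$level == lv]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("term network links query genes to enriched terms only", {
  co <- fixture_cohort()
  tn <- term_network(co, c("LAMA3", "LAMC2", "TNC", "OSMR"), "gosyn")
  expect_equal(sum(tn$nodes$type == "term"), 1)
  expect_equal(nrow(tn$edges), 4)
  expect_true(all(tn$edges$term == "GOSYN_QUAD"))
  # the enrichment p matches the single-point hypergeometric tail
  expect_equal(tn$enrichment$p[tn$enrichment$set == "GOSYN_QUAD"],
               1 / choose(500, 4), tolerance = 1e-12)
  # single-gene query: all edges incident to one gene node
  tn1 <- term_network(co, "LAMA3", "gosyn", q_threshold = 0.2)
  expect_true(all(tn1$edges$gene == "LAMA3"))
  # q_threshold 0 always yields an empty network
  expect_warning(tn0 <- term_network(co, c("LAMA3", "LAMC2"), "gosyn",
                                     q_threshold = 0), "empty")
  expect_equal(nrow(tn0$edges), 0)
})
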