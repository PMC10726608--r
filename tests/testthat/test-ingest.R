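test_that("barcodes parse per the sample-type code convention", {
  b <- parse_barcode(c("TCGA-A6-2671-01A", "TCGA-A6-2671-11A"))
  expect_equal(b$patient_id, rep("TCGA-A6-2671", 2))
  expect_equal(b$sample_code, c("01", "11"))
  expect_equal(b$group, c("tumor", "normal"))
  expect_error(parse_barcode("TCGA-A6-2671"), "4 dash-delimited")
  expect_error(parse_barcode("TCGA-A6-2671-XXA"), "two digits")
  expect_error(parse_barcode("TCGA-A6-2671-20A"), "control")
})

test_that("ingest applies the zero-gene filter and log2(TPM+1) transform", {
  raw <- tiny_raw_tpm()
  built <- build_cohort(raw, tiny_meta(), seed = 1)
  co <- built$cohort
  expect_false("GZERO" %in% colnames(co$expression))
  expect_equal(built$report$n_zero_genes_removed, 1L)
  expect_equal(built$report$n_genes_in, 4L)
  # transform identity: raw TPM 3 -> stored log2(4) = 2
  raw2 <- raw
  raw2$G1[1] <- 3
  co2 <- build_cohort(raw2, seed = 1)$cohort
  expect_equal(unname(co2$expression[raw2$sample_id[1], "G1"]), 2)
  # negatives rejected
  raw3 <- raw
  raw3$G1[2] <- -0.1
  expect_error(build_cohort(raw3, seed = 1), "negative TPM")
})

test_that("duplicated aliquots are removed by a seeded draw, one kept", {
  raw <- tiny_raw_tpm()
  dup <- raw[1, ]
  dup$sample_id <- "SYNT-AA-0001-01B"  # same patient, group, cancer
  dup$G1 <- 99
  raw2 <- dplyr::bind_rows(raw, dup)
  b1 <- build_cohort(raw2, seed = 7)
  expect_equal(b1$report$n_duplicates_removed, 1L)
  kept1 <- intersect(c("SYNT-AA-0001-01A", "SYNT-AA-0001-01B"),
                     rownames(b1$cohort$expression))
  expect_length(kept1, 1)
  # deterministic: same seed keeps the same aliquot; never removes the last
  b2 <- build_cohort(raw2, seed = 7)
  expect_identical(rownames(b2$cohort$expression),
                   rownames(b1$cohort$expression))
  expect_true(all(table(b1$cohort$samples$patient_id,
                        b1$cohort$samples$group) <= 1))
})

test_that("promoter aggregation keeps only TSS1500-island probes", {
  beta <- matrix(c(0.2, 0.4, 0.9, 0.5, NA, 0.3), nrow = 3,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  ann <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    gene = c("G1", "G1", "G2"),
    region = c("TSS1500", "TSS1500", "TSS1500"),
    island_status = c("island", "island", "shore"))
  m <- aggregate_promoter_methylation(beta, ann)
  expect_equal(unname(m["G1", "s1"]), 0.3)  # mean of 0.2, 0.4
  expect_false("G2" %in% rownames(m))       # shore probe excluded
  # p2 is missing in s2: that sample's mean uses the remaining probe
  expect_equal(unname(m["G1", "s2"]), 0.5, tolerance = 1e-12)
  expect_error(aggregate_promoter_methylation(beta * 2, ann), "\\[0, 1\\]")
  # aggregation commutes with sample subsetting
  m1 <- aggregate_promoter_methylation(beta[, "s1", drop = FALSE], ann)
  expect_equal(m1["G1", "s1"], m["G1", "s1"])
})

test_that("median aggregation is available as a configured alternative", {
  beta <- matrix(c(0.1, 0.2, 0.9), nrow = 3,
                 dimnames = list(c("p1", "p2", "p3"), "s1"))
  ann <- tibble::tibble(probe_id = c("p1", "p2", "p3"), gene = "G",
                        region = "TSS1500", island_status = "island")
  expect_equal(unname(aggregate_promoter_methylation(beta, ann,
                                                     fun = "median")["G", ]),
               0.2)
})

test_that("GMT parsing dedups genes and flags malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tG1\tG2", "", "S2\tdesc\tG1\tG1"), path)
  cat1 <- read_gmt(path)
  expect_equal(cat1$S1, c("G1", "G2"))
  expect_equal(cat1$S2, "G1")
  writeLines(c("S1\tdesc"), path)
  expect_error(read_gmt(path), "line 1")
  writeLines(c("S1\td\tG1", "S1\td\tG2"), path)
  expect_error(read_gmt(path), "duplicate set name")
  # write/read round trip
  path2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(list(A = c("x", "y"), B = "z"), path2)
  expect_equal(read_gmt(path2), list(A = c("x", "y"), B = "z"))
})

test_that("re-reading a written bundle is a fixed point of ingest", {
  # one write/read cycle normalizes the shortest-round-trip number strings;
  # from then on the bundle is a byte-level fixed point
  d0 <- withr::local_tempdir()
  write_cohort(tiny_cohort(), d0)
  co <- read_cohort(d0)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  co2 <- read_cohort(d1)
  write_cohort(co2, d2)
  f1 <- setdiff(list.files(d1, recursive = TRUE), "manifest.yaml")
  f2 <- setdiff(list.files(d2, recursive = TRUE), "manifest.yaml")
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
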