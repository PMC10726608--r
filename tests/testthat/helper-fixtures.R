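# Shared fixtures, built in code. reference_fixture() is cached by the
# package for the session; the CLI bundle is written once per test run.

.test_cache <- new.env(parent = emptyenv())

fixture_cohort <- function() reference_fixture()$cohort

fixture_truth <- function() reference_fixture()$truth

# a tiny hand-sized cohort for extraction/ingest assertions: COAD 5T/3N
# (3 paired patients), LUAD 4T/0N, 4 genes
tiny_raw_tpm <- function() {
  barcodes <- c(sprintf("SYNT-AA-%04d-01A", 1:5),
                sprintf("SYNT-AA-%04d-11A", 1:3),
                sprintf("SYNT-BB-%04d-01A", 1:4))
  set.seed(42)
  tpm <- matrix(round(stats::rexp(12 * 4, rate = 0.2), 3), nrow = 12,
                dimnames = list(NULL, c("G1", "G2", "G3", "GZERO")))
  tpm[, "GZERO"] <- 0
  tibble::tibble(sample_id = barcodes,
                 cancer_type = rep(c("COAD", "COAD", "LUAD"), c(5, 3, 4))) |>
    dplyr::bind_cols(tibble::as_tibble(tpm))
}

tiny_meta <- function() {
  pid <- unique(parse_barcode(tiny_raw_tpm()$sample_id)$patient_id)
  tibble::tibble(patient_id = pid,
                 age = seq(50, by = 3, length.out = length(pid)),
                 gender = rep(c("male", "female"), length.out = length(pid)),
                 stage = rep(c("I", "II", "III"), length.out = length(pid)),
                 os_time = seq(100, by = 90, length.out = length(pid)),
                 os_event = rep(c(1L, 0L), length.out = length(pid)))
}

tiny_cohort <- function() {
  build_cohort(tiny_raw_tpm(), tiny_meta(), seed = 7)$cohort
}

# cohort bundle on disk for CLI tests (written once)
cli_bundle_dir <- function() {
  if (is.null(.test_cache$bundle)) {
    d <- file.path(tempdir(), "pancankit-bundle")
    write_cohort(fixture_cohort(), d, seed = 20260901L)
    .test_cache$bundle <- d
  }
  .test_cache$bundle
}
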