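# The packaged reference fixture: a small synthetic cohort with every layer
# populated and one planted effect per analysis family, used across the test
# suite and the worked examples. Built in code (seed fixed here), cached per
# session.

the <- new.env(parent = emptyenv())

fixture_families <- function() {
  list(
    checkpoint = c("PDCD1", "CD274", "CTLA4", "LAG3", "HAVCR2", "TIGIT"),
    chemokine = c("CCL2", "CCL5", "CXCL9", "CXCL10", "CXCL12"),
    chemokine_receptor = c("CCR2", "CCR5", "CXCR3", "CXCR4"),
    immunostimulator = c("CD27", "CD28", "ICOS", "TNFRSF9", "CD40"),
    immunoinhibitor = c("IDO1", "TGFB1", "IL10", "VTCN1")
  )
}

#' Specification of the reference fixture
#'
#' Four cancer types (two of them with more than 20 tumor/normal pairs),
#' 500 genes, all five immune gene families, two toy gene-set catalogs, and
#' planted effects on the index gene KLF7 in cancer SYNA: differential
#' expression (log2FC 2), TMB correlation (+0.6), MSI correlation (-0.4),
#' promoter-methylation anticorrelation (-0.5), a per-SD log hazard of 0.7,
#' an Immune-score coupling (+0.5), and co-expressed partners (KLF4 and
#' CO01..CO10).
#'
#' @return A [cohort_spec()].
#' @export
reference_spec <- function() {
  named <- c("KLF7", "KLF4", sprintf("CO%02d", 1:10),
             unlist(fixture_families(), use.names = FALSE),
             "LAMA3", "LAMC2", "TNC", "OSMR")
  n_genes <- 500L
  genes <- c(named, sprintf("SG%04d", seq_len(n_genes - length(named))))
  filler <- setdiff(genes, named)
  stromal_sig <- filler[1:15]
  immune_sig <- filler[16:30]
  partners <- c("KLF4", sprintf("CO%02d", 1:10))

  # deterministic toy catalogs drawn from the filler pool
  pick <- function(i, n) filler[30 + ((i * 37 + seq_len(n) * 13) %% 400) + 1]
  gosyn <- c(
    list(GOSYN_KLF7_MODULE = partners,
         GOSYN_QUAD = c("LAMA3", "LAMC2", "TNC", "OSMR")),
    stats::setNames(purrr::map(1:8, ~ unique(pick(.x, 15))),
                    sprintf("GOSYN_SET%02d", 1:8))
  )
  keggsyn <- c(
    list(KEGGSYN_APOPTOSIS = unique(pick(20, 20))),
    stats::setNames(purrr::map(21:25, ~ unique(pick(.x, 12))),
                    sprintf("KEGGSYN_SET%02d", 21:25))
  )

  cohort_spec(
    cancers = tibble::tibble(
      code = c("SYNA", "SYNB", "SYNC", "SYND"),
      n_tumor = c(400L, 60L, 50L, 40L),
      n_normal = c(30L, 35L, 10L, 0L),
      n_paired = c(25L, 30L, 8L, 0L)
    ),
    n_genes = n_genes, genes = genes,
    planted_de = tibble::tibble(gene = "KLF7", cancer = "SYNA", log2fc = 2),
    planted_metric_corr = tibble::tibble(
      gene = "KLF7", cancer = "SYNA",
      metric = c("TMB", "MSI", "Immune"), target_r = c(0.6, -0.4, 0.5)
    ),
    planted_hazard = tibble::tibble(gene = "KLF7", cancer = "SYNA",
                                    log_hr = 0.7),
    planted_methylation_corr = tibble::tibble(gene = "KLF7", cancer = "SYNA",
                                              target_r = -0.5),
    planted_coexpression = tibble::tibble(
      gene = "KLF7", partner = partners, cancer = "SYNA",
      target_r = c(0.7, rep(0.6, 10))
    ),
    censoring_rate = 0.3,
    families = fixture_families(),
    catalogs = list(gosyn = gosyn, keggsyn = keggsyn),
    stromal_signature = stromal_sig, immune_signature = immune_sig,
    seed = 20260901L
  )
}

#' The packaged reference fixture
#'
#' Generates (and caches for the session) the cohort described by
#' [reference_spec()].
#'
#' @return List with `cohort` and `truth` (see [generate_cohort()]).
#' @export
reference_fixture <- function() {
  if (is.null(the$fixture)) the$fixture <- generate_cohort(reference_spec())
  the$fixture
}
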