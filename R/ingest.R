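# Cohort ingest: barcode parsing, the data-preparation rules (seeded removal
# of duplicated samples, all-zero-TPM gene filter, log2(TPM+1) transform,
# TSS1500-island promoter probe selection), and GMT catalog parsing.

#' Parse TCGA-style sample barcodes
#'
#' The patient id is the first three dash-delimited fields; the 4th field's
#' two leading digits encode the sample type: 01-09 tumor, 10-19 normal.
#' Codes of 20 and above (controls) are rejected rather than silently
#' grouped.
#'
#' @param barcode Character vector of barcodes.
#' @return Tibble with `sample_id`, `patient_id`, `sample_code`, `group`.
#' @export
#' @examples
#' parse_barcode(c("TCGA-A6-2671-01A", "TCGA-A6-2671-11A"))
parse_barcode <- function(barcode) {
  parts <- stringr::str_split(barcode, stringr::fixed("-"))
  bad <- lengths(parts) < 4L
  if (any(bad)) {
    stop(sprintf("barcode '%s' has fewer than 4 dash-delimited fields",
                 barcode[bad][1]), call. = FALSE)
  }
  code_str <- purrr::map_chr(parts, 4L)
  if (any(!stringr::str_detect(code_str, "^[0-9]{2}"))) {
    stop("sample-type field must start with two digits", call. = FALSE)
  }
  code <- as.integer(stringr::str_sub(code_str, 1L, 2L))
  if (any(code >= 20L)) {
    stop(sprintf("unsupported sample type code %02d (control range)",
                 code[code >= 20L][1]), call. = FALSE)
  }
  tibble::tibble(
    sample_id = barcode,
    patient_id = purrr::map_chr(parts, ~ paste(.x[1:3], collapse = "-")),
    sample_code = sprintf("%02d", code),
    group = ifelse(code <= 9L, "tumor", "normal")
  )
}

#' Build a cohort from raw tables
#'
#' Applies the preparation rules: duplicated samples — several aliquots of
#' one (patient, group, cancer) class — are removed by a seeded uniform draw
#' over the lexicographically sorted duplicates (one kept, deterministic
#' given the seed); genes with TPM 0 across all samples are excluded; values
#' are stored as log2(TPM + 1); promoter methylation is aggregated over
#' TSS1500-island probes.
#'
#' @param expression_tpm Data frame of raw TPM: columns `sample_id`
#'   (barcode), `cancer_type`, then one numeric column per gene.
#' @param meta Clinical data frame: `patient_id`, `age`, `gender`, `stage`,
#'   `os_time`, `os_event`. Missing values stay missing, never imputed.
#' @param tmb,msi Optional data frames `sample_id` + `tmb` / `msi`.
#' @param immune_ratio,immune_score Optional per-sample tables.
#' @param methylation_beta Optional probes x samples beta matrix (probe ids
#'   as rownames).
#' @param probe_annotation Probe annotation for `methylation_beta`: columns
#'   `probe_id`, `gene`, `region`, `island_status`.
#' @param families,catalogs Optional gene families / gene-set catalogs.
#' @param gene_whitelist Optional symbol vector (e.g. protein-coding genes);
#'   genes outside it are dropped before the zero filter.
#' @param seed Integer seed for the dedup draw (recorded in the report).
#' @return List with elements `cohort` and `report` (ingest tallies).
#' @export
build_cohort <- function(expression_tpm, meta = NULL, tmb = NULL, msi = NULL,
                         immune_ratio = NULL, immune_score = NULL,
                         methylation_beta = NULL, probe_annotation = NULL,
                         families = list(), catalogs = list(),
                         gene_whitelist = NULL, seed = 1L) {
  expression_tpm <- tibble::as_tibble(expression_tpm)
  stopifnot(all(c("sample_id", "cancer_type") %in% names(expression_tpm)))
  gene_cols <- setdiff(names(expression_tpm), c("sample_id", "cancer_type"))
  vals <- as.matrix(expression_tpm[, gene_cols])
  if (any(vals < 0, na.rm = TRUE)) stop("negative TPM value", call. = FALSE)
  rownames(vals) <- expression_tpm$sample_id
  n_samples_in <- nrow(vals)
  n_genes_in <- ncol(vals)

  samples <- parse_barcode(expression_tpm$sample_id) |>
    dplyr::mutate(cancer_type = expression_tpm$cancer_type)

  # seeded dedup: one sample per (patient, group, cancer)
  keep <- withr::with_seed(seed, {
    samples |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::group_by(.data$patient_id, .data$group, .data$cancer_type) |>
      dplyr::group_map(function(g, key) {
        g <- dplyr::arrange(g, .data$sample_id)
        g$.row[[sample.int(nrow(g), 1L)]]
      }) |>
      unlist() |>
      sort()
  })
  n_dups <- n_samples_in - length(keep)
  vals <- vals[keep, , drop = FALSE]
  samples <- samples[keep, ]

  if (!is.null(gene_whitelist)) {
    vals <- vals[, intersect(colnames(vals), gene_whitelist), drop = FALSE]
  }
  zero <- colSums(vals) == 0
  n_zero <- sum(zero)
  vals <- vals[, !zero, drop = FALSE]
  if (nrow(vals) == 0L || ncol(vals) == 0L) {
    stop("empty expression matrix after filters", call. = FALSE)
  }
  expr <- log2(vals + 1)

  methy <- NULL
  n_probes_in <- 0L; n_probes_kept <- 0L
  if (!is.null(methylation_beta)) {
    if (is.null(probe_annotation)) {
      stop("probe_annotation required with methylation_beta", call. = FALSE)
    }
    methy <- aggregate_promoter_methylation(methylation_beta, probe_annotation)
    n_probes_in <- nrow(methylation_beta)
    n_probes_kept <- length(unique(unlist(attr(methy, "provenance"))))
    methy <- methy[, intersect(colnames(methy), samples$sample_id), drop = FALSE]
  }

  cohort <- new_cohort(
    expression = expr, samples = samples,
    clinical = if (!is.null(meta)) tibble::as_tibble(meta),
    tmb = filter_metric(tmb, "tmb", samples$sample_id),
    msi = filter_metric(msi, "msi", samples$sample_id),
    immune_ratio = filter_metric(immune_ratio, NULL, samples$sample_id),
    immune_score = filter_metric(immune_score, NULL, samples$sample_id),
    methylation = methy, families = families, catalogs = catalogs
  )
  report <- list(
    n_samples_in = n_samples_in, n_duplicates_removed = n_dups,
    n_genes_in = n_genes_in, n_zero_genes_removed = as.integer(n_zero),
    n_probes_in = n_probes_in, n_promoter_probes_kept = n_probes_kept,
    seed = as.integer(seed)
  )
  list(cohort = cohort, report = report)
}

filter_metric <- function(tab, value_col, ids) {
  if (is.null(tab)) return(NULL)
  tab <- tibble::as_tibble(tab)
  stopifnot("sample_id" %in% names(tab))
  if (!is.null(value_col)) stopifnot(value_col %in% names(tab))
  dplyr::filter(tab, .data$sample_id %in% ids)
}

#' Aggregate probe-level methylation to promoter level
#'
#' Keeps only probes annotated to the TSS1500 region AND inside a CpG
#' island; the promoter beta of a gene in a sample is the mean (or median)
#' over its kept probes, ignoring missing values. Genes with no kept probe
#' are absent from the result.
#'
#' @param beta Probes x samples numeric matrix of beta values in \[0, 1\]
#'   (NA allowed), probe ids as rownames.
#' @param annotation Data frame: `probe_id`, `gene`, `region`,
#'   `island_status`.
#' @param fun `"mean"` (default) or `"median"`.
#' @return Genes x samples matrix with attribute `provenance` (gene ->
#'   probe ids used).
#' @export
aggregate_promoter_methylation <- function(beta, annotation,
                                           fun = c("mean", "median")) {
  fun <- match.arg(fun)
  stopifnot(is.matrix(beta))
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  ann <- tibble::as_tibble(annotation) |>
    dplyr::filter(.data$region == "TSS1500", .data$island_status == "island",
                  .data$probe_id %in% rownames(beta))
  if (nrow(ann) == 0L) {
    stop("no TSS1500-island probe found in the beta matrix", call. = FALSE)
  }
  agg <- if (fun == "mean") {
    function(m) colMeans(m, na.rm = TRUE)
  } else {
    function(m) apply(m, 2L, stats::median, na.rm = TRUE)
  }
  by_gene <- split(ann$probe_id, ann$gene)
  rows <- lapply(by_gene, function(pr) agg(beta[pr, , drop = FALSE]))
  out <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
                dimnames = list(names(by_gene), colnames(beta)))
  out[is.nan(out)] <- NA_real_
  attr(out, "provenance") <- by_gene
  out
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member symbols, tab-separated.
#' Duplicate genes within a set are collapsed; blank lines are skipped.
#'
#' @param path Path to a GMT file.
#' @return Named list of unique gene-symbol vectors (a gene-set catalog).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  keep <- which(nchar(trimws(lines)) > 0)
  sets <- list()
  for (i in keep) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    name <- fields[[1]]
    if (name %in% names(sets)) {
      stop(sprintf("duplicate set name '%s' (line %d)", name, i), call. = FALSE)
    }
    sets[[name]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write a gene-set catalog to a GMT file
#'
#' @param catalog Named list of gene-symbol vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(catalog, path) {
  lines <- purrr::imap_chr(catalog, function(genes, name) {
    paste(c(name, "na", genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}
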