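# The multi-layer cohort container and its extraction API. A cohort aligns
# expression (samples x genes, log2(TPM+1)), clinical annotation, per-sample
# scalar metrics (TMB, MSI), immune-cell ratios, immune scores, promoter
# methylation, gene families and gene-set catalogs by sample barcode.

#' Construct a cohort object
#'
#' Layers are aligned lazily at analysis time (intersection of sample ids),
#' so partial cohorts are legal; every non-expression layer's sample ids
#' must resolve to expression samples (clinical is keyed by patient).
#'
#' @param expression Samples x genes numeric matrix, log2(TPM+1), barcode
#'   rownames, gene-symbol colnames.
#' @param samples Tibble with `sample_id`, `patient_id`, `sample_code`,
#'   `group` (tumor/normal), `cancer_type`; one row per expression row.
#' @param clinical Tibble with `patient_id`, `age`, `gender`, `stage`,
#'   `os_time`, `os_event`; one row per patient.
#' @param tmb,msi Tibbles `sample_id` + `tmb` / `msi`.
#' @param immune_ratio Tibble `sample_id` + one column per cell type, values
#'   in \[0, 1\].
#' @param immune_score Tibble `sample_id`, `Stromal`, `Immune`, `ESTIMATE`.
#' @param methylation Genes x samples numeric matrix of promoter beta values
#'   in \[0, 1\] (NA allowed), with attribute `provenance` mapping gene ->
#'   probe ids.
#' @param families Named list of gene-symbol vectors (checkpoint, chemokine,
#'   chemokine_receptor, immunostimulator, immunoinhibitor).
#' @param catalogs Named list of gene-set catalogs (each a named list of
#'   symbol vectors).
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(expression, samples, clinical = NULL, tmb = NULL,
                       msi = NULL, immune_ratio = NULL, immune_score = NULL,
                       methylation = NULL, families = list(),
                       catalogs = list()) {
  obj <- structure(
    list(expression = expression, samples = tibble::as_tibble(samples),
         clinical = clinical, tmb = tmb, msi = msi,
         immune_ratio = immune_ratio, immune_score = immune_score,
         methylation = methylation, families = families, catalogs = catalogs),
    class = "cohort"
  )
  validate_cohort(obj)
  obj
}

#' Validate cohort invariants
#'
#' Checks the structural invariants: finite nonnegative expression, unique
#' genes, no all-zero gene, no duplicated (patient, group, cancer) triple,
#' layer sample ids resolvable, immune ratios and betas in \[0, 1\], and
#' ESTIMATE = Stromal + Immune.
#'
#' @param cohort A `cohort`.
#' @return Invisibly, the cohort.
#' @export
validate_cohort <- function(cohort) {
  e <- cohort$expression
  stopifnot(is.matrix(e), is.numeric(e))
  if (any(!is.finite(e)) || any(e < 0)) {
    stop("expression must be finite and nonnegative (log2(TPM+1))", call. = FALSE)
  }
  if (anyDuplicated(colnames(e))) stop("duplicated gene ids", call. = FALSE)
  if (any(colSums(e) == 0)) {
    stop("expression contains an all-zero gene (should be filtered at ingest)",
         call. = FALSE)
  }
  s <- cohort$samples
  stopifnot(identical(nrow(s), nrow(e)),
            identical(s$sample_id, rownames(e)))
  if (anyDuplicated(s[, c("patient_id", "group", "cancer_type")])) {
    stop("duplicated (patient, group, cancer) sample after dedup", call. = FALSE)
  }
  ids <- s$sample_id
  check_ids <- function(x, what) {
    if (!is.null(x) && !all(x %in% ids)) {
      stop(sprintf("%s sample ids not present in expression", what), call. = FALSE)
    }
  }
  check_ids(cohort$tmb$sample_id, "TMB")
  check_ids(cohort$msi$sample_id, "MSI")
  check_ids(cohort$immune_ratio$sample_id, "immune-ratio")
  check_ids(cohort$immune_score$sample_id, "immune-score")
  if (!is.null(cohort$immune_ratio)) {
    v <- as.matrix(cohort$immune_ratio[, -1])
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("immune cell ratios must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(cohort$immune_score)) {
    sc <- cohort$immune_score
    if (max(abs(sc$ESTIMATE - (sc$Stromal + sc$Immune))) > 1e-8) {
      stop("ESTIMATE must equal Stromal + Immune", call. = FALSE)
    }
  }
  if (!is.null(cohort$methylation)) {
    m <- cohort$methylation
    if (any(m < 0 | m > 1, na.rm = TRUE)) {
      stop("beta values must lie in [0, 1]", call. = FALSE)
    }
    check_ids(colnames(m), "methylation")
  }
  if (length(cohort$families)) {
    bad <- purrr::map_lgl(cohort$families,
                          ~ length(.x) == 0 || anyDuplicated(.x) > 0)
    if (any(bad)) stop("gene families must be non-empty with unique symbols",
                       call. = FALSE)
  }
  if (!is.null(cohort$clinical) && anyDuplicated(cohort$clinical$patient_id)) {
    stop("clinical table must have one row per patient", call. = FALSE)
  }
  invisible(cohort)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples x %d genes, %d cancer types\n",
              nrow(x$expression), ncol(x$expression),
              dplyr::n_distinct(x$samples$cancer_type)))
  layers <- c(clinical = !is.null(x$clinical), tmb = !is.null(x$tmb),
              msi = !is.null(x$msi), immune_ratio = !is.null(x$immune_ratio),
              immune_score = !is.null(x$immune_score),
              methylation = !is.null(x$methylation))
  cat("layers:", paste(names(layers)[layers], collapse = ", "), "\n")
  if (length(x$families)) cat("families:", paste(names(x$families), collapse = ", "), "\n")
  if (length(x$catalogs)) cat("catalogs:", paste(names(x$catalogs), collapse = ", "), "\n")
  invisible(x)
}

# samples tibble filtered by cancer / group
cohort_samples <- function(cohort, cancer = NULL, group = NULL) {
  s <- cohort$samples
  if (!is.null(cancer)) {
    if (!cancer %in% s$cancer_type) {
      stop(sprintf("unknown cancer code '%s'; available: %s", cancer,
                   paste(sort(unique(s$cancer_type)), collapse = ", ")),
           call. = FALSE)
    }
    s <- dplyr::filter(s, .data$cancer_type == .env$cancer)
  }
  if (!is.null(group)) s <- dplyr::filter(s, .data$group == .env$group)
  s
}

# patients having both a tumor and a normal sample within each cancer
paired_samples <- function(samples) {
  samples |>
    dplyr::group_by(.data$cancer_type, .data$patient_id) |>
    dplyr::filter(all(c("tumor", "normal") %in% .data$group)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cancer_type, .data$patient_id,
                   dplyr::desc(.data$group))  # tumor before normal
}

#' Extract one layer of a cohort as a tibble
#'
#' The Table-1-style extraction surface: returns the requested layer,
#' optionally restricted to one cancer type, optionally restricted to
#' tumor/normal pairs (expression only). The cohort itself is never
#' modified.
#'
#' @param cohort A `cohort`.
#' @param layer One of `"tpm"`, `"meta"`, `"tmb"`, `"msi"`, `"immu_ratio"`,
#'   `"immuscore"`, `"promoter_methy"`.
#' @param cancer Optional cancer code.
#' @param paired_only If `TRUE` (layer `"tpm"` only), keep only patients
#'   with both a tumor and a normal sample, rows ordered so each patient's
#'   tumor row directly precedes its normal row.
#' @return A tibble. For `"tpm"`: `sample_id`, `patient_id`, `group`,
#'   `cancer_type`, then one column per gene. For `"promoter_methy"`: a
#'   `gene` column then one column per (tumor) sample.
#' @export
extract_layer <- function(cohort, layer, cancer = NULL, paired_only = FALSE) {
  layers <- c("tpm", "meta", "tmb", "msi", "immu_ratio", "immuscore",
              "promoter_methy")
  if (!layer %in% layers) {
    stop(sprintf("unknown layer '%s'; expected one of: %s", layer,
                 paste(layers, collapse = ", ")), call. = FALSE)
  }
  if (paired_only && layer != "tpm") {
    stop("paired_only is only defined for the 'tpm' layer (group labels)",
         call. = FALSE)
  }
  s <- cohort_samples(cohort, cancer)
  if (layer == "tpm") {
    if (paired_only) s <- paired_samples(s)
    return(dplyr::bind_cols(
      s[, c("sample_id", "patient_id", "group", "cancer_type")],
      tibble::as_tibble(cohort$expression[s$sample_id, , drop = FALSE])
    ))
  }
  if (layer == "meta") {
    if (is.null(cohort$clinical)) stop("clinical layer absent", call. = FALSE)
    pts <- dplyr::distinct(s, .data$patient_id, .data$cancer_type)
    return(dplyr::inner_join(pts, cohort$clinical, by = "patient_id"))
  }
  if (layer %in% c("tmb", "msi", "immu_ratio", "immuscore")) {
    tab <- switch(layer, tmb = cohort$tmb, msi = cohort$msi,
                  immu_ratio = cohort$immune_ratio,
                  immuscore = cohort$immune_score)
    if (is.null(tab)) stop(sprintf("layer '%s' absent from cohort", layer),
                           call. = FALSE)
    return(dplyr::semi_join(tab, s, by = "sample_id"))
  }
  # promoter_methy
  m <- cohort$methylation
  if (is.null(m)) stop("promoter methylation layer absent", call. = FALSE)
  keep <- intersect(colnames(m), s$sample_id)
  tibble::as_tibble(m[, keep, drop = FALSE], rownames = "gene")
}

#' Per-cancer sample summary
#'
#' One row per cancer type with tumor, normal and pair counts and the
#' pair-eligibility flag `pair_count > paired_min_pairs` (strict, matching
#' the "more than 20 paired samples" rule).
#'
#' @param cohort A `cohort`.
#' @param paired_min_pairs Eligibility cutoff (default 20, strict `>`).
#' @return Tibble with `cancer_type`, `n_tumor`, `n_normal`, `n_pairs`,
#'   `pair_eligible`.
#' @export
list_cancers <- function(cohort, paired_min_pairs = 20) {
  cohort$samples |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(
      n_tumor = sum(.data$group == "tumor"),
      n_normal = sum(.data$group == "normal"),
      n_pairs = length(intersect(.data$patient_id[.data$group == "tumor"],
                                 .data$patient_id[.data$group == "normal"])),
      .groups = "drop"
    ) |>
    dplyr::mutate(pair_eligible = .data$n_pairs > paired_min_pairs)
}

#' Resolve a query as a single gene or a catalog gene set
#'
#' @param cohort A `cohort`.
#' @param query A gene symbol present in the expression matrix, or a set
#'   name present in one of the loaded catalogs.
#' @return A `pc_query` list: `type` ("gene" or "set"), `query`, `members`
#'   (symbols found in the matrix), `absent` (members not found).
#' @export
resolve_gene_or_set <- function(cohort, query) {
  stopifnot(is.character(query), length(query) == 1L)
  genes <- colnames(cohort$expression)
  if (query %in% genes) {
    return(structure(list(type = "gene", query = query, members = query,
                          absent = character()), class = "pc_query"))
  }
  for (cat_name in names(cohort$catalogs)) {
    sets <- cohort$catalogs[[cat_name]]
    if (query %in% names(sets)) {
      members <- intersect(sets[[query]], genes)
      if (length(members) == 0L) {
        stop(sprintf("gene set '%s' has no member in the expression matrix",
                     query), call. = FALSE)
      }
      return(structure(list(type = "set", query = query, catalog = cat_name,
                            members = members,
                            absent = setdiff(sets[[query]], members)),
                       class = "pc_query"))
    }
  }
  pool <- c(genes, unlist(purrr::map(cohort$catalogs, names)))
  near <- utils::head(pool[utils::adist(query, pool) <= 2], 5)
  stop(sprintf("'%s' is neither a gene nor a loaded gene set%s", query,
               if (length(near)) paste0("; nearest matches: ",
                                        paste(near, collapse = ", ")) else ""),
       call. = FALSE)
}

# numeric per-sample score of a resolved query (gene value or set mean)
query_score <- function(cohort, resolved, sample_ids) {
  e <- cohort$expression[sample_ids, resolved$members, drop = FALSE]
  if (length(resolved$members) == 1L) drop(e[, 1]) else rowMeans(e)
}
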