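# Pan-cancer loops: one row (or grid cell) per cancer type, backing the
# boxplot, radar, heatmap and forest payloads. All statistics come from the
# stats core; q is always BH across the rows of the table it sits in.

pan_result <- function(tab, analysis, query, ...) {
  attr(tab, "analysis") <- analysis
  attr(tab, "query") <- query
  extra <- list(...)
  for (nm in names(extra)) attr(tab, nm) <- extra[[nm]]
  class(tab) <- c("pan_result", class(tab))
  tab
}

finish_pan <- function(rows, analysis, query, ...) {
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0L) {
    stop(sprintf("no cancer type eligible for %s", analysis), call. = FALSE)
  }
  if ("p" %in% names(tab)) {
    tab$q <- benjamini_hochberg(tab$p)
    tab$stars <- significance_stars(tab$p)
  }
  pan_result(tab, analysis, query, ...)
}

#' Pan-cancer expression comparison of a gene or gene set
#'
#' Per cancer type: unpaired mode compares tumor vs normal with the
#' Mann-Whitney test (both groups need at least `min_group` samples); paired
#' mode runs the signed-rank test on tumor-normal pairs, restricted to
#' cancers with strictly more than `paired_min_pairs` pairs; tumor-only mode
#' reports the tumor expression distribution with no test.
#'
#' @param cohort A `cohort`.
#' @param query Gene symbol or loaded gene-set name (set score = member
#'   mean).
#' @param mode `"unpaired"`, `"paired"` or `"tumor_only"`.
#' @param min_group Minimum per-group size for the unpaired test.
#' @param paired_min_pairs Strict pair-count cutoff for paired mode.
#' @return A `pan_result` tibble: one row per eligible cancer with `effect`
#'   (difference of group means on the log2 scale), `stat`, `p`, `q`,
#'   `stars`, group sizes.
#' @export
pan_expression <- function(cohort, query, mode = c("unpaired", "paired",
                                                   "tumor_only"),
                           min_group = 3, paired_min_pairs = 20) {
  mode <- match.arg(mode)
  res <- resolve_gene_or_set(cohort, query)
  cancers <- sort(unique(cohort$samples$cancer_type))
  rows <- purrr::map(cancers, function(cc) {
    s <- cohort_samples(cohort, cc)
    if (mode == "tumor_only") {
      v <- query_score(cohort, res, s$sample_id[s$group == "tumor"])
      return(tibble::tibble(cancer_type = cc, mean = mean(v),
                            median = stats::median(v), sd = stats::sd(v),
                            n1 = length(v)))
    }
    if (mode == "unpaired") {
      vt <- query_score(cohort, res, s$sample_id[s$group == "tumor"])
      vn <- query_score(cohort, res, s$sample_id[s$group == "normal"])
      if (length(vt) < min_group || length(vn) < min_group) return(NULL)
      tr <- mann_whitney(vt, vn)
      return(dplyr::bind_cols(tibble::tibble(cancer_type = cc),
                              tr[, c("effect", "stat", "p", "n1", "n2")]))
    }
    # paired
    ps <- paired_samples(s)
    n_pairs <- dplyr::n_distinct(ps$patient_id)
    if (n_pairs <= paired_min_pairs) return(NULL)
    wide <- ps |>
      dplyr::mutate(score = query_score(cohort, res, .data$sample_id)) |>
      dplyr::select("patient_id", "group", "score") |>
      tidyr::pivot_wider(names_from = "group", values_from = "score")
    tr <- wilcoxon_signed_rank(wide$tumor - wide$normal)
    dplyr::bind_cols(tibble::tibble(cancer_type = cc),
                     tr[, c("effect", "stat", "p", "n1")])
  })
  finish_pan(rows, paste0("pan_expression_", mode), query,
             min_group = min_group, paired_min_pairs = paired_min_pairs,
             query_type = res$type)
}

#' Pan-cancer correlation of a gene or gene set with TMB or MSI
#'
#' Tumor samples only; cancers contribute a row when at least `min_n`
#' samples carry both the expression score and the metric. The table is the
#' radar-chart payload (r per cancer, with stars).
#'
#' @param cohort A `cohort`.
#' @param query Gene symbol or gene-set name.
#' @param metric `"TMB"` or `"MSI"`.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @param min_n Minimum overlapping samples per cancer.
#' @return A `pan_result` tibble with `effect` = r per cancer.
#' @export
pan_metric_correlation <- function(cohort, query, metric = c("TMB", "MSI"),
                                   method = "pearson", min_n = 5) {
  metric <- match.arg(metric)
  tab <- if (metric == "TMB") cohort$tmb else cohort$msi
  if (is.null(tab)) stop(sprintf("%s layer absent from cohort", metric),
                         call. = FALSE)
  val_col <- names(tab)[2]
  res <- resolve_gene_or_set(cohort, query)
  rows <- cohort$samples |>
    dplyr::filter(.data$group == "tumor") |>
    dplyr::inner_join(tab, by = "sample_id") |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < min_n) return(NULL)
      score <- query_score(cohort, res, g$sample_id)
      tr <- correlation_test(score, g[[val_col]], method = method)
      dplyr::bind_cols(tibble::tibble(cancer_type = key$cancer_type),
                       tr[, c("effect", "stat", "p", "n1")])
    })
  finish_pan(rows, paste0("pan_", tolower(metric), "_correlation"), query,
             metric = metric, method = method, min_n = min_n)
}

#' Pan-cancer correlation grid of a query against a gene family
#'
#' One cell per (cancer, family gene): correlation between the query score
#' and the family gene's expression in tumor samples. `lowcol`/`highcol`
#' are carried as plot aesthetics; the family's gene order is preserved.
#'
#' @param cohort A `cohort`.
#' @param query Gene symbol or gene-set name.
#' @param family One of the registered family names (e.g. `"checkpoint"`).
#' @param method Correlation method.
#' @param lowcol,highcol Heatmap endpoint colors (payload aesthetics only).
#' @param min_n Minimum tumor samples per cancer.
#' @return A `pan_result` tibble with one row per (cancer, gene) cell.
#' @export
pan_family_heatmap <- function(cohort, query, family, method = "pearson",
                               lowcol = "blue", highcol = "red", min_n = 5) {
  if (!family %in% names(cohort$families)) {
    stop(sprintf("unknown family '%s'; available: %s", family,
                 paste(names(cohort$families), collapse = ", ")), call. = FALSE)
  }
  members <- intersect(cohort$families[[family]], colnames(cohort$expression))
  if (length(members) == 0L) {
    stop("family has no gene in the expression matrix", call. = FALSE)
  }
  res <- resolve_gene_or_set(cohort, query)
  cancers <- sort(unique(cohort$samples$cancer_type))
  rows <- purrr::map(cancers, function(cc) {
    s <- cohort_samples(cohort, cc, group = "tumor")
    if (nrow(s) < min_n) return(NULL)
    score <- query_score(cohort, res, s$sample_id)
    purrr::map(members, function(g) {
      tr <- correlation_test(score, cohort$expression[s$sample_id, g],
                             method = method)
      dplyr::bind_cols(tibble::tibble(cancer_type = cc, gene = g),
                       tr[, c("effect", "p", "n1")])
    }) |> dplyr::bind_rows()
  })
  out <- finish_pan(rows, "pan_family_heatmap", query, family = family,
                    method = method, lowcol = lowcol, highcol = highcol)
  attr(out, "gene_order") <- members
  out
}

#' Pan-cancer correlation of a query with immune infiltration
#'
#' Per cancer and per immune column (cell type, or Stromal/Immune/ESTIMATE
#' score), the correlation with the query score over overlapping tumor
#' samples. `shape` only selects the rendering (heatmap vs triangle); the
#' numbers are identical.
#'
#' @param cohort A `cohort`.
#' @param query Gene symbol or gene-set name.
#' @param layer `"cell_ratio"` or `"immune_score"`.
#' @param shape `"heatmap"` or `"triangle"` (rendering variant only).
#' @param method Correlation method.
#' @param min_n Minimum overlapping samples per cancer.
#' @return A `pan_result` tibble with one row per (cancer, column).
#' @export
pan_immune_correlation <- function(cohort, query,
                                   layer = c("cell_ratio", "immune_score"),
                                   shape = c("heatmap", "triangle"),
                                   method = "pearson", min_n = 5) {
  layer <- match.arg(layer)
  shape <- match.arg(shape)
  tab <- if (layer == "cell_ratio") cohort$immune_ratio else cohort$immune_score
  if (is.null(tab)) stop(sprintf("layer '%s' absent from cohort", layer),
                         call. = FALSE)
  res <- resolve_gene_or_set(cohort, query)
  cols <- setdiff(names(tab), "sample_id")
  rows <- cohort$samples |>
    dplyr::filter(.data$group == "tumor") |>
    dplyr::inner_join(tab, by = "sample_id") |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < min_n) return(NULL)
      score <- query_score(cohort, res, g$sample_id)
      purrr::map(cols, function(cl) {
        tr <- correlation_test(score, g[[cl]], method = method)
        dplyr::bind_cols(
          tibble::tibble(cancer_type = key$cancer_type, column = cl),
          tr[, c("effect", "p", "n1")])
      }) |> dplyr::bind_rows()
    })
  finish_pan(rows, "pan_immune_correlation", query, layer = layer,
             shape = shape, method = method, columns = cols)
}

#' Pan-cancer Cox forest of a single gene
#'
#' Per cancer type, a proportional-hazards fit of overall survival on the
#' gene's expression, standardized within the cancer so hazard ratios are
#' per expression SD and comparable across cancers; optional age
#' adjustment. Cancers with too few events (or failed fits) are reported in
#' the `skipped` attribute rather than erroring.
#'
#' @param cohort A `cohort` with a clinical layer.
#' @param gene Gene symbol.
#' @param adjust_age Add age as a second continuous covariate.
#' @param min_events Minimum number of deaths to attempt a fit.
#' @return A `pan_result` tibble: `cancer_type`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `q`, `stars`, `n`, `n_events`.
#' @export
pan_cox_forest <- function(cohort, gene, adjust_age = FALSE, min_events = 10) {
  if (is.null(cohort$clinical)) stop("clinical layer absent", call. = FALSE)
  res <- resolve_gene_or_set(cohort, gene)
  if (res$type != "gene") stop("Cox forest expects a single gene", call. = FALSE)
  skipped <- list()
  cancers <- sort(unique(cohort$samples$cancer_type))
  rows <- purrr::map(cancers, function(cc) {
    s <- cohort_samples(cohort, cc, group = "tumor") |>
      dplyr::inner_join(cohort$clinical, by = "patient_id") |>
      dplyr::filter(!is.na(.data$os_time), !is.na(.data$os_event),
                    if (adjust_age) !is.na(.data$age) else TRUE)
    if (nrow(s) < 2L || sum(s$os_event) < min_events) {
      skipped[[cc]] <<- sprintf("%d events (< %d required)",
                                if (nrow(s)) sum(s$os_event) else 0L, min_events)
      return(NULL)
    }
    x <- as.vector(scale(cohort$expression[s$sample_id, gene]))
    fit <- tryCatch(
      cox_fit(s$os_time, s$os_event, x,
              age = if (adjust_age) s$age else NULL),
      error = function(e) { skipped[[cc]] <<- conditionMessage(e); NULL }
    )
    if (is.null(fit)) return(NULL)
    dplyr::bind_cols(tibble::tibble(cancer_type = cc),
                     fit[, c("hr", "ci_low", "ci_high", "p", "n", "n_events")])
  })
  finish_pan(rows, "pan_cox_forest", gene, adjust_age = adjust_age,
             min_events = min_events, skipped = skipped)
}
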