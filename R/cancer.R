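# Cancer-type-specific analyses: grouped expression boxplot tables, ROC
# diagnostics, DEG + preranked GSEA, gene-gene / gene-methylation scatter
# statistics, co-expression panels with ORA, median-split survival, and
# gene-term networks.

# normalize pathological stage labels: sub-stages collapse (IIA -> II);
# anything that is not stage I-IV (e.g. "Stage X") becomes missing
normalize_stage <- function(stage) {
  m <- stringr::str_match(toupper(trimws(stage)),
                          "^(?:STAGE\\s*)?(IV|III|II|I)[ABC]?$")[, 2]
  m
}

# rank-based tertiles: deterministic, sizes differ by at most 1
tertile_labels <- function(x) {
  g <- ceiling(3 * rank(x, ties.method = "first") / length(x))
  c("young", "middle", "old")[g]
}

#' Grouped expression of a gene or gene set within one cancer type
#'
#' Groupings: `tumor_normal` (Mann-Whitney), `paired` (signed-rank on
#' aligned pairs, requires strictly more than `paired_min_pairs` pairs),
#' `age2` (tumor samples split at `age_cutoff` years), `age3` (rank
#' tertiles of age, Kruskal-Wallis), `gender`, and `stage` (sub-stages
#' collapsed, `Stage X` discarded; 2 groups use the rank test, 3+ use
#' Kruskal-Wallis). Samples with the grouping variable missing are dropped
#' and counted.
#'
#' @param cohort A `cohort`.
#' @param cancer Cancer code.
#' @param query Gene symbol or gene-set name.
#' @param grouping One of `"tumor_normal"`, `"paired"`, `"age2"`, `"age3"`,
#'   `"gender"`, `"stage"`.
#' @param age_cutoff Years, for `age2` (default 65; groups `<65` / `>=65`).
#' @param paired_min_pairs Strict pair-count requirement for `paired`.
#' @return A `grouped_expression` object: `$data` (per-sample `score` and
#'   `label`), `$test` (one-row result tibble), `$n_dropped`, `$grouping`.
#' @export
grouped_expression <- function(cohort, cancer, query,
                               grouping = c("tumor_normal", "paired", "age2",
                                            "age3", "gender", "stage"),
                               age_cutoff = 65, paired_min_pairs = 20) {
  grouping <- match.arg(grouping)
  res <- resolve_gene_or_set(cohort, query)
  s <- cohort_samples(cohort, cancer)
  n_dropped <- 0L

  if (grouping == "tumor_normal") {
    dat <- tibble::tibble(sample_id = s$sample_id, label = s$group,
                          score = query_score(cohort, res, s$sample_id))
  } else if (grouping == "paired") {
    ps <- paired_samples(s)
    n_pairs <- dplyr::n_distinct(ps$patient_id)
    if (n_pairs <= paired_min_pairs) {
      stop(sprintf("only %d pairs in %s (more than %d required)",
                   n_pairs, cancer, paired_min_pairs), call. = FALSE)
    }
    dat <- tibble::tibble(sample_id = ps$sample_id, label = ps$group,
                          patient_id = ps$patient_id,
                          score = query_score(cohort, res, ps$sample_id))
  } else {
    if (is.null(cohort$clinical)) stop("clinical layer absent", call. = FALSE)
    st <- s |>
      dplyr::filter(.data$group == "tumor") |>
      dplyr::inner_join(cohort$clinical, by = "patient_id")
    var <- switch(grouping, age2 = , age3 = st$age, gender = st$gender,
                  stage = normalize_stage(st$stage))
    keep <- !is.na(var)
    n_dropped <- sum(!keep)
    if (!any(keep)) {
      stop(sprintf("grouping variable '%s' is missing for every sample",
                   grouping), call. = FALSE)
    }
    st <- st[keep, ]; var <- var[keep]
    label <- switch(
      grouping,
      age2 = ifelse(var >= age_cutoff, paste0(">=", age_cutoff),
                    paste0("<", age_cutoff)),
      age3 = tertile_labels(var),
      gender = var,
      stage = var
    )
    dat <- tibble::tibble(sample_id = st$sample_id, label = label,
                          score = query_score(cohort, res, st$sample_id))
  }

  sizes <- table(dat$label)
  if (any(sizes < 2L)) {
    stop(sprintf("group '%s' has fewer than 2 samples",
                 names(sizes)[sizes < 2L][1]), call. = FALSE)
  }
  test <- if (grouping == "paired") {
    wide <- tidyr::pivot_wider(dat[, c("patient_id", "label", "score")],
                               names_from = "label", values_from = "score")
    wilcoxon_signed_rank(wide$tumor - wide$normal)
  } else if (length(sizes) == 2L) {
    lv <- sort(names(sizes))
    mann_whitney(dat$score[dat$label == lv[2]], dat$score[dat$label == lv[1]])
  } else {
    kruskal_wallis(split(dat$score, dat$label))
  }
  structure(list(data = dat, test = test, grouping = grouping,
                 n_dropped = n_dropped, cancer = cancer, query = query),
            class = "grouped_expression")
}

#' @export
print.grouped_expression <- function(x, ...) {
  cat(sprintf("<grouped_expression> %s ~ %s in %s (%d samples, %d dropped)\n",
              x$query, x$grouping, x$cancer, nrow(x$data), x$n_dropped))
  print(x$test)
  invisible(x)
}

#' Single-gene diagnostic ROC within one cancer type
#'
#' ROC of the gene's expression with tumor as the positive class.
#'
#' @param cohort A `cohort`.
#' @param cancer Cancer code (must contain both tumor and normal samples).
#' @param gene Gene symbol.
#' @return A `pc_roc` (see [roc_auc()]).
#' @export
diagnostic_roc <- function(cohort, cancer, gene) {
  res <- resolve_gene_or_set(cohort, gene)
  if (res$type != "gene") stop("diagnostic ROC expects a single gene", call. = FALSE)
  s <- cohort_samples(cohort, cancer)
  if (length(unique(s$group)) < 2L) {
    stop(sprintf("%s lacks tumor or normal samples", cancer), call. = FALSE)
  }
  roc_auc(cohort$expression[s$sample_id, gene], s$group == "tumor")
}

#' DEGs between high/low halves of a gene, with preranked GSEA
#'
#' Tumor samples are split at the median expression of `gene` (ties low);
#' every other gene is tested with the Mann-Whitney test and the DEG log2FC
#' is used as the preranked GSEA metric against the named catalog. The
#' heatmap payload keeps the `top_n` genes by |log2FC| among those with
#' `q < q_threshold` (empty, with a warning, when none pass).
#'
#' @param cohort A `cohort`.
#' @param cancer Cancer code (needs at least 8 tumor samples).
#' @param gene Index gene symbol.
#' @param catalog_name Name of a loaded catalog (e.g. `"gosyn"`).
#' @param n_perm,seed Passed to [preranked_gsea()].
#' @param top_n,q_threshold Heatmap payload selection.
#' @return List with `deg` (tibble), `gsea` (tibble), `heatmap_genes`
#'   (character), `groups` (high/low labels by sample).
#' @export
deg_and_gsea <- function(cohort, cancer, gene, catalog_name, n_perm = 1000,
                         seed, top_n = 20, q_threshold = 0.05) {
  if (!catalog_name %in% names(cohort$catalogs)) {
    stop(sprintf(paste0("catalog '%s' is not loaded; supply a GMT file ",
                        "(read_gmt) and attach it to the cohort"),
                 catalog_name), call. = FALSE)
  }
  res <- resolve_gene_or_set(cohort, gene)
  if (res$type != "gene") stop("expected a single index gene", call. = FALSE)
  s <- cohort_samples(cohort, cancer, group = "tumor")
  if (nrow(s) < 8L) stop("need at least 8 tumor samples", call. = FALSE)
  expr <- cohort$expression[s$sample_id, , drop = FALSE]
  deg <- deg_high_low(expr, expr[, gene], exclude = gene)
  ranking <- stats::setNames(deg$log2fc, deg$gene)
  gsea <- preranked_gsea(ranking, cohort$catalogs[[catalog_name]],
                         n_perm = n_perm, seed = seed)
  hits <- deg |>
    dplyr::filter(.data$q < q_threshold) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2fc))) |>
    utils::head(top_n)
  if (nrow(hits) == 0L) {
    warning("no gene passes the q threshold; heatmap payload is empty",
            call. = FALSE)
  }
  list(deg = deg, gsea = gsea, heatmap_genes = hits$gene,
       groups = stats::setNames(attr(deg, "groups"), s$sample_id))
}

#' Gene-gene correlation scatter within one cancer type
#'
#' @param cohort A `cohort`.
#' @param cancer Cancer code.
#' @param gene_a,gene_b Gene symbols.
#' @param density Plot-only flag: adds a 2-D density layer to the figure;
#'   the statistics are unchanged.
#' @param method Correlation method.
#' @return A `gene_scatter` object: `$data` (x, y per tumor sample),
#'   `$test`, `$fit` (least-squares intercept/slope), `$density`.
#' @export
gene_gene_correlation <- function(cohort, cancer, gene_a, gene_b,
                                  density = FALSE, method = "pearson") {
  s <- cohort_samples(cohort, cancer, group = "tumor")
  for (g in c(gene_a, gene_b)) resolve_gene_or_set(cohort, g)
  x <- cohort$expression[s$sample_id, gene_a]
  y <- cohort$expression[s$sample_id, gene_b]
  test <- correlation_test(x, y, method = method)
  cf <- stats::coef(stats::lm(y ~ x))
  structure(list(
    data = tibble::tibble(sample_id = s$sample_id, x = x, y = y),
    test = test, fit = c(intercept = unname(cf[1]), slope = unname(cf[2])),
    density = density, xlab = gene_a, ylab = gene_b, cancer = cancer
  ), class = "gene_scatter")
}

#' Expression vs promoter methylation of a gene within one cancer type
#'
#' Correlates log2(TPM+1) expression against the promoter beta value over
#' tumor samples present in both layers (at least 5 required).
#'
#' @param cohort A `cohort` with a methylation layer.
#' @param cancer Cancer code.
#' @param gene Gene symbol (must have a promoter methylation row).
#' @param method Correlation method.
#' @return A `gene_scatter` object (x = beta, y = expression).
#' @export
gene_methylation_correlation <- function(cohort, cancer, gene,
                                         method = "pearson") {
  if (is.null(cohort$methylation)) {
    stop("promoter methylation layer absent", call. = FALSE)
  }
  if (!gene %in% rownames(cohort$methylation)) {
    stop(sprintf("gene '%s' has no promoter methylation row", gene),
         call. = FALSE)
  }
  s <- cohort_samples(cohort, cancer, group = "tumor")
  ids <- intersect(s$sample_id, colnames(cohort$methylation))
  beta <- cohort$methylation[gene, ids]
  ids <- ids[!is.na(beta)]
  if (length(ids) < 5L) {
    stop("fewer than 5 overlapping tumor samples with methylation", call. = FALSE)
  }
  x <- cohort$methylation[gene, ids]
  y <- cohort$expression[ids, gene]
  test <- correlation_test(x, y, method = method)
  cf <- stats::coef(stats::lm(y ~ x))
  structure(list(
    data = tibble::tibble(sample_id = ids, x = unname(x), y = unname(y)),
    test = test, fit = c(intercept = unname(cf[1]), slope = unname(cf[2])),
    density = FALSE, xlab = paste0(gene, " promoter beta"),
    ylab = paste0(gene, " expression"), cancer = cancer
  ), class = "gene_scatter")
}

#' Co-expression panel of a gene with enrichment of the correlated genes
#'
#' Pearson correlation of every other gene against the index gene over the
#' cancer's tumor samples, BH across genes; the `top_n` strongest positive
#' and `top_n` strongest negative genes with `q < q_threshold` form the
#' heatmap panel, and their union is tested by hypergeometric ORA against
#' the named catalog with the tested genes as background.
#'
#' @param cohort A `cohort`.
#' @param cancer Cancer code (needs at least 8 tumor samples).
#' @param gene Index gene (excluded from its own panel).
#' @param top_n,q_threshold Panel selection parameters.
#' @param catalog_name Catalog for the ORA step (optional).
#' @return List with `correlations` (tibble over all tested genes),
#'   `positive`, `negative` (selected symbols), `ora` (tibble or `NULL`).
#' @export
coexpression_panel <- function(cohort, cancer, gene, top_n = 20,
                               q_threshold = 0.05, catalog_name = NULL) {
  res <- resolve_gene_or_set(cohort, gene)
  if (res$type != "gene") stop("expected a single index gene", call. = FALSE)
  s <- cohort_samples(cohort, cancer, group = "tumor")
  if (nrow(s) < 8L) stop("need at least 8 tumor samples", call. = FALSE)
  expr <- cohort$expression[s$sample_id, , drop = FALSE]
  v <- expr[, gene]
  others <- setdiff(colnames(expr), gene)
  # vectorized Pearson + t-test p across all genes
  n <- nrow(expr)
  keep <- others[apply(expr[, others, drop = FALSE], 2L, stats::sd) > 0]
  r <- as.vector(stats::cor(expr[, keep, drop = FALSE], v))
  r <- pmax(-1, pmin(1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  correlations <- tibble::tibble(gene = keep, r = r, p = p,
                                 q = benjamini_hochberg(p),
                                 stars = significance_stars(p))
  sig <- dplyr::filter(correlations, .data$q < q_threshold)
  pos <- sig |> dplyr::filter(.data$r > 0) |>
    dplyr::arrange(dplyr::desc(.data$r)) |> utils::head(top_n)
  neg <- sig |> dplyr::filter(.data$r < 0) |>
    dplyr::arrange(.data$r) |> utils::head(top_n)
  if (nrow(pos) + nrow(neg) == 0L) {
    warning("no gene passes the q threshold; panel is empty", call. = FALSE)
  }
  ora <- NULL
  if (!is.null(catalog_name) && nrow(pos) + nrow(neg) > 0L) {
    if (!catalog_name %in% names(cohort$catalogs)) {
      stop(sprintf("catalog '%s' is not loaded", catalog_name), call. = FALSE)
    }
    ora <- hypergeometric_ora(c(pos$gene, neg$gene),
                              cohort$catalogs[[catalog_name]],
                              background = keep)
  }
  list(correlations = correlations, positive = pos$gene, negative = neg$gene,
       ora = ora, index = gene, cancer = cancer)
}

#' Kaplan-Meier survival split on expression or promoter methylation
#'
#' Tumor samples are split at the median of the chosen layer's value for
#' the gene (ties to the low group); the two Kaplan-Meier curves and the
#' log-rank test are returned. When the layer values are all distinct the
#' group sizes differ by at most 1.
#'
#' @param cohort A `cohort` with clinical data.
#' @param cancer Cancer code.
#' @param gene Gene symbol.
#' @param layer `"expression"` or `"methylation"`.
#' @param min_samples,min_events Preconditions (defaults 10 and 2).
#' @return A `km_split` object: `$curves` (tibble with a `level` column),
#'   `$test` (log-rank result), `$levels` (per-sample high/low labels).
#' @export
survival_by_level <- function(cohort, cancer, gene,
                              layer = c("expression", "methylation"),
                              min_samples = 10, min_events = 2) {
  layer <- match.arg(layer)
  if (is.null(cohort$clinical)) stop("clinical layer absent", call. = FALSE)
  s <- cohort_samples(cohort, cancer, group = "tumor")
  if (layer == "expression") {
    resolve_gene_or_set(cohort, gene)
    val <- stats::setNames(cohort$expression[s$sample_id, gene], s$sample_id)
  } else {
    if (is.null(cohort$methylation) || !gene %in% rownames(cohort$methylation)) {
      stop(sprintf("gene '%s' has no promoter methylation row", gene),
           call. = FALSE)
    }
    ids <- intersect(s$sample_id, colnames(cohort$methylation))
    val <- cohort$methylation[gene, ids]
    val <- val[!is.na(val)]
  }
  d <- tibble::tibble(sample_id = names(val), value = unname(val)) |>
    dplyr::inner_join(s[, c("sample_id", "patient_id")], by = "sample_id") |>
    dplyr::inner_join(cohort$clinical, by = "patient_id") |>
    dplyr::filter(!is.na(.data$os_time), !is.na(.data$os_event))
  if (nrow(d) < min_samples) {
    stop(sprintf("fewer than %d usable samples", min_samples), call. = FALSE)
  }
  if (sum(d$os_event) < min_events) {
    stop(if (sum(d$os_event) == 0) "all survival times censored"
         else sprintf("fewer than %d events", min_events), call. = FALSE)
  }
  level <- ifelse(d$value <= stats::median(d$value), "low", "high")
  test <- logrank_test(d$os_time, d$os_event, level)
  curves <- purrr::map(c("high", "low"), function(lv) {
    km <- km_estimate(d$os_time[level == lv], d$os_event[level == lv])
    dplyr::mutate(tibble::as_tibble(km), level = lv)
  }) |> dplyr::bind_rows()
  structure(list(curves = curves, test = test,
                 levels = stats::setNames(level, d$sample_id),
                 gene = gene, layer = layer, cancer = cancer),
            class = "km_split")
}

#' Gene-term membership network from over-representation
#'
#' Runs hypergeometric ORA of the query genes against a loaded catalog and
#' builds the bipartite network linking each query gene to the enriched
#' terms (q below threshold) containing it.
#'
#' @param cohort A `cohort`.
#' @param genes Character vector: a single gene or set members.
#' @param catalog_name Name of a loaded catalog.
#' @param q_threshold Enrichment cutoff for term nodes.
#' @param background Gene universe (default: all expression genes).
#' @return A `term_network` object: `$nodes` (tibble `name`, `type`),
#'   `$edges` (tibble `gene`, `term`), `$enrichment` (the ORA table).
#' @export
term_network <- function(cohort, genes, catalog_name, q_threshold = 0.05,
                         background = NULL) {
  if (!catalog_name %in% names(cohort$catalogs)) {
    stop(sprintf("catalog '%s' is not loaded", catalog_name), call. = FALSE)
  }
  if (length(genes) == 0L) stop("empty query", call. = FALSE)
  catalog <- cohort$catalogs[[catalog_name]]
  background <- background %||% colnames(cohort$expression)
  enr <- hypergeometric_ora(genes, catalog, background)
  hit <- dplyr::filter(enr, .data$q < q_threshold, .data$n_overlap > 0)
  if (nrow(hit) == 0L) {
    warning("no term passes the q threshold; network is empty", call. = FALSE)
    edges <- tibble::tibble(gene = character(), term = character())
  } else {
    edges <- hit |>
      dplyr::select("set", "overlap") |>
      tidyr::unnest_longer("overlap") |>
      dplyr::transmute(gene = .data$overlap, term = .data$set)
  }
  nodes <- dplyr::bind_rows(
    tibble::tibble(name = unique(edges$gene), type = "gene"),
    tibble::tibble(name = unique(edges$term), type = "term")
  )
  structure(list(nodes = nodes, edges = edges, enrichment = enr,
                 q_threshold = q_threshold),
            class = "term_network")
}

#' Serialize a term network as edge-list and node TSV files
#'
#' @param network A `term_network`.
#' @param path Basename; writes `<path>_edges.tsv` and `<path>_nodes.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_term_network <- function(network, path) {
  p1 <- paste0(path, "_edges.tsv"); p2 <- paste0(path, "_nodes.tsv")
  readr::write_tsv(network$edges, p1)
  readr::write_tsv(network$nodes, p2)
  invisible(c(p1, p2))
}
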