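# Gene-set statistics: set-level expression summaries, single-sample
# rank-weighted enrichment (ssGSEA) and the stromal/immune/ESTIMATE scores
# built on it, preranked GSEA with a permutation null, hypergeometric
# over-representation, and the median-split DEG screen.

#' Per-sample mean expression of a gene set
#'
#' @param expr Numeric matrix, samples x genes (log2(TPM+1)), with gene
#'   symbols as column names.
#' @param genes Character vector of member symbols.
#' @return Named numeric vector (one score per sample) with attribute
#'   `absent`: members not found in the matrix.
#' @export
gene_set_expression <- function(expr, genes) {
  stopifnot(is.matrix(expr))
  genes <- unique(genes)
  present <- intersect(genes, colnames(expr))
  if (length(present) == 0L) {
    stop("no gene-set member present in the expression matrix", call. = FALSE)
  }
  score <- rowMeans(expr[, present, drop = FALSE])
  attr(score, "absent") <- setdiff(genes, present)
  score
}

# deterministic decreasing-expression ordering: value desc, then symbol
rank_order <- function(values) order(-values, names(values), method = "radix")

#' Single-sample rank-weighted enrichment score
#'
#' Genes are ordered by decreasing expression (ties broken by symbol).
#' Walking down the list, in-set genes add their normalized rank weight
#' `(N - position + 1)^alpha` and out-of-set genes subtract a uniform
#' increment; the score is the sum of the running differences over all
#' positions, so it depends only on the expression ranking.
#'
#' @param values Named numeric vector: one sample's expression by gene.
#' @param gene_set Character vector of member symbols.
#' @param alpha Rank-weight exponent (default 0.25).
#' @return A single numeric score.
#' @export
ssgsea_score <- function(values, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(values)))
  n <- length(values)
  in_set <- names(values) %in% gene_set
  if (!any(in_set)) stop("gene set does not intersect the profile", call. = FALSE)
  if (all(in_set)) stop("gene set covers the whole profile", call. = FALSE)
  o <- rank_order(values)
  hit <- in_set[o]
  w <- (n - seq_len(n) + 1)^alpha
  inc <- ifelse(hit, w / sum(w[hit]), -1 / sum(!hit))
  sum(cumsum(inc))
}

#' Stromal, Immune and ESTIMATE scores
#'
#' Per sample, Stromal and Immune are [ssgsea_score()] of the two signature
#' sets; ESTIMATE is their sum, exactly.
#'
#' @param expr Samples x genes matrix (log2 scale).
#' @param stromal_set,immune_set Signature gene symbol vectors.
#' @param alpha Passed to [ssgsea_score()].
#' @return Tibble with columns `sample_id`, `Stromal`, `Immune`, `ESTIMATE`.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, alpha = 0.25) {
  stopifnot(is.matrix(expr))
  score_one <- function(set) {
    apply(expr, 1L, function(v) ssgsea_score(v, set, alpha = alpha))
  }
  s <- score_one(stromal_set)
  i <- score_one(immune_set)
  tibble::tibble(
    sample_id = rownames(expr),
    Stromal = unname(s), Immune = unname(i), ESTIMATE = unname(s + i)
  )
}

# Signed-extremum enrichment score of a weighted KS running sum, computed
# from the in-set positions only (O(|S|) per evaluation). `absw` are the
# |metric| values in ranked order; `pos` the (sorted) in-set positions.
es_from_positions <- function(pos, absw, n) {
  k <- length(pos)
  pos <- sort(pos)
  w <- absw[pos]
  sw <- sum(w)
  win <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  dec <- 1 / (n - k)
  at_hit <- win - (pos - seq_len(k)) * dec          # just after each hit
  before <- c(0, win[-k]) - (pos - seq_len(k)) * dec # just before each hit
  hi <- max(at_hit, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running statistic (weight exponent 1 on the
#' absolute ranking metric); ES is the signed maximum deviation. The null is
#' built from seeded gene-label permutations; the permutation p-value uses
#' the +1 correction, `(1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`, and NES
#' divides ES by the mean |null ES| of matching sign. Sets with fewer than 2
#' members in the ranking (or more than half of it) are skipped with a
#' warning.
#'
#' @param ranking Named numeric vector, gene -> metric (e.g. log2FC).
#' @param catalog Named list of gene-symbol vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (required).
#' @return Tibble with one row per scored set: `set`, `size`, `es`, `nes`,
#'   `p`, `fdr`, `leading_edge` (list-column).
#' @export
preranked_gsea <- function(ranking, catalog, n_perm = 1000, seed) {
  stopifnot(!is.null(names(ranking)), is.list(catalog))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  o <- order(-ranking, names(ranking), method = "radix")
  genes <- names(ranking)[o]
  metric <- as.numeric(ranking)[o]
  n <- length(genes)
  absw <- abs(metric)
  rows <- withr::with_seed(seed, {
    purrr::imap(catalog, function(members, set_name) {
      pos <- which(genes %in% members)
      k <- length(pos)
      if (k < 2L || k > n / 2) {
        warning(sprintf("set '%s' skipped (%d members in ranking)", set_name, k),
                call. = FALSE)
        return(NULL)
      }
      es <- es_from_positions(pos, absw, n)
      null_es <- vapply(seq_len(n_perm), function(i) {
        es_from_positions(sample.int(n, k), absw, n)
      }, numeric(1))
      p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
      same_sign <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
      pos_s <- sort(pos)
      le <- if (es >= 0) {
        peak <- pos_s[which.max(cumsum(absw[pos_s]) / max(sum(absw[pos_s]), 1e-300) -
                                  (pos_s - seq_along(pos_s)) / (n - k))]
        genes[intersect(seq_len(peak), pos_s)]
      } else {
        win <- cumsum(absw[pos_s]) / max(sum(absw[pos_s]), 1e-300)
        trough <- pos_s[which.min(c(0, win[-k]) - (pos_s - seq_along(pos_s)) / (n - k))]
        genes[intersect(seq(trough, n), pos_s)]
      }
      tibble::tibble(set = set_name, size = k, es = es, nes = nes, p = p,
                     leading_edge = list(le))
    })
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) {
    return(tibble::tibble(set = character(), size = integer(), es = double(),
                          nes = double(), p = double(), fdr = double(),
                          leading_edge = list()))
  }
  res$fdr <- benjamini_hochberg(res$p)
  dplyr::relocate(res, "fdr", .after = "p")
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a query gene list against each catalog
#' term, with terms intersected with the background universe and BH
#' adjustment across terms.
#'
#' @param query Character vector of gene symbols (must lie in `background`).
#' @param catalog Named list of gene-symbol vectors.
#' @param background Character vector: the gene universe.
#' @return Tibble with `set`, `n_set`, `n_overlap`, `p`, `q`, `overlap`
#'   (list-column of overlapping symbols).
#' @export
hypergeometric_ora <- function(query, catalog, background) {
  background <- unique(background)
  query <- unique(intersect(query, background))
  if (length(query) == 0L) {
    stop("query is empty after intersecting with the background", call. = FALSE)
  }
  n_bg <- length(background)
  res <- purrr::imap(catalog, function(members, set_name) {
    term <- intersect(unique(members), background)
    ov <- intersect(query, term)
    k <- length(ov); big_k <- length(term)
    p <- stats::phyper(k - 1, big_k, n_bg - big_k, length(query),
                       lower.tail = FALSE)
    tibble::tibble(set = set_name, n_set = big_k, n_overlap = k,
                   p = p, overlap = list(sort(ov)))
  }) |> dplyr::bind_rows()
  res$q <- benjamini_hochberg(res$p)
  dplyr::relocate(res, "q", .after = "p")
}

#' Differential expression between high and low halves of an index
#'
#' Samples are split at the median of `index` (ties go to the low group).
#' Per gene, the effect is the difference of group means on the stored log2
#' scale (a log2 fold change of geometric means of TPM+1), the p-value comes
#' from [mann_whitney()], and q from BH across genes.
#'
#' @param expr Samples x genes matrix, tumor samples only.
#' @param index Per-sample numeric values used for the split.
#' @param exclude Optional gene symbol excluded from testing (typically the
#'   index gene itself).
#' @return Tibble with `gene`, `log2fc`, `stat`, `p`, `q`, `stars`, plus
#'   attribute `groups` (the high/low labels used).
#' @export
deg_high_low <- function(expr, index, exclude = NULL) {
  stopifnot(is.matrix(expr), length(index) == nrow(expr))
  if (nrow(expr) < 4L) stop("need at least 4 samples", call. = FALSE)
  low <- index <= stats::median(index)
  if (all(low) || !any(low)) stop("degenerate median split", call. = FALSE)
  genes <- setdiff(colnames(expr), exclude)
  rows <- purrr::map(genes, function(g) {
    v <- expr[, g]
    tr <- mann_whitney(v[!low], v[low])
    tibble::tibble(gene = g, log2fc = mean(v[!low]) - mean(v[low]),
                   stat = tr$stat, p = tr$p)
  })
  res <- dplyr::bind_rows(rows)
  res$q <- benjamini_hochberg(res$p)
  res$stars <- significance_stars(res$p)
  attr(res, "groups") <- ifelse(low, "low", "high")
  res
}
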