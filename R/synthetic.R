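# Seeded synthetic-cohort generator. Produces TCGA-shaped multi-layer
# cohorts with planted, recorded effects (differential expression, metric
# correlations via a Gaussian copula, proportional hazards, promoter
# methylation coupling) so every analysis can be exercised and its recovery
# verified without any real download.

#' Specify a synthetic cohort
#'
#' @param cancers Tibble/data frame with columns `code`, `n_tumor`,
#'   `n_normal`, `n_paired` (`n_paired <= min(n_tumor, n_normal)`).
#' @param n_genes Total number of genes (named genes are taken first, then
#'   filler symbols `SG####`).
#' @param genes Optional explicit gene-symbol vector (length `n_genes`).
#' @param baseline_mean,baseline_sd Mean and SD of the per-gene baseline
#'   log2(TPM+1) level across genes.
#' @param noise_sd Within-gene, across-sample SD on the log2 scale.
#' @param planted_de Tibble `gene`, `cancer`, `log2fc`: mean shift added to
#'   tumor samples.
#' @param planted_metric_corr Tibble `gene`, `cancer`, `metric`
#'   (`"TMB"`, `"MSI"` or `"Immune"`), `target_r` in (-1, 1). TMB/MSI are
#'   coupled linearly through a Gaussian copula; `"Immune"` shifts the
#'   immune-signature genes so the ssGSEA Immune score co-varies with the
#'   planted gene.
#' @param planted_hazard Tibble `gene`, `cancer`, `log_hr`: per-sample log
#'   hazard is `log_hr` times the standardized gene expression.
#' @param planted_methylation_corr Tibble `gene`, `cancer`, `target_r`:
#'   promoter beta coupled to expression through a logistic link (sign
#'   preserved; |r| attenuated by the link).
#' @param planted_coexpression Tibble `gene`, `partner`, `cancer`,
#'   `target_r`: partner expression regenerated as a correlated draw in that
#'   cancer's tumor samples.
#' @param censoring_rate Fraction of follow-up censored (independent uniform
#'   administrative censoring), in \[0, 0.95\].
#' @param families,catalogs Gene families / gene-set catalogs carried into
#'   the cohort.
#' @param stromal_signature,immune_signature Signature symbol vectors used
#'   to compute the immune-score layer.
#' @param seed Integer seed (required; the generator is fully deterministic
#'   given the spec).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cancers, n_genes = 500, genes = NULL,
                        baseline_mean = 4, baseline_sd = 1.5, noise_sd = 1,
                        planted_de = NULL, planted_metric_corr = NULL,
                        planted_hazard = NULL, planted_methylation_corr = NULL,
                        planted_coexpression = NULL, censoring_rate = 0.3,
                        families = list(), catalogs = list(),
                        stromal_signature = NULL, immune_signature = NULL,
                        seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  cancers <- tibble::as_tibble(cancers)
  stopifnot(all(c("code", "n_tumor", "n_normal", "n_paired") %in% names(cancers)),
            censoring_rate >= 0, censoring_rate < 0.95)
  if (any(cancers$n_paired > pmin(cancers$n_tumor, cancers$n_normal))) {
    stop("infeasible spec: n_paired > min(n_tumor, n_normal)", call. = FALSE)
  }
  for (tab in list(planted_metric_corr, planted_methylation_corr,
                   planted_coexpression)) {
    if (!is.null(tab) && any(abs(tab$target_r) >= 1)) {
      stop("target_r must lie in (-1, 1)", call. = FALSE)
    }
  }
  structure(list(
    cancers = cancers, n_genes = n_genes, genes = genes,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd = noise_sd,
    planted_de = planted_de, planted_metric_corr = planted_metric_corr,
    planted_hazard = planted_hazard,
    planted_methylation_corr = planted_methylation_corr,
    planted_coexpression = planted_coexpression,
    censoring_rate = censoring_rate, families = families,
    catalogs = catalogs, stromal_signature = stromal_signature,
    immune_signature = immune_signature, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# correlated standard-normal draw (Gaussian copula building block)
couple <- function(z, r) r * z + sqrt(1 - r^2) * stats::rnorm(length(z))

#' Generate a synthetic cohort from a spec
#'
#' Deterministic given `spec$seed`. Expression is per-gene Gaussian on the
#' log2 scale around a truncated-normal baseline (clamped at 0 so stored
#' values are valid log2(TPM+1)); survival times are exponential with log
#' hazard proportional to standardized planted-gene expression and
#' independent uniform administrative censoring calibrated to the requested
#' rate; barcodes follow the TCGA grammar with a synthetic project prefix so
#' they cannot collide with real ids.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (a `cohort`) and `truth` (tibble of planted
#'   effects with their realized sample-level values).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  genes <- spec$genes %||% sprintf("SG%04d", seq_len(spec$n_genes))
  stopifnot(length(genes) == spec$n_genes, !anyDuplicated(genes))

  # --- samples and barcodes -------------------------------------------------
  samples <- purrr::pmap(spec$cancers, function(code, n_tumor, n_normal, n_paired) {
    n_pat <- n_tumor + n_normal - n_paired
    pid <- sprintf("SYNT-%s-%04d", code, seq_len(n_pat))
    has_tumor <- seq_len(n_pat) <= n_tumor
    has_normal <- seq_len(n_pat) <= n_paired |
      (seq_len(n_pat) > n_tumor)
    tibble::tibble(
      patient_id = c(pid[has_tumor], pid[has_normal]),
      group = rep(c("tumor", "normal"), c(sum(has_tumor), sum(has_normal))),
      cancer_type = code
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      sample_code = ifelse(.data$group == "tumor", "01", "11"),
      sample_id = paste0(.data$patient_id, "-", .data$sample_code, "A")
    ) |>
    dplyr::select("sample_id", "patient_id", "sample_code", "group",
                  "cancer_type")
  n_s <- nrow(samples)

  # --- expression -----------------------------------------------------------
  mu <- pmax(0.5, stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd))
  expr <- matrix(stats::rnorm(n_s * spec$n_genes, sd = spec$noise_sd),
                 nrow = n_s, ncol = spec$n_genes,
                 dimnames = list(samples$sample_id, genes))
  expr <- sweep(expr, 2L, mu, `+`)

  truth <- list()
  tumor_rows <- function(cancer) {
    which(samples$cancer_type == cancer & samples$group == "tumor")
  }
  if (!is.null(spec$planted_de)) {
    for (i in seq_len(nrow(spec$planted_de))) {
      p <- spec$planted_de[i, ]
      rows <- tumor_rows(p$cancer)
      expr[rows, p$gene] <- expr[rows, p$gene] + p$log2fc
      nr <- which(samples$cancer_type == p$cancer & samples$group == "normal")
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "de", gene = p$gene, cancer = p$cancer, target = p$log2fc,
        realized = mean(expr[rows, p$gene]) - mean(expr[nr, p$gene])
      )
    }
  }
  if (!is.null(spec$planted_coexpression)) {
    for (i in seq_len(nrow(spec$planted_coexpression))) {
      p <- spec$planted_coexpression[i, ]
      rows <- tumor_rows(p$cancer)
      z <- as.vector(scale(expr[rows, p$gene]))
      g2 <- which(genes == p$partner)
      expr[rows, g2] <- mu[g2] + spec$noise_sd * couple(z, p$target_r)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "coexpression", gene = paste(p$gene, p$partner, sep = "~"),
        cancer = p$cancer, target = p$target_r,
        realized = stats::cor(expr[rows, p$gene], expr[rows, g2])
      )
    }
  }

  # --- immune coupling (shifts signature genes before scoring) --------------
  metric_plants <- spec$planted_metric_corr
  if (!is.null(metric_plants)) {
    imm <- dplyr::filter(metric_plants, .data$metric == "Immune")
    for (i in seq_len(nrow(imm))) {
      p <- imm[i, ]
      rows <- tumor_rows(p$cancer)
      z <- as.vector(scale(expr[rows, p$gene]))
      shift <- 1.0 * couple(z, p$target_r)
      sig <- intersect(spec$immune_signature, genes)
      expr[rows, sig] <- expr[rows, sig] + shift
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "immune_coupling", gene = p$gene, cancer = p$cancer,
        target = p$target_r, realized = NA_real_
      )
    }
  }
  expr <- pmax(expr, 0)

  # --- TMB / MSI ------------------------------------------------------------
  tumor_idx <- which(samples$group == "tumor")
  metric_tab <- function(metric, base, sdv) {
    z <- stats::rnorm(length(tumor_idx))
    if (!is.null(metric_plants)) {
      pl <- dplyr::filter(metric_plants, .data$metric == .env$metric)
      for (i in seq_len(nrow(pl))) {
        p <- pl[i, ]
        rows <- tumor_rows(p$cancer)
        zg <- as.vector(scale(expr[rows, p$gene]))
        z[match(rows, tumor_idx)] <- couple(zg, p$target_r)
      }
    }
    v <- pmax(0, base + sdv * z)
    tab <- tibble::tibble(sample_id = samples$sample_id[tumor_idx], value = v)
    if (!is.null(metric_plants)) {
      pl <- dplyr::filter(metric_plants, .data$metric == .env$metric)
      for (i in seq_len(nrow(pl))) {
        p <- pl[i, ]
        rows <- tumor_rows(p$cancer)
        truth[[length(truth) + 1L]] <<- tibble::tibble(
          kind = paste0("metric_", tolower(metric)), gene = p$gene,
          cancer = p$cancer, target = p$target_r,
          realized = stats::cor(expr[rows, p$gene],
                                v[match(rows, tumor_idx)])
        )
      }
    }
    tab
  }
  tmb <- metric_tab("TMB", base = 10, sdv = 3) |> dplyr::rename(tmb = "value")
  msi <- metric_tab("MSI", base = 1, sdv = 0.3) |> dplyr::rename(msi = "value")

  # --- promoter methylation (tumor samples, logistic link) ------------------
  t_ids <- samples$sample_id[tumor_idx]
  base_beta <- stats::runif(spec$n_genes, 0.1, 0.8)
  zmat <- matrix(stats::rnorm(spec$n_genes * length(t_ids)),
                 nrow = spec$n_genes,
                 dimnames = list(genes, t_ids))
  if (!is.null(spec$planted_methylation_corr)) {
    for (i in seq_len(nrow(spec$planted_methylation_corr))) {
      p <- spec$planted_methylation_corr[i, ]
      rows <- tumor_rows(p$cancer)
      zg <- as.vector(scale(expr[rows, p$gene]))
      cols <- match(samples$sample_id[rows], t_ids)
      zmat[p$gene, cols] <- couple(zg, p$target_r)
    }
  }
  methylation <- stats::plogis(stats::qlogis(base_beta) + 0.8 * zmat)
  attr(methylation, "provenance") <-
    stats::setNames(purrr::map(genes, ~ paste0("cg_", .x)), genes)
  if (!is.null(spec$planted_methylation_corr)) {
    for (i in seq_len(nrow(spec$planted_methylation_corr))) {
      p <- spec$planted_methylation_corr[i, ]
      rows <- tumor_rows(p$cancer)
      cols <- match(samples$sample_id[rows], t_ids)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "methylation", gene = p$gene, cancer = p$cancer,
        target = p$target_r,
        realized = stats::cor(expr[rows, p$gene], methylation[p$gene, cols])
      )
    }
  }

  # --- immune-cell ratios and immune scores ---------------------------------
  cell_types <- c("B_cell", "T_cell_CD4", "T_cell_CD8", "NK_cell",
                  "Monocyte", "Macrophage", "Dendritic", "Neutrophil")
  g <- matrix(stats::rgamma(length(tumor_idx) * length(cell_types), shape = 2),
              ncol = length(cell_types))
  immune_ratio <- tibble::as_tibble(g / rowSums(g), .name_repair = "minimal")
  names(immune_ratio) <- cell_types
  immune_ratio <- dplyr::bind_cols(
    tibble::tibble(sample_id = samples$sample_id[tumor_idx]), immune_ratio)

  immune_score <- NULL
  if (!is.null(spec$stromal_signature) && !is.null(spec$immune_signature)) {
    immune_score <- estimate_scores(expr[tumor_idx, , drop = FALSE],
                                    spec$stromal_signature,
                                    spec$immune_signature)
  }

  # --- clinical + survival --------------------------------------------------
  pts <- dplyr::distinct(samples, .data$patient_id, .data$cancer_type)
  lambda0 <- log(2) / 730  # median baseline survival of two years (days)
  loghaz <- numeric(nrow(pts))
  if (!is.null(spec$planted_hazard)) {
    for (i in seq_len(nrow(spec$planted_hazard))) {
      p <- spec$planted_hazard[i, ]
      rows <- tumor_rows(p$cancer)
      zg <- as.vector(scale(expr[rows, p$gene]))
      loghaz[match(samples$patient_id[rows], pts$patient_id)] <- p$log_hr * zg
    }
  }
  t_true <- stats::rexp(nrow(pts), rate = lambda0 * exp(loghaz))
  if (spec$censoring_rate > 0) {
    # choose uniform horizon b so P(T > C) = rate at the baseline hazard
    u <- stats::uniroot(function(u) (1 - exp(-u)) / u - spec$censoring_rate,
                        c(1e-8, 1e6))$root
    cens <- stats::runif(nrow(pts), 0, u / lambda0)
    os_time <- pmin(t_true, cens)
    os_event <- as.integer(t_true <= cens)
  } else {
    os_time <- t_true
    os_event <- rep(1L, nrow(pts))
  }
  clinical <- tibble::tibble(
    patient_id = pts$patient_id,
    age = round(pmin(90, pmax(25, stats::rnorm(nrow(pts), 62, 10)))),
    gender = sample(c("male", "female"), nrow(pts), replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), nrow(pts), replace = TRUE,
                   prob = c(0.25, 0.3, 0.3, 0.15)),
    os_time = round(os_time, 1), os_event = os_event
  )
  if (!is.null(spec$planted_hazard)) {
    for (i in seq_len(nrow(spec$planted_hazard))) {
      p <- spec$planted_hazard[i, ]
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "hazard", gene = p$gene, cancer = p$cancer,
        target = p$log_hr, realized = NA_real_
      )
    }
  }

  cohort <- new_cohort(
    expression = expr, samples = samples, clinical = clinical,
    tmb = tmb, msi = msi, immune_ratio = immune_ratio,
    immune_score = immune_score, methylation = methylation,
    families = spec$families, catalogs = spec$catalogs
  )
  list(cohort = cohort, truth = dplyr::bind_rows(truth))
}
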