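# Directory-bundle serialization of a cohort: plain TSV per layer,
# families.yaml, catalogs/*.gmt and a manifest with per-file checksums.

#' Write a cohort as a directory bundle
#'
#' Layout: `expression.tsv` (samples as rows, first columns `sample_id`,
#' `cancer_type`, `group`, then genes), `meta.tsv`, `tmb.tsv`, `msi.tsv`,
#' `immune_ratio.tsv`, `immune_score.tsv`, `promoter_methylation.tsv`,
#' `families.yaml`, `catalogs/*.gmt`, `manifest.yaml` (md5 checksums plus
#' the creation seed, if any).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @param seed Optional integer recorded in the manifest.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_tab <- dplyr::bind_cols(
    cohort$samples[, c("sample_id", "cancer_type", "group")],
    tibble::as_tibble(cohort$expression)
  )
  readr::write_tsv(expr_tab, file.path(dir, "expression.tsv"))
  if (!is.null(cohort$clinical)) {
    readr::write_tsv(cohort$clinical, file.path(dir, "meta.tsv"))
  }
  for (nm in c("tmb", "msi")) {
    if (!is.null(cohort[[nm]])) {
      readr::write_tsv(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  if (!is.null(cohort$immune_ratio)) {
    readr::write_tsv(cohort$immune_ratio, file.path(dir, "immune_ratio.tsv"))
  }
  if (!is.null(cohort$immune_score)) {
    readr::write_tsv(cohort$immune_score, file.path(dir, "immune_score.tsv"))
  }
  if (!is.null(cohort$methylation)) {
    readr::write_tsv(
      tibble::as_tibble(cohort$methylation, rownames = "gene"),
      file.path(dir, "promoter_methylation.tsv")
    )
  }
  if (length(cohort$families)) {
    yaml::write_yaml(cohort$families, file.path(dir, "families.yaml"))
  }
  if (length(cohort$catalogs)) {
    dir.create(file.path(dir, "catalogs"), showWarnings = FALSE)
    for (nm in names(cohort$catalogs)) {
      write_gmt(cohort$catalogs[[nm]],
                file.path(dir, "catalogs", paste0(nm, ".gmt")))
    }
  }
  files <- list.files(dir, recursive = TRUE)
  files <- setdiff(files, "manifest.yaml")
  manifest <- list(
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, files))), files)),
    seed = seed
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Bundle directory.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  if (!file.exists(path("expression.tsv"))) {
    stop(sprintf("'%s' is not a cohort bundle (no expression.tsv)", dir),
         call. = FALSE)
  }
  expr_tab <- readr::read_tsv(path("expression.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  vals <- as.matrix(expr_tab[, setdiff(names(expr_tab),
                                       c("sample_id", "cancer_type", "group"))])
  rownames(vals) <- expr_tab$sample_id
  samples <- parse_barcode(expr_tab$sample_id) |>
    dplyr::mutate(cancer_type = expr_tab$cancer_type)
  read_if <- function(f) {
    if (file.exists(path(f))) {
      readr::read_tsv(path(f), show_col_types = FALSE, progress = FALSE)
    }
  }
  methy <- NULL
  if (file.exists(path("promoter_methylation.tsv"))) {
    mt <- readr::read_tsv(path("promoter_methylation.tsv"),
                          show_col_types = FALSE, progress = FALSE)
    methy <- as.matrix(mt[, -1])
    rownames(methy) <- mt$gene
  }
  families <- if (file.exists(path("families.yaml"))) {
    purrr::map(yaml::read_yaml(path("families.yaml")), as.character)
  } else list()
  catalogs <- list()
  if (dir.exists(path("catalogs"))) {
    for (f in list.files(path("catalogs"), pattern = "\\.gmt$")) {
      catalogs[[sub("\\.gmt$", "", f)]] <- read_gmt(path(file.path("catalogs", f)))
    }
  }
  new_cohort(
    expression = vals, samples = samples,
    clinical = read_if("meta.tsv"), tmb = read_if("tmb.tsv"),
    msi = read_if("msi.tsv"), immune_ratio = read_if("immune_ratio.tsv"),
    immune_score = read_if("immune_score.tsv"),
    methylation = methy, families = families, catalogs = catalogs
  )
}
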