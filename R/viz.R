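# Figure rendering. A plot spec pairs a figure kind with the payload table
# produced by an analysis; rendering never recomputes a statistic — stars,
# r values and HR text are read from the payload.

PLOT_KINDS <- c("box", "paired_box", "pan_box", "radar", "heatmap",
                "triangle_heatmap", "forest", "km", "roc", "scatter",
                "network", "gsea_running_sum")

REQUIRED_FIELDS <- list(
  box = c("label", "score"), paired_box = c("label", "score", "patient_id"),
  pan_box = "cancer_type", radar = c("cancer_type", "effect"),
  heatmap = c("cancer_type", "effect"),
  triangle_heatmap = c("cancer_type", "effect"),
  forest = c("cancer_type", "hr", "ci_low", "ci_high"),
  km = c("time", "surv", "level"), roc = c("fpr", "tpr"),
  scatter = c("x", "y"), network = c("gene", "term"),
  gsea_running_sum = c("position", "running")
)

#' Supported figure kinds
#' @return Character vector of plot-spec kinds.
#' @export
plot_kinds <- function() PLOT_KINDS

# small approximations of the usual publication palettes
palette_colors <- function(palette, n) {
  pal <- switch(palette,
    jco = c("#0073C2", "#EFC000", "#868686", "#CD534C",
            "#7AA6DC", "#003C67", "#8F7700", "#3B3B3B"),
    npg = c("#E64B35", "#4DBBD5", "#00A087", "#3C5488",
            "#F39B7F", "#8491B4", "#91D1C2", "#DC0000"),
    grDevices::hcl.colors(max(n, 2), "Dark 2")
  )
  rep_len(pal, n)
}

#' Build a plot specification
#'
#' @param kind One of [plot_kinds()].
#' @param data Payload data frame for the kind (see the kind's required
#'   columns in the errors of [render_plot()]).
#' @param palette,legend,lowcol,highcol,title Aesthetic options; `lowcol`
#'   and `highcol` anchor the diverging heatmap scale at r = 0.
#' @param annotations Optional tibble of annotation strings derived from
#'   the payload (e.g. [star_annotations()]).
#' @return A `plot_spec`.
#' @export
plot_spec <- function(kind, data, palette = "jco", legend = "right",
                      lowcol = "blue", highcol = "red", title = NULL,
                      annotations = NULL) {
  if (!kind %in% PLOT_KINDS) {
    stop(sprintf("unknown plot kind '%s'; expected one of: %s", kind,
                 paste(PLOT_KINDS, collapse = ", ")), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  need <- REQUIRED_FIELDS[[kind]]
  if (kind %in% c("heatmap", "triangle_heatmap")) {
    need <- c(need, if (!"gene" %in% names(data) && !"column" %in% names(data))
      "gene|column")
  }
  missing_f <- setdiff(need, names(data))
  if (length(missing_f)) {
    stop(sprintf("payload for kind '%s' is missing fields: %s", kind,
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
  structure(list(kind = kind, data = data,
                 aes = list(palette = palette, legend = legend,
                            lowcol = lowcol, highcol = highcol, title = title),
                 annotations = annotations),
            class = "plot_spec")
}

#' Star annotations from a result table
#'
#' @param table Data frame with a `p` column (a pan table or a one-row test
#'   result).
#' @return The table with a `label` column of significance stars.
#' @export
star_annotations <- function(table) {
  if (!"p" %in% names(table)) stop("no p column to annotate", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(table), label = significance_stars(.data$p))
}

# one ggplot per kind; numbers are taken from the payload only
build_plot <- function(spec, seed = 1L) {
  d <- spec$data
  a <- spec$aes
  base_theme <- ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = a$legend)
  gg <- switch(
    spec$kind,
    box = ggplot2::ggplot(d, ggplot2::aes(.data$label, .data$score,
                                          fill = .data$label)) +
      ggplot2::geom_boxplot() +
      ggplot2::scale_fill_manual(
        values = palette_colors(a$palette, dplyr::n_distinct(d$label))),
    paired_box = ggplot2::ggplot(d, ggplot2::aes(.data$label, .data$score)) +
      ggplot2::geom_boxplot(ggplot2::aes(fill = .data$label)) +
      ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                         alpha = 0.4) +
      ggplot2::scale_fill_manual(
        values = palette_colors(a$palette, dplyr::n_distinct(d$label))),
    pan_box = {
      ycol <- if ("effect" %in% names(d)) "effect" else "mean"
      gg0 <- ggplot2::ggplot(d, ggplot2::aes(.data$cancer_type,
                                             .data[[ycol]])) +
        ggplot2::geom_col(fill = palette_colors(a$palette, 1)) +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
      if ("stars" %in% names(d)) {
        gg0 <- gg0 + ggplot2::geom_text(ggplot2::aes(label = .data$stars),
                                        vjust = -0.3)
      }
      gg0
    },
    radar = ggplot2::ggplot(d, ggplot2::aes(.data$cancer_type, .data$effect,
                                            group = 1)) +
      ggplot2::geom_polygon(fill = palette_colors(a$palette, 1),
                            alpha = 0.3, color = palette_colors(a$palette, 1)) +
      ggplot2::geom_point() +
      {if ("stars" %in% names(d))
        ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.6)} +
      ggplot2::coord_polar(),
    heatmap = ggplot2::ggplot(
      d, ggplot2::aes(.data[[intersect(c("gene", "column"), names(d))[1]]],
                      .data$cancer_type, fill = .data$effect)) +
      ggplot2::geom_tile() +
      {if ("stars" %in% names(d))
        ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 2.5)} +
      ggplot2::scale_fill_gradient2(low = a$lowcol, high = a$highcol,
                                    midpoint = 0) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1)),
    triangle_heatmap = ggplot2::ggplot(
      d, ggplot2::aes(.data[[intersect(c("gene", "column"), names(d))[1]]],
                      .data$cancer_type, fill = .data$effect)) +
      ggplot2::geom_point(shape = 24, size = 5) +
      ggplot2::scale_fill_gradient2(low = a$lowcol, high = a$highcol,
                                    midpoint = 0),
    forest = ggplot2::ggplot(d, ggplot2::aes(.data$hr, .data$cancer_type)) +
      ggplot2::geom_vline(xintercept = 1, linetype = 2) +
      ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                            xmax = .data$ci_high)) +
      ggplot2::geom_text(
        ggplot2::aes(label = sprintf("%.2f [%.2f, %.2f]", .data$hr,
                                     .data$ci_low, .data$ci_high)),
        hjust = -0.1, size = 2.8) +
      ggplot2::scale_x_log10(),
    km = ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv,
                                         color = .data$level)) +
      ggplot2::geom_step() +
      ggplot2::scale_color_manual(
        values = palette_colors(a$palette, dplyr::n_distinct(d$level))) +
      ggplot2::ylim(0, 1),
    roc = ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           color = "grey60") +
      ggplot2::geom_path(color = palette_colors(a$palette, 1)),
    scatter = {
      gg0 <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
        ggplot2::geom_point(alpha = 0.5)
      if (isTRUE(attr(spec$data, "density")) ||
          isTRUE(spec$aes$title == "density")) {
        gg0 <- gg0 + ggplot2::geom_density_2d()
      }
      if (!is.null(attr(d, "fit"))) {
        f <- attr(d, "fit")
        gg0 <- gg0 + ggplot2::geom_abline(intercept = f["intercept"],
                                          slope = f["slope"],
                                          color = palette_colors(a$palette, 1))
      }
      gg0
    },
    network = {
      g <- igraph::graph_from_data_frame(d, directed = FALSE)
      lay <- withr::with_seed(seed, igraph::layout_with_fr(g))
      nodes <- tibble::tibble(
        name = igraph::V(g)$name, x = lay[, 1], y = lay[, 2],
        type = ifelse(igraph::V(g)$name %in% d$term, "term", "gene"))
      edges <- d |>
        dplyr::left_join(nodes, by = c(gene = "name")) |>
        dplyr::left_join(nodes, by = c(term = "name"),
                         suffix = c("", "_end"))
      ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y)) +
        ggplot2::geom_segment(
          data = edges, ggplot2::aes(x = .data$x, y = .data$y,
                                     xend = .data$x_end, yend = .data$y_end),
          color = "grey70") +
        ggplot2::geom_point(ggplot2::aes(color = .data$type), size = 3) +
        ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1,
                           size = 2.5) +
        ggplot2::theme_void()
    },
    gsea_running_sum = ggplot2::ggplot(
      d, ggplot2::aes(.data$position, .data$running)) +
      ggplot2::geom_line(color = palette_colors(a$palette, 1)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2)
  )
  gg <- gg + base_theme
  if (!is.null(a$title)) gg <- gg + ggplot2::ggtitle(a$title)
  if (!is.null(spec$annotations) && "label" %in% names(spec$annotations) &&
      all(c("x", "y") %in% names(spec$annotations))) {
    gg <- gg + ggplot2::geom_text(
      data = spec$annotations,
      ggplot2::aes(.data$x, .data$y, label = .data$label),
      inherit.aes = FALSE)
  }
  gg
}

#' Render a plot spec to a file
#'
#' Writes the figure and a `render_manifest.yaml` sidecar recording the
#' payload hash, kind and layout seed; rendering is a pure function of the
#' spec (network layouts are seeded).
#'
#' @param spec A [plot_spec()].
#' @param path Output file; extension decides the format unless `format`
#'   is given.
#' @param format `"pdf"`, `"png"` or `"svg"`.
#' @param seed Layout seed (networks).
#' @return Tibble record: `path`, `format`, `kind`, `n_rows`,
#'   `payload_hash`.
#' @export
render_plot <- function(spec, path, format = NULL, seed = 1L) {
  stopifnot(inherits(spec, "plot_spec"))
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("pdf", "png", "svg")) {
    stop(sprintf("unsupported format '%s'", format), call. = FALSE)
  }
  gg <- build_plot(spec, seed = seed)
  dev <- switch(format,
    png = function(filename, ...) grDevices::png(filename, width = 2100,
                                                 height = 1500, res = 300),
    svg = function(filename, ...) grDevices::svg(filename, width = 7,
                                                 height = 5),
    "pdf")
  suppressMessages(ggplot2::ggsave(path, gg, device = dev,
                                   width = 7, height = 5))
  hash <- rlang::hash(spec$data)
  yaml::write_yaml(
    list(payload_hash = hash, kind = spec$kind, seed = seed,
         n_rows = nrow(spec$data)),
    paste0(path, ".render_manifest.yaml"))
  tibble::tibble(path = path, format = format, kind = spec$kind,
                 n_rows = nrow(spec$data), payload_hash = hash)
}

#' GSEA running-sum payload for one gene set
#'
#' The weighted Kolmogorov-Smirnov running statistic along the ranking
#' (weight exponent 1 on |metric|), for plotting.
#'
#' @param ranking Named numeric vector (gene -> metric).
#' @param members Gene-set member symbols.
#' @return Tibble `position`, `running`, `in_set`.
#' @export
gsea_running_sum <- function(ranking, members) {
  o <- order(-ranking, names(ranking), method = "radix")
  genes <- names(ranking)[o]
  absw <- abs(as.numeric(ranking)[o])
  hit <- genes %in% members
  n <- length(genes); k <- sum(hit)
  stopifnot(k >= 1, k < n)
  inc <- ifelse(hit,
                if (sum(absw[hit]) > 0) absw / sum(absw[hit]) else 1 / k,
                0)
  inc[!hit] <- -1 / (n - k)
  tibble::tibble(position = seq_len(n), running = cumsum(inc), in_set = hit)
}

# --- autoplot methods -------------------------------------------------------

#' @rdname pan_expression
#' @param object A result object.
#' @param ... Passed to [plot_spec()].
#' @method autoplot pan_result
#' @export
autoplot.pan_result <- function(object, ...) {
  analysis <- attr(object, "analysis")
  kind <- if (analysis == "pan_cox_forest") "forest"
  else if (grepl("correlation$", analysis) &&
           "column" %in% names(object)) "heatmap"
  else if ("gene" %in% names(object)) "heatmap"
  else if (grepl("pan_(tmb|msi)", analysis)) "radar"
  else "pan_box"
  spec <- plot_spec(kind, tibble::as_tibble(object),
                    lowcol = attr(object, "lowcol") %||% "blue",
                    highcol = attr(object, "highcol") %||% "red",
                    title = paste(analysis, attr(object, "query")), ...)
  build_plot(spec)
}

#' @rdname grouped_expression
#' @param object A result object.
#' @param ... Passed to [plot_spec()].
#' @method autoplot grouped_expression
#' @export
autoplot.grouped_expression <- function(object, ...) {
  kind <- if (object$grouping == "paired") "paired_box" else "box"
  build_plot(plot_spec(kind, object$data,
                       title = sprintf("%s in %s (%s, p = %.3g)", object$query,
                                       object$cancer, object$grouping,
                                       object$test$p), ...))
}

#' @rdname roc_auc
#' @param object A result object.
#' @param ... Passed to [plot_spec()].
#' @method autoplot pc_roc
#' @export
autoplot.pc_roc <- function(object, ...) {
  build_plot(plot_spec("roc", tibble::as_tibble(unclass(object)),
                       title = sprintf("AUC = %.3f", attr(object, "auc")), ...))
}

#' @rdname survival_by_level
#' @param object A result object.
#' @param ... Passed to [plot_spec()].
#' @method autoplot km_split
#' @export
autoplot.km_split <- function(object, ...) {
  build_plot(plot_spec("km", object$curves,
                       title = sprintf("%s (%s), log-rank p = %.3g",
                                       object$gene, object$layer,
                                       object$test$p), ...))
}

#' @rdname gene_gene_correlation
#' @param object A result object.
#' @param ... Passed to [plot_spec()].
#' @method autoplot gene_scatter
#' @export
autoplot.gene_scatter <- function(object, ...) {
  d <- object$data
  attr(d, "fit") <- object$fit
  attr(d, "density") <- object$density
  build_plot(plot_spec("scatter", d,
                       title = sprintf("%s vs %s: r = %.3f, p = %.3g",
                                       object$xlab, object$ylab,
                                       object$test$effect, object$test$p), ...))
}

#' @rdname term_network
#' @param object A result object.
#' @param seed Layout seed.
#' @param ... Passed to [plot_spec()].
#' @method autoplot term_network
#' @export
autoplot.term_network <- function(object, seed = 1L, ...) {
  if (nrow(object$edges) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty network"))
  }
  build_plot(plot_spec("network", object$edges, ...), seed = seed)
}
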