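# broom-style tidy()/glance() methods for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname cox_fit
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy pc_cox
#' @export
tidy.pc_cox <- function(x, ...) {
  co <- attr(x, "coef"); se <- attr(x, "se")
  tibble::tibble(
    term = names(co), estimate = unname(co), std.error = unname(se),
    statistic = unname(co / se),
    p.value = 2 * stats::pnorm(abs(co / se), lower.tail = FALSE)
  )
}

#' @rdname cox_fit
#' @method glance pc_cox
#' @export
glance.pc_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, logLik = attr(x, "loglik"),
                 converged = x$converged)
}

#' @rdname km_estimate
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy pc_km
#' @export
tidy.pc_km <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname roc_auc
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy pc_roc
#' @export
tidy.pc_roc <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname roc_auc
#' @method glance pc_roc
#' @export
glance.pc_roc <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_pos = attr(x, "n_pos"),
                 n_neg = attr(x, "n_neg"))
}

#' @rdname grouped_expression
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy grouped_expression
#' @export
tidy.grouped_expression <- function(x, ...) {
  x$data |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     median = stats::median(.data$score),
                     sd = stats::sd(.data$score), .groups = "drop")
}

#' @rdname grouped_expression
#' @method glance grouped_expression
#' @export
glance.grouped_expression <- function(x, ...) {
  dplyr::mutate(x$test, grouping = x$grouping, n_dropped = x$n_dropped)
}

#' @rdname survival_by_level
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy km_split
#' @export
tidy.km_split <- function(x, ...) x$curves

#' @rdname survival_by_level
#' @method glance km_split
#' @export
glance.km_split <- function(x, ...) x$test

#' @rdname term_network
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy term_network
#' @export
tidy.term_network <- function(x, ...) x$edges

#' @rdname term_network
#' @method glance term_network
#' @export
glance.term_network <- function(x, ...) {
  tibble::tibble(n_genes = sum(x$nodes$type == "gene"),
                 n_terms = sum(x$nodes$type == "term"),
                 n_edges = nrow(x$edges), q_threshold = x$q_threshold)
}
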