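#' Broom-style tidiers for mitoscreen result objects
#'
#' `tidy()` returns the per-unit table (per gene, per term, per edge) as a
#' plain tibble; `glance()` returns a one-row summary.
#'
#' @param x A result object (`mi_screen`, `hit_table`, `enrich_result`,
#'   `qc_report` or `typed_graph`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @export
tidy.mi_screen <- function(x, ...) {
  tibble::as_tibble(unclass_keep_cols(x))
}

#' @rdname tidiers
#' @export
glance.mi_screen <- function(x, ...) {
  fc <- attr(x, "filter_counts")
  ok <- is.finite(x$log2_mi)
  tibble::tibble(
    n_genes = nrow(x),
    n_genes_defined = sum(ok),
    n_removed_low_dapi = unname(fc["low_dapi"]),
    n_removed_inconsistent = unname(fc["inconsistent"]),
    median_mi = stats::median(x$mi[ok]),
    median_log2_mi = stats::median(x$log2_mi[ok]),
    mad_log2_mi = stats::mad(x$log2_mi[ok],
                             constant = attr(x, "params")$mad_constant %||% 1.4826)
  )
}

#' @rdname tidiers
#' @export
tidy.hit_table <- function(x, ...) {
  tibble::as_tibble(unclass_keep_cols(x))
}

#' @rdname tidiers
#' @export
glance.hit_table <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble::tibble(
    n_genes = nrow(x),
    n_hits = sum(x$call == "hit"),
    n_low = sum(x$group == "low"),
    n_high = sum(x$group == "high"),
    median_log2_mi = attr(x, "median"),
    mad_log2_mi = attr(x, "mad"),
    k = attr(x, "k"),
    lower_threshold = unname(thr["lower"]),
    upper_threshold = unname(thr["upper"])
  )
}

#' @rdname tidiers
#' @export
tidy.enrich_result <- function(x, ...) {
  tibble::as_tibble(unclass_keep_cols(x))
}

#' @rdname tidiers
#' @export
glance.enrich_result <- function(x, ...) {
  tibble::tibble(
    n_terms_tested = nrow(x),
    n_significant = sum(x$adjusted_p < 0.05),
    min_adjusted_p = if (nrow(x) > 0) min(x$adjusted_p) else NA_real_
  )
}

#' @rdname tidiers
#' @export
tidy.typed_graph <- function(x, ...) as_edge_tibble(x)

#' @rdname tidiers
#' @export
glance.typed_graph <- function(x, ...) {
  s <- degree_stats(x, fit_gamma = FALSE)$summary
  s$n_unmapped_hits <- length(unmapped_hits(x))
  s
}

unclass_keep_cols <- function(x) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "records") <- NULL
  attr(out, "filter_counts") <- NULL
  attr(out, "params") <- NULL
  out
}

#' Plot the hit-calling landscape of a screen
#'
#' Ranked per-gene log2 mitotic index with the screen median and the
#' median +/- k*MAD selection thresholds; hits are colored by group
#' (low MI / high MI).
#'
#' @param object A `hit_table` from [call_hits()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hit_table <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$log2_mi), ]
  df$rank <- rank(df$log2_mi, ties.method = "first")
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$log2_mi,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "median"), linetype = 1) +
    ggplot2::geom_hline(yintercept = unname(thr), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(low = "#d7301f", high = "#0570b0", none = "grey60")
    ) +
    ggplot2::labs(x = "gene rank", y = "log2 mitotic index", colour = "hit group",
                  title = "Hit calling: median ± k·MAD on log2 MI") +
    ggplot2::theme_minimal()
}

#' Plot top enriched terms
#'
#' @param object An `enrich_result`.
#' @param n_terms Terms to show (by p-value), default 15.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrich_result <- function(object, n_terms = 15, ...) {
  df <- utils::head(tidy(object), n_terms)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no terms tested"))
  }
  df$term <- stats::reorder(paste0(df$term_id, ": ", df$term_name),
                            -log10(df$adjusted_p))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$adjusted_p), y = .data$term)) +
    ggplot2::geom_col(fill = "#0570b0") +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL, title = "Term enrichment") +
    ggplot2::theme_minimal()
}

#' Degree distribution of a typed graph on log-log axes
#'
#' @param graph A `typed_graph`.
#' @return A ggplot object with the fitted power-law exponent in the
#'   subtitle (when fittable).
#' @export
plot_degree_distribution <- function(graph) {
  stats <- degree_stats(graph)
  hist <- stats$histogram
  hist <- hist[hist$degree > 0, ]
  gamma <- stats$summary$power_law_gamma
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$degree, y = .data$n_nodes)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree k", y = "number of nodes",
      title = "Degree distribution",
      subtitle = if (is.finite(gamma)) {
        sprintf("power-law fit: gamma = %.2f", gamma)
      } else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-plate control separation
#'
#' @param object A `qc_report` from [qc_controls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qc_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("pos_median_z", "neg_median_z"),
                            names_to = "control", values_to = "median_z")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$plate_id, y = .data$median_z,
                                   colour = .data$control, group = .data$control)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "plate", y = "median control z-score",
                  title = "Plate QC: positive vs negative controls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
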