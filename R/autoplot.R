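#' Plot methods for hetexpr result objects
#'
#' `autoplot()` methods give each result type its conventional display:
#' a volcano plot for DEG results, a class bar chart for pattern calls, a
#' gene-level allelic-ratio histogram with the calling band for ASE
#' results, a rich-factor dot plot for enrichment results, and
#' per-environment over-standard heterosis bars for trait tables.
#'
#' @param object A hetexpr result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name hetexpr-autoplot
NULL

#' @rdname hetexpr-autoplot
#' @method autoplot deg_results
#' @export
autoplot.deg_results <- function(object, ...) {
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$log2fc, y = -log10(pmax(.data$q, 1e-300)),
                 colour = .data$call)
  ) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#D55E00", down = "#0072B2", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 fold change (test / reference)",
                  y = "-log10 q", colour = NULL)
}

#' @rdname hetexpr-autoplot
#' @method autoplot pattern_calls
#' @export
autoplot.pattern_calls <- function(object, ...) {
  s <- pattern_summary(object)
  s$class <- factor(s$class, levels = rev(pattern_classes))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n, y = .data$class)) +
    ggplot2::geom_col(fill = "#317EC2") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.2f%%)", .data$n,
                                                    .data$pct)),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, .2))) +
    ggplot2::labs(x = "genes", y = NULL)
}

#' @rdname hetexpr-autoplot
#' @method autoplot ase_calls
#' @export
autoplot.ase_calls <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$gene_p, fill = .data$is_ase)) +
    ggplot2::geom_histogram(binwidth = 0.02, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(attr(object, "p_lo"),
                                       attr(object, "p_hi")),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "gene-level allelic ratio P (tester allele)",
                  y = "genes", fill = "ASE")
}

#' @rdname hetexpr-autoplot
#' @param top Number of top terms to display (default 20).
#' @method autoplot enrich_results
#' @export
autoplot.enrich_results <- function(object, top = 20, ...) {
  d <- utils::head(as_tibble(object), top)
  d$term_name <- factor(d$term_name, levels = rev(unique(d$term_name)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rich_factor, y = .data$term_name,
                                  size = .data$k, colour = .data$q)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#D7191C", high = "#2C7BB6") +
    ggplot2::labs(x = "rich factor (k / K)", y = NULL, size = "genes",
                  colour = "q")
}

#' @rdname hetexpr-autoplot
#' @method autoplot heterosis_tbl
#' @export
autoplot.heterosis_tbl <- function(object, ...) {
  d <- as_tibble(object)
  d$is_avg <- d$environment == "Average"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$environment,
                                  y = .data$over_standard_pct,
                                  fill = .data$is_avg)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00",
                                          `FALSE` = "#317EC2")) +
    ggplot2::labs(x = NULL, y = "over-standard heterosis (%)")
}
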