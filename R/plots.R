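#' Plot a neutral community model fit
#'
#' Occurrence frequency against log10 mean relative abundance, with the
#' fitted neutral curve and its Wilson band; OTUs are coloured by whether
#' they fall above, within or below the band.
#'
#' @param object An `ncm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ncm_fit <- function(object, ...) {
  tab <- tidy(object)
  curve <- tibble::tibble(
    p = 10^seq(log10(min(tab$p)), log10(max(tab$p)), length.out = 200)
  )
  curve$predicted <- ncm_predict(curve$p, object$N, object$m)
  band <- wilson_interval(curve$predicted, object$n_samples,
                          object$confidence)
  curve$ci_lower <- band$lower
  curve$ci_upper <- band$upper
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_ribbon(data = curve,
                         ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$freq, colour = .data$band),
                        size = 1, alpha = 0.7) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$predicted),
                       linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(above = "#2166ac", within = "grey40", below = "#b2182b")
    ) +
    ggplot2::labs(
      x = "Mean relative abundance (log scale)",
      y = "Occurrence frequency",
      colour = "Wilson band",
      title = sprintf("Neutral fit: m = %.3g, R² = %.3f",
                      object$m, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of assembly process fractions
#'
#' @param partitions A partitions tibble (from [aggregate_partition()] with
#'   `group`/`category` columns, or `tidy(analysis, "partitions")`).
#' @return A ggplot of process fractions per group, faceted by category when
#'   present.
#' @export
plot_partition <- function(partitions) {
  long <- tidyr::pivot_longer(partitions,
                              cols = dplyr::any_of(process_levels()),
                              names_to = "process", values_to = "fraction")
  long$process <- factor(long$process, levels = rev(process_levels()))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$group, y = .data$fraction,
                                    fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               na.value = "grey90") +
    ggplot2::labs(x = NULL, y = "Fraction of pairwise comparisons",
                  fill = "Assembly process") +
    ggplot2::theme_minimal()
  if ("category" %in% names(partitions)) {
    p <- p + ggplot2::facet_wrap(~category)
  }
  p
}

#' @rdname plot_partition
#' @param object An `assembly_analysis`.
#' @param ... Unused.
#' @export
autoplot.assembly_analysis <- function(object, ...) {
  plot_partition(tidy(object, "partitions"))
}
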