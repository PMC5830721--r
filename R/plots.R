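hist_long <- function(hl) {
  dplyr::bind_rows(
    dplyr::mutate(hl$reference, cohort = "reference"),
    dplyr::mutate(hl$labile, cohort = "labile"))
}

#' Plot a strain-metric histogram pair
#'
#' Relative-frequency histograms of one strain metric for the reference and
#' labile cohorts, over the conventional display range (DSE 0-60 kJ/mol,
#' S-S distance 1.96-2.14 angstrom, average alpha angle 95-120 degrees).
#'
#' @param summary A `cohort_summary`.
#' @param metric One of `"dse"`, `"d"`, `"alpha"`.
#' @return A ggplot object.
#' @export
plot_strain_distribution <- function(summary, metric = c("dse", "d", "alpha")) {
  metric <- match.arg(metric)
  lab <- switch(metric,
                dse = "dihedral strain energy (kJ/mol)",
                d = "S-S distance (Å)",
                alpha = "average α angle (°)")
  df <- hist_long(summary$histograms[[metric]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$rel_freq,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = lab, y = "relative frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the configuration distribution of both cohorts
#'
#' @param summary A `cohort_summary`.
#' @return A ggplot object with one bar per configuration class and cohort.
#' @export
plot_configuration_distribution <- function(summary) {
  tab <- summary$config_table
  df <- tibble::tibble(
    config = rep(colnames(tab), each = 2),
    cohort = rep(rownames(tab), times = ncol(tab)),
    freq = as.vector(tab) / rep(rowSums(tab), times = ncol(tab)))
  df$config <- factor(df$config, levels = configuration_names())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$config, y = .data$freq,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "relative frequency", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Heatmap of secondary structures linked by disulfide bonds
#'
#' @param summary A `cohort_summary`.
#' @return A ggplot tile plot of relative pair frequencies per cohort.
#' @export
plot_ss_heatmap <- function(summary) {
  tab <- summary$ss_table
  df <- tibble::tibble(
    pair = rep(colnames(tab), each = 2),
    cohort = rep(rownames(tab), times = ncol(tab)),
    freq = as.vector(tab) / rep(rowSums(tab), times = ncol(tab)))
  df <- tidyr::separate(df, "pair", into = c("ss1", "ss2"), sep = "-")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ss1, y = .data$ss2,
                                   fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "rel. freq.") +
    ggplot2::theme_minimal()
}

#' Autoplot a cohort summary
#'
#' @param object A `cohort_summary`.
#' @param which Which panel: a strain metric histogram, the configuration
#'   bars or the secondary-structure heatmap.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object,
                                    which = c("dse", "d", "alpha", "config", "ss"),
                                    ...) {
  which <- match.arg(which)
  switch(which,
         config = plot_configuration_distribution(object),
         ss = plot_ss_heatmap(object),
         plot_strain_distribution(object, which))
}
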