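#' Manhattan plot of a pedigree scan
#'
#' Plots each mutation's best -log10 raw p-value against its cumulative
#' genomic position, faceted by pedigree, with horizontal reference lines
#' at p = 0.05 with (red) and without (pink) the Bonferroni correction.
#'
#' @param manhattan Output of [manhattan_table()].
#' @param n_tests Bonferroni family size used for the corrected threshold;
#'   defaults to 3 models x the number of mutations per pedigree in the
#'   table.
#' @param alpha Significance level for the threshold lines.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(manhattan, n_tests = NULL, alpha = 0.05) {
  if (is.null(n_tests)) {
    n_tests <- 3 * max(table(manhattan$pedigree_id))
  }
  ggplot2::ggplot(manhattan,
                  ggplot2::aes(x = .data$genome_pos / 1e6,
                               y = .data$neg_log10_p,
                               colour = .data$chrom)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "pink") +
    ggplot2::geom_hline(yintercept = -log10(alpha / n_tests),
                        colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pedigree_id)) +
    ggplot2::labs(x = "cumulative genome position (Mb)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' Genotype-stratified Kaplan-Meier plot for one mutation
#'
#' Onset-free survival curves for the REF/HET/VAR classes at a mutation,
#' annotated with the logrank p-value comparing carriers-or-mutants
#' against reference mice.
#'
#' @param screen An `amm_screen` object.
#' @param mutation_id Mutation to stratify by.
#' @return A ggplot object.
#' @export
plot_km_genotype <- function(screen, mutation_id) {
  check_screen_tables(screen)
  if (!mutation_id %in% screen$mutations$id) {
    stop_bad_arg("unknown mutation id.")
  }
  frame <- scan_frame(screen)
  frame$call <- frame[[mutation_id]]
  frame <- filter(frame, !is.na(.data$call))
  curves <- frame %>%
    group_by(.data$call) %>%
    dplyr::group_modify(~ {
      km <- km_estimate(.x)
      bind_rows(tibble(time = 0, n_risk = nrow(.x), n_event = 0L,
                       n_censor = 0L, survival = 1), km)
    }) %>%
    ungroup()
  ref <- filter(frame, .data$call == "REF")
  alt <- filter(frame, .data$call != "REF")
  p_lab <- if (nrow(ref) && nrow(alt)) {
    sprintf("logrank p = %.3g", logrank_test(ref, alt)$p)
  } else ""
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$call)) +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0, y = 0.05, hjust = 0, label = p_lab) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "age (weeks)", y = "onset-free fraction",
                  colour = "genotype", title = mutation_id) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.amm_report <- function(object, ...) {
  plot_manhattan(object$manhattan)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
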