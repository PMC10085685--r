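#' Per-plant recombination dot plot
#'
#' One dot per plant (cM with its Wald interval), grouped by genotype, with a
#' horizontal bar at each genotype's mean — the standard presentation of FTL
#' results. Requires ggplot2.
#'
#' @param results Per-plant results data frame from
#'   [estimate_recombination_table()].
#' @return A ggplot object.
#' @export
plot_recombination <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    ftl_stop("plot_recombination requires the ggplot2 package", "ftl_domain_error")
  }
  means <- stats::aggregate(cM ~ genotype, data = results, FUN = mean)
  ggplot2::ggplot(results, ggplot2::aes(x = genotype, y = cM)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_crossbar(data = means,
                           ggplot2::aes(y = cM, ymin = cM, ymax = cM),
                           width = 0.4, colour = "red", linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "genetic distance (cM)") +
    ggplot2::theme_classic()
}

utils::globalVariables(c("genotype", "cM", "ci_low", "ci_high"))
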