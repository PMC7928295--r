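#' Plot a segregation table
#'
#' Stacked proportion bars of the three segregation categories per stratum
#' (unclassifiable embryos, which carry no percentage, are dropped).
#'
#' @param object A `rob_seg_table` from [tabulate_segregation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rob_seg_table
#' @export
autoplot.rob_seg_table <- function(object, ...) {
  data <- dplyr::filter(tibble::as_tibble(object),
                        .data$segregation != "unclassifiable")
  strata <- setdiff(names(data), c("segregation", "n", "total", "percent"))
  data$stratum <- if (length(strata) == 0) "all" else
    do.call(paste, c(data[strata], sep = " / "))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$stratum, y = .data$n,
                                     fill = .data$segregation)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of classifiable embryos",
                  fill = "segregation",
                  title = "Trivalent segregation products") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rob_seg_table
#' @param table A `rob_seg_table`.
#' @export
plot_segregation <- function(table, ...) autoplot.rob_seg_table(table, ...)

#' Plot a chromosome abnormality spectrum
#'
#' Per-chromosome proportions of aneuploid and mosaic abnormalities across a
#' cohort, chromosomes ordered 1-22, X, Y.
#'
#' @param object A `rob_spectrum` from [chromosome_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rob_spectrum
#' @export
autoplot.rob_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$chromosome, y = .data$proportion,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "chromosome", y = "proportion of embryos",
                  fill = "abnormality",
                  title = "Chromosome abnormality spectrum") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rob_spectrum
#' @param spectrum A `rob_spectrum`.
#' @export
plot_chromosome_spectrum <- function(spectrum, ...) {
  autoplot.rob_spectrum(spectrum, ...)
}
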