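#' Plot methods for npxflow results
#'
#' `autoplot()` methods give each result type its standard display:
#' inter- vs intra-individual CV scatter for variance profiles, a volcano
#' plot for association results, correlation histograms for concordance
#' reports, 2-D scatter for embeddings, and per-subject fasting-glucose
#' trajectories coloured by response group via [plot_fpg_response()].
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.variance_profile <- function(object, ...) {
  lim <- max(c(object$inter_cv, object$intra_cv), na.rm = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$intra_cv, y = .data$inter_cv)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::coord_equal(xlim = c(0, lim), ylim = c(0, lim)) +
    ggplot2::labs(x = "intra-individual CV (across visits)",
                  y = "inter-individual CV (across subjects)") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.assoc_result <- function(object, ...) {
  hit_col <- if ("de" %in% names(object)) "de" else "significant"
  x_col <- if ("log2_fc" %in% names(object) && !all(is.na(object$log2_fc))) {
    "log2_fc"
  } else "coefficient"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[x_col]],
                               y = -log10(.data$adjusted_p),
                               colour = .data[[hit_col]])) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "hit") +
    ggplot2::labs(x = if (x_col == "log2_fc") "log2 fold change" else "coefficient",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.concordance_report <- function(object, ...) {
  ggplot2::ggplot(object$by_protein, ggplot2::aes(x = .data$pearson)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$summary$r_cut, linetype = "dashed") +
    ggplot2::labs(x = "per-protein Pearson r between platforms", y = "proteins") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param visits Visit-level tibble with `subject_id`, `visit`, `fpg`.
#' @param groups A `response_groups` tibble from [stratify_response()].
#' @export
plot_fpg_response <- function(visits, groups) {
  dat <- dplyr::inner_join(visits, groups, by = "subject_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$visit, y = .data$fpg,
                                    group = .data$subject_id,
                                    colour = .data$response_group)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(responder = "forestgreen",
                                            indeterminate = "purple",
                                            `non-responder` = "darkorange"),
                                 na.value = "grey70") +
    ggplot2::labs(x = "visit", y = "fasting plasma glucose (mmol/L)",
                  colour = "response") +
    ggplot2::theme_minimal()
}
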