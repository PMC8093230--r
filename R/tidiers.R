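#' Broom-style tidiers for npxflow result objects
#'
#' `tidy()` returns the per-unit (protein, variant, sample) result rows as
#' a plain tibble; `glance()` returns a one-row summary of the whole
#' analysis.
#'
#' @param x A result object (`pqtl_result`, `assoc_result`,
#'   `variance_profile`, `concordance_report`, `response_groups`).
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.pqtl_result <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @rdname tidiers
#' @export
glance.pqtl_result <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_proteins = dplyr::n_distinct(x$protein_id),
    n_variants = dplyr::n_distinct(x$variant_id),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_cis = sum(x$significant & x$label == "cis", na.rm = TRUE),
    n_trans = sum(x$significant & x$label == "trans", na.rm = TRUE),
    threshold = attr(x, "threshold")
  )
}

#' @rdname tidiers
#' @export
tidy.assoc_result <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @rdname tidiers
#' @export
glance.assoc_result <- function(x, ...) {
  hit_col <- if ("de" %in% names(x)) "de" else "significant"
  tibble::tibble(
    method = x$method[1],
    n_proteins = dplyr::n_distinct(x$protein_id),
    n_hits = sum(x[[hit_col]], na.rm = TRUE),
    min_adjusted_p = min(x$adjusted_p, na.rm = TRUE)
  )
}

#' @rdname tidiers
#' @export
tidy.variance_profile <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @rdname tidiers
#' @export
glance.variance_profile <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    median_inter_cv = stats::median(x$inter_cv, na.rm = TRUE),
    median_intra_cv = stats::median(x$intra_cv, na.rm = TRUE),
    frac_inter_gt_intra = mean(x$inter_gt_intra, na.rm = TRUE),
    scale = attr(x, "scale") %||% "linear"
  )
}

#' @rdname tidiers
#' @export
tidy.concordance_report <- function(x, ...) x$by_protein

#' @rdname tidiers
#' @export
glance.concordance_report <- function(x, ...) x$summary

#' @rdname tidiers
#' @export
tidy.response_groups <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' @rdname tidiers
#' @export
glance.response_groups <- function(x, ...) {
  tibble::tibble(
    n_classified = sum(!is.na(x$response_group)),
    n_responder = sum(x$response_group == "responder", na.rm = TRUE),
    n_indeterminate = sum(x$response_group == "indeterminate", na.rm = TRUE),
    n_non_responder = sum(x$response_group == "non-responder", na.rm = TRUE)
  )
}

unclass_result <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attributes(x)[setdiff(names(attributes(x)),
                        c("names", "row.names", "class"))] <- NULL
  x
}
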