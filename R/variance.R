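#' Coefficient of variation
#'
#' Sample SD divided by mean, for ratio-scale (positive, linear) values.
#' Undefined (returned as `NA`) when fewer than 2 values are present or
#' the mean is not positive.
#'
#' @param values Numeric vector on a linear scale.
#' @return CV as a fraction, or `NA_real_`.
#' @export
#' @examples
#' cv(c(2, 8))  # 4.2426 / 5
cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  stats::sd(values) / m
}

#' Inter- and intra-individual variation per protein
#'
#' Decomposes longitudinal variation: the inter-individual CV is the mean
#' over visits of the CV across individuals within that visit; the
#' intra-individual CV is the mean over individuals of the CV across that
#' individual's visits. NPX values are linearized (\eqn{2^{NPX}}) before
#' computing CVs, since CV is only meaningful on a ratio scale; set
#' `scale = "npx"` to compute directly on log2 values for comparability
#' with conventions that do so. Only QC-pass samples enter; individuals
#' with fewer than 2 visits are skipped for the intra component and visits
#' with fewer than 2 individuals for the inter component, with counts
#' recorded.
#'
#' @param npx Long NPX tibble with `subject_id`, `visit`, `protein_id`,
#'   `npx` (and optionally `qc_flag`).
#' @param scale `"linear"` (default) or `"npx"`.
#' @return Tibble of class `variance_profile`: `protein_id`, `inter_cv`,
#'   `intra_cv`, `inter_gt_intra`, `n_individuals`, `n_visits`.
#' @export
inter_intra_cv <- function(npx, scale = c("linear", "npx")) {
  scale <- match.arg(scale)
  stopifnot(all(c("subject_id", "visit", "protein_id", "npx") %in% names(npx)))
  dat <- npx
  if ("qc_flag" %in% names(dat)) dat <- dplyr::filter(dat, .data$qc_flag == "pass")
  dat$value <- if (scale == "linear") 2^dat$npx else dat$npx

  inter <- dat |>
    dplyr::group_by(.data$protein_id, .data$visit) |>
    dplyr::summarise(cv_visit = cv(.data$value),
                     n_ind = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_ind >= 2) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(inter_cv = mean(.data$cv_visit, na.rm = TRUE),
                     n_visits = dplyr::n(), .groups = "drop")
  intra <- dat |>
    dplyr::group_by(.data$protein_id, .data$subject_id) |>
    dplyr::summarise(cv_subj = cv(.data$value),
                     n_vis = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_vis >= 2) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(intra_cv = mean(.data$cv_subj, na.rm = TRUE),
                     n_individuals = dplyr::n(), .groups = "drop")

  out <- dplyr::full_join(inter, intra, by = "protein_id") |>
    dplyr::mutate(inter_gt_intra = .data$inter_cv > .data$intra_cv) |>
    dplyr::select("protein_id", "inter_cv", "intra_cv", "inter_gt_intra",
                  "n_individuals", "n_visits")
  class(out) <- c("variance_profile", class(out))
  attr(out, "scale") <- scale
  out
}
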