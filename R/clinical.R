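#' HOMA-IR insulin-resistance index
#'
#' Homeostatic model assessment of insulin resistance:
#' fasting insulin (mU/L) x fasting glucose (mmol/L) / 22.5.
#'
#' @param insulin Fasting insulin in mU/L (>= 0).
#' @param glucose Fasting glucose in mmol/L (>= 0).
#' @return Numeric index.
#' @export
#' @examples
#' homa_ir(45, 11.25)  # 22.5
homa_ir <- function(insulin, glucose) {
  if (any(insulin < 0, na.rm = TRUE) || any(glucose < 0, na.rm = TRUE)) {
    stop("Insulin and glucose must be non-negative.", call. = FALSE)
  }
  insulin * glucose / 22.5
}

#' Body mass index
#'
#' Weight (kg) divided by the square of height (m).
#'
#' @param weight Weight in kilograms.
#' @param height Height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(81, 1.80)  # 25
bmi <- function(weight, height) {
  if (any(height <= 0, na.rm = TRUE)) stop("Height must be positive.", call. = FALSE)
  weight / height^2
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of p-values (monotone, capped
#' at 1); a thin wrapper over [stats::p.adjust()] with `method = "BH"` so
#' the package's multiple-testing policy has a single named entry point.
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values in the same order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Stratify subjects into obesity groups by baseline BMI
#'
#' Subjects with baseline (first-visit) BMI strictly above `cutoff` form
#' the obesity group; a BMI exactly at the cutoff is non-obesity (the
#' boundary is assigned to the lower group by policy).
#'
#' @param visits Visit-level tibble with `subject_id`, `visit`, `bmi`.
#' @param cutoff BMI cutoff in kg/m^2.
#' @return Tibble with `subject_id`, `baseline_bmi`, `bmi_group`.
#' @export
stratify_bmi <- function(visits, cutoff = 30) {
  stopifnot(all(c("subject_id", "visit", "bmi") %in% names(visits)))
  visits |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_min(.data$visit, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      baseline_bmi = .data$bmi,
      bmi_group = ifelse(.data$bmi > cutoff, "obesity", "non-obesity")
    )
}

#' Stratify treated subjects by fasting-glucose response
#'
#' The treatment response is the decrease in fasting plasma glucose from
#' the baseline visit to the final visit,
#' `fpg_decrease = FPG(baseline) - FPG(final)`. Decreases above 1 mmol/L
#' are responders, below 0.1 mmol/L non-responders, and anything between
#' 0.1 and 1 (both boundaries inclusive) indeterminate. An instability
#' override assigns indeterminate regardless of the net decrease when two
#' successive per-visit changes have opposite signs and both exceed
#' `instability` in magnitude (a glucose trajectory that swings down then
#' up — or vice versa — is not a stable response).
#'
#' @param visits Visit-level tibble with `subject_id`, `visit`, `fpg` and
#'   optionally `treatment` (when present, only rows with
#'   `treatment == treated` are classified).
#' @param baseline_visit,final_visit Visit indices defining the endpoint.
#' @param responder_cut,nonresponder_cut FPG-decrease cuts in mmol/L.
#' @param instability Magnitude (mmol/L) both opposite-sign successive
#'   changes must exceed to trigger the override.
#' @param treated Treatment label selecting the classified subjects.
#' @return Tibble of class `response_groups` with `subject_id`,
#'   `fpg_decrease`, `unstable`, `response_group`
#'   (`responder`/`indeterminate`/`non-responder`, `NA` when an endpoint
#'   visit is missing).
#' @export
#' @examples
#' v <- tibble::tibble(subject_id = "a", visit = 1:3, fpg = c(9, 8.5, 7.8))
#' stratify_response(v)$response_group  # decrease 1.2: responder
stratify_response <- function(visits, baseline_visit = 1, final_visit = 3,
                              responder_cut = 1.0, nonresponder_cut = 0.1,
                              instability = 1.5, treated = "metformin") {
  stopifnot(all(c("subject_id", "visit", "fpg") %in% names(visits)))
  dat <- visits
  if ("treatment" %in% names(dat)) dat <- dplyr::filter(dat, .data$treatment == treated)
  dat <- dplyr::arrange(dat, .data$subject_id, .data$visit)

  dat |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      fpg_decrease = {
        b <- .data$fpg[.data$visit == baseline_visit]
        f <- .data$fpg[.data$visit == final_visit]
        if (length(b) == 1 && length(f) == 1) b - f else NA_real_
      },
      unstable = {
        d <- diff(.data$fpg[order(.data$visit)])
        any(utils::head(d, -1) * utils::tail(d, -1) < 0 &
              abs(utils::head(d, -1)) >= instability &
              abs(utils::tail(d, -1)) >= instability)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      response_group = dplyr::case_when(
        is.na(.data$fpg_decrease) ~ NA_character_,
        .data$unstable ~ "indeterminate",
        .data$fpg_decrease > responder_cut ~ "responder",
        .data$fpg_decrease < nonresponder_cut ~ "non-responder",
        TRUE ~ "indeterminate"
      )
    ) |>
    structure(class = c("response_groups", class(tibble::tibble())))
}
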