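#' Extension-control normalization (counts to extension-normalized log2)
#'
#' First step of NPX generation: each assay count is divided by its well's
#' extension-control count and log2-transformed,
#' \eqn{extnpx = \log_2(count / ext)}. Zero assay counts are replaced by a
#' pseudocount of 0.5 (recorded in the `pseudocount` attribute); wells
#' whose extension-control count is missing or zero cannot be normalized
#' and are excluded with a reason (attribute `excluded`).
#'
#' @param counts Long count tibble (as `assay_counts$counts`): one row per
#'   well x assay with `well_id` and `count`.
#' @param controls Control-count tibble with `well_id`, `control`, `count`;
#'   only `control == "extension"` is used here.
#' @param pseudocount Replacement for zero assay counts.
#' @return `counts` with an `extnpx` column added; excluded wells are
#'   dropped and listed in `attr(, "excluded")`.
#' @export
#' @examples
#' counts <- tibble::tibble(well_id = "w1", assay_id = "p1", count = 1024L)
#' ext <- tibble::tibble(well_id = "w1", control = "extension", count = 256L)
#' counts_to_extnpx(counts, ext)$extnpx  # log2(1024/256) = 2
counts_to_extnpx <- function(counts, controls, pseudocount = 0.5) {
  stopifnot(all(c("well_id", "count") %in% names(counts)))
  ext <- controls |>
    dplyr::filter(.data$control == "extension") |>
    dplyr::select("well_id", ext_count = "count")
  out <- dplyr::left_join(counts, ext, by = "well_id")
  bad <- is.na(out$ext_count) | out$ext_count <= 0
  excluded <- tibble::tibble(
    well_id = unique(out$well_id[bad]),
    reason = "missing or zero extension-control count"
  )
  if (nrow(excluded) > 0) {
    warning(sprintf("%d well(s) excluded: missing/zero extension control.",
                    nrow(excluded)), call. = FALSE)
  }
  out <- out[!bad, , drop = FALSE]
  out$extnpx <- log2(ifelse(out$count == 0, pseudocount, out$count) / out$ext_count)
  out$ext_count <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Sample QC flagging from the incubation control
#'
#' A sample flags (fails QC) when its incubation-control value deviates by
#' more than `threshold` (default 0.3 log2 units) from the median
#' incubation-control value of all study samples on its plate. The
#' incubation control is put on the NPX-like scale as its
#' extension-normalized log2 ratio, so the threshold is in log2 units.
#' Flagged samples are retained in all tables and marked, never removed.
#'
#' @param extnpx Extension-normalized table with `well_id`, `plate_id`,
#'   `well_type` (from [counts_to_extnpx()]).
#' @param controls Control-count tibble with `extension` and `incubation`
#'   rows per well.
#' @param threshold Flagging threshold in log2 units.
#' @return `extnpx` with `qc_flag` (`"pass"`/`"flagged"`) and `qc_reason`
#'   columns; per-well QC table in `attr(, "sample_qc")`.
#' @export
flag_samples <- function(extnpx, controls, threshold = 0.3) {
  inc <- controls |>
    tidyr::pivot_wider(id_cols = c("well_id", "plate_id", "well_type"),
                       names_from = "control", values_from = "count")
  if (!all(c("extension", "incubation") %in% names(inc))) {
    stop("Controls must include extension and incubation counts.", call. = FALSE)
  }
  inc$inc_value <- log2(pmax(inc$incubation, 0.5) / inc$extension)
  study <- inc$well_type %in% c("sample", "bridge")
  qc <- inc |>
    dplyr::filter(study) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::mutate(deviation = .data$inc_value - stats::median(.data$inc_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      qc_flag = ifelse(abs(.data$deviation) > threshold, "flagged", "pass"),
      qc_reason = ifelse(.data$qc_flag == "flagged",
                         sprintf("incubation control deviates %+.2f from plate median",
                                 .data$deviation),
                         NA_character_)
    ) |>
    dplyr::select("well_id", "inc_value", "deviation", "qc_flag", "qc_reason")

  out <- extnpx |>
    dplyr::left_join(dplyr::select(qc, "well_id", "qc_flag", "qc_reason"),
                     by = "well_id") |>
    dplyr::mutate(qc_flag = dplyr::coalesce(.data$qc_flag, "pass"))
  attr(out, "sample_qc") <- qc
  attr(out, "qc_threshold") <- threshold
  out
}

#' Plate-control level adjustment (extension-normalized values to NPX)
#'
#' Third step of NPX generation: per assay, each value is shifted by the
#' median extension-normalized value of its plate's plate-control (plasma
#' pool) wells, and re-anchored to the per-assay median of plate-control
#' values across all plates of the same batch, keeping a stable absolute
#' level:
#' \deqn{NPX_{sa} = extnpx_{sa} - \mathrm{med}_{plate(s)}(extnpx_{\cdot a})
#'   + anchor_{a,batch(s)}}
#' Anchoring within batch leaves genuine between-batch level differences in
#' place for [bridge_normalize()] to remove; with a single batch the anchor
#' is global. The adjustment is idempotent. A plate without plate-control
#' wells cannot be adjusted: its samples are flagged
#' (`qc_reason = "no plate controls"`), not silently shifted.
#'
#' @param extnpx Table from [counts_to_extnpx()] (optionally after
#'   [flag_samples()]), containing plate-control wells.
#' @return Same table with an `npx` column; plate-control medians per
#'   assay/plate in `attr(, "plate_medians")`.
#' @export
adjust_plate_control <- function(extnpx) {
  pc <- dplyr::filter(extnpx, .data$well_type == "plate_control")
  if (nrow(pc) == 0) stop("No plate-control wells present.", call. = FALSE)

  plate_med <- pc |>
    dplyr::group_by(.data$batch_id, .data$plate_id, .data$assay_id) |>
    dplyr::summarise(plate_median = stats::median(.data$extnpx), .groups = "drop")
  anchor <- plate_med |>
    dplyr::group_by(.data$batch_id, .data$assay_id) |>
    dplyr::summarise(anchor = stats::median(.data$plate_median), .groups = "drop")

  out <- extnpx |>
    dplyr::left_join(plate_med, by = c("batch_id", "plate_id", "assay_id")) |>
    dplyr::left_join(anchor, by = c("batch_id", "assay_id")) |>
    dplyr::mutate(npx = .data$extnpx - .data$plate_median + .data$anchor)

  no_pc <- is.na(out$plate_median)
  if (any(no_pc)) {
    warning("Plate(s) without plate controls: samples flagged, not adjusted.",
            call. = FALSE)
    out$npx[no_pc] <- out$extnpx[no_pc]
    if (!"qc_flag" %in% names(out)) out$qc_flag <- "pass"
    if (!"qc_reason" %in% names(out)) out$qc_reason <- NA_character_
    out$qc_flag[no_pc] <- "flagged"
    out$qc_reason[no_pc] <- "no plate controls"
  }
  out <- dplyr::select(out, -"plate_median", -"anchor")
  attr(out, "plate_medians") <- plate_med
  out
}

#' Limit of detection from negative controls
#'
#' Per assay and plate, LOD is the median NPX of the buffer-only negative-
#' control wells plus three times their sample SD; when the SD is zero
#' (degenerate replicates) a fixed offset of `fallback_offset` log2 units
#' is used instead. Values below LOD are annotated, never removed.
#'
#' @param npx Adjusted table from [adjust_plate_control()] including
#'   negative-control wells.
#' @param fallback_offset Offset added to the median when the negative-
#'   control SD is zero.
#' @return Tibble with `assay_id`, `plate_id`, `lod`, `n_negative`.
#' @export
compute_lod <- function(npx, fallback_offset = 0.2) {
  neg <- dplyr::filter(npx, .data$well_type == "negative_control")
  if (nrow(neg) == 0) stop("No negative-control wells present.", call. = FALSE)
  neg |>
    dplyr::group_by(.data$plate_id, .data$assay_id) |>
    dplyr::summarise(
      n_negative = dplyr::n(),
      med = stats::median(.data$npx),
      sd = stats::sd(.data$npx),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lod = ifelse(is.na(.data$sd) | .data$sd == 0,
                   .data$med + fallback_offset,
                   .data$med + 3 * .data$sd)
    ) |>
    dplyr::select("plate_id", "assay_id", "lod", "n_negative")
}

#' Counts to NPX: the full three-step normalization with QC
#'
#' Convenience wrapper running extension-control normalization,
#' incubation-control sample flagging, plate-control level adjustment and
#' LOD computation, and returning the study-sample NPX table in the
#' package's canonical long format.
#'
#' @param assay An `assay_counts` object (or a list with `counts` and
#'   `controls` tibbles).
#' @param qc_threshold Incubation-control flagging threshold (log2 units).
#' @param pseudocount Zero-count replacement.
#' @return Tibble of class `npx_tbl`: `sample_id`, `subject_id`,
#'   `protein_id`, `assay_id`, `panel`, `plate_id`, `batch_id`, `npx`,
#'   `lod`, `below_lod`, `qc_flag`, `provenance = "ngs"`. The full
#'   well-level table (controls included) is in `attr(, "wells")`, the LOD
#'   table in `attr(, "lod")`.
#' @export
counts_to_npx <- function(assay, qc_threshold = 0.3, pseudocount = 0.5) {
  extnpx <- counts_to_extnpx(assay$counts, assay$controls, pseudocount = pseudocount)
  extnpx <- flag_samples(extnpx, assay$controls, threshold = qc_threshold)
  adj <- adjust_plate_control(extnpx)
  lod <- compute_lod(adj)

  out <- adj |>
    dplyr::filter(.data$well_type %in% c("sample", "bridge")) |>
    dplyr::left_join(lod, by = c("plate_id", "assay_id")) |>
    dplyr::mutate(below_lod = .data$npx < .data$lod, provenance = "ngs") |>
    dplyr::select("sample_id", "subject_id", "protein_id", "assay_id", "panel",
                  "plate_id", "batch_id", "npx", "lod", "below_lod",
                  "qc_flag", "provenance")
  attr(out, "wells") <- adj
  attr(out, "lod") <- lod
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("npx_tbl", class(out))
  out
}
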