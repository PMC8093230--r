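#' Reference-sample (bridging) normalization between batches
#'
#' Adjusts batch B onto batch A's level using samples measured in both
#' batches: per assay, the median of the paired differences (B minus A)
#' over the bridging samples is subtracted from every batch-B value.
#'
#' @param batch_a,batch_b NPX tibbles (long format with `sample_id`,
#'   `assay_id`, `npx`) for the reference batch and the batch to adjust.
#' @param bridge_ids Sample ids measured in both batches; defaults to the
#'   intersection of the two tables' sample ids.
#' @param key Column identifying an assay (defaults to `"assay_id"`, falls
#'   back to `"protein_id"`).
#' @return `batch_b` with `npx` shifted; per-assay adjustments in
#'   `attr(, "adjustment")`.
#' @export
bridge_normalize <- function(batch_a, batch_b, bridge_ids = NULL, key = NULL) {
  key <- key %||% intersect(c("assay_id", "protein_id"), names(batch_b))[1]
  if (is.na(key)) stop("No assay_id/protein_id column found.", call. = FALSE)
  if (is.null(bridge_ids)) {
    bridge_ids <- intersect(unique(batch_a$sample_id), unique(batch_b$sample_id))
  }
  if (length(bridge_ids) < 2) {
    stop("Bridging requires at least 2 samples measured in both batches.",
         call. = FALSE)
  }
  pairs <- dplyr::inner_join(
    batch_a |>
      dplyr::filter(.data$sample_id %in% bridge_ids) |>
      dplyr::select(dplyr::all_of(c("sample_id", key)), npx_a = "npx"),
    batch_b |>
      dplyr::filter(.data$sample_id %in% bridge_ids) |>
      dplyr::select(dplyr::all_of(c("sample_id", key)), npx_b = "npx"),
    by = c("sample_id", key)
  )
  adj <- pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(shift = stats::median(.data$npx_b - .data$npx_a),
                     n_bridges = dplyr::n(), .groups = "drop")
  out <- batch_b |>
    dplyr::left_join(adj, by = key) |>
    dplyr::mutate(npx = .data$npx - dplyr::coalesce(.data$shift, 0)) |>
    dplyr::select(-"shift", -"n_bridges")
  attr(out, "adjustment") <- adj
  out
}

#' Bridge every batch of one NPX table onto a reference batch
#'
#' Splits a multi-batch NPX table by `batch_id`, bridges each non-reference
#' batch onto the reference with [bridge_normalize()], and drops the
#' duplicate bridge measurements (the re-run wells), keeping the reference
#' batch's copy.
#'
#' @param npx Long NPX tibble with `batch_id`.
#' @param reference Reference batch id (default: first sorted batch).
#' @return The bridged table (class preserved).
#' @export
bridge_batches <- function(npx, reference = NULL) {
  batches <- sort(unique(npx$batch_id))
  reference <- reference %||% batches[1]
  if (!reference %in% batches) stop("Unknown reference batch.", call. = FALSE)
  if (length(batches) == 1) return(npx)
  ref_tbl <- dplyr::filter(npx, .data$batch_id == reference)
  rest <- purrr::map(setdiff(batches, reference), function(b) {
    adj <- bridge_normalize(ref_tbl, dplyr::filter(npx, .data$batch_id == b))
    # bridge re-runs are kept once, in the reference batch
    dplyr::anti_join(adj,
                     dplyr::distinct(ref_tbl[, "sample_id"]),
                     by = "sample_id")
  })
  out <- dplyr::bind_rows(ref_tbl, !!!rest)
  class(out) <- class(npx)
  out
}

#' Cross-platform median normalization
#'
#' Puts two platforms' measurements of the same samples on a common level:
#' per protein, each platform's values are shifted by subtracting the
#' platform-specific median and adding the median of the pooled values
#' from both platforms. After adjustment the two platform medians are
#' equal for every protein; correlations are unchanged (affine shift).
#'
#' @param ngs,qpcr Long NPX tibbles sharing `sample_id` and `protein_id`.
#' @return List with adjusted `ngs` and `qpcr` tibbles.
#' @export
cross_platform_normalize <- function(ngs, qpcr) {
  shared <- intersect(unique(ngs$sample_id), unique(qpcr$sample_id))
  if (length(shared) == 0) stop("No shared samples between platforms.", call. = FALSE)
  n2 <- dplyr::filter(ngs, .data$sample_id %in% shared)
  q2 <- dplyr::filter(qpcr, .data$sample_id %in% shared)
  med_n <- n2 |> dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(med_platform = stats::median(.data$npx), .groups = "drop")
  med_q <- q2 |> dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(med_platform = stats::median(.data$npx), .groups = "drop")
  med_all <- dplyr::bind_rows(n2, q2) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(med_pooled = stats::median(.data$npx), .groups = "drop")
  fix <- function(tbl, med) {
    tbl |>
      dplyr::left_join(med, by = "protein_id") |>
      dplyr::left_join(med_all, by = "protein_id") |>
      dplyr::mutate(npx = .data$npx - .data$med_platform + .data$med_pooled) |>
      dplyr::select(-"med_platform", -"med_pooled")
  }
  list(ngs = fix(n2, med_n), qpcr = fix(q2, med_q))
}

#' Concordance between two platforms
#'
#' Computes per-protein Pearson and Spearman correlations across shared
#' QC-pass samples, per-sample Pearson correlations across shared
#' proteins, the medians of both distributions, and the fraction of
#' proteins with Pearson r above `r_cut`.
#'
#' @param a,b Long NPX tibbles with `sample_id`, `protein_id`, `npx` (and
#'   optionally `qc_flag`).
#' @param r_cut Headline cut for well-correlating assays.
#' @return List of class `concordance_report` with `by_protein`,
#'   `by_sample` and `summary`.
#' @export
platform_concordance <- function(a, b, r_cut = 0.7) {
  keep_pass <- function(x) {
    if ("qc_flag" %in% names(x)) dplyr::filter(x, .data$qc_flag == "pass") else x
  }
  pairs <- dplyr::inner_join(
    keep_pass(a) |> dplyr::select("sample_id", "protein_id", npx_a = "npx"),
    keep_pass(b) |> dplyr::select("sample_id", "protein_id", npx_b = "npx"),
    by = c("sample_id", "protein_id")
  )
  if (nrow(pairs) == 0) stop("No shared sample x protein measurements.", call. = FALSE)
  by_protein <- pairs |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      pearson = stats::cor(.data$npx_a, .data$npx_b),
      spearman = stats::cor(.data$npx_a, .data$npx_b, method = "spearman"),
      .groups = "drop"
    )
  by_sample <- pairs |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n = dplyr::n(),
                     pearson = stats::cor(.data$npx_a, .data$npx_b),
                     .groups = "drop")
  summary <- tibble::tibble(
    median_protein_pearson = stats::median(by_protein$pearson, na.rm = TRUE),
    median_protein_spearman = stats::median(by_protein$spearman, na.rm = TRUE),
    median_sample_pearson = stats::median(by_sample$pearson, na.rm = TRUE),
    frac_protein_r_above_cut = mean(by_protein$pearson > r_cut, na.rm = TRUE),
    r_cut = r_cut
  )
  structure(list(by_protein = by_protein, by_sample = by_sample,
                 summary = summary),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  s <- x$summary
  cat("<concordance_report>\n")
  cat(sprintf("  proteins: %d (median Pearson %.3f, %.0f%% with r > %.2f)\n",
              nrow(x$by_protein), s$median_protein_pearson,
              100 * s$frac_protein_r_above_cut, s$r_cut))
  cat(sprintf("  samples: %d (median Pearson %.3f)\n",
              nrow(x$by_sample), s$median_sample_pearson))
  invisible(x)
}

#' Assay precision from sample-control wells
#'
#' Estimates per-assay precision from the replicated reference-plasma
#' (sample control) wells. CVs are computed on linearized values
#' (\eqn{2^{NPX}}): the intra-plate CV is the CV across replicate wells
#' within a plate, averaged over plates; the inter-plate CV is the CV of
#' the plate-level means.
#'
#' @param wells Well-level adjusted table (e.g. `attr(counts_to_npx(x),
#'   "wells")`) containing `well_type == "sample_control"` rows with `npx`.
#' @return Tibble with `assay_id`, `intra_cv`, `inter_cv`, `n_plates`.
#' @export
assay_precision <- function(wells) {
  sc <- dplyr::filter(wells, .data$well_type == "sample_control")
  if (nrow(sc) == 0) stop("No sample-control wells present.", call. = FALSE)
  per_plate <- sc |>
    dplyr::mutate(lin = 2^.data$npx) |>
    dplyr::group_by(.data$assay_id, .data$plate_id) |>
    dplyr::summarise(cv_within = cv(.data$lin),
                     plate_mean = mean(.data$lin), .groups = "drop")
  per_plate |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(
      intra_cv = mean(.data$cv_within, na.rm = TRUE),
      inter_cv = cv(.data$plate_mean),
      n_plates = dplyr::n(),
      .groups = "drop"
    )
}
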