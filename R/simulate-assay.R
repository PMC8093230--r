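#' Simulate assay-level sequencing counts with internal controls
#'
#' Converts true log2 abundances into per-well matched sequencing counts.
#' For well \eqn{w} and assay \eqn{a} the count is drawn from a negative
#' binomial with mean \eqn{depth_w \cdot 2^{x + po_{plate(w)} + bo_{batch(w)}}}
#' and variance \eqn{\mu + \phi\mu^2}; \eqn{\phi = 0} gives Poisson counts.
#' The abundance \eqn{x} is the study sample's true value for sample and
#' bridge wells, a constant background for buffer-only negative-control
#' wells, a fixed plasma-pool vector shared by all plate-control wells, and
#' a fixed reference-plasma vector for sample-control wells.
#'
#' Each well also receives internal-control counts: an extension control
#' (always in proximity, tracking depth only — the basis of NPX
#' normalization), an incubation control (a non-human immuno-assay, which
#' like the protein assays picks up plate and batch offsets), and an
#' amplification control (monitored, no correction derived from it).
#'
#' @param truth A `sim_cohort` (or its `truth` list) carrying the true
#'   abundances.
#' @param design Panel design from [panel_design()].
#' @param layout Plate layout from [assign_plates()].
#' @param config The [sim_config()] used to generate `truth`.
#' @return List of class `assay_counts` with `counts` (one row per well x
#'   assay), `controls` (one row per well x control class), `depths`, and
#'   the drawn `plate_offsets` / `batch_offsets` (ground truth for recovery
#'   tests).
#' @export
simulate_assay <- function(truth, design, layout, config) {
  if (inherits(truth, "sim_cohort")) truth <- truth$truth
  ab <- truth$abundance
  needed <- unique(layout$sample_id[layout$well_type %in% c("sample", "bridge")])
  if (!all(needed %in% ab$sample_id)) {
    stop("Plate layout contains samples absent from the simulated truth.",
         call. = FALSE)
  }

  withr::with_seed(config$seed + 303L, {
    prots <- design$protein_id
    x_wide <- ab |>
      dplyr::select("sample_id", "protein_id", "log_abund") |>
      tidyr::pivot_wider(names_from = "protein_id", values_from = "log_abund")
    x_mat <- as.matrix(x_wide[, -1])
    rownames(x_mat) <- x_wide$sample_id
    if (!all(prots %in% colnames(x_mat))) {
      stop("Panel design references proteins absent from the truth.", call. = FALSE)
    }

    mu_p <- truth$mu$mu[match(colnames(x_mat), truth$mu$protein_id)]
    pool <- mu_p + stats::rnorm(length(mu_p), 0, config$sigma_between)
    ref <- mu_p + stats::rnorm(length(mu_p), 0, config$sigma_between)
    names(pool) <- names(ref) <- colnames(x_mat)

    plates <- unique(layout$plate_id)
    batches <- unique(layout$batch_id)
    plate_off <- stats::setNames(stats::rnorm(length(plates), 0, config$plate_offset_sd), plates)
    batch_off <- stats::setNames(stats::rnorm(length(batches), 0, config$batch_offset_sd), batches)

    wells <- layout
    wells$depth <- config$depth_mean * 2^stats::rnorm(nrow(wells), 0, config$depth_dispersion)

    # abundance matrix per well (wells x proteins)
    A <- matrix(NA_real_, nrow(wells), length(prots),
                dimnames = list(wells$well_id, design$assay_id))
    is_study <- wells$well_type %in% c("sample", "bridge")
    A[is_study, ] <- x_mat[wells$sample_id[is_study], prots, drop = FALSE]
    A[wells$well_type == "negative_control", ] <- config$background_log2
    A[wells$well_type == "plate_control", ] <-
      matrix(pool[prots], sum(wells$well_type == "plate_control"),
             length(prots), byrow = TRUE)
    A[wells$well_type == "sample_control", ] <-
      matrix(ref[prots], sum(wells$well_type == "sample_control"),
             length(prots), byrow = TRUE)

    tech <- plate_off[wells$plate_id] + batch_off[wells$batch_id]
    mean_mat <- wells$depth * 2^(A + tech)
    counts <- draw_counts(mean_mat, config$count_dispersion)

    counts_tbl <- tibble::as_tibble(counts, rownames = "well_id") |>
      tidyr::pivot_longer(-"well_id", names_to = "assay_id", values_to = "count") |>
      dplyr::left_join(design, by = "assay_id") |>
      dplyr::left_join(
        dplyr::select(wells, "well_id", "plate_id", "batch_id", "well_type",
                      "sample_id", "subject_id"),
        by = "well_id") |>
      dplyr::select("well_id", "sample_id", "subject_id", "plate_id", "batch_id",
                    "well_type", "assay_id", "protein_id", "panel", "count")

    ctrl_mean <- cbind(
      extension = wells$depth * 2^config$ext_control_log2,
      incubation = wells$depth * 2^(config$inc_control_log2 + tech),
      amplification = wells$depth * 2^config$amp_control_log2
    )
    rownames(ctrl_mean) <- wells$well_id
    ctrl_counts <- draw_counts(ctrl_mean, config$count_dispersion)
    controls_tbl <- tibble::as_tibble(ctrl_counts, rownames = "well_id") |>
      tidyr::pivot_longer(-"well_id", names_to = "control", values_to = "count") |>
      dplyr::left_join(
        dplyr::select(wells, "well_id", "plate_id", "batch_id", "well_type", "sample_id"),
        by = "well_id")

    structure(list(
      counts = counts_tbl,
      controls = controls_tbl,
      depths = dplyr::select(wells, "well_id", "depth"),
      plate_offsets = tibble::enframe(plate_off, name = "plate_id", value = "offset"),
      batch_offsets = tibble::enframe(batch_off, name = "batch_id", value = "offset"),
      pool_abundance = tibble::enframe(pool, name = "protein_id", value = "log_abund"),
      reference_abundance = tibble::enframe(ref, name = "protein_id", value = "log_abund")
    ), class = "assay_counts")
  })
}

draw_counts <- function(mean_mat, dispersion) {
  n <- length(mean_mat)
  out <- if (dispersion <= 0) {
    stats::rpois(n, lambda = mean_mat)
  } else {
    stats::rnbinom(n, mu = mean_mat, size = 1 / dispersion)
  }
  matrix(out, nrow(mean_mat), ncol(mean_mat), dimnames = dimnames(mean_mat))
}

#' @export
print.assay_counts <- function(x, ...) {
  cat(sprintf("<assay_counts> %d wells x %d assays (%d plates, %d batches)\n",
              dplyr::n_distinct(x$counts$well_id),
              dplyr::n_distinct(x$counts$assay_id),
              nrow(x$plate_offsets), nrow(x$batch_offsets)))
  invisible(x)
}

#' Simulate a paired second-platform (qPCR) readout
#'
#' Emits the same true abundances on an NPX-like log2 scale as measured by
#' a second platform: a fixed per-protein platform offset plus independent
#' measurement noise. Comparisons between platforms operate on NPX, so no
#' Ct-level mechanics are modelled.
#'
#' @param truth A `sim_cohort` (or its `truth` list).
#' @param config The matching [sim_config()].
#' @return Tibble with `sample_id`, `subject_id`, `visit`, `protein_id`,
#'   `npx`, `qc_flag`, `provenance = "qpcr"`.
#' @export
simulate_qpcr_readout <- function(truth, config) {
  if (inherits(truth, "sim_cohort")) truth <- truth$truth
  ab <- truth$abundance
  withr::with_seed(config$seed + 404L, {
    prots <- unique(ab$protein_id)
    offs <- stats::setNames(stats::rnorm(length(prots), 0, config$qpcr_offset_sd), prots)
    ab |>
      dplyr::mutate(
        npx = .data$log_abund + unname(offs[.data$protein_id]) +
          stats::rnorm(dplyr::n(), 0, config$qpcr_noise_sd),
        qc_flag = "pass",
        provenance = "qpcr"
      ) |>
      dplyr::select("sample_id", "subject_id", "visit", "protein_id",
                    "npx", "qc_flag", "provenance")
  })
}
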