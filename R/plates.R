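#' Panel design
#'
#' Splits the study proteins over multiplexed panels and, optionally, adds
#' three QC proteins (inflammation markers) that are measured once on every
#' panel so that inter-panel consistency can be monitored.
#'
#' @param config A [sim_config()].
#' @return Tibble with `assay_id`, `protein_id`, `panel`,
#'   `is_control_assay`.
#' @export
panel_design <- function(config) {
  validate_sim_config(config)
  prots <- protein_ids(config)
  design <- tibble::tibble(
    assay_id = prots,
    protein_id = prots,
    panel = rep(seq_len(config$n_panels), length.out = length(prots)),
    is_control_assay = FALSE
  )
  if (config$include_control_assays) {
    ctrl <- tidyr::expand_grid(protein_id = control_protein_ids(),
                               panel = seq_len(config$n_panels)) |>
      dplyr::mutate(assay_id = sprintf("%s_p%d", .data$protein_id, .data$panel),
                    is_control_assay = TRUE) |>
      dplyr::select("assay_id", "protein_id", "panel", "is_control_assay")
    design <- dplyr::bind_rows(design, ctrl)
  }
  per_panel <- dplyr::count(design, .data$panel)
  if (any(per_panel$n > config$n_assays_per_panel)) {
    stop("Panel plexity exceeded in design.", call. = FALSE)
  }
  dplyr::arrange(design, .data$panel, .data$assay_id)
}

#' Assign study samples to randomized plates with control wells
#'
#' Every plate reserves 8 wells for internal controls (3 negative, 3 plate,
#' 2 sample controls); the remaining wells hold study samples. Subjects are
#' shuffled and all visits of one subject are placed on the same plate
#' whenever capacity permits (a subject whose visit set does not fit on any
#' single plate is split with a warning, never dropped). Plates are divided
#' contiguously into `n_batches` batches, and `n_bridges` samples from the
#' first batch are re-run as bridging wells in every other batch.
#'
#' @param visits Tibble with at least `sample_id` and `subject_id` (as from
#'   [simulate_cohort()]'s `visits`).
#' @param plate_capacity Total wells per plate (> 8).
#' @param n_batches Number of batches.
#' @param n_bridges Bridging samples per non-reference batch.
#' @param seed Integer seed for the randomization.
#' @return Tibble of class `plate_layout`: one row per well with
#'   `plate_id`, `batch_id`, `well`, `well_type`
#'   (`sample`/`negative_control`/`plate_control`/`sample_control`/`bridge`),
#'   `sample_id`, `subject_id`.
#' @export
assign_plates <- function(visits, plate_capacity = 96, n_batches = 1,
                          n_bridges = 8, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for plate randomization.", call. = FALSE)
  }
  n_ctrl <- 8L
  cap <- plate_capacity - n_ctrl
  if (cap <= 0) {
    stop("plate_capacity leaves no sample wells after the 8 control wells.",
         call. = FALSE)
  }
  stopifnot(all(c("sample_id", "subject_id") %in% names(visits)))

  withr::with_seed(seed, {
    subjects <- split(visits$sample_id, visits$subject_id)
    subjects <- subjects[sample(names(subjects))]

    plates <- list()
    current <- character(0)
    flush <- function() {
      if (length(current) > 0) plates[[length(plates) + 1L]] <<- current
      current <<- character(0)
    }
    split_warned <- FALSE
    for (ids in subjects) {
      ids <- sample(ids)
      if (length(ids) > cap) {
        if (!split_warned) {
          warning("Some subjects have more visits than a plate can hold; ",
                  "their samples were split across plates.", call. = FALSE)
          split_warned <- TRUE
        }
        while (length(ids) > 0) {
          take <- min(cap - length(current), length(ids))
          current <- c(current, ids[seq_len(take)])
          ids <- ids[-seq_len(take)]
          if (length(current) == cap) flush()
        }
      } else {
        if (length(current) + length(ids) > cap) flush()
        current <- c(current, ids)
        if (length(current) == cap) flush()
      }
    }
    flush()

    n_plates <- length(plates)
    batch_of_plate <- sort(rep(seq_len(n_batches), length.out = n_plates))

    layout <- purrr::map2_dfr(plates, seq_along(plates), function(ids, p) {
      ctrl <- tibble::tibble(
        well_type = c(rep("negative_control", 3), rep("plate_control", 3),
                      rep("sample_control", 2)),
        sample_id = NA_character_
      )
      smp <- tibble::tibble(well_type = "sample", sample_id = ids)
      wells <- dplyr::bind_rows(smp, ctrl)
      wells <- wells[sample(nrow(wells)), ]
      wells$plate_id <- sprintf("plate_%02d", p)
      wells$batch_id <- sprintf("batch_%d", batch_of_plate[p])
      wells$well <- seq_len(nrow(wells))
      wells
    })

    # bridging: re-run samples from the reference batch in every other batch
    if (n_batches > 1 && n_bridges > 0) {
      ref_samples <- layout$sample_id[layout$batch_id == "batch_1" &
                                        layout$well_type == "sample"]
      bridges <- sample(ref_samples, min(n_bridges, length(ref_samples)))
      # scatter bridge wells round-robin over the batch's plates so that
      # plate-level correction errors average out of the bridge estimate
      extra <- purrr::map_dfr(setdiff(unique(layout$batch_id), "batch_1"), function(b) {
        plates_b <- unique(layout$plate_id[layout$batch_id == b])
        on_plate <- rep(plates_b, length.out = length(bridges))
        purrr::map2_dfr(bridges, on_plate, function(s, p) {
          tibble::tibble(well_type = "bridge", sample_id = s,
                         plate_id = p, batch_id = b,
                         well = max(layout$well[layout$plate_id == p]) +
                           sum(on_plate[seq_len(match(s, bridges))] == p))
        })
      })
      layout <- dplyr::bind_rows(layout, extra)
    }

    layout$well_id <- sprintf("%s_w%03d", layout$plate_id, layout$well)
    layout <- dplyr::left_join(
      layout,
      dplyr::distinct(dplyr::select(visits, "sample_id", "subject_id")),
      by = "sample_id"
    )
    out <- dplyr::select(layout, "well_id", "plate_id", "batch_id", "well",
                         "well_type", "sample_id", "subject_id")
    class(out) <- c("plate_layout", class(out))
    out
  })
}
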