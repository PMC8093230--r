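# Build count tables whose extension-normalized values are known exactly:
# every well gets extension count `ext`, and assay counts ext * 2^target.
# `tbl` is long with well_id, sample_id, plate_id, batch_id, well_type,
# assay_id, extnpx and optionally inc_value (incubation log2 ratio).
counts_from_extnpx <- function(tbl, ext = 1024) {
  stopifnot(all(c("well_id", "plate_id", "batch_id", "well_type",
                  "assay_id", "extnpx") %in% names(tbl)))
  if (!"sample_id" %in% names(tbl)) tbl$sample_id <- tbl$well_id
  if (!"inc_value" %in% names(tbl)) tbl$inc_value <- 0
  counts <- tbl |>
    dplyr::mutate(protein_id = .data$assay_id, panel = 1L,
                  count = ext * 2^.data$extnpx) |>
    dplyr::select("well_id", "sample_id", "plate_id", "batch_id",
                  "well_type", "assay_id", "protein_id", "panel", "count")
  wells <- dplyr::distinct(tbl, .data$well_id, .data$sample_id, .data$plate_id,
                           .data$batch_id, .data$well_type, .data$inc_value)
  controls <- dplyr::bind_rows(
    dplyr::transmute(wells, well_id = .data$well_id, sample_id = .data$sample_id,
                     plate_id = .data$plate_id, batch_id = .data$batch_id,
                     well_type = .data$well_type,
                     control = "extension", count = ext),
    dplyr::transmute(wells, well_id = .data$well_id, sample_id = .data$sample_id,
                     plate_id = .data$plate_id, batch_id = .data$batch_id,
                     well_type = .data$well_type,
                     control = "incubation", count = ext * 2^.data$inc_value),
    dplyr::transmute(wells, well_id = .data$well_id, sample_id = .data$sample_id,
                     plate_id = .data$plate_id, batch_id = .data$batch_id,
                     well_type = .data$well_type,
                     control = "amplification", count = ext)
  )
  structure(list(counts = counts, controls = controls), class = "assay_counts")
}

# one plate with given per-sample extnpx values for a single assay, plus
# plate controls at plate_ctrl and negative controls at neg
one_plate_tbl <- function(values, plate_id = "plate_01", batch_id = "batch_1",
                          plate_ctrl = 0, neg = -6, inc_values = NULL) {
  n <- length(values)
  smp <- tibble::tibble(
    well_id = sprintf("%s_s%02d", plate_id, seq_len(n)),
    sample_id = sprintf("smp%02d_%s", seq_len(n), plate_id),
    plate_id = plate_id, batch_id = batch_id,
    well_type = "sample", assay_id = "A1", extnpx = values,
    inc_value = if (is.null(inc_values)) 0 else inc_values
  )
  ctl <- tibble::tibble(
    well_id = sprintf("%s_c%d", plate_id, 1:6),
    sample_id = NA_character_,
    plate_id = plate_id, batch_id = batch_id,
    well_type = rep(c("plate_control", "negative_control"), each = 3),
    assay_id = "A1",
    extnpx = rep(c(plate_ctrl, neg), each = 3),
    inc_value = 0
  )
  dplyr::bind_rows(smp, ctl)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 10, n_proteins = 12, n_variants = 60,
         n_causal_cis = 2, n_causal_trans = 1,
         ld_block_size = 4, plate_capacity = 40, seed = 42),
    list(...)
  )
  do.call(sim_config, args)
}
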