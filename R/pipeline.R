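#' Simulate a complete study: cohort, genotypes, plates, counts, qPCR
#'
#' Runs the whole generator: cohort and genotypes, panel design, plate
#' randomization (with batches and bridging samples), the count-level
#' assay readout, and the paired second-platform readout.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study` with `cohort` (a `sim_cohort`),
#'   `design`, `layout`, `assay` (an `assay_counts`), `qpcr`, `config`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_subjects = 6, n_proteins = 8,
#'                                    plate_capacity = 32, seed = 1))
#' names(study)
simulate_study <- function(config) {
  validate_sim_config(config)
  cohort <- simulate_cohort(config)
  design <- panel_design(config)
  layout <- assign_plates(cohort$visits, plate_capacity = config$plate_capacity,
                          n_batches = config$n_batches,
                          n_bridges = config$n_bridges,
                          seed = config$seed + 505L)
  assay <- simulate_assay(cohort, design, layout, config)
  qpcr <- simulate_qpcr_readout(cohort, config)
  structure(list(cohort = cohort, design = design, layout = layout,
                 assay = assay, qpcr = qpcr, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d subjects, %d proteins, %d plates, %d batch(es)\n",
              nrow(x$cohort$subjects),
              dplyr::n_distinct(x$design$protein_id),
              dplyr::n_distinct(x$layout$plate_id),
              dplyr::n_distinct(x$layout$batch_id)))
  invisible(x)
}

#' Run the full analysis pipeline on a simulated study
#'
#' End-to-end composition: simulate, counts to NPX (normalization + QC +
#' LOD), bridge batches, variance decomposition, baseline pQTL scan with
#' sentinel/conditional reduction, sex differential expression, and
#' BMI/treatment-response stratification. Every stage writes its
#' tab-delimited table under `outdir` together with a provenance block
#' (config echo, seed, package version); re-running with the same config
#' reproduces the outputs.
#'
#' @param config A [sim_config()] (its `seed` drives every stage).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with every in-memory result and the paths
#'   written.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("npxflow pipeline, seed %d", config$seed))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  study <- simulate_study(config)
  write_counts(study$assay, file.path(outdir, "counts"))
  write_vcf(study$cohort$genotypes, file.path(outdir, "genotypes.vcf"))
  write_tss(study$cohort$genotypes$tss, file.path(outdir, "tss.tsv"))
  readr::write_tsv(study$cohort$visits, file.path(outdir, "cohort.tsv"), na = "NA")
  write_sim_truth(study$cohort, file.path(outdir, "sim_truth.json"))
  say("simulated %d subjects x %d visits, %d proteins",
      nrow(study$cohort$subjects), config$n_visits,
      dplyr::n_distinct(study$design$protein_id))

  npx <- counts_to_npx(study$assay)
  say("NPX: %d measurements, %d flagged wells (threshold 0.3 log2)",
      nrow(npx), sum(npx$qc_flag == "flagged"))
  if (config$n_batches > 1) {
    npx <- bridge_batches(npx)
    say("bridged %d batches onto batch_1", config$n_batches)
  }
  npx_out <- dplyr::left_join(
    npx,
    dplyr::select(study$cohort$visits, "sample_id", "visit", "sex", "age",
                  "cohort_label", "treatment"),
    by = "sample_id")
  write_npx_long(npx_out, file.path(outdir, "npx.tsv"))

  prof <- inter_intra_cv(npx_out)
  readr::write_tsv(prof, file.path(outdir, "variance_profile.tsv"), na = "NA")
  say("variance: inter > intra for %.1f%% of proteins",
      100 * mean(prof$inter_gt_intra, na.rm = TRUE))

  gqc <- genotype_qc(study$cohort$genotypes)
  covars <- dplyr::select(study$cohort$subjects, "subject_id", "age", "sex")
  basel <- baseline_phenotype(npx_out)
  scan <- pqtl_scan(basel, gqc, covars)
  sent <- select_independent(scan, basel, gqc, covars)
  readr::write_tsv(scan, file.path(outdir, "pqtl_scan.tsv"), na = "NA")
  readr::write_tsv(sent, file.path(outdir, "pqtl_independent.tsv"), na = "NA")
  say("pQTL: %d significant associations (threshold %.3g), %d independent",
      sum(scan$significant), attr(scan, "threshold"), nrow(sent))

  de <- anova_de(dplyr::filter(npx_out, .data$qc_flag == "pass"),
                 factor = "sex", covariates = c("age", "visit"))
  readr::write_tsv(de, file.path(outdir, "sex_de.tsv"), na = "NA")
  say("sex DE: %d proteins at FDR 0.05", sum(de$de))

  strat_bmi <- stratify_bmi(study$cohort$visits)
  readr::write_tsv(strat_bmi, file.path(outdir, "bmi_groups.tsv"), na = "NA")
  strat_resp <- stratify_response(study$cohort$visits,
                                  final_visit = config$n_visits)
  readr::write_tsv(strat_resp, file.path(outdir, "response_groups.tsv"), na = "NA")
  say("stratification: %d obesity, %d responders",
      sum(strat_bmi$bmi_group == "obesity"),
      sum(strat_resp$response_group == "responder", na.rm = TRUE))

  provenance <- list(
    package = "npxflow",
    version = as.character(utils::packageVersion("npxflow")),
    seed = config$seed,
    config = unclass(config),
    thresholds = list(qc_flag = 0.3, fdr = 0.05, lmm_alpha = 0.01,
                      maf = 0.05, hwe_p = 0.001, missingness = 0.05,
                      cis_window = 1e6, ld_r2 = 0.1, conditional_p = 0.01,
                      bmi_cutoff = 30, fpg_cuts = c(0.1, 1.0))
  )
  jsonlite::write_json(provenance, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(outdir, "pipeline.log"))

  invisible(list(study = study, npx = npx_out, variance = prof,
                 pqtl = scan, pqtl_independent = sent, sex_de = de,
                 bmi_groups = strat_bmi, response_groups = strat_resp,
                 outdir = outdir))
}
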