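#' Simulation configuration
#'
#' Builds and validates the configuration object that drives every part of
#' the synthetic-data generator: cohort design, genetics, true protein
#' abundances, and the assay (count) layer with its internal controls.
#'
#' All standard deviations are on the log2 (NPX-like) scale unless noted.
#' The defaults emulate a two-cohort longitudinal plasma-profiling study:
#' a healthy ("wellness") cohort sampled at three visits plus an optional
#' type-2-diabetes (T2D) cohort in which most patients receive metformin.
#'
#' @param n_subjects Number of wellness (healthy) subjects.
#' @param n_t2d Number of T2D subjects (0 disables the disease cohort).
#' @param n_visits Visits per subject.
#' @param n_proteins Number of study proteins (control-assay proteins are
#'   added on top when `include_control_assays` is `TRUE`).
#' @param n_panels Number of multiplexed panels the proteins are split over.
#' @param n_assays_per_panel Panel plexity cap (assays per panel including
#'   the replicated control assays).
#' @param include_control_assays Add three QC proteins replicated on every
#'   panel (inflammation markers measured once per panel).
#' @param sigma_between Between-subject SD of true log2 abundance.
#' @param sigma_within Within-subject (visit-to-visit) SD.
#' @param sex_effect_fraction,sex_effect_size Fraction of proteins carrying
#'   a sex effect and its size (log2 units, male minus female).
#' @param disease_effect_fraction,disease_effect_size Fraction/size of T2D
#'   effects (log2 units).
#' @param responder_effect_fraction,responder_effect_size Fraction/size of
#'   baseline protein differences between metformin responders and
#'   non-responders.
#' @param n_variants,maf_range,ld_block_size,ld_mutation_prob Genotype
#'   layer: number of biallelic variants, minor-allele-frequency range,
#'   variants per LD block, and the per-variant probability that a
#'   haplotype's allele deviates from its block founder.
#' @param n_chromosomes,variant_spacing Chromosomes used and base-pair
#'   spacing between consecutive variants.
#' @param n_causal_cis,n_causal_trans,genetic_beta Number of proteins with
#'   a cis (resp. trans) causal variant and the allelic effect
#'   (log2 units per alternate allele).
#' @param plate_offset_sd,batch_offset_sd SDs of the technical offsets
#'   shared by all immuno-assays on a plate (resp. in a batch).
#' @param depth_mean,depth_dispersion Per-well sequencing depth scale and
#'   its log2 SD across wells.
#' @param count_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param background_log2 Log2 abundance read in buffer-only (negative
#'   control) wells.
#' @param ext_control_log2,inc_control_log2,amp_control_log2 Log2 spike
#'   levels of the extension, incubation and amplification controls
#'   relative to unit abundance.
#' @param qpcr_offset_sd,qpcr_noise_sd Per-protein platform offset SD and
#'   measurement noise SD of the paired second-platform (qPCR) readout.
#' @param plate_capacity Wells per plate (8 are reserved for controls:
#'   3 negative, 3 plate, 2 sample controls).
#' @param n_batches Number of batches the plates are split into.
#' @param n_bridges Bridging samples re-run in every non-reference batch.
#' @param metformin_fraction Fraction of T2D subjects on metformin.
#' @param mu_range Range of per-protein baseline log2 abundance.
#' @param seed Integer seed; required — every generator draws from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 8, n_proteins = 10, seed = 1)
#' cfg$n_visits
sim_config <- function(n_subjects = 76,
                       n_t2d = 0,
                       n_visits = 3,
                       n_proteins = 100,
                       n_panels = 2,
                       n_assays_per_panel = 384,
                       include_control_assays = TRUE,
                       sigma_between = 0.5,
                       sigma_within = 0.125,
                       sex_effect_fraction = 0.1,
                       sex_effect_size = 1.0,
                       disease_effect_fraction = 0.1,
                       disease_effect_size = 1.0,
                       responder_effect_fraction = 0.1,
                       responder_effect_size = 1.0,
                       n_variants = 400,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 8,
                       ld_mutation_prob = 0.05,
                       n_chromosomes = 4,
                       variant_spacing = 20000,
                       n_causal_cis = 5,
                       n_causal_trans = 2,
                       genetic_beta = 1.0,
                       plate_offset_sd = 0.5,
                       batch_offset_sd = 0.4,
                       depth_mean = 100,
                       depth_dispersion = 0.3,
                       count_dispersion = 0.001,
                       background_log2 = 0,
                       ext_control_log2 = 6,
                       inc_control_log2 = 4,
                       amp_control_log2 = 5,
                       qpcr_offset_sd = 1.0,
                       qpcr_noise_sd = 0.15,
                       plate_capacity = 96,
                       n_batches = 1,
                       n_bridges = 8,
                       metformin_fraction = 0.8,
                       mu_range = c(3, 7),
                       seed = NULL) {
  if (is.null(seed)) {
    stop("`seed` is required: simulations must be reproducible.", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos_int <- function(x) length(x) == 1 && is.finite(x) && x == as.integer(x) && x > 0
  if (!pos_int(cfg$n_subjects)) stop("n_subjects must be a positive integer.", call. = FALSE)
  if (!(length(cfg$n_t2d) == 1 && cfg$n_t2d >= 0)) stop("n_t2d must be >= 0.", call. = FALSE)
  if (!pos_int(cfg$n_visits)) stop("n_visits must be >= 1.", call. = FALSE)
  if (!pos_int(cfg$n_proteins)) stop("n_proteins must be a positive integer.", call. = FALSE)
  sds <- c("sigma_between", "sigma_within", "plate_offset_sd", "batch_offset_sd",
           "depth_dispersion", "count_dispersion", "qpcr_offset_sd", "qpcr_noise_sd")
  for (s in sds) {
    if (cfg[[s]] < 0) stop(sprintf("%s must be >= 0.", s), call. = FALSE)
  }
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must lie within (0, 0.5].", call. = FALSE)
  }
  if (cfg$n_variants < cfg$n_causal_cis + cfg$n_causal_trans) {
    stop("n_variants must be at least the number of causal variants.", call. = FALSE)
  }
  if (cfg$n_proteins < cfg$n_causal_cis + cfg$n_causal_trans) {
    stop("n_proteins must be at least the number of causal proteins.", call. = FALSE)
  }
  n_per_panel <- ceiling(cfg$n_proteins / cfg$n_panels) +
    if (cfg$include_control_assays) 3L else 0L
  if (n_per_panel > cfg$n_assays_per_panel) {
    stop("Panel plexity exceeded: reduce n_proteins or increase n_panels/n_assays_per_panel.",
         call. = FALSE)
  }
  if (cfg$plate_capacity <= 8) {
    stop("plate_capacity must exceed the 8 control wells per plate.", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d wellness + %d T2D subjects, %d visits\n",
              x$n_subjects, x$n_t2d, x$n_visits))
  cat(sprintf("  proteins: %d over %d panels; variants: %d (blocks of %d)\n",
              x$n_proteins, x$n_panels, x$n_variants, x$ld_block_size))
  cat(sprintf("  variance: between %.3g / within %.3g (log2 SD)\n",
              x$sigma_between, x$sigma_within))
  cat(sprintf("  plates: capacity %d, %d batch(es); seed %d\n",
              x$plate_capacity, x$n_batches, x$seed))
  invisible(x)
}

protein_ids <- function(cfg) {
  sprintf("prot_%04d", seq_len(cfg$n_proteins))
}

control_protein_ids <- function() c("ctrl_IL6", "ctrl_CXCL8", "ctrl_TNF")
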