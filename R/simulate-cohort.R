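#' Simulate a longitudinal two-cohort study with ground truth
#'
#' Generates subjects (sex, age, cohort, treatment), their visit-level
#' clinical chemistry (fasting plasma glucose, insulin, BMI) and the true
#' log2 protein abundances underlying the assay layer:
#'
#' \deqn{x_{ivp} = \mu_p + s_p 1[\mathrm{male}_i] + \sum_k \beta_{pk} g_{ik}
#'   + d_p 1[\mathrm{T2D}_i] + r_p 1[\mathrm{responder}_i] + b_{ip} + e_{ivp}}
#'
#' with subject-level deviations \eqn{b \sim N(0, \sigma^2_{between})} and
#' visit-level deviations \eqn{e \sim N(0, \sigma^2_{within})}. Metformin-
#' treated T2D subjects are split into responder / indeterminate /
#' non-responder classes whose fasting-glucose trajectories decline by
#' more than 1, between 0.1 and 1, or less than 0.1 mmol/L respectively.
#'
#' @param config A [sim_config()]; `seed` is mandatory.
#' @param genotypes Optional [geno_matrix()]; generated from `config` when
#'   missing so that genetic effects can enter the abundances.
#' @return A list of class `sim_cohort` with elements `subjects`, `visits`
#'   (one row per subject x visit, `sample_id` included), `genotypes`, and
#'   `truth` (abundance table plus every effect map drawn).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 6, n_proteins = 5, seed = 1))
#' dplyr::count(sim$visits, visit)
simulate_cohort <- function(config, genotypes = NULL) {
  validate_sim_config(config)
  if (is.null(genotypes)) genotypes <- simulate_genotypes(config)

  n_well <- config$n_subjects
  n_t2d <- config$n_t2d
  n_sub <- n_well + n_t2d
  subject_id <- rownames(genotypes$geno)
  if (length(subject_id) != n_sub) {
    stop("Genotype matrix does not match the configured number of subjects.",
         call. = FALSE)
  }

  withr::with_seed(config$seed + 202L, {
    subjects <- tibble::tibble(
      subject_id = subject_id,
      sex = sample(c("male", "female"), n_sub, replace = TRUE),
      age = sample(50:65, n_sub, replace = TRUE),
      cohort_label = rep(c("wellness", "T2D"), c(n_well, n_t2d))
    )
    subjects$treatment <- ifelse(
      subjects$cohort_label == "T2D",
      ifelse(stats::runif(n_sub) < config$metformin_fraction, "metformin", "other"),
      "none"
    )
    subjects$response_class <- NA_character_
    on_met <- subjects$treatment == "metformin"
    subjects$response_class[on_met] <- sample(
      c("responder", "indeterminate", "non-responder"),
      sum(on_met), replace = TRUE, prob = c(0.35, 0.3, 0.35)
    )

    visits <- tidyr::expand_grid(subject_id = subject_id,
                                 visit = seq_len(config$n_visits)) |>
      dplyr::left_join(subjects, by = "subject_id") |>
      dplyr::mutate(
        sample_id = sprintf("%s_v%d", .data$subject_id, .data$visit),
        date_offset = (.data$visit - 1L) * 90L
      )
    visits <- clinical_trajectories(visits, config)

    prots <- protein_ids(config)
    all_prots <- c(prots, if (config$include_control_assays) control_protein_ids())
    P <- length(all_prots)

    mu <- stats::runif(P, config$mu_range[1], config$mu_range[2])
    pick <- function(fraction, size) {
      eff <- numeric(length(prots))
      n_eff <- round(fraction * length(prots))
      if (n_eff > 0) {
        idx <- sample(seq_along(prots), n_eff)
        eff[idx] <- size * sample(c(-1, 1), n_eff, replace = TRUE)
      }
      eff
    }
    sex_eff <- c(pick(config$sex_effect_fraction, config$sex_effect_size),
                 numeric(P - length(prots)))
    dis_eff <- c(pick(config$disease_effect_fraction, config$disease_effect_size),
                 numeric(P - length(prots)))
    resp_eff <- c(pick(config$responder_effect_fraction, config$responder_effect_size),
                  numeric(P - length(prots)))

    # subject-level fixed part
    fixed <- matrix(rep(mu, each = n_sub), n_sub, P)
    fixed <- fixed + outer(subjects$sex == "male", sex_eff)
    fixed <- fixed + outer(subjects$cohort_label == "T2D", dis_eff)
    is_resp <- !is.na(subjects$response_class) & subjects$response_class == "responder"
    is_ind <- !is.na(subjects$response_class) & subjects$response_class == "indeterminate"
    fixed <- fixed + outer(is_resp, resp_eff) + outer(is_ind, resp_eff / 2)
    if (!is.null(genotypes$causal) && nrow(genotypes$causal) > 0) {
      for (k in seq_len(nrow(genotypes$causal))) {
        p_idx <- match(genotypes$causal$protein_id[k], all_prots)
        g <- genotypes$geno[, genotypes$causal$variant_id[k]]
        fixed[, p_idx] <- fixed[, p_idx] + genotypes$causal$beta[k] * g
      }
    }
    b <- matrix(stats::rnorm(n_sub * P, 0, config$sigma_between), n_sub, P)

    nv <- config$n_visits
    x <- (fixed + b)[rep(seq_len(n_sub), each = nv), , drop = FALSE] +
      matrix(stats::rnorm(n_sub * nv * P, 0, config$sigma_within), n_sub * nv, P)
    dimnames(x) <- list(sprintf("%s_v%d", rep(subject_id, each = nv), rep(seq_len(nv), n_sub)),
                        all_prots)

    abundance <- tibble::as_tibble(x, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "protein_id",
                          values_to = "log_abund") |>
      dplyr::left_join(dplyr::select(visits, "sample_id", "subject_id", "visit"),
                       by = "sample_id") |>
      dplyr::select("subject_id", "visit", "sample_id", "protein_id", "log_abund")

    truth <- list(
      abundance = abundance,
      mu = tibble::tibble(protein_id = all_prots, mu = mu),
      sex_effect_map = tibble::tibble(protein_id = all_prots, effect = sex_eff),
      disease_effect_map = tibble::tibble(protein_id = all_prots, effect = dis_eff),
      responder_effect_map = tibble::tibble(protein_id = all_prots, effect = resp_eff),
      causal_map = genotypes$causal,
      responder_labels = dplyr::select(subjects, "subject_id", "treatment", "response_class"),
      sigma_between = config$sigma_between,
      sigma_within = config$sigma_within
    )

    structure(list(subjects = subjects, visits = visits,
                   genotypes = genotypes, truth = truth, config = config),
              class = "sim_cohort")
  })
}

# visit-level clinical values; FPG trajectories encode the response classes
clinical_trajectories <- function(visits, config) {
  n <- nrow(visits)
  is_t2d <- visits$cohort_label == "T2D"
  base_fpg <- ifelse(is_t2d, pmax(stats::rnorm(n, 9, 1.5), 6.5),
                     pmax(stats::rnorm(n, 5.5, 0.4), 4))
  base_ins <- ifelse(is_t2d, pmax(stats::rnorm(n, 15, 5), 2),
                     pmax(stats::rnorm(n, 8, 2), 1))
  base_bmi <- ifelse(is_t2d, pmax(stats::rnorm(n, 30, 4), 18),
                     pmax(stats::rnorm(n, 25.5, 3), 16))
  # per-subject baselines: keep the visit-1 draw for all visits
  u <- !duplicated(visits$subject_id)
  per_subject <- function(val) val[u][match(visits$subject_id, visits$subject_id[u])]
  base_fpg <- per_subject(base_fpg)
  base_ins <- per_subject(base_ins)
  base_bmi <- per_subject(base_bmi)

  cls <- visits$response_class
  dd <- numeric(sum(u))
  cls_u <- cls[u]
  dd[!is.na(cls_u) & cls_u == "responder"] <-
    stats::runif(sum(!is.na(cls_u) & cls_u == "responder"), 1.15, 3)
  dd[!is.na(cls_u) & cls_u == "indeterminate"] <-
    stats::runif(sum(!is.na(cls_u) & cls_u == "indeterminate"), 0.2, 0.9)
  dd[!is.na(cls_u) & cls_u == "non-responder"] <-
    stats::runif(sum(!is.na(cls_u) & cls_u == "non-responder"), -0.3, 0.05)
  drop_by_subject <- dd[match(visits$subject_id, visits$subject_id[u])]
  drop_by_subject[is.na(cls)] <- 0

  nv <- max(visits$visit)
  frac <- if (nv > 1) (visits$visit - 1) / (nv - 1) else rep(0, n)
  fpg <- base_fpg - drop_by_subject * frac +
    ifelse(visits$visit > 1 & visits$cohort_label == "wellness",
           stats::rnorm(n, 0, 0.15), 0)
  visits$fpg <- round(pmax(fpg, 3), 2)
  visits$insulin <- round(pmax(base_ins + ifelse(visits$visit > 1, stats::rnorm(n, 0, 0.5), 0), 0.5), 2)
  visits$bmi <- round(pmax(base_bmi + ifelse(visits$visit > 1, stats::rnorm(n, 0, 0.3), 0), 15), 1)
  visits
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects (%d T2D), %d visits, %d proteins\n",
              nrow(x$subjects), sum(x$subjects$cohort_label == "T2D"),
              x$config$n_visits, dplyr::n_distinct(x$truth$abundance$protein_id)))
  invisible(x)
}
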