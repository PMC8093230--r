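test_that("extension normalization computes log2 ratios with pseudocount and exclusions", {
  tbl <- tibble::tibble(
    well_id = c("w1", "w2", "w3", "w4"),
    count = c(1024, 256, 0, 100),
    assay_id = "A1"
  )
  ctrl <- tibble::tibble(
    well_id = c("w1", "w2", "w3", "w4"),
    control = "extension",
    count = c(256, 256, 256, 0)
  )
  expect_warning(out <- counts_to_extnpx(tbl, ctrl), "excluded")
  expect_equal(out$extnpx[out$well_id == "w1"], 2)          # log2(1024/256)
  expect_equal(out$extnpx[out$well_id == "w2"], 0)          # count == ext
  expect_equal(out$extnpx[out$well_id == "w3"], log2(0.5 / 256))
  expect_false("w4" %in% out$well_id)                       # zero ext excluded
  expect_equal(attr(out, "excluded")$well_id, "w4")

  # depth invariance: doubling both count and ext leaves extnpx unchanged
  # (up to pseudocount effects at zero counts, which scale with ext)
  ctrl2 <- dplyr::mutate(ctrl, count = count * 2)
  tbl2 <- dplyr::mutate(tbl, count = count * 2)
  expect_warning(out2 <- counts_to_extnpx(tbl2, ctrl2))
  nz <- out$count > 0
  expect_equal(out2$extnpx[nz], out$extnpx[nz])
})

test_that("plate-control adjustment equalizes injected plate offsets and is idempotent", {
  # two plates with offsets +0.8 / -0.8 applied to all wells, noiseless
  base <- c(1, 2, 3, 4)
  tbl <- dplyr::bind_rows(
    one_plate_tbl(base + 0.8, plate_id = "plate_01", plate_ctrl = 0 + 0.8),
    one_plate_tbl(base - 0.8, plate_id = "plate_02", plate_ctrl = 0 - 0.8)
  )
  assay <- counts_from_extnpx(tbl)
  ext <- counts_to_extnpx(assay$counts, assay$controls)
  adj <- adjust_plate_control(ext)
  pc_med <- adj |>
    dplyr::filter(well_type == "plate_control") |>
    dplyr::group_by(plate_id) |>
    dplyr::summarise(m = stats::median(npx), .groups = "drop")
  expect_equal(pc_med$m[1], pc_med$m[2])
  # samples recover their plate-free values up to the common anchor
  smp <- dplyr::filter(adj, well_type == "sample")
  expect_equal(sort(smp$npx[smp$plate_id == "plate_01"]),
               sort(smp$npx[smp$plate_id == "plate_02"]))

  # idempotence: adjusting the adjusted values changes nothing
  again <- adj |> dplyr::mutate(extnpx = npx) |> adjust_plate_control()
  expect_equal(again$npx, adj$npx)

  # single plate: a per-assay constant shift, ranks unchanged
  one <- counts_from_extnpx(one_plate_tbl(c(5, 1, 3), plate_ctrl = 2))
  e1 <- counts_to_extnpx(one$counts, one$controls)
  a1 <- adjust_plate_control(e1)
  s1 <- dplyr::filter(a1, well_type == "sample")
  expect_equal(length(unique(s1$npx - s1$extnpx)), 1)
  expect_equal(order(s1$npx), order(s1$extnpx))
})

test_that("plate/batch offset recovery on a simulated multi-plate run", {
  cfg <- sim_config(n_subjects = 40, n_proteins = 30, n_visits = 3,
                    plate_capacity = 48, plate_offset_sd = 0.5,
                    seed = 31)
  study <- simulate_study(cfg)
  extnpx <- counts_to_extnpx(study$assay$counts, study$assay$controls)
  adj <- adjust_plate_control(extnpx)
  truth <- study$cohort$truth$abundance
  est <- adj |>
    dplyr::filter(well_type == "sample") |>
    dplyr::inner_join(truth, by = c("sample_id", "protein_id")) |>
    dplyr::group_by(plate_id) |>
    dplyr::summarise(resid = stats::median(npx - log_abund), .groups = "drop")
  # before adjustment the per-plate residuals track the injected offsets;
  # after adjustment they are flat (injected offsets explain nothing)
  inj <- study$assay$plate_offsets
  j <- dplyr::inner_join(est, inj, by = "plate_id")
  expect_gt(dplyr::n_distinct(j$plate_id), 2)
  expect_lt(stats::sd(j$resid), 0.1 * stats::sd(j$offset))

  raw <- extnpx |>
    dplyr::filter(well_type == "sample") |>
    dplyr::inner_join(truth, by = c("sample_id", "protein_id")) |>
    dplyr::group_by(plate_id) |>
    dplyr::summarise(resid = stats::median(extnpx - log_abund), .groups = "drop") |>
    dplyr::inner_join(inj, by = "plate_id")
  expect_gt(stats::cor(raw$resid, raw$offset), 0.95)
})

test_that("incubation-control QC flags exactly the deviating samples", {
  # one plate, 10 samples, one incubation outlier at +1.0
  inc <- c(rep(0, 9), 1.0)
  tbl <- one_plate_tbl(rep(1, 10), inc_values = inc)
  assay <- counts_from_extnpx(tbl)
  ext <- counts_to_extnpx(assay$counts, assay$controls)
  fl <- flag_samples(ext, assay$controls)
  qc <- attr(fl, "sample_qc")
  expect_equal(sum(qc$qc_flag == "flagged"), 1)
  expect_equal(qc$well_id[qc$qc_flag == "flagged"], tbl$well_id[10])

  # all identical incubation values: none flagged
  fl0 <- flag_samples(ext, counts_from_extnpx(one_plate_tbl(rep(1, 10)))$controls)
  expect_true(all(attr(fl0, "sample_qc")$qc_flag == "pass"))

  # monotonicity: raising the threshold never flags more samples
  devs <- seq(-0.6, 0.6, length.out = 9)
  tbl2 <- one_plate_tbl(rep(1, 9), inc_values = devs)
  a2 <- counts_from_extnpx(tbl2)
  e2 <- counts_to_extnpx(a2$counts, a2$controls)
  n_flagged <- vapply(c(0.1, 0.3, 0.5, 0.8), function(th) {
    sum(attr(flag_samples(e2, a2$controls, threshold = th), "sample_qc")$qc_flag
        == "flagged")
  }, numeric(1))
  expect_true(all(diff(n_flagged) <= 0))
})

test_that("LOD follows median + 3 SD with the zero-SD fallback", {
  mk <- function(neg_values) {
    tbl <- one_plate_tbl(c(5, 6), plate_ctrl = 0)
    tbl$extnpx[tbl$well_type == "negative_control"] <- neg_values
    a <- counts_from_extnpx(tbl)
    adj <- adjust_plate_control(counts_to_extnpx(a$counts, a$controls))
    compute_lod(adj)
  }
  # identical negatives: fallback offset 0.2 above the median
  lod1 <- mk(c(1, 1, 1))
  # plate-control median is 0 and the anchor restores it, so NPX == extnpx
  expect_equal(lod1$lod, 1.2)
  # negatives {0, 1, 2}: median 1, sample SD 1, LOD 4
  lod2 <- mk(c(0, 1, 2))
  expect_equal(lod2$lod, 4)

  # on simulated data, signal sits far above background: below-LOD rare
  study <- simulate_study(small_config(n_subjects = 20, n_proteins = 20, seed = 33))
  npx <- counts_to_npx(study$assay)
  expect_lt(mean(npx$below_lod), 0.01)
})

test_that("bridging removes batch offsets and is transitive on clean data", {
  mk_batch <- function(shift, batch, samples) {
    tibble::tibble(sample_id = rep(samples, each = 3),
                   assay_id = rep(c("A1", "A2", "A3"), length(samples)),
                   batch_id = batch,
                   npx = rep(c(1, 2, 3), length(samples)) + shift)
  }
  s <- sprintf("s%02d", 1:8)
  a <- mk_batch(0, "batch_1", s)
  b <- mk_batch(0.5, "batch_2", s)
  adj <- bridge_normalize(a, b)
  expect_equal(adj$npx, a$npx)

  # zero offset: adjustment ~ 0
  b0 <- mk_batch(0, "batch_2", s)
  adj0 <- bridge_normalize(a, b0)
  expect_equal(attr(adj0, "adjustment")$shift, rep(0, 3))

  expect_error(bridge_normalize(a, dplyr::filter(b, sample_id == "s01")),
               "at least 2")

  # transitivity: C -> B -> A agrees with C -> A on noiseless data
  cc <- mk_batch(-0.7, "batch_3", s)
  via_b <- bridge_normalize(a, bridge_normalize(b, cc))
  direct <- bridge_normalize(a, cc)
  per_assay <- dplyr::inner_join(via_b, direct, by = c("sample_id", "assay_id")) |>
    dplyr::group_by(assay_id) |>
    dplyr::summarise(d = stats::median(abs(npx.x - npx.y)), .groups = "drop")
  expect_true(all(per_assay$d < 0.05))
})

test_that("batch-offset recovery with bridging on a simulated two-batch run", {
  cfg <- sim_config(n_subjects = 60, n_proteins = 40, n_visits = 3,
                    plate_capacity = 68, n_batches = 2, n_bridges = 8,
                    batch_offset_sd = 0.4, seed = 35)
  study <- simulate_study(cfg)
  npx <- bridge_batches(counts_to_npx(study$assay))
  truth <- study$cohort$truth$abundance
  resid <- npx |>
    dplyr::inner_join(truth, by = c("sample_id", "protein_id")) |>
    dplyr::group_by(assay_id, batch_id) |>
    dplyr::summarise(m = stats::median(npx - log_abund), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "batch_id", values_from = "m") |>
    dplyr::mutate(gap = abs(batch_2 - batch_1))
  expect_gte(mean(resid$gap < 0.1), 0.95)
})

test_that("cross-platform normalization equalizes medians without touching correlation", {
  set.seed(1)
  samples <- sprintf("s%02d", 1:21)
  ngs <- tidyr::expand_grid(sample_id = samples, protein_id = c("p1", "p2")) |>
    dplyr::mutate(npx = stats::rnorm(dplyr::n(), 5, 1))
  qpcr <- ngs |> dplyr::mutate(npx = npx * 0.9 + stats::rnorm(dplyr::n(), -2, 0.3))
  adj <- cross_platform_normalize(ngs, qpcr)
  med_n <- adj$ngs |> dplyr::group_by(protein_id) |>
    dplyr::summarise(m = stats::median(npx), .groups = "drop")
  med_q <- adj$qpcr |> dplyr::group_by(protein_id) |>
    dplyr::summarise(m = stats::median(npx), .groups = "drop")
  expect_equal(med_n$m, med_q$m)
  r_before <- platform_concordance(ngs, qpcr)$by_protein$pearson
  r_after <- platform_concordance(adj$ngs, adj$qpcr)$by_protein$pearson
  expect_equal(r_after, r_before)

  # hand arithmetic: medians 5 vs 3, pooled 4 -> shifts -1 and +1
  n1 <- tibble::tibble(sample_id = sprintf("x%d", 1:3), protein_id = "p",
                       npx = c(4, 5, 6))
  q1 <- tibble::tibble(sample_id = sprintf("x%d", 1:3), protein_id = "p",
                       npx = c(2, 3, 4))
  adj1 <- cross_platform_normalize(n1, q1)
  expect_equal(adj1$ngs$npx, c(3, 4, 5))
  expect_equal(adj1$qpcr$npx, c(3, 4, 5))
})

test_that("platform concordance: identity, null, and attenuation behaviour", {
  cfg <- sim_config(n_subjects = 124, n_proteins = 60, n_visits = 3,
                    qpcr_noise_sd = 0.25, seed = 37)
  sim <- simulate_cohort(cfg)
  ngs <- sim$truth$abundance |>
    dplyr::mutate(npx = log_abund, qc_flag = "pass")
  q <- simulate_qpcr_readout(sim, cfg)

  same <- platform_concordance(ngs, ngs)
  expect_true(all(abs(same$by_protein$pearson - 1) < 1e-12))
  expect_true(all(abs(same$by_sample$pearson - 1) < 1e-12))

  # permuting sample labels destroys per-protein correlation
  perm <- q |>
    dplyr::group_by(protein_id) |>
    dplyr::mutate(npx = sample(npx)) |>
    dplyr::ungroup()
  null_rep <- platform_concordance(ngs, perm)
  expect_lt(abs(stats::median(null_rep$by_protein$pearson)), 0.05)

  # attenuation: noise sd for target r = 0.9 given signal var sb^2 + sw^2
  var_x <- cfg$sigma_between^2 + cfg$sigma_within^2
  sd_target <- sqrt(var_x * (1 / 0.9^2 - 1))
  cfg2 <- sim_config(n_subjects = 124, n_proteins = 60, n_visits = 3,
                     qpcr_noise_sd = sd_target, seed = 38)
  sim2 <- simulate_cohort(cfg2)
  ngs2 <- sim2$truth$abundance |> dplyr::mutate(npx = log_abund, qc_flag = "pass")
  rep2 <- platform_concordance(ngs2, simulate_qpcr_readout(sim2, cfg2))
  expect_gt(stats::median(rep2$by_protein$pearson), 0.88)
  expect_lt(stats::median(rep2$by_protein$pearson), 0.92)
})

test_that("assay precision separates intra- from inter-plate variation", {
  # identical replicates: both CVs zero
  tbl <- dplyr::bind_rows(
    one_plate_tbl(c(1, 2), plate_id = "plate_01"),
    one_plate_tbl(c(1, 2), plate_id = "plate_02")
  )
  tbl$extnpx[tbl$well_type == "sample_control"] <- 3
  # one_plate_tbl books no sample-control wells; add them
  sc <- tibble::tibble(
    well_id = sprintf("plate_%02d_sc%d", rep(1:2, each = 2), rep(1:2, 2)),
    sample_id = NA_character_,
    plate_id = sprintf("plate_%02d", rep(1:2, each = 2)),
    batch_id = "batch_1", well_type = "sample_control",
    assay_id = "A1", extnpx = 3, inc_value = 0
  )
  a <- counts_from_extnpx(dplyr::bind_rows(tbl, sc))
  adj <- adjust_plate_control(counts_to_extnpx(a$counts, a$controls))
  prec <- assay_precision(adj)
  expect_equal(prec$intra_cv, 0)
  expect_equal(prec$inter_cv, 0)

  # pure within-plate noise: inter-plate CV (of plate means) is smaller
  set.seed(40)
  sigma <- 0.2
  wells <- tidyr::expand_grid(plate = sprintf("plate_%02d", 1:20), repl = 1:2) |>
    dplyr::mutate(
      well_id = sprintf("%s_sc%d", plate, repl), sample_id = NA_character_,
      plate_id = plate, batch_id = "batch_1", well_type = "sample_control",
      assay_id = "A1", npx = 3 + stats::rnorm(dplyr::n(), 0, sigma)
    )
  prec2 <- assay_precision(wells)
  expect_lt(prec2$inter_cv, prec2$intra_cv)

  # lognormal identity: CV = sqrt(exp(sigma_ln^2) - 1) with sigma_ln = sigma*ln 2
  set.seed(41)
  many <- tidyr::expand_grid(plate = sprintf("plate_%03d", 1:400), repl = 1:2) |>
    dplyr::mutate(well_id = sprintf("%s_sc%d", plate, repl),
                  plate_id = plate, batch_id = "batch_1",
                  well_type = "sample_control", assay_id = "A1",
                  npx = 3 + stats::rnorm(dplyr::n(), 0, sigma))
  # the closed-form lognormal CV, corrected for the expectation of a
  # two-replicate SD (E[s] = c4 * sigma with c4 = sqrt(2/pi) at n = 2)
  cv_theory <- sqrt(exp((sigma * log(2))^2) - 1) * sqrt(2 / pi)
  prec3 <- assay_precision(many)
  expect_lt(abs(prec3$intra_cv - cv_theory) / cv_theory, 0.05)
})

test_that("full counts-to-NPX pipeline recovers true abundances", {
  study <- simulate_study(small_config(n_subjects = 20, n_proteins = 25, seed = 43))
  npx <- counts_to_npx(study$assay)
  j <- dplyr::inner_join(npx, study$cohort$truth$abundance,
                         by = c("sample_id", "protein_id"))
  per_assay <- j |>
    dplyr::group_by(assay_id) |>
    dplyr::summarise(rho = stats::cor(npx, log_abund, method = "spearman"),
                     .groups = "drop")
  expect_true(all(per_assay$rho > 0.95))
})
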