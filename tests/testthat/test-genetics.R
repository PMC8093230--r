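test_that("HWE chi-square matches hand arithmetic and the brute-force oracle", {
  expect_equal(hwe_test(25, 50, 25)$chisq, 0)
  expect_equal(hwe_test(25, 50, 25)$p_value, 1)

  h <- hwe_test(30, 40, 30)
  expect_equal(h$chisq, 4)
  expect_equal(round(h$p_value, 4), 0.0455)

  ext <- hwe_test(0, 100, 0)
  expect_equal(ext$chisq, 100)
  expect_lt(ext$p_value, 0.001)

  expect_error(hwe_test(0, 0, 0), "positive")

  set.seed(60)
  for (i in 1:50) {
    tri <- as.vector(stats::rmultinom(1, size = sample(30:500, 1),
                                      prob = stats::runif(3)))
    got <- hwe_test(tri[1], tri[2], tri[3])
    want <- hwe_oracle(tri[1], tri[2], tri[3])
    expect_equal(got$chisq, want$chisq, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("genotype QC applies the four filters in order with a ledger", {
  set.seed(61)
  n_sub <- 50; n_var <- 50
  g <- matrix(stats::rbinom(n_sub * n_var, 2, 0.3), n_sub, n_var,
              dimnames = list(sprintf("s%02d", 1:n_sub), sprintf("v%02d", 1:n_var)))
  # individual 1: 6% missing (3/50) -> removed; individual 2: 4% -> kept
  g[1, 1:3] <- NA
  g[2, 1:2] <- NA
  G <- geno_matrix(g, tibble::tibble(variant_id = colnames(g),
                                     chrom = "1", pos = seq_len(n_var) * 1000,
                                     ref = "A", alt = "G", maf = 0.3))
  out <- genotype_qc(G)
  expect_false("s01" %in% rownames(out$geno))
  expect_true("s02" %in% rownames(out$geno))

  # MAF boundary: 0.04 removed, 0.06 kept (100 subjects for exact rates)
  g2 <- matrix(0L, 100, 2, dimnames = list(sprintf("i%03d", 1:100), c("low", "ok")))
  g2[1:8, 1] <- 1L   # MAF 0.04
  g2[1:12, 2] <- 1L  # MAF 0.06
  G2 <- geno_matrix(g2, tibble::tibble(variant_id = c("low", "ok"), chrom = "1",
                                       pos = c(1000, 2000), ref = "A", alt = "G",
                                       maf = c(0.04, 0.06)))
  # all-heterozygote columns would also fail HWE; these don't
  out2 <- genotype_qc(G2)
  expect_identical(colnames(out2$geno), "ok")
  ledger2 <- attr(out2, "qc_ledger")
  expect_equal(ledger2$removed[ledger2$filter == "maf"], 1)

  # constructed matrix tripping each filter exactly once: 40 variants so a
  # single missing cell is only 2.5% of an individual's genotypes
  n <- 60; nv <- 40
  gm <- matrix(stats::rbinom(n * nv, 2, 0.4), n, nv,
               dimnames = list(sprintf("x%02d", 1:n), sprintf("v%02d", 1:nv)))
  gm[1, 5:7] <- NA                               # x01: 7.5% missing -> filter 1
  gm[2:7, 1] <- NA                               # v01: ~10% missing -> filter 2
  gm[, 2] <- c(rep(1L, 2), rep(0L, n - 2))       # v02: MAF 1/60 -> filter 3
  gm[, 3] <- 1L                                  # v03: all het -> HWE filter
  G3 <- geno_matrix(gm, tibble::tibble(variant_id = colnames(gm), chrom = "1",
                                       pos = seq_len(nv) * 1000, ref = "A",
                                       alt = "G", maf = NA_real_))
  out3 <- genotype_qc(G3)
  ledger3 <- attr(out3, "qc_ledger")
  expect_equal(ledger3$removed, c(1, 1, 1, 1))
  expect_equal(ncol(out3$geno), nv - 3)
  expect_false(any(c("v01", "v02", "v03") %in% colnames(out3$geno)))
  expect_false("x01" %in% rownames(out3$geno))

  # MAF is recomputed from the retained data
  expect_equal(out3$variants$maf,
               unname(pmin(colMeans(out3$geno, na.rm = TRUE) / 2,
                           1 - colMeans(out3$geno, na.rm = TRUE) / 2)))
})

test_that("LD r2 is the squared allele-count correlation, sign-free", {
  g1 <- c(0, 0, 1, 1, 2, 2)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  g2 <- c(0, 1, 0, 1, 2, 2)
  # brute-force Pearson from sums
  n <- 6
  num <- n * sum(g1 * g2) - sum(g1) * sum(g2)
  den <- sqrt(n * sum(g1^2) - sum(g1)^2) * sqrt(n * sum(g2^2) - sum(g2)^2)
  expect_equal(ld_r2(g1, g2), (num / den)^2)
  expect_equal(ld_r2(g1, g2), 0.5625)
  expect_true(is.na(ld_r2(g1, rep(1, 6))))
})

test_that("cis/trans classification follows the inclusive 1 Mb TSS rule", {
  expect_equal(classify_cis_trans("1", 1e6 + 999999, "1", 1e6), "cis")
  expect_equal(classify_cis_trans("1", 1e6 + 1000000, "1", 1e6), "cis")
  expect_equal(classify_cis_trans("1", 1e6 + 1000001, "1", 1e6), "trans")
  expect_equal(classify_cis_trans("2", 1e6 + 10, "1", 1e6), "trans")
  # partition is total and exclusive
  set.seed(62)
  lab <- classify_cis_trans(sample(1:3, 200, TRUE), stats::runif(200, 1, 5e6),
                            sample(1:3, 200, TRUE), stats::runif(200, 1, 5e6))
  expect_true(all(lab %in% c("cis", "trans")))
})

test_that("baseline phenotype is the median over QC-pass visits", {
  npx <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 3),
    visit = rep(1:3, 3), protein_id = "p1",
    npx = c(1, 2, 9, 4, 6, 100, 1, 1, 1),
    qc_flag = c("pass", "pass", "pass",
                "pass", "pass", "flagged",
                "flagged", "flagged", "flagged")
  )
  b <- baseline_phenotype(npx)
  expect_equal(b$value[b$subject_id == "a"], 2)   # median of {1,2,9}
  expect_equal(b$value[b$subject_id == "b"], 5)   # even-count median of {4,6}
  expect_false("c" %in% b$subject_id)             # all visits flagged
})

test_that("pQTL scan recovers injected effects and is calibrated under the null", {
  set.seed(63)
  n <- 150
  g <- stats::rbinom(n, 2, 0.3)
  age <- sample(50:65, n, TRUE)
  sex <- sample(c("male", "female"), n, TRUE)
  y <- 1.0 * g + 0.02 * age + 0.5 * (sex == "male") + stats::rnorm(n, 0, 0.5)
  subj <- sprintf("s%03d", 1:n)
  G <- geno_matrix(matrix(as.integer(g), n, 1,
                          dimnames = list(subj, "v1")),
                   tibble::tibble(variant_id = "v1", chrom = "1", pos = 1000,
                                  ref = "A", alt = "G", maf = 0.3))
  basel <- tibble::tibble(subject_id = subj, protein_id = "p1", value = y)
  cov <- tibble::tibble(subject_id = subj, age = age, sex = sex)
  res <- pqtl_scan(basel, G, cov)
  expect_lt(abs(res$beta - 1.0), 2 * res$se)
  # cross-check against stats::lm
  ref <- summary(stats::lm(y ~ g + age + I(sex == "male")))$coefficients
  expect_equal(res$beta, ref["g", "Estimate"], tolerance = 1e-10)
  expect_equal(res$se, ref["g", "Std. Error"], tolerance = 1e-10)
  expect_equal(res$p_value, ref["g", "Pr(>|t|)"], tolerance = 1e-10)

  # affine phenotype rescaling leaves the p-value unchanged
  res2 <- pqtl_scan(dplyr::mutate(basel, value = 3 * value + 10), G, cov)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-10)
  expect_equal(res2$beta, 3 * res$beta, tolerance = 1e-10)

  # permuted genotypes: nothing survives Bonferroni
  Gp <- geno_matrix(matrix(as.integer(sample(g)), n, 1,
                           dimnames = list(subj, "v1")), G$variants)
  resp <- pqtl_scan(basel, Gp, cov)
  expect_equal(sum(resp$significant), 0)

  # constant genotype columns are skipped with a reason
  Gc <- geno_matrix(cbind(G$geno, v2 = rep(1L, n)),
                    dplyr::bind_rows(G$variants,
                                     tibble::tibble(variant_id = "v2", chrom = "1",
                                                    pos = 2000, ref = "A", alt = "G",
                                                    maf = 0.5)))
  resc <- pqtl_scan(basel, Gc, cov)
  expect_equal(attr(resc, "skipped")$variant_id, "v2")
  expect_false("v2" %in% resc$variant_id)

  # missing genotypes: complete-case equals lm on the complete cases
  gm <- G$geno
  gm[1:10, 1] <- NA
  Gm <- geno_matrix(gm, G$variants)
  resm <- pqtl_scan(basel, Gm, cov)
  keep <- !is.na(gm[, 1])
  refm <- summary(stats::lm(y[keep] ~ g[keep] + age[keep] +
                              I(sex[keep] == "male")))$coefficients
  expect_equal(resm$beta, refm[2, "Estimate"], tolerance = 1e-10)
  expect_equal(resm$p_value, refm[2, "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("beta estimation is unbiased across a MAF x effect grid", {
  set.seed(64)
  n <- 200
  grid <- tidyr::expand_grid(maf = c(0.1, 0.3, 0.5), beta = c(0.5, 1.0))
  subj <- sprintf("s%03d", 1:n)
  cov <- tibble::tibble(subject_id = subj, age = sample(50:65, n, TRUE),
                        sex = sample(c("male", "female"), n, TRUE))
  bias <- purrr::pmap_dbl(grid, function(maf, beta) {
    est <- replicate(30, {
      g <- stats::rbinom(n, 2, maf)
      y <- beta * g + stats::rnorm(n, 0, 0.5)
      G <- geno_matrix(matrix(as.integer(g), n, 1, dimnames = list(subj, "v")),
                       tibble::tibble(variant_id = "v", chrom = "1", pos = 1,
                                      ref = "A", alt = "G", maf = maf))
      pqtl_scan(tibble::tibble(subject_id = subj, protein_id = "p", value = y),
                G, cov)$beta
    })
    (stats::median(est) - beta) / beta
  })
  expect_true(all(abs(bias) <= 0.05))
})

test_that("sentinel selection prunes LD and keeps independent signals", {
  set.seed(65)
  n <- 200
  subj <- sprintf("s%03d", 1:n)
  cov <- tibble::tibble(subject_id = subj, age = sample(50:65, n, TRUE),
                        sex = sample(c("male", "female"), n, TRUE))

  # two perfectly linked significant variants -> one sentinel
  g <- stats::rbinom(n, 2, 0.4)
  G <- geno_matrix(cbind(v1 = as.integer(g), v2 = as.integer(g)) |>
                     `rownames<-`(subj),
                   tibble::tibble(variant_id = c("v1", "v2"), chrom = "1",
                                  pos = c(1e5, 2e5), ref = "A", alt = "G", maf = 0.4))
  y <- 1.5 * g + stats::rnorm(n, 0, 0.4)
  basel <- tibble::tibble(subject_id = subj, protein_id = "p1", value = y)
  scan <- pqtl_scan(basel, G, cov)
  expect_equal(sum(scan$significant), 2)
  sel <- select_independent(scan, basel, G, cov)
  expect_equal(nrow(sel), 1)

  # two independent causal variants, both strong -> both retained
  g1 <- stats::rbinom(n, 2, 0.4); g2 <- stats::rbinom(n, 2, 0.4)
  G2 <- geno_matrix(cbind(a = as.integer(g1), b = as.integer(g2)) |>
                      `rownames<-`(subj),
                    tibble::tibble(variant_id = c("a", "b"), chrom = c("1", "2"),
                                   pos = c(1e5, 1e5), ref = "A", alt = "G", maf = 0.4))
  y2 <- 1.2 * g1 + 1.2 * g2 + stats::rnorm(n, 0, 0.4)
  basel2 <- tibble::tibble(subject_id = subj, protein_id = "p1", value = y2)
  scan2 <- pqtl_scan(basel2, G2, cov)
  sel2 <- select_independent(scan2, basel2, G2, cov)
  expect_equal(nrow(sel2), 2)
  expect_setequal(sel2$variant_id, c("a", "b"))
  expect_true(is.na(sel2$conditional_p[sel2$rank == 1]))
  expect_lt(sel2$conditional_p[sel2$rank == 2], 0.01)

  # conditioning never increases the number of reported loci
  expect_lte(nrow(sel2), sum(scan2$significant))

  # empty input -> empty output
  empty <- select_independent(dplyr::mutate(scan2, significant = FALSE),
                              basel2, G2, cov)
  expect_equal(nrow(empty), 0)
})

test_that("greedy selection matches the rule-by-rule oracle on random instances", {
  set.seed(66)
  n <- 120
  subj <- sprintf("s%03d", 1:n)
  for (case in 1:12) {
    nv <- sample(3:10, 1)
    # blocks of correlated variants on two chromosomes
    base <- stats::rbinom(n, 2, stats::runif(1, 0.2, 0.5))
    G <- sapply(seq_len(nv), function(j) {
      if (stats::runif(1) < 0.5) {
        flip <- stats::rbinom(n, 1, 0.1)
        pmax(pmin(base + flip * sample(c(-1L, 1L), n, TRUE), 2L), 0L)
      } else {
        stats::rbinom(n, 2, stats::runif(1, 0.2, 0.5))
      }
    })
    colnames(G) <- sprintf("v%02d", seq_len(nv))
    rownames(G) <- subj
    variants <- tibble::tibble(
      variant_id = colnames(G),
      chrom = as.character(sample(1:2, nv, TRUE)),
      pos = sample(1e4:3e6, nv),
      ref = "A", alt = "G", maf = colMeans(G) / 2
    )
    age <- sample(50:65, n, TRUE)
    sex <- sample(c("male", "female"), n, TRUE)
    causal <- sample(nv, min(2, nv))
    y <- G[, causal, drop = FALSE] %*% rep(1.2, length(causal)) +
      0.01 * age + stats::rnorm(n, 0, 0.5)
    y <- as.vector(y)
    basel <- tibble::tibble(subject_id = subj, protein_id = "p", value = y)
    cov <- tibble::tibble(subject_id = subj, age = age, sex = sex)
    gm <- geno_matrix(G, variants)
    # permissive threshold so several variants are in play
    scan <- pqtl_scan(basel, gm, cov, genomewide_alpha = 1e-3, divisor = 1)
    got <- select_independent(scan, basel, gm, cov)
    want <- selection_oracle(y, G, variants, age, sex, threshold = 1e-3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_identical(got$variant_id, want$variant_id)
      expect_equal(got$conditional_p, want$conditional_p, tolerance = 1e-8)
    }
  }
})
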