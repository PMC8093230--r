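#' Baseline phenotype: per-subject median NPX across visits
#'
#' The pQTL phenotype for each subject and protein is the median NPX over
#' that subject's QC-pass visits. Subjects whose visits are all flagged
#' contribute no value for that protein (dropped, not imputed).
#'
#' @param npx Long NPX tibble with `subject_id`, `protein_id`, `npx` and
#'   optionally `qc_flag`.
#' @return Tibble with `subject_id`, `protein_id`, `value`, `n_visits`.
#' @export
baseline_phenotype <- function(npx) {
  dat <- npx
  if ("qc_flag" %in% names(dat)) dat <- dplyr::filter(dat, .data$qc_flag == "pass")
  dat |>
    dplyr::group_by(.data$subject_id, .data$protein_id) |>
    dplyr::summarise(value = stats::median(.data$npx),
                     n_visits = dplyr::n(), .groups = "drop")
}

#' Classify pQTL variants as cis or trans
#'
#' A variant is cis to a protein when it lies on the same chromosome as
#' the protein-coding gene and within `window` (default 1 Mb, boundary
#' inclusive) upstream or downstream of its transcription start site;
#' otherwise — farther away or on a different chromosome — it is trans.
#'
#' @param variant_chrom,variant_pos Variant coordinates (1-based).
#' @param tss_chrom,tss_pos Gene TSS coordinates.
#' @param window Window in base pairs.
#' @return Character vector `"cis"`/`"trans"` (NA when a TSS is missing).
#' @export
#' @examples
#' classify_cis_trans("1", 2e6, "1", 1e6)      # exactly 1 Mb: cis
#' classify_cis_trans("1", 2e6 + 1, "1", 1e6)  # trans
classify_cis_trans <- function(variant_chrom, variant_pos, tss_chrom, tss_pos,
                               window = 1e6) {
  out <- ifelse(
    is.na(tss_chrom) | is.na(tss_pos), NA_character_,
    ifelse(as.character(variant_chrom) == as.character(tss_chrom) &
             abs(variant_pos - tss_pos) <= window, "cis", "trans")
  )
  out
}

# align phenotype matrix, genotype matrix and covariate design over the
# common subjects; sex is encoded male = 1, female = 0, age in years
align_pqtl_inputs <- function(baseline, G, covariates) {
  Ywide <- tidyr::pivot_wider(
    dplyr::select(baseline, "subject_id", "protein_id", "value"),
    names_from = "protein_id", values_from = "value")
  subjects <- Reduce(intersect, list(Ywide$subject_id, rownames(G$geno),
                                     covariates$subject_id))
  if (length(subjects) < 4) stop("Too few subjects shared across inputs.", call. = FALSE)
  Y <- as.matrix(Ywide[match(subjects, Ywide$subject_id), -1, drop = FALSE])
  rownames(Y) <- subjects
  cv <- covariates[match(subjects, covariates$subject_id), ]
  sex01 <- if (is.numeric(cv$sex)) cv$sex else as.numeric(cv$sex == "male")
  C <- cbind(intercept = 1, age = cv$age, sex = sex01)
  list(Y = Y, Gm = G$geno[subjects, , drop = FALSE], C = C, subjects = subjects)
}

#' Genome-wide pQTL scan
#'
#' For every protein x variant pair, fits ordinary least squares of the
#' baseline phenotype on the additive allele count with age and sex as
#' covariates, and reports the genotype coefficient (NPX units per
#' alternate allele), its standard error and the two-sided t-test
#' p-value. Subjects with a missing genotype are dropped for that variant
#' (complete case). The significance threshold is Bonferroni-style:
#' `genomewide_alpha / divisor`, with the divisor defaulting to the number
#' of proteins tested. When the genotype object carries a TSS annotation,
#' hits are labelled cis or trans by the 1 Mb rule.
#'
#' @param baseline Output of [baseline_phenotype()] (or any tibble with
#'   `subject_id`, `protein_id`, `value`).
#' @param G A [geno_matrix()] (after [genotype_qc()]).
#' @param covariates Tibble with `subject_id`, `age`, `sex`.
#' @param genomewide_alpha Genome-wide level before the protein-count
#'   correction.
#' @param divisor Bonferroni divisor; default the number of proteins.
#' @return Tibble of class `pqtl_result` with `protein_id`, `variant_id`,
#'   `chrom`, `pos`, `beta`, `se`, `statistic`, `p_value`, `n`, `label`,
#'   `significant`. The threshold is in `attr(, "threshold")`; constant
#'   genotype columns are skipped and listed in `attr(, "skipped")`.
#' @export
pqtl_scan <- function(baseline, G, covariates,
                      genomewide_alpha = 5e-8, divisor = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  al <- align_pqtl_inputs(baseline, G, covariates)
  Y <- al$Y; Gm <- al$Gm; C <- al$C
  n <- nrow(Y)
  df <- n - ncol(C) - 1
  if (df < 1) stop("Not enough subjects for the covariate-adjusted scan.", call. = FALSE)

  const <- apply(Gm, 2, function(g) {
    g <- g[!is.na(g)]
    length(unique(g)) < 2
  })
  skipped <- tibble::tibble(variant_id = colnames(Gm)[const],
                            reason = "constant genotype")
  Gm <- Gm[, !const, drop = FALSE]

  qrC <- qr(C)
  res <- scan_ols(Y, Gm, C, qrC, df)

  res <- dplyr::left_join(res,
                          dplyr::select(G$variants, "variant_id", "chrom", "pos"),
                          by = "variant_id")
  if (!is.null(G$tss)) {
    tss <- G$tss
    i <- match(res$protein_id, tss$protein_id)
    res$label <- classify_cis_trans(res$chrom, res$pos,
                                    tss$chrom[i], tss$tss_pos[i])
  } else {
    res$label <- NA_character_
  }

  divisor <- divisor %||% dplyr::n_distinct(res$protein_id)
  threshold <- genomewide_alpha / divisor
  res$significant <- res$p_value < threshold
  res <- dplyr::select(res, "protein_id", "variant_id", "chrom", "pos",
                       "beta", "se", "statistic", "p_value", "n",
                       "label", "significant")
  class(res) <- c("pqtl_result", class(res))
  attr(res, "threshold") <- threshold
  attr(res, "genomewide_alpha") <- genomewide_alpha
  attr(res, "divisor") <- divisor
  attr(res, "skipped") <- skipped
  res
}

# vectorized OLS via Frisch-Waugh: residualize phenotype and genotype on
# the covariates, then per-variant simple regression; complete-case rows
# for variants or proteins with missing values
scan_ols <- function(Y, Gm, C, qrC, df) {
  ok_y <- colSums(is.na(Y)) == 0
  ok_g <- colSums(is.na(Gm)) == 0

  pieces <- list()
  if (any(ok_y) && any(ok_g)) {
    Ys <- qr.resid(qrC, Y[, ok_y, drop = FALSE])
    Gs <- qr.resid(qrC, Gm[, ok_g, drop = FALSE])
    pieces[[1]] <- fast_block(Ys, Gs, df)
  }
  # variants with missing genotypes, complete phenotypes
  for (v in colnames(Gm)[!ok_g]) {
    ok <- !is.na(Gm[, v])
    sub_y <- which(ok_y)
    if (length(sub_y) == 0 || sum(ok) < ncol(C) + 2) next
    qrs <- qr(C[ok, , drop = FALSE])
    Ys <- qr.resid(qrs, Y[ok, sub_y, drop = FALSE])
    Gs <- qr.resid(qrs, Gm[ok, v, drop = FALSE])
    pieces[[length(pieces) + 1]] <- fast_block(Ys, Gs, sum(ok) - ncol(C) - 1)
  }
  # proteins with missing phenotypes: per-variant complete case
  for (p in colnames(Y)[!ok_y]) {
    y <- Y[, p]
    rows <- purrr::map_dfr(colnames(Gm), function(v) {
      ok <- !is.na(y) & !is.na(Gm[, v])
      if (sum(ok) < ncol(C) + 2) return(NULL)
      qrs <- qr(C[ok, , drop = FALSE])
      ys <- qr.resid(qrs, y[ok])
      gs <- qr.resid(qrs, Gm[ok, v])
      fast_block(matrix(ys, dimnames = list(NULL, p)),
                 matrix(gs, dimnames = list(NULL, v)),
                 sum(ok) - ncol(C) - 1)
    })
    pieces[[length(pieces) + 1]] <- rows
  }
  dplyr::bind_rows(pieces)
}

fast_block <- function(Ys, Gs, df) {
  gss <- colSums(Gs^2)
  keep <- gss > 1e-12
  Gs <- Gs[, keep, drop = FALSE]
  gss <- gss[keep]
  if (ncol(Gs) == 0) return(NULL)
  cross <- crossprod(Gs, Ys)                    # V x P
  beta <- sweep(cross, 1, gss, "/")
  yss <- colSums(Ys^2)
  rss <- pmax(outer(rep(1, nrow(beta)), yss) - cross^2 / gss, 0)
  sigma2 <- rss / df
  se <- sqrt(sweep(sigma2, 1, gss, "/"))
  tstat <- beta / se
  tibble::tibble(
    protein_id = rep(colnames(Ys), each = nrow(beta)),
    variant_id = rep(rownames(beta) %||% colnames(Gs), ncol(Ys)),
    beta = as.vector(beta),
    se = as.vector(se),
    statistic = as.vector(tstat),
    p_value = 2 * stats::pt(-abs(as.vector(tstat)), df = df),
    n = nrow(Ys)
  )
}

#' Sentinel selection, LD pruning and conditional analysis
#'
#' Reduces the significant scan hits of each protein to independent pQTLs:
#' the lowest-p variant is taken as sentinel (ties broken by chromosome
#' then position); candidates within `window` of the sentinel on the same
#' chromosome with LD r-squared above `r2_max` to it are pruned; the
#' remaining candidates are refit with all sentinels selected so far added
#' as covariates, and only those with conditional p below `conditional_p`
#' stay in play. The procedure iterates until no candidate remains. The
#' first sentinel of a protein carries no conditional p; later ones carry
#' the conditional p from the model that admitted them.
#'
#' @param results A `pqtl_result` from [pqtl_scan()].
#' @param baseline,G,covariates The inputs given to [pqtl_scan()] (needed
#'   for the conditional refits).
#' @param r2_max LD pruning threshold.
#' @param window LD pruning window in base pairs (same chromosome only;
#'   cross-chromosome pairs are never pruned).
#' @param conditional_p Conditional significance threshold.
#' @return Tibble with `protein_id`, `variant_id`, `chrom`, `pos`, `rank`,
#'   `p_value`, `conditional_p`, `sentinel = TRUE`.
#' @export
select_independent <- function(results, baseline, G, covariates,
                               r2_max = 0.1, window = 1e6,
                               conditional_p = 0.01) {
  hits <- dplyr::filter(results, .data$significant)
  if (nrow(hits) == 0) {
    return(tibble::tibble(protein_id = character(), variant_id = character(),
                          chrom = character(), pos = numeric(), rank = integer(),
                          p_value = numeric(), conditional_p = numeric(),
                          sentinel = logical()))
  }
  al <- align_pqtl_inputs(baseline, G, covariates)

  purrr::map_dfr(split(hits, hits$protein_id), function(h) {
    y <- al$Y[, h$protein_id[1]]
    cand <- h
    cand$cond_p <- cand$p_value
    sentinels <- character(0)
    out <- list()
    rank <- 0L
    while (nrow(cand) > 0) {
      cand <- dplyr::arrange(cand, .data$cond_p, .data$chrom, .data$pos)
      s <- cand[1, ]
      rank <- rank + 1L
      out[[rank]] <- tibble::tibble(
        protein_id = s$protein_id, variant_id = s$variant_id,
        chrom = s$chrom, pos = s$pos, rank = rank,
        p_value = s$p_value,
        conditional_p = if (rank == 1) NA_real_ else s$cond_p,
        sentinel = TRUE
      )
      sentinels <- c(sentinels, s$variant_id)
      cand <- cand[-1, , drop = FALSE]
      if (nrow(cand) == 0) break
      # LD pruning against the new sentinel (same chromosome, within window)
      r2 <- vapply(cand$variant_id, function(v) {
        ld_r2(al$Gm[, v], al$Gm[, s$variant_id])
      }, numeric(1))
      near <- cand$chrom == s$chrom & abs(cand$pos - s$pos) <= window
      cand <- cand[!(near & !is.na(r2) & r2 > r2_max), , drop = FALSE]
      if (nrow(cand) == 0) break
      # conditional refit with all sentinels as covariates
      cand$cond_p <- unname(vapply(cand$variant_id, function(v) {
        conditional_pvalue(y, al$Gm[, v, drop = TRUE],
                           al$Gm[, sentinels, drop = FALSE], al$C)
      }, numeric(1)))
      cand <- cand[!is.na(cand$cond_p) & cand$cond_p < conditional_p, , drop = FALSE]
    }
    dplyr::bind_rows(out)
  })
}

conditional_pvalue <- function(y, g, Gsent, C) {
  dat <- data.frame(.y = y, .g = g,
                    Gsent,
                    C[, setdiff(colnames(C), "intercept"), drop = FALSE],
                    check.names = TRUE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < ncol(dat) + 1) return(NA_real_)
  fit <- stats::lm(.y ~ ., data = dat)
  co <- summary(fit)$coefficients
  if (!".g" %in% rownames(co)) return(NA_real_)  # collinear with sentinels
  co[".g", "Pr(>|t|)"]
}
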