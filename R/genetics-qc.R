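#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the Hardy-Weinberg expectation at the observed allele
#' frequency. Vectorized over triples. Monomorphic variants (allele
#' frequency 0 or 1) fit HWE trivially and return p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Tibble with `chisq` and `p_value`.
#' @export
#' @examples
#' hwe_test(30, 40, 30)  # chisq 4, p ~ 0.0455
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n <= 0)) stop("Total genotype count must be positive.", call. = FALSE)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  exp_AA <- n * p^2
  exp_Aa <- n * 2 * p * q
  exp_aa <- n * q^2
  chisq <- ifelse(
    p == 0 | q == 0, 0,
    (n_AA - exp_AA)^2 / exp_AA + (n_Aa - exp_Aa)^2 / exp_Aa +
      (n_aa - exp_aa)^2 / exp_aa
  )
  tibble::tibble(chisq = chisq,
                 p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Genotype quality control
#'
#' Applies the four standard filters in order: (1) remove individuals with
#' missing genotype rate above `ind_missing`; (2) remove variants with
#' missing rate above `var_missing`; (3) remove variants with minor allele
#' frequency below `maf_min` (MAF recomputed from the retained
#' individuals); (4) remove variants failing the Hardy-Weinberg test at
#' `hwe_p`. A removal ledger with per-filter counts is attached as
#' `attr(, "qc_ledger")`.
#'
#' @param G A [geno_matrix()].
#' @param ind_missing,var_missing Missing-rate thresholds (exclusive: a
#'   rate strictly above the threshold removes).
#' @param maf_min MAF threshold (exclusive: MAF strictly below removes).
#' @param hwe_p HWE p-value threshold (exclusive: p strictly below removes).
#' @return Filtered [geno_matrix()] with recomputed MAF.
#' @export
genotype_qc <- function(G, ind_missing = 0.05, var_missing = 0.05,
                        maf_min = 0.05, hwe_p = 0.001) {
  stopifnot(inherits(G, "geno_matrix"))
  g <- G$geno

  ind_rate <- rowMeans(is.na(g))
  drop_ind <- ind_rate > ind_missing
  g <- g[!drop_ind, , drop = FALSE]
  if (nrow(g) == 0) stop("All individuals removed by missingness filter.", call. = FALSE)

  var_rate <- colMeans(is.na(g))
  drop_miss <- var_rate > var_missing
  g <- g[, !drop_miss, drop = FALSE]

  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  drop_maf <- maf < maf_min
  g <- g[, !drop_maf, drop = FALSE]

  hwe <- apply(g, 2, function(col) {
    col <- col[!is.na(col)]
    hwe_test(sum(col == 0), sum(col == 1), sum(col == 2))$p_value
  })
  drop_hwe <- hwe < hwe_p
  g <- g[, !drop_hwe, drop = FALSE]
  if (ncol(g) == 0) stop("All variants removed by QC.", call. = FALSE)

  ledger <- tibble::tibble(
    filter = c("individual_missingness", "variant_missingness", "maf", "hwe"),
    threshold = c(ind_missing, var_missing, maf_min, hwe_p),
    removed = c(sum(drop_ind), sum(drop_miss), sum(drop_maf), sum(drop_hwe))
  )

  variants <- G$variants[match(colnames(g), G$variants$variant_id), ]
  af2 <- unname(colMeans(g, na.rm = TRUE) / 2)
  variants$maf <- pmin(af2, 1 - af2)
  out <- geno_matrix(g, variants, tss = G$tss, causal = G$causal)
  attr(out, "qc_ledger") <- ledger
  out
}

#' Linkage disequilibrium as squared Pearson correlation
#'
#' LD between two variants is the square of the Pearson correlation of
#' their additive allele counts over subjects with both genotypes present.
#' Returns `NA` when either vector is constant.
#'
#' @param g1,g2 Allele-count vectors (0/1/2, `NA` allowed).
#' @return r-squared in \[0, 1\] or `NA_real_`.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  a <- g1[ok]; b <- g2[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}
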