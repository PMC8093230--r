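#' Genotype container
#'
#' Bundles an additive allele-count matrix (subjects x variants, values
#' 0/1/2 or `NA`) with variant metadata, a protein-gene TSS annotation used
#' for cis/trans classification, and (for simulated data) the causal map.
#'
#' @param geno Integer matrix, subjects in rows (rownames = subject ids),
#'   variants in columns (colnames = variant ids).
#' @param variants Tibble with `variant_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt` and `maf`.
#' @param tss Optional tibble with `protein_id`, `chrom`, `tss_pos`.
#' @param causal Optional tibble with `protein_id`, `variant_id`, `type`
#'   (`"cis"`/`"trans"`) and `beta` (log2 units per alternate allele).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, variants, tss = NULL, causal = NULL) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)))
  variants <- tibble::as_tibble(variants)
  req <- c("variant_id", "chrom", "pos")
  if (!all(req %in% names(variants))) {
    stop("variants must contain variant_id, chrom, pos.", call. = FALSE)
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("variant ids must be unique.", call. = FALSE)
  }
  if (!identical(colnames(geno), variants$variant_id)) {
    stop("geno columns must match variants$variant_id in order.", call. = FALSE)
  }
  if (any(variants$pos <= 0)) stop("positions must be positive (1-based).", call. = FALSE)
  structure(list(geno = geno, variants = variants, tss = tss, causal = causal),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d subjects x %d variants, %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), dplyr::n_distinct(x$variants$chrom)))
  if (!is.null(x$causal)) {
    cat(sprintf("  causal map: %d cis, %d trans\n",
                sum(x$causal$type == "cis"), sum(x$causal$type == "trans")))
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Simulate genotypes in LD blocks
#'
#' Draws biallelic variants in Hardy-Weinberg proportions. Variants are
#' organised in LD blocks: each subject carries two haplotypes per block;
#' within a block every variant copies the haplotype's founder allele and
#' flips it with probability `ld_mutation_prob`, so within-block r-squared
#' is high and between-block r-squared is zero in expectation. Variants are
#' laid out on `n_chromosomes` chromosomes at `variant_spacing` intervals,
#' and each protein is assigned a transcription start site: proteins chosen
#' to carry a cis effect get a TSS within 0.5 Mb of their causal variant,
#' trans proteins a TSS on a different chromosome.
#'
#' @param config A [sim_config()].
#' @param subject_ids Optional subject ids (defaults to the ids
#'   [simulate_cohort()] generates for the same config).
#' @return A [geno_matrix()] with `tss` and `causal` filled in.
#' @export
simulate_genotypes <- function(config, subject_ids = NULL) {
  validate_sim_config(config)
  n_sub <- config$n_subjects + config$n_t2d
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(n_sub))
  n_sub <- length(subject_ids)
  nv <- config$n_variants

  withr::with_seed(config$seed + 101L, {
    block <- ceiling(seq_len(nv) / config$ld_block_size)
    n_blocks <- max(block)
    founder_maf <- stats::runif(n_blocks, config$maf_range[1], config$maf_range[2])

    g <- matrix(0L, n_sub, nv, dimnames = list(subject_ids, sprintf("var_%05d", seq_len(nv))))
    for (b in seq_len(n_blocks)) {
      idx <- which(block == b)
      hap1 <- stats::rbinom(n_sub, 1, founder_maf[b])
      hap2 <- stats::rbinom(n_sub, 1, founder_maf[b])
      for (j in idx) {
        flip1 <- stats::rbinom(n_sub, 1, config$ld_mutation_prob)
        flip2 <- stats::rbinom(n_sub, 1, config$ld_mutation_prob)
        g[, j] <- as.integer(abs(hap1 - flip1) + abs(hap2 - flip2))
      }
    }

    # contiguous blocks laid across chromosomes
    chrom_of_block <- rep(seq_len(config$n_chromosomes), length.out = n_blocks)
    chrom <- as.character(chrom_of_block[block])
    pos <- integer(nv)
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      pos[sel] <- seq_len(sum(sel)) * config$variant_spacing
    }
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))

    variants <- tibble::tibble(
      variant_id = colnames(g), chrom = chrom, pos = pos,
      ref = ref, alt = alt,
      maf = pmin(colMeans(g) / 2, 1 - colMeans(g) / 2),
      block = block
    )

    prots <- protein_ids(config)
    n_cis <- config$n_causal_cis
    n_trans <- config$n_causal_trans
    causal_prots <- sample(prots, n_cis + n_trans)
    cis_prots <- causal_prots[seq_len(n_cis)]
    trans_prots <- setdiff(causal_prots, cis_prots)
    causal_vars <- sample(variants$variant_id, n_cis + n_trans)

    chrom_len <- vapply(as.character(seq_len(config$n_chromosomes)),
                        function(ch) max(c(variants$pos[variants$chrom == ch], 1L)),
                        numeric(1))

    tss <- tibble::tibble(
      protein_id = prots,
      chrom = as.character(sample(seq_len(config$n_chromosomes), length(prots), replace = TRUE)),
      tss_pos = NA_real_
    )
    tss$tss_pos <- unname(vapply(tss$chrom, function(ch) {
      max(1, round(stats::runif(1, 1, chrom_len[[ch]])))
    }, numeric(1)))

    causal <- tibble::tibble(
      protein_id = causal_prots,
      variant_id = causal_vars,
      type = c(rep("cis", n_cis), rep("trans", n_trans)),
      beta = config$genetic_beta
    )
    vmeta <- variants[match(causal_vars, variants$variant_id), ]
    for (k in seq_len(nrow(causal))) {
      i <- match(causal$protein_id[k], tss$protein_id)
      if (causal$type[k] == "cis") {
        tss$chrom[i] <- vmeta$chrom[k]
        tss$tss_pos[i] <- max(1, vmeta$pos[k] + round(stats::runif(1, -5e5, 5e5)))
      } else {
        other <- setdiff(as.character(seq_len(config$n_chromosomes)), vmeta$chrom[k])
        if (length(other) == 0) {
          # single chromosome: place the TSS beyond the 1 Mb window instead
          tss$chrom[i] <- vmeta$chrom[k]
          tss$tss_pos[i] <- vmeta$pos[k] + 2e6
        } else {
          ch <- sample(other, 1)
          tss$chrom[i] <- ch
          tss$tss_pos[i] <- max(1, round(stats::runif(1, 1, chrom_len[[ch]])))
        }
      }
    }

    geno_matrix(g, variants, tss = tss, causal = causal)
  })
}
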