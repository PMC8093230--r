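#' Read and write the canonical long-format tables
#'
#' All interchange tables are tab-delimited with a header row and `NA` for
#' missing values. The NPX long format carries one row per sample x
#' protein measurement with the plate/batch annotations attached per
#' measurement; writers and readers round-trip losslessly.
#'
#' @param npx NPX tibble to write.
#' @param path File path.
#' @return `read_npx_long()` returns a validated tibble of class
#'   `npx_tbl`; `write_npx_long()` returns `path` invisibly.
#' @name npx_io
NULL

npx_required_cols <- c("sample_id", "protein_id", "npx")

#' @rdname npx_io
#' @export
write_npx_long <- function(npx, path) {
  readr::write_tsv(npx, path, na = "NA")
  invisible(path)
}

#' @rdname npx_io
#' @export
read_npx_long <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  missing_cols <- setdiff(npx_required_cols, names(tbl))
  if (length(missing_cols) > 0) {
    stop("NPX file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0) tbl$npx <- as.numeric(tbl$npx)  # header-only file
  if (!is.numeric(tbl$npx)) stop("NPX column is not numeric.", call. = FALSE)
  if ("qc_flag" %in% names(tbl)) {
    bad <- setdiff(unique(tbl$qc_flag), c("pass", "flagged", NA))
    if (length(bad) > 0) {
      stop("Unknown qc_flag value(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  # panel-replicated control assays share a protein id, so the assay id is
  # the measurement key when present
  unit <- if ("assay_id" %in% names(tbl)) "assay_id" else "protein_id"
  keys <- c("sample_id", unit, intersect("batch_id", names(tbl)))
  dup <- duplicated(tbl[keys])
  if (any(dup)) {
    off <- tbl[dup, keys][1, ]
    stop("Duplicated measurement row(s), first offending key: ",
         paste(sprintf("%s=%s", names(off), unlist(off)), collapse = ", "),
         call. = FALSE)
  }
  class(tbl) <- c("npx_tbl", class(tbl))
  tbl
}

#' Write and read simulated count tables
#'
#' The count long format has one row per well x assay
#' (`well_id, sample_id, plate_id, batch_id, well_type, assay_id,
#' protein_id, panel, count`) plus a separate control-count table
#' (`well_id, control, count`, one row per well and internal-control
#' class).
#'
#' @param assay An `assay_counts` object.
#' @param dir Directory to write `counts.tsv` and `control_counts.tsv` in.
#' @return `read_counts()` returns an `assay_counts`-like list;
#'   `write_counts()` the directory, invisibly.
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
write_counts <- function(assay, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(assay$counts, file.path(dir, "counts.tsv"), na = "NA")
  readr::write_tsv(assay$controls, file.path(dir, "control_counts.tsv"), na = "NA")
  invisible(dir)
}

#' @rdname counts_io
#' @export
read_counts <- function(dir) {
  counts <- readr::read_tsv(file.path(dir, "counts.tsv"),
                            show_col_types = FALSE, na = "NA")
  controls <- readr::read_tsv(file.path(dir, "control_counts.tsv"),
                              show_col_types = FALSE, na = "NA")
  if (any(counts$count < 0, na.rm = TRUE)) stop("Counts must be >= 0.", call. = FALSE)
  if ("panel" %in% names(counts)) counts$panel <- as.integer(counts$panel)
  structure(list(counts = counts, controls = controls), class = "assay_counts")
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 (biallelic SNVs, `GT` genotype field) that
#' [read_vcf_genotypes()] — or any standard VCF tool — can consume.
#'
#' @param G A [geno_matrix()].
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  v <- G$variants
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- apply(G$geno, 2, function(col) {
    ifelse(is.na(col), "./.", gt_code[col + 1L])
  })
  gt <- matrix(gt, nrow = nrow(G$geno))  # subjects x variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=npxflow",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G$geno)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
            ".", "PASS", ".", "GT", gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses a VCF (via \pkg{vcfR}), keeps biallelic SNV records, and
#' converts `GT` fields to additive alternate-allele counts: `0/0` to 0,
#' `0/1` (or phased `0|1`) to 1, `1/1` to 2, `./.` to missing.
#' Multiallelic records are skipped; their count is recorded in
#' `attr(, "n_multiallelic_skipped")`.
#'
#' @param path VCF path.
#' @param tss Optional TSS annotation tibble (`protein_id`, `chrom`,
#'   `tss_pos`), e.g. from [read_tss()].
#' @return A [geno_matrix()].
#' @export
read_vcf_genotypes <- function(path, tss = NULL) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("Malformed VCF '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  n_multi <- sum(multi)
  if (n_multi > 0) message(n_multi, " multiallelic record(s) skipped.")
  keep <- !multi
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gt_raw <- gt_raw[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  g <- t(apply(gt_raw, 1, code))
  g <- matrix(as.integer(g), nrow = nrow(gt_raw),
              dimnames = list(NULL, colnames(gt_raw)))
  g <- t(g)  # subjects x variants
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix$CHROM, fix$POS)[is.na(ids) | ids == "."]
  colnames(g) <- ids

  af <- colMeans(g, na.rm = TRUE) / 2
  variants <- tibble::tibble(
    variant_id = ids, chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT, maf = pmin(af, 1 - af)
  )
  out <- geno_matrix(g, variants, tss = tss)
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' TSS annotation IO
#'
#' Tab-delimited gene annotation mapping each protein to the chromosome
#' and 1-based transcription start site of its coding gene
#' (`protein_id`, `chrom`, `tss_pos`).
#'
#' @param tss Annotation tibble. @param path File path.
#' @return `read_tss()` the tibble; `write_tss()` the path, invisibly.
#' @name tss_io
NULL

#' @rdname tss_io
#' @export
write_tss <- function(tss, path) {
  readr::write_tsv(tss, path, na = "NA")
  invisible(path)
}

#' @rdname tss_io
#' @export
read_tss <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  need <- c("protein_id", "chrom", "tss_pos")
  if (!all(need %in% names(tbl))) {
    stop("TSS file must contain protein_id, chrom, tss_pos.", call. = FALSE)
  }
  tbl$chrom <- as.character(tbl$chrom)
  tbl
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth The `truth` element of a `sim_cohort` (or the object).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  if (inherits(truth, "sim_cohort")) truth <- truth$truth
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       na = "null", auto_unbox = TRUE)
  invisible(path)
}
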