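#' Low-dimensional embedding of samples from a protein panel
#'
#' Pivots the NPX table to samples x proteins, centres and scales each
#' protein, and embeds the samples in two dimensions. `method = "pca"`
#' uses deterministic principal components ([stats::prcomp()]);
#' `method = "umap"` runs Uniform Manifold Approximation and Projection
#' through the system `python` interpreter's `umap-learn` package with a
#' fixed `random_state`, so repeated runs with the same seed are
#' identical.
#'
#' @param npx Long NPX tibble with `sample_id`, `protein_id`, `npx`.
#' @param proteins Protein subset defining the panel (default: all).
#' @param method `"pca"` or `"umap"`.
#' @param seed Seed for the UMAP initialisation (ignored by PCA).
#' @param n_neighbors UMAP neighbourhood size.
#' @return Tibble of class `embedding` with `sample_id`, `dim1`, `dim2`;
#'   for PCA the variance explained is in `attr(, "var_explained")`.
#' @export
embed_samples <- function(npx, proteins = NULL, method = c("pca", "umap"),
                          seed = 1L, n_neighbors = 15) {
  method <- match.arg(method)
  dat <- npx
  if (!is.null(proteins)) dat <- dplyr::filter(dat, .data$protein_id %in% proteins)
  wide <- dat |>
    dplyr::group_by(.data$sample_id, .data$protein_id) |>
    dplyr::summarise(npx = mean(.data$npx), .groups = "drop") |>  # panel replicates
    tidyr::pivot_wider(names_from = "protein_id", values_from = "npx")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  if (nrow(m) < 3) stop("Embedding requires at least 3 samples.", call. = FALSE)
  keep <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
  m <- scale(m[, keep, drop = FALSE])

  coords <- if (method == "pca") {
    pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
    out <- pc$x[, 1:2, drop = FALSE]
    attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
    out
  } else {
    umap_via_python(m, seed = seed, n_neighbors = min(n_neighbors, nrow(m) - 1))
  }

  res <- tibble::tibble(sample_id = rownames(m),
                        dim1 = coords[, 1], dim2 = coords[, 2])
  attr(res, "method") <- method
  attr(res, "var_explained") <- attr(coords, "var_explained")
  class(res) <- c("embedding", class(res))
  res
}

# run umap-learn in a python subprocess; the matrix travels as CSV
umap_via_python <- function(m, seed, n_neighbors) {
  py <- Sys.which("python")
  if (py == "") stop("UMAP requires a python interpreter with umap-learn.", call. = FALSE)
  din <- tempfile(fileext = ".csv"); dout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(din, dout)), add = TRUE)
  utils::write.table(m, din, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import warnings; warnings.filterwarnings('ignore')\n",
    "import numpy as np, umap\n",
    "x = np.loadtxt(%s, delimiter=',', ndmin=2)\n",
    "emb = umap.UMAP(n_components=2, n_neighbors=%d, random_state=%d).fit_transform(x)\n",
    "np.savetxt(%s, emb, delimiter=',')\n"),
    deparse(din), as.integer(n_neighbors), as.integer(seed), deparse(dout))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  on.exit(unlink(sf), add = TRUE)
  status <- system2(py, sf, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(dout)) {
    stop("UMAP embedding failed (is umap-learn installed for `python`?).",
         call. = FALSE)
  }
  as.matrix(utils::read.table(dout, sep = ","))
}
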