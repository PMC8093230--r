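#' Differential expression by ANOVA
#'
#' Per protein, fits an additive linear model of NPX on the stated
#' covariates plus the factor of interest (covariates entered first, the
#' factor last, sequential sums of squares), and reports the F-test on the
#' factor. P-values are Benjamini-Hochberg adjusted across proteins and
#' proteins with adjusted p below `fdr` form the differentially expressed
#' set. For a two-level factor the log2 fold change is the difference of
#' factor-level means of NPX (NPX is already on a log2 scale), second
#' level minus first. An unbalanced design triggers a warning (sequential
#' sums of squares then depend on covariate order), not a failure.
#'
#' @param npx Long NPX tibble with `protein_id`, `npx` and the model
#'   columns.
#' @param factor Name of the factor column (>= 2 levels).
#' @param covariates Character vector of covariate column names.
#' @param fdr FDR cut defining the DE set.
#' @return Tibble of class `assoc_result` with `protein_id`, `term`,
#'   `log2_fc`, `statistic` (F), `p_value`, `adjusted_p`, `de`,
#'   `method = "anova"`.
#' @export
anova_de <- function(npx, factor, covariates = c("age", "visit"), fdr = 0.05) {
  stopifnot(all(c("protein_id", "npx", factor, covariates) %in% names(npx)))
  f <- as.factor(npx[[factor]])
  if (nlevels(droplevels(f)) < 2) {
    stop(sprintf("Factor '%s' must have at least 2 levels.", factor), call. = FALSE)
  }
  if (length(unique(table(droplevels(f)))) > 1) {
    warning("Design is unbalanced; sequential (type-I) sums of squares are used.",
            call. = FALSE)
  }
  rhs <- paste(c(covariates, factor), collapse = " + ")
  form <- stats::as.formula(paste("npx ~", rhs))
  lv <- levels(droplevels(f))

  res <- npx |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(d, key) {
      fit <- stats::lm(form, data = d)
      a <- stats::anova(fit)
      row <- a[factor, ]
      fc <- if (length(lv) == 2) {
        mean(d$npx[d[[factor]] == lv[2]]) - mean(d$npx[d[[factor]] == lv[1]])
      } else NA_real_
      tibble::tibble(term = factor, log2_fc = fc,
                     statistic = row[["F value"]],
                     p_value = row[["Pr(>F)"]])
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(adjusted_p = bh_adjust(.data$p_value),
                  de = .data$adjusted_p < fdr,
                  method = "anova")
  class(res) <- c("assoc_result", class(res))
  attr(res, "fdr") <- fdr
  attr(res, "levels") <- lv
  res
}

#' Protein-clinical association by linear mixed models
#'
#' Per protein, fits a linear mixed model of NPX on a clinical parameter
#' with gender, age and visit as fixed covariates and a random intercept
#' per subject (repeated measures), and reports the clinical term's
#' coefficient and p-value. Degrees of freedom use the Satterthwaite
#' approximation (via \pkg{lmerTest}); see the methods vignette for why
#' this stands in for the Kenward-Roger correction. P-values are BH
#' adjusted across proteins and called significant below `alpha`.
#'
#' @param npx Long NPX tibble with `protein_id`, `npx`, `subject_id`, the
#'   parameter column and the covariate columns.
#' @param parameter Name of the clinical parameter column.
#' @param covariates Fixed-effect covariate column names.
#' @param alpha Adjusted-p significance level.
#' @return Tibble of class `assoc_result` with `protein_id`, `term`,
#'   `coefficient`, `se`, `statistic`, `df`, `p_value`, `adjusted_p`,
#'   `significant`, `method = "lmm"`.
#' @export
lmm_association <- function(npx, parameter,
                            covariates = c("sex", "age", "visit"),
                            alpha = 0.01) {
  stopifnot(all(c("protein_id", "npx", "subject_id", parameter, covariates)
                %in% names(npx)))
  n_sub <- dplyr::n_distinct(npx$subject_id)
  n_fixed <- length(covariates) + 2L
  if (n_sub <= n_fixed) {
    stop("Fewer subjects than fixed-effect parameters.", call. = FALSE)
  }
  rhs <- paste(c(parameter, covariates, "(1 | subject_id)"), collapse = " + ")
  form <- stats::as.formula(paste("npx ~", rhs))

  res <- npx |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(d, key) {
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(form, data = d,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))
      ))
      co <- stats::coef(summary(fit))
      r <- co[parameter, ]
      tibble::tibble(term = parameter,
                     coefficient = r[["Estimate"]],
                     se = r[["Std. Error"]],
                     statistic = r[["t value"]],
                     df = r[["df"]],
                     p_value = r[["Pr(>|t|)"]])
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(adjusted_p = bh_adjust(.data$p_value),
                  significant = .data$adjusted_p < alpha,
                  method = "lmm")
  class(res) <- c("assoc_result", class(res))
  attr(res, "alpha") <- alpha
  res
}
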