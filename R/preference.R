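#' Chi-square preference test with per-cell post hoc residuals
#'
#' Pearson chi-square test of independence (no continuity correction) on a
#' category-by-level contingency table, with per-cell standardized
#' residuals (obs - exp) / sqrt(exp (1 - row/N) (1 - col/N)), two-sided
#' normal p-values per cell, Bonferroni-adjusted over all cells. Used to
#' ask, e.g., whether duplication categories distribute preferentially over
#' coexpression modules or tau peak conditions.
#'
#' @param table a matrix or table of counts with at least 2 rows and 2
#'   columns; any expected cell count of zero is an error (merge levels
#'   first).
#' @return An object of class `posthoc_result`: `chi2`, `df`, `pvalue`,
#'   `residuals` (standardized), `cell_pvalues` (Bonferroni-adjusted).
#' @export
categorical_preference <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table needs >= 2 rows and >= 2 columns")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("expected cell count of zero; merge sparse levels")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  stdres <- ct$stdres
  cell_p <- pmin(2 * pnorm(-abs(stdres)) * length(tab), 1)
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 pvalue = ct$p.value, residuals = stdres,
                 cell_pvalues = cell_p, observed = tab,
                 expected = expected),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g on %d df, p = %.4g\n", x$chi2, x$df, x$pvalue))
  cat("standardized residuals:\n")
  print(round(x$residuals, 2))
  invisible(x)
}
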