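#' Differential exon usage between the conditions of a contrast
#'
#' For each exon bin the relative usage u = bin count / gene total is
#' compared between the two condition groups of the contrast with a
#' quasi-binomial score test: the binomial score statistic on pooled
#' per-group counts is divided by a per-gene dispersion factor estimated
#' from per-sample Pearson residuals. Per-gene significance combines bin
#' p-values with a Sidak minimum-p rule and is Benjamini-Hochberg adjusted
#' across genes; a bin is flagged significant when its gene passes at
#' `alpha` and its usage shift exceeds `min_delta` in absolute value.
#'
#' @param bin_counts integer bin-by-sample matrix (rownames = bin ids).
#' @param bin_info data.frame mapping `bin_id` to `gene_id`.
#' @param samples sample sheet.
#' @param contrast one of `"L-28"`, `"L-34"`, `"T-Fr"`, `"T-Sy"`.
#' @param gene_totals optional gene-by-sample totals; by default the sum of
#'   the gene's bins. Samples where a gene's total is zero are skipped for
#'   that gene.
#' @param alpha gene-level FDR threshold for flagging bins (default 0.05).
#' @param min_delta minimum absolute usage shift for flagging (default 0.1).
#' @return data.frame `bin_id`, `gene_id`, `contrast`, `delta_usage`,
#'   `pvalue`, `gene_fdr`, `significant`.
#' @export
test_deu <- function(bin_counts, bin_info, samples, contrast,
                     gene_totals = NULL, alpha = 0.05, min_delta = 0.1) {
  samples <- validate_sample_sheet(samples)
  samples <- samples[match(colnames(bin_counts), samples$sample), , drop = FALSE]
  cmap <- list("L-28" = c("free_28", "symbiotic_28"),
               "L-34" = c("free_34", "symbiotic_34"),
               "T-Fr" = c("free_28", "free_34"),
               "T-Sy" = c("symbiotic_28", "symbiotic_34"))
  if (!contrast %in% names(cmap)) stop("unknown contrast: ", contrast)
  gid <- bin_info$gene_id[match(rownames(bin_counts), bin_info$bin_id)]
  if (anyNA(gid)) stop("bin(s) missing from bin_info")
  if (is.null(gene_totals)) {
    gene_totals <- rowsum(bin_counts, gid)
  }
  tot <- gene_totals[gid, , drop = FALSE]
  if (any(bin_counts > tot))
    stop("bin count exceeds gene total")
  grp1 <- samples$condition == cmap[[contrast]][1]
  grp2 <- samples$condition == cmap[[contrast]][2]

  usable <- tot > 0
  k <- bin_counts; k[!usable] <- 0L
  n <- tot; n[!usable] <- 0L
  k1 <- rowSums(k[, grp1, drop = FALSE]); n1 <- rowSums(n[, grp1, drop = FALSE])
  k2 <- rowSums(k[, grp2, drop = FALSE]); n2 <- rowSums(n[, grp2, drop = FALSE])
  p1 <- ifelse(n1 > 0, k1 / n1, NA)
  p2 <- ifelse(n2 > 0, k2 / n2, NA)
  pp <- (k1 + k2) / pmax(n1 + n2, 1)
  v1 <- n1 * pp * (1 - pp); v2 <- n2 * pp * (1 - pp)
  x2 <- ifelse(v1 > 0, (k1 - n1 * pp)^2 / v1, 0) +
        ifelse(v2 > 0, (k2 - n2 * pp)^2 / v2, 0)

  ## per-gene overdispersion from per-sample Pearson residuals against the
  ## group proportion
  use <- grp1 | grp2
  pg <- matrix(NA_real_, nrow(k), sum(use))
  cols <- which(use)
  for (ci in seq_along(cols)) {
    j <- cols[ci]
    pref <- if (grp1[j]) p1 else p2
    pg[, ci] <- pref
  }
  kk <- k[, cols, drop = FALSE]; nn <- n[, cols, drop = FALSE]
  vv <- nn * pg * (1 - pg)
  r2 <- ifelse(vv > 0, (kk - nn * pg)^2 / vv, NA)
  r2sum <- rowsum(rowSums(r2, na.rm = TRUE), gid)
  r2cnt <- rowsum(rowSums(!is.na(r2)), gid)
  nbins_gene <- as.vector(table(gid)[rownames(r2sum)])
  df <- pmax(r2cnt - 2 * nbins_gene, 1)
  phi_gene <- pmax(r2sum / df, 1)
  phi <- phi_gene[match(gid, rownames(r2sum)), 1]

  pval <- pchisq(x2 / phi, df = 1, lower.tail = FALSE)
  pval[n1 == 0 | n2 == 0] <- 1
  delta <- p2 - p1

  minp <- tapply(pval, gid, min)
  nb <- tapply(pval, gid, length)
  gene_p <- 1 - (1 - minp)^nb
  gene_fdr_by_gene <- p.adjust(gene_p, method = "BH")
  gene_fdr <- as.numeric(gene_fdr_by_gene[match(gid, names(gene_fdr_by_gene))])

  data.frame(bin_id = rownames(bin_counts), gene_id = gid,
             contrast = contrast, delta_usage = delta, pvalue = pval,
             gene_fdr = gene_fdr,
             significant = gene_fdr < alpha & abs(delta) > min_delta &
               !is.na(delta),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-pair differential exon usage summary
#'
#' Combines the DEU results of the two copies of an ohnolog pair over their
#' matched bins: `overall_deu` is the summed absolute difference in usage
#' shift across matched bins, `proportion_deu` the fraction of all the
#' pair's bins flagged significant (unmatched bins count in the denominator
#' only).
#'
#' @param deu_a,deu_b DEU rows (one contrast) for the two copies.
#' @param bin_matches data.frame with `bin_a`, `bin_b` giving matched bin
#'   ids; `NULL` or empty marks the pair incomparable.
#' @param pearson_r optional expression correlation carried through.
#' @return List `overall_deu`, `proportion_deu`, `pearson_r`,
#'   `comparable`.
#' @export
pair_deu_summary <- function(deu_a, deu_b, bin_matches = NULL,
                             pearson_r = NA_real_) {
  n_bins <- nrow(deu_a) + nrow(deu_b)
  prop <- if (n_bins > 0)
    (sum(deu_a$significant) + sum(deu_b$significant)) / n_bins else NA_real_
  if (is.null(bin_matches) || !nrow(bin_matches))
    return(list(overall_deu = NA_real_, proportion_deu = prop,
                pearson_r = pearson_r, comparable = FALSE))
  da <- deu_a$delta_usage[match(bin_matches$bin_a, deu_a$bin_id)]
  db <- deu_b$delta_usage[match(bin_matches$bin_b, deu_b$bin_id)]
  list(overall_deu = sum(abs(da - db), na.rm = TRUE),
       proportion_deu = prop, pearson_r = pearson_r, comparable = TRUE)
}
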