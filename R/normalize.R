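## median-of-ratios size factors; genes with any zero are excluded from the
## reference, with a positive-counts fallback when no gene qualifies
.size_factors <- function(counts) {
  if (all(counts == 0)) stop("all-zero count matrix")
  ref_ok <- rowSums(counts == 0) == 0
  if (any(ref_ok)) {
    lgm <- rowMeans(log(counts[ref_ok, , drop = FALSE]))
    ratios <- log(counts[ref_ok, , drop = FALSE]) - lgm
  } else {
    pos <- counts
    pos[pos == 0] <- NA
    lgm <- rowMeans(log(pos), na.rm = TRUE)
    keep <- is.finite(lgm) & rowSums(!is.na(pos)) >= ncol(counts) / 2
    if (!any(keep)) stop("no usable reference genes for size factors")
    ratios <- log(pos[keep, , drop = FALSE]) - lgm[keep]
  }
  sf <- exp(apply(ratios, 2, median, na.rm = TRUE))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Normalise a count matrix
#'
#' Median-of-ratios size factors (genes containing any zero are excluded
#' from the reference), counts per million on the size-factor-scaled
#' library, FPKM (requires gene lengths) and log2(FPKM + 1).
#'
#' @param counts integer gene-by-sample matrix.
#' @param gene_lengths named vector of summed exon lengths in bp; FPKM is
#'   omitted when absent.
#' @return List with `size_factors`, `effective_lib_sizes`, `cpm`, and (with
#'   lengths) `fpkm`, `log2fpkm`.
#' @export
normalize_counts <- function(counts, gene_lengths = NULL) {
  sf <- .size_factors(counts)
  eff_lib <- sf * mean(colSums(counts) / sf)
  cpm <- sweep(counts, 2, eff_lib / 1e6, "/")
  out <- list(size_factors = sf, effective_lib_sizes = eff_lib, cpm = cpm)
  if (!is.null(gene_lengths)) {
    len <- gene_lengths[rownames(counts)]
    if (anyNA(len)) stop("gene lengths missing for some genes")
    out$fpkm <- cpm / (len / 1e3)
    out$log2fpkm <- log2(out$fpkm + 1)
  }
  out
}
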