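#' Tau expression-specificity index
#'
#' tau = sum_i (1 - x_i / x_max) / (N - 1) over the N = 4 condition means
#' x_i of log2(FPKM + 1), after averaging replicates within each
#' lifestyle-by-temperature condition. tau is 0 for uniform expression and
#' 1 for expression confined to a single condition. A gene is eligible only
#' when its maximal condition mean exceeds 1 on the log2(FPKM + 1) scale;
#' ineligible genes carry no tau.
#'
#' @param fpkm FPKM matrix, genes x samples.
#' @param samples sample sheet assigning each column a condition.
#' @return data.frame `gene_id`, `tau` (NA when ineligible), `eligible`,
#'   `peak_condition`.
#' @export
tau_index <- function(fpkm, samples) {
  samples <- validate_sample_sheet(samples)
  samples <- samples[match(colnames(fpkm), samples$sample), , drop = FALSE]
  if (anyNA(samples$sample)) stop("fpkm columns missing from sample sheet")
  lx <- log2(fpkm + 1)
  conds <- sort(unique(samples$condition))
  cm <- vapply(conds, function(cc)
    rowMeans(lx[, samples$condition == cc, drop = FALSE]), numeric(nrow(lx)))
  cm <- matrix(cm, nrow = nrow(lx), dimnames = list(rownames(fpkm), conds))
  xmax <- apply(cm, 1, max)
  eligible <- xmax > 1
  N <- length(conds)
  tau <- rowSums(1 - cm / ifelse(xmax > 0, xmax, NA)) / (N - 1)
  tau[!eligible] <- NA_real_
  peak <- conds[max.col(cm, ties.method = "first")]
  data.frame(gene_id = rownames(fpkm), tau = tau, eligible = eligible,
             peak_condition = peak, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Compare tau across duplication categories
#'
#' Kruskal-Wallis rank sum test over duplication classes, followed by
#' pairwise Wilcoxon rank sum tests with continuity correction and Holm
#' adjustment. Classes with fewer than two eligible members are excluded
#' with a warning.
#'
#' @param tau output of [tau_index()].
#' @param classes output of [classify_duplicates()].
#' @return List with `kruskal_statistic`, `kruskal_p`, `pairwise_p` (matrix
#'   of Holm-adjusted p-values), and `n_by_class`.
#' @export
tau_class_tests <- function(tau, classes) {
  d <- merge(tau[tau$eligible & !is.na(tau$tau), c("gene_id", "tau")],
             classes, by = "gene_id")
  n_by <- table(d$category)
  small <- names(n_by)[n_by < 2]
  if (length(small)) {
    warning("class(es) with < 2 members excluded: ",
            paste(small, collapse = ", "))
    d <- d[!d$category %in% small, , drop = FALSE]
  }
  if (length(unique(d$category)) < 2)
    stop("need >= 2 classes with >= 2 members")
  kw <- kruskal.test(tau ~ factor(category), data = d)
  pw <- suppressWarnings(
    pairwise.wilcox.test(d$tau, factor(d$category),
                         p.adjust.method = "holm"))
  list(kruskal_statistic = unname(kw$statistic), kruskal_p = kw$p.value,
       pairwise_p = pw$p.value, n_by_class = table(d$category))
}
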