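#' Filter ohnolog pairs to expressed pairs
#'
#' A pair is retained iff both members have a raw count of at least
#' `min_count` in at least `min_sample_frac` of all samples (pooled over
#' conditions).
#'
#' @param counts integer gene-by-sample matrix of raw counts.
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param min_count minimum mapped transcripts (default 10).
#' @param min_sample_frac minimum fraction of samples (default 0.5).
#' @return The retained subset of `pairs`.
#' @export
filter_expressed_pairs <- function(counts, pairs, min_count = 10,
                                   min_sample_frac = 0.5) {
  ok <- rowMeans(counts >= min_count) >= min_sample_frac
  gene_ok <- function(g) g %in% rownames(counts) & ok[g]
  keep <- gene_ok(pairs$gene_a) & gene_ok(pairs$gene_b)
  keep[is.na(keep)] <- FALSE
  pairs[keep, , drop = FALSE]
}

#' Classify ohnolog pairs into five expression-divergence groups
#'
#' Let D(g) be the set of contrasts in which gene g is DE (up or down).
#' Rules, tested in order: (1) neither copy DE anywhere -> group 1; (2)
#' exactly one copy DE -> group 2; (3) some shared contrast with opposite
#' directions -> group 5; (4) some shared contrast with the same direction
#' -> group 3; (5) otherwise (both DE, in disjoint contrast sets) ->
#' group 4. Opposing DE in any one comparison therefore takes precedence
#' over same-direction DE elsewhere.
#'
#' @param de DE results over all four contrasts (from [test_de()]) covering
#'   every pair member; missing rows are an error.
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @return data.frame `gene_a`, `gene_b`, `group` (integer 1-5), plus the
#'   per-copy DE contrast strings `de_a`, `de_b`.
#' @export
classify_pair_groups <- function(de, pairs) {
  contrasts <- c("L-28", "L-34", "T-Fr", "T-Sy")
  if (!all(contrasts %in% de$contrast))
    stop("DE results must cover all four contrasts")
  key <- paste(de$gene_id, de$contrast, sep = "\r")
  status <- setNames(de$status, key)
  get_status <- function(g) {
    s <- status[paste(g, contrasts, sep = "\r")]
    if (anyNA(s)) stop("missing DE rows for gene ", g)
    setNames(s, contrasts)
  }
  grp <- integer(nrow(pairs))
  de_a <- de_b <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sa <- get_status(pairs$gene_a[i])
    sb <- get_status(pairs$gene_b[i])
    Da <- contrasts[sa != "ns"]
    Db <- contrasts[sb != "ns"]
    shared <- intersect(Da, Db)
    grp[i] <- if (!length(Da) && !length(Db)) 1L
      else if (xor(length(Da) > 0, length(Db) > 0)) 2L
      else if (length(shared) && any(sa[shared] != sb[shared])) 5L
      else if (length(shared)) 3L
      else 4L
    de_a[i] <- paste(paste0(Da, ":", sa[Da]), collapse = ",")
    de_b[i] <- paste(paste0(Db, ":", sb[Db]), collapse = ",")
  }
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b, group = grp,
             de_a = de_a, de_b = de_b, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pearson correlation of expression profiles within pairs
#'
#' Correlation across all samples of the two copies' log2(FPKM + 1)
#' profiles; a zero-variance profile yields NA.
#'
#' @param expr expression matrix (log2 FPKM recommended), genes x samples.
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @return Numeric vector of correlations, one per pair.
#' @export
pair_correlation <- function(expr, pairs) {
  vapply(seq_len(nrow(pairs)), function(i) {
    a <- expr[pairs$gene_a[i], ]
    b <- expr[pairs$gene_b[i], ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
}
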