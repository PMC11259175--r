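#' Homology hit sets
#'
#' A `hit_set` wraps an all-versus-all similarity table (BLAST outfmt-6
#' dialect with two extra coverage columns) together with a flag recording
#' whether the top-five/coverage/E-value filter has been applied. Downstream
#' collinearity detection refuses unfiltered hit sets.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`, `identity`,
#'   `evalue`, `query_coverage`, `subject_coverage`, `bitscore` (coverages as
#'   percentages of the full sequence length aligned).
#' @param filtered logical; has [filter_hits()] been applied?
#' @return An object of class `hit_set`.
#' @export
hit_set <- function(hits, filtered = FALSE) {
  need <- c("query_id", "subject_id", "identity", "evalue",
            "query_coverage", "subject_coverage", "bitscore")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hits is missing columns: ", paste(miss, collapse = ", "))
  hits$query_id <- as.character(hits$query_id)
  hits$subject_id <- as.character(hits$subject_id)
  if (any(hits$evalue < 0)) stop("negative E-value")
  cov <- c(hits$query_coverage, hits$subject_coverage)
  if (any(cov < 0 | cov > 100)) stop("coverage outside [0, 100]")
  rownames(hits) <- NULL
  structure(list(hits = hits, filtered = isTRUE(filtered)), class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat("hit_set: ", nrow(x$hits), " hits, ",
      length(unique(x$hits$query_id)), " queries",
      if (x$filtered) " [filtered]" else " [unfiltered]", "\n", sep = "")
  invisible(x)
}

#' Read a BLAST tabular hit file
#'
#' Expects the 12 standard outfmt-6 columns plus two extra columns 13-14
#' giving query and subject coverage as percentages (alignment length over
#' full sequence length).
#'
#' @param path path to the tabular file.
#' @return An unfiltered [hit_set].
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c("query_id", "subject_id", "identity", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore", "query_coverage", "subject_coverage")
  raw <- read.delim(path, header = FALSE, quote = "")
  if (ncol(raw) < 14) stop("expected 14 columns (outfmt 6 + coverages), got ", ncol(raw))
  names(raw)[1:14] <- cols
  hit_set(raw[, c("query_id", "subject_id", "identity", "evalue",
                  "query_coverage", "subject_coverage", "bitscore")])
}

#' Filter homology hits to the top candidates per query
#'
#' Applies the canonical pre-synteny filter: self-hits are removed, hits must
#' satisfy query OR subject coverage above `min_cov_pct` and E-value at most
#' `max_evalue`, and each query retains at most `max_hits` subjects (smallest
#' E-value first, ties broken by descending bitscore then subject id). The
#' operation is idempotent.
#'
#' @param raw a [hit_set] (filtered or not).
#' @param max_hits maximum subjects retained per query (default 5).
#' @param min_cov_pct coverage threshold in percent, exceeded on at least one
#'   side (default 50).
#' @param max_evalue E-value ceiling (default 1e-5).
#' @return A filtered [hit_set].
#' @export
filter_hits <- function(raw, max_hits = 5, min_cov_pct = 50, max_evalue = 1e-5) {
  stopifnot(inherits(raw, "hit_set"))
  h <- raw$hits
  h <- h[h$query_id != h$subject_id, , drop = FALSE]
  keep <- (h$query_coverage > min_cov_pct | h$subject_coverage > min_cov_pct) &
    h$evalue <= max_evalue
  h <- h[keep, , drop = FALSE]
  if (nrow(h)) {
    ord <- order(h$query_id, h$evalue, -h$bitscore, h$subject_id)
    h <- h[ord, , drop = FALSE]
    idx <- stats::ave(seq_len(nrow(h)), h$query_id, FUN = seq_along)
    h <- h[idx <= max_hits, , drop = FALSE]
  }
  hit_set(h, filtered = TRUE)
}

## unordered unique gene pairs present in a hit set (either direction)
.hit_pairs <- function(hits) {
  h <- if (inherits(hits, "hit_set")) hits$hits else hits
  if (!nrow(h)) return(data.frame(gene_a = character(), gene_b = character()))
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  u <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(gene_a = a[u], gene_b = b[u], stringsAsFactors = FALSE)
}
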