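## Local nucleotide alignment with Karlin-Altschul significance.
## Scoring: match +1, mismatch -2, gap open 5, gap extension 2 (penalties);
## E = K * m * n * exp(-lambda * S) with the ungapped +1/-2 parameters
## (lambda = 1.332, K = 0.621).
.ka_lambda <- 1.332
.ka_K <- 0.621

.nt_submat <- function() {
  if (is.null(.ohno_cache$ntmat)) {
    letters <- c("A", "C", "G", "T", "N")
    m <- matrix(-2, 5, 5, dimnames = list(letters, letters))
    diag(m) <- 1
    m["N", ] <- m[, "N"] <- 0
    .ohno_cache$ntmat <- m
  }
  .ohno_cache$ntmat
}

## align a set of query sequences against one subject; returns per query the
## local score, E-value, and aligned span widths on each side
.local_align_stats <- function(queries, subject) {
  if (!length(queries))
    return(data.frame(score = numeric(), evalue = numeric(),
                      width_q = integer(), width_s = integer()))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(subject),
    substitutionMatrix = .nt_submat(), gapOpening = 5, gapExtension = 2,
    type = "local")
  sc <- Biostrings::score(aln)
  wq <- Biostrings::width(Biostrings::pattern(aln))
  ws <- Biostrings::width(Biostrings::subject(aln))
  m <- nchar(queries)
  n <- nchar(subject)
  ev <- .ka_K * m * n * exp(-.ka_lambda * pmax(sc, 0))
  data.frame(score = sc, evalue = ev, width_q = wq, width_s = ws)
}

#' Exon-level sequence conservation within a duplicate pair
#'
#' All exon-versus-exon local alignments between the two gene copies; an
#' exon pair matches when query or subject coverage exceeds `min_cov_pct`
#' and the Karlin-Altschul E-value is at most `max_evalue`. Matched exon
#' counts are resolved by maximum bipartite matching so each exon pairs with
#' at most one counterpart.
#'
#' @param exon_seqs_a,exon_seqs_b character vectors of exon sequences for
#'   the two copies (order along the gene).
#' @param min_cov_pct coverage threshold in percent (default 50).
#' @param max_evalue significance threshold (default 1e-20).
#' @param gene_a,gene_b optional ids carried into the result.
#' @return An object of class `exon_conservation`: `n_exons_a`, `n_exons_b`,
#'   `n_matched`, `shared_pct` (= 100 x 2 matched / (na + nb)) and
#'   `gain_loss` (= unmatched exons summed over both copies).
#' @export
exon_conservation <- function(exon_seqs_a, exon_seqs_b, min_cov_pct = 50,
                              max_evalue = 1e-20,
                              gene_a = NA_character_, gene_b = NA_character_) {
  na <- length(exon_seqs_a); nb <- length(exon_seqs_b)
  if (na == 0 || nb == 0) {
    warning("missing exon sequences for pair ", gene_a, "/", gene_b,
            "; skipped")
    return(NULL)
  }
  edges <- NULL
  for (j in seq_len(nb)) {
    st <- .local_align_stats(exon_seqs_a, exon_seqs_b[[j]])
    cov_a <- 100 * st$width_q / nchar(exon_seqs_a)
    cov_b <- 100 * st$width_s / nchar(exon_seqs_b[[j]])
    hit <- (cov_a > min_cov_pct | cov_b > min_cov_pct) &
      st$evalue <= max_evalue
    if (any(hit))
      edges <- rbind(edges, data.frame(a = which(hit), b = j,
                                       score = st$score[hit]))
  }
  n_matched <- if (is.null(edges)) 0L else .bipartite_match_size(edges, na, nb)
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 n_exons_a = na, n_exons_b = nb, n_matched = n_matched,
                 shared_pct = 100 * 2 * n_matched / (na + nb),
                 gain_loss = (na - n_matched) + (nb - n_matched)),
            class = "exon_conservation")
}

## maximum bipartite matching size over candidate edges (a-side indices
## 1..na, b-side 1..nb)
.bipartite_match_size <- function(edges, na, nb) {
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, nb)),
    edges = as.vector(rbind(edges$a, na + edges$b)))
  igraph::max_bipartite_match(g)$matching_size
}

## maximum-weight one-to-one assignment; returns data.frame(a, b) of matched
## index pairs
.bipartite_match_pairs <- function(edges, na, nb) {
  if (is.null(edges) || !nrow(edges))
    return(data.frame(a = integer(), b = integer()))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, nb)),
    edges = as.vector(rbind(edges$a, na + edges$b)))
  m <- igraph::max_bipartite_match(g, weights = edges$score)$matching
  a_names <- seq_len(na)
  matched_b <- m[seq_len(na)]
  ok <- !is.na(matched_b)
  data.frame(a = a_names[ok], b = as.integer(matched_b[ok]) - na)
}
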