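#' Extract flanking sequences around splice-junction events
#'
#' For each retained splice event (alternative acceptor/donor, alternative
#' exon, retained exon, skipped exon) the `flank_bp` regions immediately
#' upstream and downstream of the junction are extracted. Event `start` and
#' `end` are 1-based inclusive junction bounds; in BED (0-based half-open)
#' convention the flanks are `[start0 - flank, start0)` and
#' `[end0, end0 + flank)`. Flanks running off a scaffold edge are truncated
#' and flagged; events lying outside their scaffold are skipped with a
#' warning.
#'
#' @param events data.frame with `event_id`, `gene_id`, `scaffold`,
#'   `start`, `end`, `type`.
#' @param genome_seqs named character vector (or DNAStringSet) of scaffold
#'   sequences.
#' @param flank_bp flank width (default 300).
#' @return data.frame with the event columns plus `upstream_seq`,
#'   `downstream_seq`, `truncated`, and BED coordinates `up_start0`,
#'   `up_end0`, `down_start0`, `down_end0`.
#' @export
extract_junction_flanks <- function(events, genome_seqs, flank_bp = 300) {
  if (!nrow(events))
    return(cbind(events, data.frame(upstream_seq = character(),
                                    downstream_seq = character(),
                                    truncated = logical(),
                                    up_start0 = integer(), up_end0 = integer(),
                                    down_start0 = integer(),
                                    down_end0 = integer())))
  seqs <- if (methods::is(genome_seqs, "DNAStringSet"))
    setNames(as.character(genome_seqs), names(genome_seqs)) else genome_seqs
  len <- nchar(seqs)[events$scaffold]
  inside <- !is.na(len) & events$start >= 1 & events$end <= len &
    events$start <= events$end
  if (any(!inside))
    warning(sum(!inside), " event(s) outside scaffold bounds skipped")
  ev <- events[inside, , drop = FALSE]
  len <- len[inside]
  s0 <- ev$start - 1L
  e0 <- ev$end
  up_start0 <- pmax(s0 - flank_bp, 0L)
  up_end0 <- s0
  down_start0 <- e0
  down_end0 <- pmin(e0 + flank_bp, len)
  truncated <- (s0 - flank_bp < 0) | (e0 + flank_bp > len)
  scaf <- seqs[ev$scaffold]
  up <- substr(scaf, up_start0 + 1L, up_end0)
  dn <- substr(scaf, down_start0 + 1L, down_end0)
  out <- cbind(ev,
               data.frame(upstream_seq = unname(up),
                          downstream_seq = unname(dn),
                          truncated = unname(truncated),
                          up_start0 = unname(up_start0),
                          up_end0 = unname(up_end0),
                          down_start0 = unname(down_start0),
                          down_end0 = unname(down_end0),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Match splice junctions between two ohnolog copies
#'
#' A junction in copy A is conserved with one in copy B only when BOTH its
#' upstream and downstream flank sequences align significantly (E-value at
#' most `max_evalue`, local alignment) with the counterpart's. Candidate
#' pairs are resolved one-to-one by maximum combined alignment score
#' (weighted bipartite matching).
#'
#' Candidate pairs are pre-screened with an exact shared k-mer seed
#' (BLAST-style seeding) on the upstream flank before any alignment is
#' computed; a flank pair without a shared `seed_k`-mer cannot reach the
#' default E-value threshold at these flank lengths.
#'
#' @param flanks_a,flanks_b data.frames with `event_id`, `upstream_seq`,
#'   `downstream_seq` (e.g. from [extract_junction_flanks()] or the
#'   simulator).
#' @param max_evalue significance threshold per flank (default 1e-5).
#' @param seed_k word size of the seeding prescreen (default 11).
#' @return data.frame `event_a`, `event_b`, `score` of conserved junction
#'   pairs.
#' @export
match_junctions <- function(flanks_a, flanks_b, max_evalue = 1e-5,
                            seed_k = 11) {
  empty <- data.frame(event_a = character(), event_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  na <- nrow(flanks_a); nb <- nrow(flanks_b)
  if (!na || !nb) return(empty)
  kmers <- function(s) {
    n <- nchar(s)
    if (n < seed_k) return(character(0))
    unique(substring(s, 1:(n - seed_k + 1), seed_k:n))
  }
  km_a <- lapply(flanks_a$upstream_seq, kmers)
  km_b <- lapply(flanks_b$upstream_seq, kmers)
  edges <- NULL
  for (j in seq_len(nb)) {
    cand <- which(vapply(km_a, function(k) any(k %in% km_b[[j]]), logical(1)))
    if (!length(cand)) next
    up <- .local_align_stats(flanks_a$upstream_seq[cand],
                             flanks_b$upstream_seq[j])
    dn <- .local_align_stats(flanks_a$downstream_seq[cand],
                             flanks_b$downstream_seq[j])
    hit <- up$evalue <= max_evalue & dn$evalue <= max_evalue
    if (any(hit))
      edges <- rbind(edges, data.frame(a = cand[hit], b = j,
                                       score = up$score[hit] + dn$score[hit]))
  }
  if (is.null(edges)) return(empty)
  m <- .bipartite_match_pairs(edges, na, nb)
  key <- paste(edges$a, edges$b)
  sc <- setNames(edges$score, key)
  data.frame(event_a = flanks_a$event_id[m$a],
             event_b = flanks_b$event_id[m$b],
             score = unname(sc[paste(m$a, m$b)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Binary junction conservation profiles for a pair
#'
#' Builds equal-length binary vectors over the union of junction
#' identities: conserved junctions (matched between copies) are 1 in both
#' profiles; copy-exclusive junctions are 1 in one profile and 0 in the
#' other.
#'
#' @param events_a,events_b character vectors of event ids for each copy.
#' @param matches output of [match_junctions()].
#' @return List with binary vectors `profile_a`, `profile_b` and the
#'   identity labels `ids`.
#' @export
junction_profiles <- function(events_a, events_b, matches) {
  conserved_a <- matches$event_a
  conserved_b <- matches$event_b
  only_a <- setdiff(events_a, conserved_a)
  only_b <- setdiff(events_b, conserved_b)
  ids <- c(paste0("shared:", conserved_a),
           paste0("a:", only_a), paste0("b:", only_b))
  pa <- c(rep(1L, length(conserved_a)), rep(1L, length(only_a)),
          rep(0L, length(only_b)))
  pb <- c(rep(1L, length(conserved_b)), rep(0L, length(only_a)),
          rep(1L, length(only_b)))
  list(profile_a = pa, profile_b = pb, ids = ids)
}

#' Junction conservation statistics for one pair
#'
#' Kendall tau-b (with tie correction) between the binary profiles,
#' measuring conservation of the splice-junction repertoire; an exact
#' two-sided binomial test of junction-count divergence with k = junctions
#' present only in copy A, n = junctions present in exactly one copy, and
#' a symmetric null of 0.5. Constant profiles yield an undefined tau.
#'
#' @param profile_a,profile_b binary vectors of equal length >= 2.
#' @return List `kendall_tau`, `kendall_p`, `binom_k`, `binom_n`,
#'   `binom_p`, `conserved_fraction` (2 x conserved / (n_a + n_b)).
#' @export
junction_conservation_stats <- function(profile_a, profile_b) {
  a <- as.integer(profile_a); b <- as.integer(profile_b)
  if (length(a) != length(b)) stop("profiles differ in length")
  if (length(a) < 2) stop("profiles must have length >= 2")
  constant <- var(a) == 0 || var(b) == 0
  if (constant) {
    tau <- NA_real_; tau_p <- NA_real_
  } else {
    tau <- cor(a, b, method = "kendall")
    tau_p <- suppressWarnings(
      cor.test(a, b, method = "kendall")$p.value)
  }
  k <- sum(a == 1 & b == 0)
  n <- k + sum(a == 0 & b == 1)
  binom_p <- if (n > 0) binom.test(k, n, p = 0.5)$p.value else 1
  conserved <- sum(a == 1 & b == 1)
  list(kendall_tau = tau, kendall_p = tau_p,
       binom_k = k, binom_n = n, binom_p = binom_p,
       conserved_fraction = 2 * conserved / (sum(a) + sum(b)))
}
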