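#' @title Nei-Gojobori (NG86) Ka/Ks estimation
#' @description Counting-method estimator of synonymous (Ks) and
#' nonsynonymous (Ka) substitutions per site on a codon alignment, with
#' Jukes-Cantor multiple-hit correction. Synonymous site counts per codon
#' average the fraction of the three possible changes at each position that
#' preserve the amino acid; changes creating a stop codon count as
#' nonsynonymous. Differences between a codon pair are averaged over all
#' minimal single-nucleotide mutation paths, excluding paths that pass
#' through a stop codon (all-stop path sets fall back to counting stop steps
#' as nonsynonymous). Estimates with proportions of difference at or above
#' 3/4 are flagged saturated (the Jukes-Cantor log is undefined there) and
#' should be excluded from mixture modelling.
#' @name ng86-estimation
NULL

.codon_universe <- function() {
  gc <- Biostrings::GENETIC_CODE
  list(codons = names(gc), aa = gc, stops = names(gc)[gc == "*"])
}

## per-codon synonymous site count (sum over positions of syn fraction)
.ng86_sites_table <- function() {
  if (!is.null(.ohno_cache$sites)) return(.ohno_cache$sites)
  u <- .codon_universe()
  bases <- c("A", "C", "G", "T")
  s <- setNames(numeric(length(u$codons)), u$codons)
  for (cd in u$codons) {
    if (u$aa[[cd]] == "*") { s[cd] <- NA_real_; next }
    nt <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (b in setdiff(bases, nt[pos])) {
      alt <- nt; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (u$aa[[alt]] != "*" && u$aa[[alt]] == u$aa[[cd]])
        s[cd] <- s[cd] + 1 / 3
    }
  }
  .ohno_cache$sites <- s
  s
}

## expected syn/nonsyn difference counts for one codon pair, averaged over
## minimal mutation paths (stop-free paths preferred)
.ng86_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (!is.null(.ohno_cache$diffs[[key]])) return(.ohno_cache$diffs[[key]])
  u <- .codon_universe()
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  res <- c(sd = 0, nd = 0)
  if (length(pos)) {
    perms <- if (length(pos) == 1) list(pos) else {
      pm <- list()
      rec <- function(prefix, rest) {
        if (!length(rest)) { pm[[length(pm) + 1]] <<- prefix; return() }
        for (r in rest) rec(c(prefix, r), setdiff(rest, r))
      }
      rec(integer(0), pos)
      pm
    }
    walk <- function(order) {
      cur <- n1; sd <- 0; nd <- 0; via_stop <- FALSE
      for (p in order) {
        nxt <- cur; nxt[p] <- n2[p]
        a1 <- u$aa[[paste(cur, collapse = "")]]
        a2 <- u$aa[[paste(nxt, collapse = "")]]
        if (a2 == "*" || a1 == "*") via_stop <- TRUE
        if (a1 == a2 && a1 != "*") sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      list(sd = sd, nd = nd, via_stop = via_stop)
    }
    paths <- lapply(perms, walk)
    ok <- !vapply(paths, `[[`, logical(1), "via_stop")
    use <- if (any(ok)) paths[ok] else paths
    res <- c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
             nd = mean(vapply(use, `[[`, numeric(1), "nd")))
  }
  if (is.null(.ohno_cache$diffs)) .ohno_cache$diffs <- list()
  .ohno_cache$diffs[[key]] <- res
  res
}

#' NG86 Ka/Ks estimate from a codon alignment
#'
#' @param alignment a list with character vectors `codons_a` and `codons_b`
#'   of equal length (e.g. from [align_pair_codons()]); codons containing
#'   gaps or ambiguous bases are dropped from site counting. Stop codons are
#'   dropped with a warning.
#' @param gene_a,gene_b optional gene ids carried into the result.
#' @return An object of class `ks_estimate`: list with `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ks`, `Ka`, `omega` (NA when Ks is 0) and a `saturated`
#'   flag. Recommended input is at least 10 ungapped codons.
#' @export
ng86 <- function(alignment, gene_a = NA_character_, gene_b = NA_character_) {
  ca <- toupper(alignment$codons_a)
  cb <- toupper(alignment$codons_b)
  if (length(ca) != length(cb)) stop("codon vectors differ in length")
  u <- .codon_universe()
  ok <- ca %in% u$codons & cb %in% u$codons
  ca <- ca[ok]; cb <- cb[ok]
  stop_col <- u$aa[ca] == "*" | u$aa[cb] == "*"
  if (any(stop_col)) {
    warning(sum(stop_col), " codon column(s) containing stop codons dropped")
    ca <- ca[!stop_col]; cb <- cb[!stop_col]
  }
  nc <- length(ca)
  if (nc == 0) stop("no usable codon columns")
  sites <- .ng86_sites_table()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * nc - S
  d <- vapply(seq_len(nc), function(i) .ng86_pair_diffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 / 3 * p) else NA_real_
  Ks <- jc(ps); Ka <- jc(pn)
  saturated <- ps >= 0.75 || pn >= 0.75
  omega <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(gene_a = gene_a, gene_b = gene_b, n_codons = nc,
                 S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ks = Ks, Ka = Ka, omega = omega, saturated = saturated),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("ks_estimate (%s vs %s): %d codons, Ks = %s, Ka = %s%s\n",
              x$gene_a, x$gene_b, x$n_codons,
              format(x$Ks, digits = 4), format(x$Ka, digits = 4),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Globally aligns the protein translations (match +1, mismatch -1, gap open
#' 2, gap extension 0.5, all as penalties subtracted from the score) and
#' back-translates to codons. Trailing partial codons are trimmed with a
#' warning; a stop codon internal to a CDS is an error naming the gene.
#'
#' @param cds_a,cds_b coding sequences (character).
#' @param protein_a,protein_b optional translations; computed when missing.
#' @param gene_a,gene_b gene ids used in messages and in the result.
#' @return A list with `codons_a`, `codons_b` (gap codons `---`), the
#'   alignment `score`, and the gene ids.
#' @export
align_pair_codons <- function(cds_a, cds_b, protein_a = NULL, protein_b = NULL,
                              gene_a = "a", gene_b = "b") {
  prep <- function(cds, gene) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3 != 0) {
      warning("trailing partial codon trimmed for ", gene)
      cds <- substr(cds, 1, 3 * (nchar(cds) %/% 3))
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             if.fuzzy.codon = "X"))
    internal_stop <- grepl("\\*", substr(aa, 1, nchar(aa) - 1))
    if (internal_stop) stop("internal stop codon in CDS of ", gene)
    if (substr(aa, nchar(aa), nchar(aa)) == "*") {  # trim terminal stop
      aa <- substr(aa, 1, nchar(aa) - 1)
      codons <- codons[-length(codons)]
    }
    list(codons = codons, aa = aa)
  }
  a <- prep(cds_a, gene_a)
  b <- prep(cds_b, gene_b)
  if (!is.null(protein_a)) a$aa <- gsub("\\*$", "", toupper(protein_a))
  if (!is.null(protein_b)) b$aa <- gsub("\\*$", "", toupper(protein_b))

  if (is.null(.ohno_cache$aamat)) {
    letters <- Biostrings::AA_ALPHABET
    m <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- 1
    .ohno_cache$aamat <- m
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$aa), Biostrings::AAString(b$aa),
    substitutionMatrix = .ohno_cache$aamat,
    gapOpening = 2, gapExtension = 0.5, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ca <- cb <- character(length(pa))
  ia <- ib <- 0L
  for (i in seq_along(pa)) {
    if (pa[i] == "-") ca[i] <- "---" else { ia <- ia + 1L; ca[i] <- a$codons[ia] }
    if (pb[i] == "-") cb[i] <- "---" else { ib <- ib + 1L; cb[i] <- b$codons[ib] }
  }
  list(codons_a = ca, codons_b = cb, score = Biostrings::score(aln),
       gene_a = gene_a, gene_b = gene_b)
}

#' Ka/Ks table for a set of gene pairs
#'
#' Convenience wrapper: aligns and estimates NG86 Ka/Ks for each pair using
#' the CDS (and protein, when available) sequences stored in a catalog.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param catalog a [gene_catalog] carrying `cds` sequences.
#' @return data.frame with one row per pair: Sd/Nd/S/N, Ks, Ka, omega,
#'   saturated.
#' @export
ks_for_pairs <- function(pairs, catalog) {
  if (is.null(catalog$cds)) stop("catalog carries no CDS sequences")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (is.na(catalog$cds[ga]) || is.na(catalog$cds[gb])) return(NULL)
    aln <- align_pair_codons(catalog$cds[[ga]], catalog$cds[[gb]],
                             gene_a = ga, gene_b = gb)
    est <- ng86(aln, gene_a = ga, gene_b = gb)
    data.frame(gene_a = ga, gene_b = gb, n_codons = est$n_codons,
               S = est$S, N = est$N, Sd = est$Sd, Nd = est$Nd,
               Ks = est$Ks, Ka = est$Ka, omega = est$omega,
               saturated = est$saturated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_a = character(), gene_b = character(),
                      n_codons = integer(), S = numeric(), N = numeric(),
                      Sd = numeric(), Nd = numeric(), Ks = numeric(),
                      Ka = numeric(), omega = numeric(), saturated = logical())
  rownames(out) <- NULL
  out
}
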