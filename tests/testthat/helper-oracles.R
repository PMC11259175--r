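## Independent oracles and small fixture builders used across the suite.

## exhaustive best-chain score: enumerate every strictly monotone chain
## (both orientations) under the gap cap by depth-first search
oracle_best_chain_score <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0
  for (orient in c(1, -1)) {
    r2 <- orient * rb
    dfs <- function(i, score) {
      best <<- max(best, score)
      for (j in seq_len(n)) {
        ga <- ra[j] - ra[i] - 1
        gb <- r2[j] - r2[i] - 1
        if (ra[j] > ra[i] && r2[j] > r2[i] && ga <= max_gap && gb <= max_gap)
          dfs(j, score + 1 - max(0, ga + gb - 1))
      }
    }
    for (i in seq_len(n)) dfs(i, 1)
  }
  best
}

## brute-force NG86 difference counts for one codon pair: enumerate the
## explicit permutations of the differing positions, walk each path,
## excluding paths through stop codons (falling back to all paths when
## every path hits a stop)
oracle_codon_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  res <- lapply(perms(pos), function(ord) {
    cur <- n1
    sd <- nd <- 0
    stopped <- FALSE
    for (p in ord) {
      prv <- paste(cur, collapse = "")
      cur[p] <- n2[p]
      nxt <- paste(cur, collapse = "")
      if (code[[prv]] == "*" || code[[nxt]] == "*") stopped <- TRUE
      if (code[[prv]] == code[[nxt]] && code[[prv]] != "*")
        sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd, stopped = as.numeric(stopped))
  })
  m <- do.call(rbind, res)
  keep <- m[, "stopped"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(sd = mean(m[keep, "sd"]), nd = mean(m[keep, "nd"]))
}

## Gotoh global alignment score oracle: match +1 mismatch -1, a gap of
## length L costs 2 + 0.5 L (same accounting as the implementation's
## aligner, independently coded)
oracle_global_align_score <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  go <- 2; ge <- 0.5
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -go - ge * i
  for (j in seq_len(m)) Y[1, j + 1] <- -go - ge * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (a[i] == b[j]) 1 else -1
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## hand-rolled Benjamini-Hochberg ladder (independent of p.adjust)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## toy catalog: two scaffolds holding given gene id vectors in order
toy_catalog <- function(ids_by_scaffold) {
  rows <- lapply(names(ids_by_scaffold), function(sc) {
    ids <- ids_by_scaffold[[sc]]
    data.frame(gene_id = ids, scaffold = sc,
               start = seq(100, by = 1000, length.out = length(ids)),
               end = seq(600, by = 1000, length.out = length(ids)),
               strand = "+")
  })
  gene_catalog(do.call(rbind, rows))
}

## passing hit rows between given gene id pairs
toy_hits <- function(qs, ss, evalue = 1e-30) {
  n <- length(qs)
  hit_set(data.frame(query_id = qs, subject_id = ss,
                     identity = rep(90, n),
                     evalue = rep_len(evalue, n),
                     query_coverage = rep(90, n),
                     subject_coverage = rep(90, n),
                     bitscore = rep(200, n)))
}

## standard 4-condition sample sheet (validated: includes `condition`)
toy_samples <- function(nrep = 3) {
  cells <- c("free_28", "free_34", "symbiotic_28", "symbiotic_34")
  validate_sample_sheet(data.frame(
    sample = paste0(rep(cells, each = nrep), "_r", seq_len(nrep)),
    lifestyle = rep(c("free", "symbiotic"), each = 2 * nrep),
    temperature = rep(c(28, 34, 28, 34), each = nrep),
    replicate = rep(seq_len(nrep), 4)))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

.random_test_protein <- function(n) {
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  sample(aas, n, replace = TRUE)
}

.backtranslate_test <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) names(code)[code == a][1], character(1)),
        collapse = "")
}
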