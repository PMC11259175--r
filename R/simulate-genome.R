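#' Parameters for the post-WGD genome simulator
#'
#' Defaults emulate a compact haploid genome that underwent a recent
#' whole-genome duplication: high retention of duplicated copies, a narrow
#' low-Ks divergence peak for WGD pairs, a small admixture of tandem,
#' proximal and dispersed small-scale duplicates diverging at a much older
#' background Ks.
#'
#' @param n_ancestral_genes genes in the pre-WGD genome (default 200).
#' @param n_scaffolds ancestral scaffolds (default 4); each gains a
#'   duplicated counterpart.
#' @param wgd_retention probability a duplicated copy survives (default
#'   0.85).
#' @param tandem_rate,proximal_rate,dispersed_rate per-gene probabilities
#'   of an additional small-scale duplication (defaults 0.03, 0.02, 0.03).
#' @param ks_peak_mean,ks_peak_sd target synonymous divergence of WGD pairs
#'   (defaults 0.2, 0.05), the recent-WGD peak.
#' @param background_ks_mean divergence of small-scale paralogs (default
#'   1.0).
#' @param codons_per_gene CDS length in codons (default 100).
#' @param exons_per_gene integer range of exons per gene (default c(2, 6)).
#' @param seed RNG seed.
#' @return A validated parameter list of class `genome_sim_params`.
#' @export
genome_sim_params <- function(n_ancestral_genes = 200, n_scaffolds = 4,
                              wgd_retention = 0.85, tandem_rate = 0.03,
                              proximal_rate = 0.02, dispersed_rate = 0.03,
                              ks_peak_mean = 0.2, ks_peak_sd = 0.05,
                              background_ks_mean = 1.0,
                              codons_per_gene = 100,
                              exons_per_gene = c(2, 6), seed = 1) {
  p <- as.list(environment())
  probs <- c(wgd_retention, tandem_rate, proximal_rate, dispersed_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (tandem_rate + proximal_rate + dispersed_rate > 1)
    stop("small-scale duplication rates sum above 1")
  if (ks_peak_mean <= 0 || ks_peak_sd <= 0 || background_ks_mean <= 0)
    stop("Ks parameters must be positive")
  if (codons_per_gene < 10) stop("codons_per_gene must be >= 10")
  structure(p, class = "genome_sim_params")
}

## codon alternatives one substitution away, cached
.codon_alts <- function() {
  if (!is.null(.ohno_cache$alts)) return(.ohno_cache$alts)
  u <- .codon_universe()
  bases <- c("A", "C", "G", "T")
  syn <- nonsyn <- vector("list", length(u$codons))
  names(syn) <- names(nonsyn) <- u$codons
  for (cd in u$codons) {
    if (u$aa[[cd]] == "*") next
    nt <- strsplit(cd, "")[[1]]
    s <- n <- character(0)
    for (pos in 1:3) for (b in setdiff(bases, nt[pos])) {
      alt <- nt; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (u$aa[[alt]] == "*") next
      if (u$aa[[alt]] == u$aa[[cd]]) s <- c(s, alt) else n <- c(n, alt)
    }
    syn[[cd]] <- s; nonsyn[[cd]] <- n
  }
  .ohno_cache$alts <- list(syn = syn, nonsyn = nonsyn)
  .ohno_cache$alts
}

.random_cds <- function(n_codons) {
  u <- .codon_universe()
  sense <- setdiff(u$codons, u$stops)
  sample(sense, n_codons, replace = TRUE)
}

## mutate a codon vector so that NG86 Ks/Ka land near the targets: apply
## single synonymous (nonsynonymous) substitutions at distinct codons,
## count set by inverting the Jukes-Cantor correction
.mutate_codons <- function(codons, ks_target, ka_target) {
  alts <- .codon_alts()
  sites <- .ng86_sites_table()
  S <- sum(sites[codons])
  N <- 3 * length(codons) - S
  p_from_k <- function(k) 0.75 * (1 - exp(-4 / 3 * k))
  n_syn <- round(min(p_from_k(ks_target), 0.70) * S)
  n_non <- round(min(p_from_k(ka_target), 0.70) * N)
  out <- codons
  can_syn <- which(lengths(alts$syn[out]) > 0)
  pick_syn <- sample(can_syn, min(n_syn, length(can_syn)))
  for (i in pick_syn) out[i] <- sample(alts$syn[[out[i]]], 1)
  can_non <- setdiff(which(lengths(alts$nonsyn[out]) > 0), pick_syn)
  pick_non <- sample(can_non, min(n_non, length(can_non)))
  for (i in pick_non) out[i] <- sample(alts$nonsyn[[out[i]]], 1)
  out
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a post-WGD genome with known ground truth
#'
#' Generates an ancestral gene complement, duplicates every scaffold (the
#' WGD), prunes duplicated copies at `1 - wgd_retention` with rank
#' compaction, plants tandem/proximal/dispersed small-scale duplicates, and
#' mutates duplicate CDSs so WGD-pair synonymous divergence concentrates at
#' `ks_peak_mean` while small-scale paralogs sit at `background_ks_mean`.
#' Collinearity of duplicated segments is preserved, so surviving WGD pairs
#' form anchor chains; a homology hit table with passing E-values and
#' coverages is emitted for every true duplicate pair. Deterministic under
#' a fixed seed.
#'
#' @param params a [genome_sim_params] list.
#' @return A list with `catalog` (a [gene_catalog] with CDS and protein
#'   sequences), `hits` (an unfiltered [hit_set]), `truth` (per-gene
#'   `gene_class`, per-pair `pairs` with relation and target Ks), and
#'   `scaffold_seqs` (named character).
#' @export
simulate_wgd_genome <- function(params = genome_sim_params()) {
  stopifnot(inherits(params, "genome_sim_params"))
  set.seed(params$seed)
  n <- params$n_ancestral_genes
  nsc <- params$n_scaffolds
  scafs <- sprintf("sc%02d", seq_len(nsc))
  anc_scaf <- scafs[ceiling(seq_len(n) / ceiling(n / nsc))]
  ids <- sprintf("g%04d", seq_len(n))

  cds <- lapply(seq_len(n), function(i) .random_cds(params$codons_per_gene))
  names(cds) <- ids

  ## WGD: duplicated copy per gene, surviving with wgd_retention
  wgd_alive <- runif(n) < params$wgd_retention
  wgd_ids <- paste0(ids, "w")
  wgd_ks <- pmax(rnorm(n, params$ks_peak_mean, params$ks_peak_sd), 0.01)
  wgd_cds <- vector("list", n)
  for (i in which(wgd_alive))
    wgd_cds[[i]] <- .mutate_codons(cds[[i]], wgd_ks[i], 0.2 * wgd_ks[i])

  ## small-scale duplications on the ancestral copies
  rates <- c(none = 1 - params$tandem_rate - params$proximal_rate -
               params$dispersed_rate,
             tandem = params$tandem_rate, proximal = params$proximal_rate,
             dispersed = params$dispersed_rate)
  ssd_type <- sample(names(rates), n, replace = TRUE, prob = rates)
  ssd_ids <- paste0(ids, substr(ssd_type, 1, 1))
  ssd_ks <- pmax(rnorm(n, params$background_ks_mean,
                       0.15 * params$background_ks_mean), 0.05)
  ssd_cds <- vector("list", n)
  for (i in which(ssd_type != "none"))
    ssd_cds[[i]] <- .mutate_codons(cds[[i]], ssd_ks[i], 0.2 * ssd_ks[i])

  ## assemble gene order per scaffold
  order_by_scaf <- split(seq_len(n), anc_scaf)
  gene_order <- list()
  for (sc in scafs) {
    base <- order_by_scaf[[sc]]
    lst <- as.list(ids[base])
    ## tandem: insert right after the base copy
    for (i in rev(base[ssd_type[base] == "tandem"])) {
      at <- which(vapply(lst, identical, logical(1), ids[i]))
      lst <- append(lst, ssd_ids[i], after = at)
    }
    ## proximal: insert 2-19 positions downstream of the base copy
    for (i in base[ssd_type[base] == "proximal"]) {
      at <- which(vapply(lst, identical, logical(1), ids[i]))
      lst <- append(lst, ssd_ids[i],
                    after = min(at + sample(2:19, 1), length(lst)))
    }
    gene_order[[sc]] <- unlist(lst)
  }
  ## dispersed: random position on a random different scaffold
  for (i in which(ssd_type == "dispersed")) {
    target <- if (nsc > 1) sample(setdiff(scafs, anc_scaf[i]), 1) else scafs
    at <- sample(0:length(gene_order[[target]]), 1)
    gene_order[[target]] <- append(gene_order[[target]], ssd_ids[i],
                                   after = at)
  }
  ## WGD scaffolds: surviving copies in ancestral order (rank compaction)
  for (sc in scafs) {
    base <- order_by_scaf[[sc]]
    alive <- base[wgd_alive[base]]
    if (length(alive)) gene_order[[paste0(sc, "w")]] <- wgd_ids[alive]
  }

  all_cds <- c(cds,
               setNames(wgd_cds[wgd_alive], wgd_ids[wgd_alive]),
               setNames(ssd_cds[ssd_type != "none"],
                        ssd_ids[ssd_type != "none"]))

  ## coordinates, exon structure, scaffold sequences
  genes_rows <- list(); exon_rows <- list(); scaffold_seqs <- character(0)
  ex_rng <- params$exons_per_gene
  for (sc in names(gene_order)) {
    pos <- 0L
    chunks <- character(0)
    for (gid in gene_order[[sc]]) {
      gap <- sample(100:300, 1)
      chunks <- c(chunks, .random_dna(gap))
      pos <- pos + gap
      cdsv <- all_cds[[gid]]
      L <- 3L * length(cdsv)
      n_ex <- sample(ex_rng[1]:ex_rng[2], 1)
      cuts <- if (n_ex > 1) sort(sample(seq_len(L - 1), n_ex - 1)) else integer(0)
      ex_len <- diff(c(0L, cuts, L))
      cds_nt <- paste(cdsv, collapse = "")
      gstart <- pos + 1L
      off <- 0L
      for (e in seq_len(n_ex)) {
        estart <- pos + 1L
        eend <- pos + ex_len[e]
        exon_rows[[length(exon_rows) + 1L]] <-
          data.frame(gene_id = gid, start = estart, end = eend)
        chunks <- c(chunks, substr(cds_nt, off + 1L, off + ex_len[e]))
        off <- off + ex_len[e]
        pos <- eend
        if (e < n_ex) {
          ilen <- sample(50:150, 1)
          chunks <- c(chunks, .random_dna(ilen))
          pos <- pos + ilen
        }
      }
      genes_rows[[length(genes_rows) + 1L]] <-
        data.frame(gene_id = gid, scaffold = sc, start = gstart, end = pos,
                   strand = "+")
    }
    scaffold_seqs[sc] <- paste(chunks, collapse = "")
  }
  genes <- do.call(rbind, genes_rows)
  exons <- do.call(rbind, exon_rows)

  cds_str <- vapply(all_cds, paste, character(1), collapse = "")
  prot <- vapply(cds_str, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))), character(1))
  catalog <- gene_catalog(genes, exons, genome_id = "sim", cds = cds_str,
                          protein = prot)

  ## truth: duplicate pairs and per-gene classes (precedence wgd > tandem >
  ## proximal > dispersed > singleton)
  pair_rows <- list()
  for (i in which(wgd_alive))
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(gene_a = ids[i], gene_b = wgd_ids[i], relation = "wgd",
                 ks_target = wgd_ks[i])
  for (i in which(ssd_type != "none"))
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(gene_a = ids[i], gene_b = ssd_ids[i],
                 relation = ssd_type[i], ks_target = ssd_ks[i])
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(gene_a = character(), gene_b = character(),
               relation = character(), ks_target = numeric())

  cls <- setNames(rep("singleton", length(all_cds)), names(all_cds))
  for (i in which(ssd_type != "none")) {
    cls[ssd_ids[i]] <- ssd_type[i]
    cls[ids[i]] <- ssd_type[i]
  }
  for (i in which(wgd_alive)) {
    cls[ids[i]] <- "wgd_segmental"
    cls[wgd_ids[i]] <- "wgd_segmental"
  }
  truth <- list(
    gene_class = data.frame(gene_id = names(cls), class = unname(cls),
                            stringsAsFactors = FALSE),
    pairs = pairs, params = params)

  ## homology hits within each family (all duplicate pairs, plus the
  ## transitive pairs when a gene has both a WGD and a small-scale copy)
  fam <- lapply(seq_len(n), function(i) {
    m <- ids[i]
    if (wgd_alive[i]) m <- c(m, wgd_ids[i])
    if (ssd_type[i] != "none") m <- c(m, ssd_ids[i])
    m
  })
  hit_rows <- list()
  for (m in fam[lengths(fam) > 1]) {
    cmb <- utils::combn(m, 2)
    for (ci in seq_len(ncol(cmb))) {
      L <- nchar(cds_str[[cmb[1, ci]]])
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_id = cmb[1, ci], subject_id = cmb[2, ci],
        identity = round(runif(1, 80, 99), 1),
        evalue = 10^-runif(1, 40, 120),
        query_coverage = round(runif(1, 85, 100), 1),
        subject_coverage = round(runif(1, 85, 100), 1),
        bitscore = round(1.9 * L * runif(1, 0.8, 1)))
    }
  }
  hits <- if (length(hit_rows)) hit_set(do.call(rbind, hit_rows)) else
    hit_set(data.frame(query_id = character(), subject_id = character(),
                       identity = numeric(), evalue = numeric(),
                       query_coverage = numeric(),
                       subject_coverage = numeric(), bitscore = numeric()))

  list(catalog = catalog, hits = hits, truth = truth,
       scaffold_seqs = scaffold_seqs)
}
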