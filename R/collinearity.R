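#' Collinear gene-block detection
#'
#' Detects collinear blocks by dynamic-programming chaining of homology
#' anchors over gene-rank coordinates, per scaffold pair. A chain extends
#' between two anchors when the gene rank is strictly monotone on both sides
#' (increasing, or decreasing on side b for inverted blocks) and the number
#' of skipped genes on each side is at most `max_gene_gap`. Chain score is
#' the anchor count minus a gap penalty of one per skipped gene beyond the
#' first at each link. Chains are extracted greedily by descending score and
#' an anchor is assigned to at most one block; chains with fewer than
#' `min_block_genes` anchors are discarded. A block of at least five genes
#' conserved in order and orientation is the classical evidence for
#' segmental duplication or WGD.
#'
#' @param catalog a [gene_catalog] (side a; also side b in `intra` mode).
#' @param hits a filtered [hit_set]; an unfiltered set is a hard error.
#' @param min_block_genes minimum anchors per reported block (default 5).
#' @param max_gene_gap maximum genes skipped between consecutive anchors on
#'   either side (default 25, the MCScanX default).
#' @param mode `"intra"` (duplicated blocks within one genome) or `"inter"`
#'   (syntenic blocks between two genomes).
#' @param catalog_b second [gene_catalog], required in `inter` mode.
#' @return A data.frame of anchor pairs with columns `block_id`, `gene_a`,
#'   `gene_b`, `scaffold_a`, `scaffold_b`, `orientation` (`same`/`inverted`)
#'   and `score`, of class `collinear_blocks`.
#' @export
detect_collinear_blocks <- function(catalog, hits, min_block_genes = 5,
                                    max_gene_gap = 25,
                                    mode = c("intra", "inter"),
                                    catalog_b = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(catalog, "gene_catalog"), inherits(hits, "hit_set"))
  if (!hits$filtered)
    stop("hit set must be filtered with filter_hits() before chaining")
  if (mode == "inter" && is.null(catalog_b))
    stop("inter mode requires catalog_b")
  cat_b <- if (mode == "intra") catalog else catalog_b

  ga <- catalog$genes
  gb <- cat_b$genes
  pos_a <- data.frame(scaffold = ga$scaffold, rank = ga$rank,
                      row.names = ga$gene_id)
  pos_b <- data.frame(scaffold = gb$scaffold, rank = gb$rank,
                      row.names = gb$gene_id)

  p <- .hit_pairs(hits)
  if (mode == "inter") {
    ## orient pairs so side a is from catalog, side b from catalog_b
    a_in_a <- p$gene_a %in% rownames(pos_a) & p$gene_b %in% rownames(pos_b)
    b_in_a <- p$gene_b %in% rownames(pos_a) & p$gene_a %in% rownames(pos_b)
    swap <- !a_in_a & b_in_a
    tmp <- p$gene_a[swap]; p$gene_a[swap] <- p$gene_b[swap]; p$gene_b[swap] <- tmp
    p <- p[(a_in_a | b_in_a), , drop = FALSE]
  } else {
    p <- p[p$gene_a %in% rownames(pos_a) & p$gene_b %in% rownames(pos_a), , drop = FALSE]
  }
  if (!nrow(p)) return(.empty_blocks())

  anchors <- data.frame(
    gene_a = p$gene_a, gene_b = p$gene_b,
    sa = pos_a[p$gene_a, "scaffold"], sb = pos_b[p$gene_b, "scaffold"],
    ra = pos_a[p$gene_a, "rank"], rb = pos_b[p$gene_b, "rank"],
    stringsAsFactors = FALSE)
  if (mode == "intra") {
    ## canonical orientation of intra scaffold pairs; on one scaffold keep
    ## the upper triangle so a block and its mirror are counted once
    flip <- anchors$sa > anchors$sb |
      (anchors$sa == anchors$sb & anchors$ra > anchors$rb)
    anchors[flip, c("gene_a", "gene_b", "sa", "sb", "ra", "rb")] <-
      anchors[flip, c("gene_b", "gene_a", "sb", "sa", "rb", "ra")]
  }

  out <- list()
  bid <- 0L
  for (key in sort(unique(paste(anchors$sa, anchors$sb, sep = "\r")))) {
    an <- anchors[paste(anchors$sa, anchors$sb, sep = "\r") == key, , drop = FALSE]
    an <- an[order(an$ra, an$rb, an$gene_a, an$gene_b), , drop = FALSE]
    repeat {
      if (nrow(an) < min_block_genes) break
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- .chain_dp(an$ra, if (orient == "same") an$rb else -an$rb,
                        max_gene_gap)
        if (is.null(best) || ch$score > best$score) {
          best <- ch; best$orientation <- orient
        }
      }
      if (length(best$idx) < min_block_genes) break
      bid <- bid + 1L
      sel <- an[best$idx, , drop = FALSE]
      out[[bid]] <- data.frame(
        block_id = bid, gene_a = sel$gene_a, gene_b = sel$gene_b,
        scaffold_a = sel$sa, scaffold_b = sel$sb,
        orientation = best$orientation, score = best$score,
        stringsAsFactors = FALSE)
      an <- an[-best$idx, , drop = FALSE]
    }
  }
  if (!length(out)) return(.empty_blocks())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("collinear_blocks", "data.frame")
  res
}

.empty_blocks <- function() {
  res <- data.frame(block_id = integer(), gene_a = character(),
                    gene_b = character(), scaffold_a = character(),
                    scaffold_b = character(), orientation = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  class(res) <- c("collinear_blocks", "data.frame")
  res
}

## best-scoring strictly increasing chain (both coordinates) with gap cap;
## score = anchors - sum over links of max(0, skipped_a + skipped_b - 1).
## Deterministic tie-breaks: higher score, then earlier end index; among
## predecessors higher dp, then smaller combined gap, then earlier index.
.chain_dp <- function(ra, rb, max_gap) {
  n <- length(ra)
  dp <- rep(1, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- seq_len(i - 1L)
    ga <- ra[i] - ra[j] - 1L
    gb <- rb[i] - rb[j] - 1L
    ok <- ra[j] < ra[i] & rb[j] < rb[i] & ga <= max_gap & gb <= max_gap
    if (!any(ok)) next
    pen <- pmax(0, ga + gb - 1)
    cand <- dp[j] + 1 - pen
    cand[!ok] <- -Inf
    m <- max(cand)
    if (m > dp[i]) {
      ties <- which(cand == m)
      best <- ties[order((ga + gb)[ties], ties)][1]
      dp[i] <- m
      prev[i] <- best
    }
  }
  end <- which(dp == max(dp))[1]
  idx <- integer(0)
  k <- end
  while (k > 0L) { idx <- c(k, idx); k <- prev[k] }
  list(idx = idx, score = dp[end])
}

#' Classify genes into the five duplication categories
#'
#' Every gene in the catalog receives exactly one category, by precedence:
#' `wgd_segmental` (anchor in at least one collinear block) beats `tandem`
#' (a homology partner at the adjacent rank on the same scaffold), beats
#' `proximal` (a partner within `proximal_max_gap` ranks on the same
#' scaffold), beats `dispersed` (any remaining partner), beats `singleton`
#' (no partners). "Separated by" is measured as the difference in gene rank:
#' proximal means rank difference at most `proximal_max_gap`, dispersed more
#' than that or a different scaffold.
#'
#' @param catalog a [gene_catalog].
#' @param hits a filtered [hit_set].
#' @param blocks intra-genome blocks from [detect_collinear_blocks()].
#' @param proximal_max_gap rank-distance bound for proximal duplicates
#'   (default 20).
#' @return data.frame with columns `gene_id`, `category`.
#' @export
classify_duplicates <- function(catalog, hits, blocks, proximal_max_gap = 20) {
  stopifnot(inherits(catalog, "gene_catalog"))
  g <- catalog$genes
  cat_out <- setNames(rep("singleton", nrow(g)), g$gene_id)

  p <- .hit_pairs(hits)
  p <- p[p$gene_a %in% g$gene_id & p$gene_b %in% g$gene_id, , drop = FALSE]
  if (nrow(p)) {
    scaf <- setNames(g$scaffold, g$gene_id)
    rank <- setNames(g$rank, g$gene_id)
    same <- scaf[p$gene_a] == scaf[p$gene_b]
    rd <- abs(rank[p$gene_a] - rank[p$gene_b])
    lvl <- ifelse(same & rd == 1, 3L,                     # tandem
           ifelse(same & rd <= proximal_max_gap, 2L, 1L)) # proximal / dispersed
    for (side in c("gene_a", "gene_b")) {
      best <- tapply(lvl, p[[side]], max)
      cur <- c("dispersed", "proximal", "tandem")[pmax(best, 1L)]
      prev <- cat_out[names(best)]
      ord <- c(singleton = 0L, dispersed = 1L, proximal = 2L, tandem = 3L)
      upgrade <- ord[cur] > ord[prev]
      cat_out[names(best)[upgrade]] <- cur[upgrade]
    }
  }
  if (nrow(blocks)) {
    in_block <- unique(c(blocks$gene_a, blocks$gene_b))
    cat_out[intersect(in_block, names(cat_out))] <- "wgd_segmental"
  }
  data.frame(gene_id = g$gene_id, category = unname(cat_out[g$gene_id]),
             stringsAsFactors = FALSE)
}

#' Extract ohnolog pairs from intra-genome collinear blocks
#'
#' One pair per anchor, deduplicated as unordered pairs (a pair appearing in
#' two blocks is reported once, with the first block id).
#'
#' @param blocks blocks from [detect_collinear_blocks()] in `intra` mode.
#' @return data.frame with columns `gene_a`, `gene_b` (lexicographically
#'   ordered), `block_id`.
#' @export
extract_ohnolog_pairs <- function(blocks) {
  if (!nrow(blocks))
    return(data.frame(gene_a = character(), gene_b = character(),
                      block_id = integer(), stringsAsFactors = FALSE))
  a <- pmin(blocks$gene_a, blocks$gene_b)
  b <- pmax(blocks$gene_a, blocks$gene_b)
  u <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(gene_a = a[u], gene_b = b[u], block_id = blocks$block_id[u],
             stringsAsFactors = FALSE)
}

#' Summarise collinear blocks
#'
#' Headline statistics: block count, distinct genes implicated in blocks and
#' their percentage of the catalog (two decimals, half-up). In `inter` mode
#' (when `catalog_b` is given) the per-genome syntenic gene counts are
#' reported, and, when duplication classes are supplied, the percentage of
#' syntenic genes classed as ohnologs.
#'
#' @param blocks a `collinear_blocks` data.frame.
#' @param catalog the side-a [gene_catalog].
#' @param catalog_b optional side-b catalog (inter mode).
#' @param classes_a,classes_b optional outputs of [classify_duplicates()].
#' @return A list of summary statistics.
#' @export
block_summary <- function(blocks, catalog, catalog_b = NULL,
                          classes_a = NULL, classes_b = NULL) {
  genes_a <- unique(blocks$gene_a)
  genes_b <- unique(blocks$gene_b)
  n_total_a <- nrow(catalog$genes)
  res <- list(
    n_blocks = length(unique(blocks$block_id)),
    n_genes_in_blocks = length(unique(c(
      genes_a, if (is.null(catalog_b)) genes_b))),
    n_total_genes = n_total_a)
  res$pct_genes_in_blocks <- if (n_total_a > 0)
    report_percentages(res$n_genes_in_blocks, n_total_a) else 0
  if (!is.null(catalog_b)) {
    res$n_syntenic_genes_a <- length(genes_a)
    res$n_syntenic_genes_b <- length(genes_b)
    pct_ohno <- function(genes, classes) {
      if (is.null(classes) || !length(genes)) return(NA_real_)
      cl <- classes$category[match(genes, classes$gene_id)]
      report_percentages(sum(cl == "wgd_segmental", na.rm = TRUE), length(genes))
    }
    res$pct_ohnologs_in_synteny_a <- pct_ohno(genes_a, classes_a)
    res$pct_ohnologs_in_synteny_b <- pct_ohno(genes_b, classes_b)
  }
  res
}
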