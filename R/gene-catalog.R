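#' Gene catalogs
#'
#' A `gene_catalog` is the coordinate backbone used throughout the package:
#' an ordered set of gene models per scaffold, with exon structure, optional
#' CDS/protein sequences and summed exon lengths (used for FPKM). Coordinates
#' follow the GFF3 convention (1-based, inclusive); every internal interval
#' computation converts to 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `scaffold`, `start`,
#'   `end`, `strand`; a `rank` column (0-based order along the scaffold by
#'   ascending start, ties broken by `gene_id`) is recomputed.
#' @param exons data.frame with columns `gene_id`, `start`, `end` (may be
#'   empty; genes without exon rows are treated as single-exon spans).
#' @param genome_id single string naming the genome/isolate.
#' @param cds,protein optional named character vectors of sequences keyed by
#'   `gene_id`.
#'
#' @return An object of class `gene_catalog`: a list with elements `genome_id`,
#'   `genes` (with `rank` and `length` columns), `exons`, `cds`, `protein`.
#' @export
gene_catalog <- function(genes, exons = NULL, genome_id = "genome",
                         cds = NULL, protein = NULL) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "scaffold", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes is missing columns: ", paste(miss, collapse = ", "))
  genes$gene_id <- as.character(genes$gene_id)
  genes$scaffold <- as.character(genes$scaffold)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in catalog: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (any(genes$end < genes$start)) stop("gene with end < start")
  if (is.null(exons))
    exons <- data.frame(gene_id = character(), start = integer(), end = integer())
  exons$gene_id <- as.character(exons$gene_id)
  bad <- setdiff(exons$gene_id, genes$gene_id)
  if (length(bad)) stop("exon rows reference unknown gene_id: ", bad[1])

  ## rank per scaffold: ascending start, ties by gene_id
  ord <- order(genes$scaffold, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- as.integer(
    stats::ave(seq_len(nrow(genes)), genes$scaffold,
               FUN = function(i) seq_along(i) - 1L))
  rownames(genes) <- NULL

  ## summed exon length; genes without exon rows fall back to the gene span
  len <- genes$end - genes$start + 1L
  names(len) <- genes$gene_id
  if (nrow(exons)) {
    exlen <- tapply(exons$end - exons$start + 1L, exons$gene_id, sum)
    len[names(exlen)] <- as.integer(exlen)
  }
  genes$length <- as.integer(len[genes$gene_id])
  if (any(genes$length <= 0)) stop("non-positive gene length")

  structure(list(genome_id = genome_id, genes = genes, exons = exons,
                 cds = cds, protein = protein),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("gene_catalog '", x$genome_id, "': ", nrow(x$genes), " genes on ",
      length(unique(x$genes$scaffold)), " scaffold(s), ",
      nrow(x$exons), " exon records",
      if (!is.null(x$cds)) ", with CDS sequences" else "", "\n", sep = "")
  invisible(x)
}

#' Parse gene positions from a GFF3-like file
#'
#' Reads `gene` and `exon` features from a 9-column GFF3-style table and
#' builds a [gene_catalog]. Rows with `end < start` are rejected with a
#' warning; a duplicated gene ID is a hard error. Exons are attached to their
#' parent gene via the `Parent=` attribute.
#'
#' @param path path to the GFF3-like file.
#' @param genome_id genome identifier stored in the catalog.
#' @return A [gene_catalog].
#' @export
parse_gene_positions <- function(path, genome_id = "genome") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               colClasses = "character", quote = ""),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0)
    return(gene_catalog(
      data.frame(gene_id = character(), scaffold = character(),
                 start = integer(), end = integer(), strand = character()),
      genome_id = genome_id))
  if (ncol(raw) < 9) stop("expected 9 GFF3 columns, got ", ncol(raw))
  names(raw)[1:9] <- c("seqid", "source", "type", "start", "end",
                       "score", "strand", "phase", "attributes")
  raw$start <- suppressWarnings(as.integer(raw$start))
  raw$end <- suppressWarnings(as.integer(raw$end))
  bad <- is.na(raw$start) | is.na(raw$end) | raw$end < raw$start
  if (any(bad)) {
    warning(sum(bad), " row(s) with malformed coordinates rejected")
    raw <- raw[!bad, , drop = FALSE]
  }
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]+"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "=[^;]+"), attrs))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  g <- raw[raw$type == "gene", , drop = FALSE]
  e <- raw[raw$type == "exon", , drop = FALSE]
  gid <- attr_field(g$attributes, "ID")
  if (anyNA(gid)) stop("gene row without ID attribute")
  if (anyDuplicated(gid))
    stop("duplicate gene_id: ", gid[duplicated(gid)][1])
  genes <- data.frame(gene_id = gid, scaffold = g$seqid,
                      start = g$start, end = g$end, strand = g$strand)
  exons <- data.frame(gene_id = attr_field(e$attributes, "Parent"),
                      start = e$start, end = e$end)
  exons <- exons[!is.na(exons$gene_id) & exons$gene_id %in% genes$gene_id, , drop = FALSE]
  gene_catalog(genes, exons, genome_id = genome_id)
}

#' Write a gene catalog as GFF3
#'
#' Inverse of [parse_gene_positions()]; the write/parse round trip reproduces
#' coordinates, strands and ranks exactly.
#'
#' @param catalog a [gene_catalog].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(catalog, path) {
  g <- catalog$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tohnoscope\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$scaffold, g$start, g$end, g$strand, g$gene_id))
  e <- catalog$exons
  if (nrow(e)) {
    scaf <- setNames(g$scaffold, g$gene_id)
    str <- setNames(g$strand, g$gene_id)
    lines <- c(lines,
               sprintf("%s\tohnoscope\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       scaf[e$gene_id], e$start, e$end, str[e$gene_id], e$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}
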