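#' Enzymes uniquely retained as ohnologs or singletons, per pathway
#'
#' An enzyme (distinct enzyme identifier) counts as uniquely retained as an
#' ohnolog iff every gene encoding it is classed `wgd_segmental`, and as
#' uniquely singleton iff every encoding gene is `singleton`; enzymes with
#' mixed classes count to neither. The genome background is the number of
#' ohnolog and singleton genes among the annotated genes.
#'
#' @param classes output of [classify_duplicates()].
#' @param annotation data.frame with `gene_id`, `enzyme_id`, `pathway_id`.
#' @return List with `pathways` (data.frame `pathway_id`,
#'   `n_unique_ohnolog`, `n_unique_singleton`), `background_ohnolog`,
#'   `background_singleton`.
#' @export
unique_retention <- function(classes, annotation) {
  unknown <- !annotation$gene_id %in% classes$gene_id
  if (any(unknown)) {
    warning(sum(unknown), " annotation row(s) reference unknown genes; skipped")
    annotation <- annotation[!unknown, , drop = FALSE]
  }
  cls <- setNames(classes$category, classes$gene_id)
  annotation$class <- cls[annotation$gene_id]

  ## uniqueness judged over all genes encoding the enzyme
  enz_split <- split(annotation$class, annotation$enzyme_id)
  enz_status <- vapply(enz_split, function(cl) {
    if (all(cl == "wgd_segmental")) "ohnolog"
    else if (all(cl == "singleton")) "singleton"
    else "mixed"
  }, character(1))

  pw <- unique(annotation[, c("pathway_id", "enzyme_id")])
  pw$status <- enz_status[pw$enzyme_id]
  counts <- do.call(rbind, lapply(split(pw, pw$pathway_id), function(d)
    data.frame(pathway_id = d$pathway_id[1],
               n_unique_ohnolog = sum(d$status == "ohnolog"),
               n_unique_singleton = sum(d$status == "singleton"))))
  rownames(counts) <- NULL
  anno_genes <- unique(annotation$gene_id)
  list(pathways = counts,
       background_ohnolog = sum(cls[anno_genes] == "wgd_segmental"),
       background_singleton = sum(cls[anno_genes] == "singleton"))
}

#' Test pathways for preferential retention in duplicate
#'
#' Per isolate and pathway, a one-sided Fisher exact test compares the
#' pathway's uniquely-retained ohnolog/singleton enzyme counts against the
#' genome background proportion, with Benjamini-Hochberg adjustment across
#' pathways within each isolate. A pathway is reported as retained in
#' duplicate only when it has at least `min_enzymes` uniquely retained
#' enzymes on one side AND fdr < `alpha`, in every isolate (at least two
#' isolates required for the combined verdict; with one isolate, per-isolate
#' results are emitted and the verdict withheld).
#'
#' @param counts_by_isolate named list of [unique_retention()] outputs, one
#'   per isolate.
#' @param min_enzymes minimum uniquely retained enzymes (default 5).
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with one row per isolate x pathway (`isolate`,
#'   `pathway_id`, counts, `pvalue`, `fdr`, `passes_min_enzymes`,
#'   `significant`), with a `verdict` attribute: data.frame `pathway_id`,
#'   `retained_in_duplicate` (NA when fewer than two isolates).
#' @export
test_retention <- function(counts_by_isolate, min_enzymes = 5, alpha = 0.05) {
  if (is.null(names(counts_by_isolate)))
    names(counts_by_isolate) <- paste0("isolate", seq_along(counts_by_isolate))
  per <- lapply(names(counts_by_isolate), function(iso) {
    u <- counts_by_isolate[[iso]]
    d <- u$pathways
    p <- vapply(seq_len(nrow(d)), function(i) {
      m <- matrix(c(d$n_unique_ohnolog[i], d$n_unique_singleton[i],
                    u$background_ohnolog, u$background_singleton),
                  nrow = 2, byrow = TRUE)
      fisher.test(m, alternative = "greater")$p.value
    }, numeric(1))
    data.frame(isolate = iso, d,
               pvalue = p, fdr = p.adjust(p, method = "BH"),
               passes_min_enzymes = pmax(d$n_unique_ohnolog,
                                         d$n_unique_singleton) >= min_enzymes,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, per)
  res$significant <- res$passes_min_enzymes & res$fdr < alpha
  rownames(res) <- NULL

  pws <- unique(res$pathway_id)
  if (length(counts_by_isolate) >= 2) {
    retained <- vapply(pws, function(pw) {
      rows <- res[res$pathway_id == pw, , drop = FALSE]
      nrow(rows) == length(counts_by_isolate) && all(rows$significant)
    }, logical(1))
  } else {
    retained <- rep(NA, length(pws))
  }
  attr(res, "verdict") <- data.frame(pathway_id = pws,
                                     retained_in_duplicate = retained,
                                     row.names = NULL)
  res
}
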