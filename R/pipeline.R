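#' Percentage with the reporter's rounding
#'
#' 100 * numerator / denominator, rounded half-up to two decimals (the
#' convention used for all headline percentages).
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return A numeric percentage with two decimals.
#' @export
report_percentages <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  floor(100 * numerator / denominator * 100 + 0.5 + 1e-9) / 100
}

#' Simulate a gene-to-enzyme-to-pathway annotation
#'
#' Random annotation used to exercise the pathway-retention test on
#' simulated genomes: enzymes are assigned to one or two genes each and
#' grouped into pathways.
#'
#' @param catalog a [gene_catalog].
#' @param n_pathways,enzymes_per_pathway annotation shape (defaults 6, 8).
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `enzyme_id`, `pathway_id`.
#' @export
simulate_annotation <- function(catalog, n_pathways = 6,
                                enzymes_per_pathway = 8, seed = 1) {
  set.seed(seed)
  gids <- catalog$genes$gene_id
  rows <- list()
  for (p in seq_len(n_pathways)) {
    for (e in seq_len(enzymes_per_pathway)) {
      genes <- sample(gids, sample(1:2, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes,
        enzyme_id = sprintf("EC%02d.%02d", p, e),
        pathway_id = sprintf("map%03d", p))
    }
  }
  do.call(rbind, rows)
}

.default_config <- function() {
  list(
    seed = 1,
    outdir = NULL,
    simulate = list(genome = list(), expression = list()),
    inputs = list(),
    stages = list(collinearity = TRUE, divergence = TRUE,
                  expression = TRUE, splicing = TRUE, pathways = TRUE),
    thresholds = list(min_block_genes = 5, max_gene_gap = 25,
                      proximal_max_gap = 20, max_hits = 5,
                      min_cov_pct = 50, max_evalue = 1e-5,
                      de_fdr = 0.01, de_lfc = 1,
                      pair_min_count = 10, pair_min_sample_frac = 0.5,
                      tau_cut = 0.7, gmm_k_max = 4,
                      deu_alpha = 0.05, deu_min_delta = 0.1,
                      pathway_min_enzymes = 5, pathway_alpha = 0.05))
}

#' Run the ohnolog analysis pipeline end to end
#'
#' Stages run in dependency order: collinearity (block detection, duplicate
#' classification, ohnolog pairs) -> sequence divergence (NG86 Ks,
#' node-averaged distribution, Gaussian mixture) -> expression (DE over the
#' four contrasts, expressed-pair filter, five-group classification, pair
#' correlation, tau, module-preference test) -> splicing (DEU, junction
#' conservation) -> pathway retention. Inputs are either simulated (the
#' default; see [simulate_wgd_genome()] and [simulate_expression()]) or
#' provided as file paths under `config$inputs`. Any stage hard error
#' aborts with the stage named.
#'
#' @param config a configuration list or the path to a YAML file. Unknown
#'   top-level keys are rejected; recognised keys are `seed`, `outdir`,
#'   `simulate` (genome/expression parameter overrides), `inputs` (paths:
#'   `gff`, `hits`, `counts`, `samples`, `annotation`, `modules`), `stages`
#'   (logical toggles) and `thresholds`.
#' @return An object of class `ohnoscope_report` (nested list of summary
#'   statistics); written as JSON to `outdir` when set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  th <- cfg$thresholds
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("ohnoscope")),
    seed = cfg$seed, thresholds = th,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- inputs -------------------------------------------------------
  simulated <- is.null(cfg$inputs$gff)
  if (simulated) {
    gp <- do.call(genome_sim_params,
                  utils::modifyList(list(seed = cfg$seed),
                                    cfg$simulate$genome))
    sim <- stage("simulate", simulate_wgd_genome(gp))
    catalog <- sim$catalog
    hits_raw <- sim$hits
    truth <- sim$truth
  } else {
    catalog <- stage("parse", parse_gene_positions(cfg$inputs$gff))
    hits_raw <- stage("parse", read_hit_table(cfg$inputs$hits))
    truth <- NULL
  }
  hits <- filter_hits(hits_raw, max_hits = th$max_hits,
                      min_cov_pct = th$min_cov_pct,
                      max_evalue = th$max_evalue)

  ## ---- collinearity -------------------------------------------------
  blocks <- classes <- pairs <- NULL
  if (isTRUE(cfg$stages$collinearity)) {
    blocks <- stage("collinearity", detect_collinear_blocks(
      catalog, hits, min_block_genes = th$min_block_genes,
      max_gene_gap = th$max_gene_gap, mode = "intra"))
    classes <- classify_duplicates(catalog, hits, blocks,
                                   proximal_max_gap = th$proximal_max_gap)
    pairs <- extract_ohnolog_pairs(blocks)
    census <- table(factor(classes$category,
                           levels = c("singleton", "dispersed", "proximal",
                                      "tandem", "wgd_segmental")))
    report$collinearity <- c(
      block_summary(blocks, catalog),
      list(duplication_census = as.list(census),
           n_ohnolog_pairs = nrow(pairs)))
  }

  ## ---- sequence divergence ------------------------------------------
  if (isTRUE(cfg$stages$divergence) && !is.null(catalog$cds) &&
      !is.null(pairs) && nrow(pairs) > 0) {
    report$divergence <- stage("divergence", {
      ks_tab <- ks_for_pairs(pairs, catalog)
      usable <- ks_tab[!ks_tab$saturated & is.finite(ks_tab$Ks), , drop = FALSE]
      clusters <- cluster_homologs(hits)
      cl_tabs <- lapply(clusters, function(genes) {
        sub <- usable[usable$gene_a %in% genes & usable$gene_b %in% genes, ,
                      drop = FALSE]
        if (nrow(sub)) data.frame(gene_a = sub$gene_a, gene_b = sub$gene_b,
                                  Ks = sub$Ks) else NULL
      })
      node_ks <- node_average_ks(Filter(Negate(is.null), cl_tabs))
      out <- list(n_pairs_estimated = nrow(ks_tab),
                  n_saturated = sum(ks_tab$saturated),
                  median_ks = median(usable$Ks),
                  mean_omega = mean(ks_tab$omega, na.rm = TRUE),
                  n_node_averaged = length(node_ks))
      if (length(node_ks) >= 50) {
        gmm <- fit_ks_gmm(node_ks, k_max = th$gmm_k_max, seed = cfg$seed)
        out$gmm <- list(k = gmm$k, weights = gmm$weights, means = gmm$means,
                        sds = gmm$sds, aic_by_k = as.list(gmm$aic_by_k))
      }
      out
    })
  }

  ## ---- expression ---------------------------------------------------
  expr <- NULL
  if (isTRUE(cfg$stages$expression) && !is.null(pairs) && nrow(pairs) > 0) {
    report$expression <- stage("expression", {
      if (simulated) {
        ep <- do.call(expr_sim_params,
                      utils::modifyList(list(seed = cfg$seed),
                                        cfg$simulate$expression))
        expr <- simulate_expression(pairs, ep)
      } else {
        sheet <- read_sample_sheet(cfg$inputs$samples)
        pc <- parse_counts(cfg$inputs$counts, sheet)
        expr <- list(counts = pc$counts, samples = pc$samples,
                      gene_lengths = setNames(
                        catalog$genes$length,
                        catalog$genes$gene_id)[rownames(pc$counts)])
      }
      counts <- expr$counts
      samples <- expr$samples
      de <- test_de(counts, samples, c("L-28", "L-34", "T-Fr", "T-Sy"),
                    fdr_level = th$de_fdr, lfc_threshold = th$de_lfc)
      kept <- filter_expressed_pairs(counts, pairs,
                                     min_count = th$pair_min_count,
                                     min_sample_frac = th$pair_min_sample_frac)
      kept <- kept[kept$gene_a %in% de$gene_id & kept$gene_b %in% de$gene_id, ,
                   drop = FALSE]
      groups <- classify_pair_groups(de, kept)
      nm <- normalize_counts(counts, expr$gene_lengths)
      groups$pearson_r <- pair_correlation(nm$log2fpkm, groups)
      tau <- tau_index(nm$fpkm, samples)
      gcensus <- table(factor(groups$group, levels = 1:5))
      high_tau <- tau[!is.na(tau$tau) & tau$tau > th$tau_cut, , drop = FALSE]
      cls_high <- classes$category[match(high_tau$gene_id, classes$gene_id)]
      module_pref <- NULL
      if (!is.null(cfg$inputs$modules)) {
        mods <- read.delim(cfg$inputs$modules, quote = "")
        tab <- table(classes$category[match(mods$gene_id, classes$gene_id)],
                     mods$module)
        pref <- categorical_preference(tab)
        module_pref <- list(chi2 = pref$chi2, pvalue = pref$pvalue)
      }
      list(
        n_expressed_pairs = nrow(groups),
        group_census = as.list(gcensus),
        group_pct = as.list(setNames(
          report_percentages(as.integer(gcensus), max(nrow(groups), 1)),
          names(gcensus))),
        median_pearson_r_by_group = as.list(tapply(
          groups$pearson_r, groups$group, median, na.rm = TRUE)),
        n_high_tau = nrow(high_tau),
        n_high_tau_ohnolog = sum(cls_high == "wgd_segmental", na.rm = TRUE),
        pct_high_tau_ohnolog = if (nrow(high_tau) > 0)
          report_percentages(sum(cls_high == "wgd_segmental", na.rm = TRUE),
                             nrow(high_tau)) else NA,
        module_preference = module_pref,
        de = de, groups = groups, tau = tau)
    })
  }

  ## ---- splicing -----------------------------------------------------
  if (isTRUE(cfg$stages$splicing) && !is.null(expr) &&
      !is.null(expr$bin_counts)) {
    report$splicing <- stage("splicing", {
      deu <- test_deu(expr$bin_counts, expr$bin_info, expr$samples, "L-28",
                      alpha = th$deu_alpha, min_delta = th$deu_min_delta)
      jstats <- lapply(expr$junctions, function(jp) {
        m <- match_junctions(jp$flanks_a, jp$flanks_b)
        pr <- junction_profiles(jp$flanks_a$event_id, jp$flanks_b$event_id, m)
        junction_conservation_stats(pr$profile_a, pr$profile_b)
      })
      list(
        n_bins_tested = nrow(deu),
        n_genes_deu = length(unique(deu$gene_id[deu$significant])),
        mean_conserved_fraction = mean(vapply(jstats, `[[`, numeric(1),
                                              "conserved_fraction")),
        median_kendall_tau = median(vapply(jstats, `[[`, numeric(1),
                                           "kendall_tau"), na.rm = TRUE),
        n_diverged_pairs = sum(vapply(jstats, `[[`, numeric(1),
                                      "binom_p") < 0.05))
    })
  }

  ## ---- pathway retention --------------------------------------------
  if (isTRUE(cfg$stages$pathways) && !is.null(classes)) {
    report$pathways <- stage("pathways", {
      anno <- if (!is.null(cfg$inputs$annotation))
        read.delim(cfg$inputs$annotation, quote = "")
      else simulate_annotation(catalog, seed = cfg$seed)
      u <- unique_retention(classes, anno)
      res <- test_retention(list(isolate1 = u),
                            min_enzymes = th$pathway_min_enzymes,
                            alpha = th$pathway_alpha)
      list(n_pathways = length(unique(res$pathway_id)),
           n_significant = sum(res$significant),
           verdict_withheld = all(is.na(attr(res, "verdict")$retained_in_duplicate)))
    })
  }

  if (!is.null(truth)) {
    report$truth_summary <- list(
      n_true_wgd_pairs = sum(truth$pairs$relation == "wgd"),
      class_census = as.list(table(truth$gene_class$class)))
  }

  report <- structure(report, class = "ohnoscope_report")
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    slim <- report
    if (!is.null(slim$expression)) {
      slim$expression$de <- NULL
      slim$expression$groups <- NULL
      slim$expression$tau <- NULL
    }
    jsonlite::write_json(unclass(slim),
                         file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (!is.null(report$expression)) {
      write.table(report$expression$groups,
                  file.path(cfg$outdir, "pair_groups.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(report$expression$tau, file.path(cfg$outdir, "tau.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' @export
print.ohnoscope_report <- function(x, ...) {
  cat("ohnoscope pipeline report\n")
  if (!is.null(x$collinearity))
    cat(sprintf("  collinearity: %d blocks, %d genes in blocks (%.2f%%), %d ohnolog pairs\n",
                x$collinearity$n_blocks, x$collinearity$n_genes_in_blocks,
                x$collinearity$pct_genes_in_blocks,
                x$collinearity$n_ohnolog_pairs))
  if (!is.null(x$divergence))
    cat(sprintf("  divergence: %d pairs, median Ks = %.3f%s\n",
                x$divergence$n_pairs_estimated, x$divergence$median_ks,
                if (!is.null(x$divergence$gmm))
                  sprintf(", GMM k = %d", x$divergence$gmm$k) else ""))
  if (!is.null(x$expression))
    cat(sprintf("  expression: %d expressed pairs; groups 1-5: %s\n",
                x$expression$n_expressed_pairs,
                paste(unlist(x$expression$group_census), collapse = "/")))
  if (!is.null(x$splicing))
    cat(sprintf("  splicing: mean conserved junction fraction = %.3f\n",
                x$splicing$mean_conserved_fraction))
  if (!is.null(x$pathways))
    cat(sprintf("  pathways: %d tested, %d significant\n",
                x$pathways$n_pathways, x$pathways$n_significant))
  invisible(x)
}
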