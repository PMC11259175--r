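#' Parameters for the expression/splicing experiment simulator
#'
#' Defaults emulate a lifestyle-by-temperature RNA-seq design (free-living
#' vs symbiotic, 28 vs 34 C, `n_replicates` each). The planted composition
#' of the five ohnolog expression-divergence groups follows the published
#' composition of the real dataset where stated (group 2 at 36.5% and
#' group 5 at 1.6% of expressed pairs), with the remainder split
#' plausibly among groups 1, 3 and 4.
#'
#' @param group_fractions numeric length-5 vector of planted group
#'   probabilities (must sum to 1).
#' @param de_log2fc planted effect size on the log2 scale (default 3).
#' @param nb_dispersion negative-binomial dispersion (default 0.1).
#' @param library_size_sd log-normal sd of per-sample library scale
#'   (default 0.15).
#' @param n_replicates replicates per condition, 4 conditions (default 3).
#' @param base_log2_mean,base_log2_sd baseline log2 expression (defaults
#'   6.5, 1).
#' @param tau_specific_fraction fraction of extra genes expressed in
#'   exactly one condition (default 0.05).
#' @param deu_fraction fraction of pairs with a planted exon-usage shift
#'   (default 0.3).
#' @param exon_bins_per_gene counting bins per gene (default 4).
#' @param junctions_per_gene splice-junction events per gene (default 4).
#' @param junction_conservation_p probability a junction is conserved
#'   within a pair (default 0.8).
#' @param junction_flank_bp flank length emitted per junction (default
#'   300).
#' @param seed RNG seed.
#' @return A validated list of class `expr_sim_params`.
#' @export
expr_sim_params <- function(group_fractions = c(0.449, 0.365, 0.08, 0.09, 0.016),
                            de_log2fc = 3, nb_dispersion = 0.1,
                            library_size_sd = 0.15, n_replicates = 3,
                            base_log2_mean = 6.5, base_log2_sd = 1,
                            tau_specific_fraction = 0.05,
                            deu_fraction = 0.3, exon_bins_per_gene = 4,
                            junctions_per_gene = 4,
                            junction_conservation_p = 0.8,
                            junction_flank_bp = 300, seed = 1) {
  p <- as.list(environment())
  if (length(group_fractions) != 5)
    stop("group_fractions must have length 5")
  if (abs(sum(group_fractions) - 1) > 1e-9)
    stop("group_fractions must sum to 1")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  structure(p, class = "expr_sim_params")
}

## planted mean-shift pattern per group over the four condition cells
## (free_28, free_34, symbiotic_28, symbiotic_34), log2 scale
.plant_shifts <- function(group, delta) {
  cells <- c("free_28", "free_34", "symbiotic_28", "symbiotic_34")
  za <- zb <- setNames(numeric(4), cells)
  sgn <- sample(c(-1, 1), 1)
  if (group == 2) {
    za[sample(cells, 1)] <- sgn * delta
  } else if (group == 3) {
    cell <- sample(cells, 1)
    za[cell] <- zb[cell] <- sgn * delta
  } else if (group == 5) {
    cell <- sample(cells, 1)
    za[cell] <- sgn * delta
    zb[cell] <- -sgn * delta
  } else if (group == 4) {
    ## cell pairs whose affected contrast sets are disjoint
    pick <- sample(1:2, 1)
    ca <- if (pick == 1) "free_34" else "free_28"
    cb <- if (pick == 1) "symbiotic_28" else "symbiotic_34"
    za[ca] <- sgn * delta
    zb[cb] <- sample(c(-1, 1), 1) * delta
  }
  list(a = za, b = zb)
}

## true log2 fold changes per contrast implied by a cell-shift vector
.true_lfc <- function(z) {
  c("L-28" = unname(z["symbiotic_28"] - z["free_28"]),
    "L-34" = unname(z["symbiotic_34"] - z["free_34"]),
    "T-Fr" = unname(z["free_34"] - z["free_28"]),
    "T-Sy" = unname(z["symbiotic_34"] - z["symbiotic_28"]))
}

## group implied by true fold changes under the classification rules
.true_group <- function(za, zb, lfc_threshold = 1) {
  la <- .true_lfc(za); lb <- .true_lfc(zb)
  Da <- names(la)[abs(la) > lfc_threshold]
  Db <- names(lb)[abs(lb) > lfc_threshold]
  shared <- intersect(Da, Db)
  if (!length(Da) && !length(Db)) 1L
  else if (xor(length(Da) > 0, length(Db) > 0)) 2L
  else if (length(shared) && any(sign(la[shared]) != sign(lb[shared]))) 5L
  else if (length(shared)) 3L
  else 4L
}

.mutate_dna <- function(seq, rate) {
  nt <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(nt)) < rate)
  for (i in hit) nt[i] <- sample(setdiff(c("A", "C", "G", "T"), nt[i]), 1)
  paste(nt, collapse = "")
}

#' Simulate a lifestyle-by-temperature expression experiment
#'
#' Draws negative-binomial counts for every gene of the supplied ohnolog
#' pairs with condition-mean shifts implementing a planted five-group
#' structure: group 1 no shifts; group 2 a shift in one copy only; group 3
#' the same shift in both copies; group 4 shifts in cells whose affected
#' contrasts are disjoint between copies; group 5 opposite shifts in the
#' same cell. Adds tau-specific genes expressed in exactly one condition,
#' exon-bin counts with planted usage shifts for a fraction of pairs, and
#' per-pair splice-junction flank sequences conserved with probability
#' `junction_conservation_p`. Deterministic under a fixed seed.
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (ohnolog pairs).
#' @param params an [expr_sim_params] list.
#' @return A list: `counts` (gene x sample integers), `samples` (sheet),
#'   `gene_lengths`, `bin_counts`, `bin_info`, `junctions` (per-pair list
#'   of `flanks_a`, `flanks_b`, `conserved`), and `truth` (`groups` with
#'   sampled and implied labels, `shifts`, `tau_genes`, `deu_pairs`).
#' @export
simulate_expression <- function(pairs, params = expr_sim_params()) {
  stopifnot(inherits(params, "expr_sim_params"))
  if (abs(sum(params$group_fractions) - 1) > 1e-9)
    stop("group_fractions must sum to 1")
  set.seed(params$seed)
  n_pairs <- nrow(pairs)
  if (n_pairs < 1) stop("need at least one pair")
  cells <- c("free_28", "free_34", "symbiotic_28", "symbiotic_34")
  samples <- data.frame(
    sample = paste0(rep(cells, each = params$n_replicates), "_r",
                    seq_len(params$n_replicates)),
    lifestyle = rep(rep(c("free", "symbiotic"), each = 2 * params$n_replicates)),
    temperature = rep(rep(c(28, 34, 28, 34), each = params$n_replicates)),
    replicate = rep(seq_len(params$n_replicates), 4))
  samples <- validate_sample_sheet(samples)
  ns <- nrow(samples)

  grp <- sample(1:5, n_pairs, replace = TRUE, prob = params$group_fractions)
  shift_a <- matrix(0, n_pairs, 4, dimnames = list(NULL, cells))
  shift_b <- shift_a
  true_grp <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    z <- .plant_shifts(grp[i], params$de_log2fc)
    shift_a[i, ] <- z$a
    shift_b[i, ] <- z$b
    true_grp[i] <- .true_group(z$a, z$b)
  }

  genes <- c(pairs$gene_a, pairs$gene_b)
  shifts <- rbind(shift_a, shift_b)
  rownames(shifts) <- genes
  base <- rnorm(length(genes), params$base_log2_mean, params$base_log2_sd)

  n_tau <- round(params$tau_specific_fraction * length(genes))
  tau_genes <- if (n_tau > 0) sprintf("tauspec%04d", seq_len(n_tau)) else character(0)
  tau_cond <- sample(cells, n_tau, replace = TRUE)

  lib <- rlnorm(ns, 0, params$library_size_sd)
  cond_of <- samples$condition
  mu <- matrix(0, length(genes) + n_tau, ns,
               dimnames = list(c(genes, tau_genes), samples$sample))
  for (j in seq_len(ns)) {
    cell <- cond_of[j]
    mu[seq_along(genes), j] <- 2^(base + shifts[, cell]) * lib[j]
    if (n_tau > 0)
      mu[length(genes) + seq_len(n_tau), j] <-
        ifelse(tau_cond == cell, 2^params$base_log2_mean, 0.05) * lib[j]
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / params$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"

  ## exon-bin counts: multinomial split of the gene count over bins, with a
  ## planted usage swap between the two halves of a random contrast for a
  ## deu_fraction of pairs (copy A only)
  B <- params$exon_bins_per_gene
  deu_pair <- runif(n_pairs) < params$deu_fraction
  deu_contrast <- sample(c("L-28", "L-34", "T-Fr", "T-Sy"), n_pairs,
                         replace = TRUE)
  contrast_cells <- list("L-28" = c("free_28", "symbiotic_28"),
                         "L-34" = c("free_34", "symbiotic_34"),
                         "T-Fr" = c("free_28", "free_34"),
                         "T-Sy" = c("symbiotic_28", "symbiotic_34"))
  bin_rows <- list(); bin_counts <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    pi <- ((gi - 1L) %% n_pairs) + 1L
    is_a <- gi <= n_pairs
    planted <- deu_pair[pi] && is_a
    props <- if (planted) {
      p <- c(0.45, 0.15, rep(0.4 / (B - 2), B - 2))
      p
    } else {
      p <- rgamma(B, 2); p / sum(p)
    }
    swapped <- props
    if (planted) { swapped[1] <- props[2]; swapped[2] <- props[1] }
    shifted_cell <- contrast_cells[[deu_contrast[pi]]][2]
    cnt <- vapply(seq_len(ns), function(j) {
      pr <- if (planted && cond_of[j] == shifted_cell) swapped else props
      as.integer(rmultinom(1, counts[g, j], pr))
    }, integer(B))
    ids <- sprintf("%s:%03d", g, seq_len(B))
    bin_counts[[g]] <- matrix(cnt, nrow = B, dimnames = list(ids, samples$sample))
    bin_rows[[g]] <- data.frame(bin_id = ids, gene_id = g)
  }
  bin_counts <- do.call(rbind, bin_counts)
  bin_info <- do.call(rbind, bin_rows)
  rownames(bin_info) <- NULL

  ## splice-junction flanks: conserved junctions share (slightly mutated)
  ## flank sequence, non-conserved junctions get unrelated flanks
  types <- c("alternative acceptor", "alternative donor", "alternative exon",
             "retained exon", "skipped exon")
  J <- params$junctions_per_gene
  fb <- params$junction_flank_bp
  junctions <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    conserved <- runif(J) < params$junction_conservation_p
    ty <- sample(types, J, replace = TRUE)
    up_a <- vapply(seq_len(J), function(k) .random_dna(fb), character(1))
    dn_a <- vapply(seq_len(J), function(k) .random_dna(fb), character(1))
    up_b <- ifelse(conserved, vapply(up_a, .mutate_dna, character(1), rate = 0.01),
                   vapply(seq_len(J), function(k) .random_dna(fb), character(1)))
    dn_b <- ifelse(conserved, vapply(dn_a, .mutate_dna, character(1), rate = 0.01),
                   vapply(seq_len(J), function(k) .random_dna(fb), character(1)))
    junctions[[i]] <- list(
      gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
      flanks_a = data.frame(
        event_id = sprintf("%s:j%02d", pairs$gene_a[i], seq_len(J)),
        type = ty, upstream_seq = up_a, downstream_seq = dn_a,
        stringsAsFactors = FALSE),
      flanks_b = data.frame(
        event_id = sprintf("%s:j%02d", pairs$gene_b[i], seq_len(J)),
        type = ty, upstream_seq = unname(up_b), downstream_seq = unname(dn_b),
        stringsAsFactors = FALSE),
      conserved = conserved)
  }

  truth <- list(
    groups = data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                        group = grp, true_group = true_grp,
                        stringsAsFactors = FALSE),
    shifts = shifts,
    tau_genes = data.frame(gene_id = tau_genes, condition = tau_cond,
                           stringsAsFactors = FALSE),
    deu_pairs = data.frame(gene_a = pairs$gene_a, planted = deu_pair,
                           contrast = deu_contrast, stringsAsFactors = FALSE),
    junction_conservation_p = params$junction_conservation_p)

  gene_lengths <- setNames(rep(1000L, nrow(counts)), rownames(counts))
  list(counts = counts, samples = samples, gene_lengths = gene_lengths,
       bin_counts = bin_counts, bin_info = bin_info, junctions = junctions,
       truth = truth)
}
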