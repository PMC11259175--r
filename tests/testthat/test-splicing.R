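test_that("exon bins flatten overlapping variants at every boundary", {
  genes <- data.frame(gene_id = c("g1", "g2"), scaffold = "sc1",
                      start = c(1, 1000), end = c(500, 1600), strand = "+")
  ## g1: two plain exons -> 2 bins; g2: shared exon1 plus two 3' variants of
  ## exon2 -> 3 bins split at the internal boundary
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g2"),
    start = c(1, 201, 1000, 1200, 1200),
    end = c(100, 300, 1100, 1400, 1600))
  cat1 <- gene_catalog(genes, exons)
  bins <- make_exon_bins(cat1)
  b1 <- bins[bins$gene_id == "g1", ]
  expect_equal(nrow(b1), 2L)
  b2 <- bins[bins$gene_id == "g2", ]
  expect_equal(nrow(b2), 3L)
  expect_equal(b2$start, c(999, 1199, 1400))  # 0-based half-open
  expect_equal(b2$end, c(1100, 1400, 1600))
  ## disjoint bins covering the exonic footprint exactly
  expect_equal(sum(b2$width), 1100 - 1000 + 1 + 1600 - 1200 + 1)
  expect_equal(nrow(make_exon_bins(gene_catalog(genes[0, ]))), 0L)
})

test_that("DEU flags planted usage swaps and controls the gene-level null", {
  samples <- toy_samples(3)
  set.seed(41)
  G <- 150
  gene_ids <- sprintf("g%03d", 1:G)
  totals <- matrix(rnbinom(G * 12, mu = 400, size = 10), nrow = G,
                   dimnames = list(gene_ids, samples$sample))
  ## 2 bins per gene at 0.8/0.2; first 10 genes swap usage in symbiotic_28
  sel <- samples$condition == "symbiotic_28"
  bin_counts <- matrix(0L, 2 * G, 12,
                       dimnames = list(paste0(rep(gene_ids, each = 2), ":", 1:2),
                                       samples$sample))
  for (g in seq_len(G)) for (j in 1:12) {
    p <- if (g <= 10 && sel[j]) c(0.2, 0.8) else c(0.8, 0.2)
    bin_counts[(2 * g - 1):(2 * g), j] <-
      as.integer(rmultinom(1, totals[g, j], p))
  }
  bin_info <- data.frame(bin_id = rownames(bin_counts),
                         gene_id = rep(gene_ids, each = 2))
  deu <- test_deu(bin_counts, bin_info, samples, "L-28")
  planted <- gene_ids[1:10]
  sig_genes <- unique(deu$gene_id[deu$significant])
  expect_gte(sum(planted %in% sig_genes), 9)
  ## relative usage sums to 1 over bins, delta bounded
  expect_true(all(abs(deu$delta_usage) <= 1, na.rm = TRUE))
  ## gene fdr never below the smallest bin p of the gene
  by_gene <- split(deu, deu$gene_id)
  expect_true(all(vapply(by_gene, function(d)
    all(d$gene_fdr >= min(d$pvalue) - 1e-12), logical(1))))
  ## null false-positive fraction at gene level
  null_genes <- gene_ids[11:G]
  expect_lte(mean(null_genes %in% sig_genes), 0.07)
})

test_that("gene-level adjustment reproduces an independent BH ladder", {
  samples <- toy_samples(3)
  set.seed(42)
  G <- 25
  gene_ids <- sprintf("g%03d", 1:G)
  totals <- matrix(rnbinom(G * 12, mu = 300, size = 5), nrow = G,
                   dimnames = list(gene_ids, samples$sample))
  bin_counts <- matrix(0L, 2 * G, 12,
                       dimnames = list(paste0(rep(gene_ids, each = 2), ":", 1:2),
                                       samples$sample))
  for (g in seq_len(G)) for (j in 1:12)
    bin_counts[(2 * g - 1):(2 * g), j] <-
      as.integer(rmultinom(1, totals[g, j], c(0.6, 0.4)))
  bin_info <- data.frame(bin_id = rownames(bin_counts),
                         gene_id = rep(gene_ids, each = 2))
  deu <- test_deu(bin_counts, bin_info, samples, "T-Fr")
  gene_p <- vapply(split(deu, deu$gene_id), function(d)
    1 - (1 - min(d$pvalue))^nrow(d), numeric(1))
  expect_equal(
    unname(vapply(split(deu$gene_fdr, deu$gene_id), unique, numeric(1))),
    unname(oracle_bh(gene_p)), tolerance = 1e-12)
})

test_that("pair DEU summaries combine matched bins as defined", {
  deu_a <- data.frame(bin_id = paste0("a:", 1:4), gene_id = "a",
                      delta_usage = c(0.3, -0.2, 0.0, 0.1),
                      significant = c(TRUE, TRUE, FALSE, FALSE))
  deu_b <- data.frame(bin_id = paste0("b:", 1:4), gene_id = "b",
                      delta_usage = c(0.1, -0.2, 0.0, 0.0),
                      significant = FALSE)
  matches <- data.frame(bin_a = paste0("a:", 1:3), bin_b = paste0("b:", 1:3))
  s <- pair_deu_summary(deu_a, deu_b, matches)
  expect_equal(s$proportion_deu, 2 / 8)
  expect_equal(s$overall_deu, abs(0.3 - 0.1) + 0 + 0)
  expect_true(s$comparable)
  s0 <- pair_deu_summary(deu_a, deu_b, NULL)
  expect_false(s0$comparable)
  ## identical shifts over matched bins -> overall 0
  s1 <- pair_deu_summary(deu_a, deu_a,
                         data.frame(bin_a = deu_a$bin_id, bin_b = deu_a$bin_id))
  expect_equal(s1$overall_deu, 0)
})

test_that("junction flank extraction follows BED arithmetic and truncation rules", {
  set.seed(43)
  scaf <- setNames(paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                         collapse = ""), "sc1")
  events <- data.frame(event_id = c("e1", "e2", "e3"), gene_id = "g",
                       scaffold = "sc1",
                       start = c(1001, 100, 20000), end = c(1100, 150, 20100),
                       type = "skipped exon")
  expect_warning(fl <- extract_junction_flanks(events, scaf, flank_bp = 300),
                 "outside scaffold")
  expect_equal(nrow(fl), 2L)
  e1 <- fl[fl$event_id == "e1", ]
  expect_equal(c(e1$up_start0, e1$up_end0), c(700, 1000))
  expect_equal(c(e1$down_start0, e1$down_end0), c(1100, 1400))
  expect_equal(e1$upstream_seq, unname(substr(scaf, 701, 1000)))
  expect_false(e1$truncated)
  ## event near the scaffold start is truncated and flagged
  expect_true(fl$truncated[fl$event_id == "e2"])
  expect_equal(nrow(extract_junction_flanks(events[0, ], scaf)), 0L)
})

test_that("junction matching demands both flanks and equals best assignment on a toy set", {
  set.seed(44)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  ups <- vapply(rep(300, 3), rnd, character(1))
  dns <- vapply(rep(300, 3), rnd, character(1))
  fa <- data.frame(event_id = paste0("a", 1:3), upstream_seq = ups,
                   downstream_seq = dns)
  ## b1/b2 conserved with a1/a2; b3 upstream matches a3 but downstream random
  fb <- data.frame(event_id = paste0("b", 1:3),
                   upstream_seq = ups,
                   downstream_seq = c(dns[1:2], rnd(300)))
  m <- match_junctions(fa, fb)
  expect_setequal(paste(m$event_a, m$event_b),
                  c("a1 b1", "a2 b2"))
  ## identical flank sets match one-to-one (best assignment on 3 vs 3)
  m3 <- match_junctions(fa, data.frame(event_id = paste0("b", 1:3),
                                       upstream_seq = ups,
                                       downstream_seq = dns))
  expect_equal(sort(paste(m3$event_a, m3$event_b)),
               c("a1 b1", "a2 b2", "a3 b3"))
})

test_that("junction statistics reproduce the hand-computed tau-b and binomial cases", {
  ## identical non-constant profiles
  s1 <- junction_conservation_stats(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(s1$kendall_tau, 1)
  ## balanced toy profile: concordant = discordant
  s2 <- junction_conservation_stats(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(s2$kendall_tau, 0)
  expect_equal(s2$binom_k, 1)
  expect_equal(s2$binom_n, 2)
  ## symmetric null: k = n/2 -> p = 1; and p(k, n) = p(n - k, n)
  expect_equal(binom.test(5, 10, 0.5)$p.value,
               junction_conservation_stats(
                 c(rep(1, 5), rep(0, 5), 1), c(rep(0, 5), rep(1, 5), 1))$binom_p)
  s3 <- junction_conservation_stats(c(1, 1, 1, 0, 0), c(0, 0, 0, 1, 1))
  s4 <- junction_conservation_stats(c(0, 0, 1, 1, 1), c(1, 1, 0, 0, 0))
  expect_equal(s3$binom_p, s4$binom_p)
  ## constant profile -> tau undefined
  expect_true(is.na(junction_conservation_stats(c(1, 1, 1), c(1, 0, 1))$kendall_tau))
})
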