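test_that("an ordered 6-anchor instance yields one block; 4 anchors yield none", {
  cat2 <- toy_catalog(list(s1 = paste0("a", 1:6), s2 = paste0("b", 1:6)))
  hits6 <- filter_hits(toy_hits(paste0("a", 1:6), paste0("b", 1:6)))
  bl <- detect_collinear_blocks(cat2, hits6, mode = "intra")
  expect_equal(length(unique(bl$block_id)), 1L)
  expect_equal(nrow(bl), 6L)
  expect_equal(bl$orientation[1], "same")

  hits4 <- filter_hits(toy_hits(paste0("a", 1:4), paste0("b", 1:4)))
  expect_equal(nrow(detect_collinear_blocks(cat2, hits4, mode = "intra")), 0L)

  ## no hits -> no blocks; unfiltered hits -> hard error
  empty <- filter_hits(toy_hits(character(0), character(0)))
  expect_equal(nrow(detect_collinear_blocks(cat2, empty, mode = "intra")), 0L)
  expect_error(detect_collinear_blocks(cat2, toy_hits("a1", "b1"), mode = "intra"),
               "filtered")
})

test_that("inverted segments are chained with decreasing partner ranks", {
  cat2 <- toy_catalog(list(s1 = paste0("a", 1:6), s2 = paste0("b", 1:6)))
  inv <- filter_hits(toy_hits(paste0("a", 1:6), paste0("b", 6:1)))
  bl <- detect_collinear_blocks(cat2, inv, mode = "intra")
  expect_equal(nrow(bl), 6L)
  expect_equal(bl$orientation[1], "inverted")
})

test_that("duplicate classification follows the documented precedence", {
  cat1 <- toy_catalog(list(s1 = sprintf("g%02d", 1:40)))
  no_blocks <- detect_collinear_blocks(
    cat1, filter_hits(toy_hits(character(0), character(0))), mode = "intra")
  ## adjacent homologs -> tandem; 30 ranks apart -> dispersed; within 20 ->
  ## proximal; no hits -> singleton
  h <- filter_hits(toy_hits(c("g01", "g05", "g10"), c("g02", "g35", "g20")))
  cl <- classify_duplicates(cat1, h, no_blocks)
  lookup <- setNames(cl$category, cl$gene_id)
  expect_equal(unname(lookup[c("g01", "g02")]), rep("tandem", 2))
  expect_equal(unname(lookup[c("g05", "g35")]), rep("dispersed", 2))
  expect_equal(unname(lookup[c("g10", "g20")]), rep("proximal", 2))
  expect_equal(unname(lookup["g03"]), "singleton")
  ## total function: every gene categorized exactly once
  expect_equal(sort(cl$gene_id), sort(cat1$genes$gene_id))
  expect_equal(sum(table(cl$category)), nrow(cat1$genes))
})

test_that("chaining matches the exhaustive oracle on random small instances", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    k <- sample(3:min(n, 8), 1)
    ra <- sort(sample(0:(n - 1), k))
    rb <- sample(0:(n - 1), k)
    cat2 <- toy_catalog(list(s1 = paste0("a", 1:n), s2 = paste0("b", 1:n)))
    h <- filter_hits(toy_hits(paste0("a", ra + 1), paste0("b", rb + 1)))
    bl <- detect_collinear_blocks(cat2, h, min_block_genes = 1,
                                  max_gene_gap = 25, mode = "intra")
    got <- if (nrow(bl)) max(bl$score) else 0
    expect_equal(got, oracle_best_chain_score(ra, rb, 25),
                 info = paste("instance", rep))
  }
})

test_that("ohnolog pairs deduplicate anchors and summaries count distinct genes", {
  cat2 <- toy_catalog(list(s1 = paste0("a", 1:6), s2 = paste0("b", 1:6)))
  bl <- detect_collinear_blocks(
    cat2, filter_hits(toy_hits(paste0("a", 1:6), paste0("b", 1:6))),
    mode = "intra")
  pr <- extract_ohnolog_pairs(bl)
  expect_equal(nrow(pr), 6L)
  expect_equal(nrow(extract_ohnolog_pairs(bl[0, ])), 0L)
  s <- block_summary(bl, cat2)
  expect_equal(s$n_blocks, 1L)
  expect_equal(s$n_genes_in_blocks, 12L)
  expect_equal(s$pct_genes_in_blocks, 100)
})

test_that("simulated WGD pairs are recovered as ohnolog pairs with few false positives", {
  sim <- simulate_wgd_genome(genome_sim_params(n_ancestral_genes = 150,
                                               wgd_retention = 0.85, seed = 17))
  fh <- filter_hits(sim$hits)
  blocks <- detect_collinear_blocks(sim$catalog, fh, mode = "intra")
  pairs <- extract_ohnolog_pairs(blocks)
  truth <- sim$truth$pairs[sim$truth$pairs$relation == "wgd", ]
  recovered <- mean(pair_key(truth$gene_a, truth$gene_b) %in%
                      pair_key(pairs$gene_a, pairs$gene_b))
  false_pos <- mean(!pair_key(pairs$gene_a, pairs$gene_b) %in%
                      pair_key(truth$gene_a, truth$gene_b))
  expect_gte(recovered, 0.9)
  expect_lte(false_pos, 0.05)
})
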