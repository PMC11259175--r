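test_that("NG86 reproduces hand-computed values and flags saturation", {
  ## 10 codons, one synonymous third-position difference
  est <- ng86(list(codons_a = rep("TTT", 10),
                   codons_b = c(rep("TTT", 9), "TTC")))
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$S, 10 / 3)
  expect_equal(est$ps, 0.3)
  expect_equal(est$Ks, -0.75 * log(0.6), tolerance = 1e-10)
  expect_equal(est$Ka, 0)

  ## identical sequences
  id <- ng86(list(codons_a = rep("GCT", 12), codons_b = rep("GCT", 12)))
  expect_equal(id$Ks, 0)
  expect_equal(id$Ka, 0)
  expect_true(is.na(id$omega))

  ## synonymous third-position changes at every fourfold site push ps to 1
  sat <- ng86(list(codons_a = rep("GCT", 12), codons_b = rep("GCA", 12)))
  expect_true(sat$saturated)
  expect_true(is.na(sat$Ks) || sat$ps >= 0.75)
})

test_that("NG86 is symmetric and matches the path-enumeration oracle", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  set.seed(5)
  picks <- expand.grid(a = sample(sense, 18), b = sample(sense, 18),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(picks))) {
    c1 <- picks$a[i]; c2 <- picks$b[i]
    est <- ng86(list(codons_a = c1, codons_b = c2))
    orc <- oracle_codon_diffs(c1, c2)
    expect_equal(est$Sd, unname(orc["sd"]), tolerance = 1e-12)
    expect_equal(est$Nd, unname(orc["nd"]), tolerance = 1e-12)
    rev <- ng86(list(codons_a = c2, codons_b = c1))
    expect_equal(est$Sd, rev$Sd)
    expect_equal(est$Nd, rev$Nd)
    expect_equal(est$S, rev$S)
  }
})

test_that("codon alignment back-translates gaps and matches the Gotoh oracle score", {
  a <- align_pair_codons("ATGGCTGCTAAA", "ATGGCTAAA")
  expect_equal(sum(a$codons_b == "---"), 1L)
  expect_equal(a$codons_a[a$codons_b != "---"], c("ATG", "GCT", "AAA"))

  set.seed(6)
  for (i in 1:10) {
    na <- sample(4:10, 1); nb <- sample(4:10, 1)
    pa <- paste(.random_test_protein(na), collapse = "")
    pb <- paste(.random_test_protein(nb), collapse = "")
    cds_a <- .backtranslate_test(pa)
    cds_b <- .backtranslate_test(pb)
    aln <- align_pair_codons(cds_a, cds_b)
    expect_equal(aln$score, oracle_global_align_score(pa, pb),
                 tolerance = 1e-9)
  }

  ## identical sequences align without gaps
  same <- align_pair_codons("ATGAAATTTGGG", "ATGAAATTTGGG")
  expect_false(any(same$codons_a == "---" | same$codons_b == "---"))

  ## internal stop is an error naming the gene
  expect_error(align_pair_codons("ATGTAAAAA", "ATGAAAAAA", gene_a = "gX"),
               "gX")
})

test_that("node averaging consolidates duplication events", {
  ## two genes: the single pairwise value
  one <- list(data.frame(gene_a = "a", gene_b = "b", Ks = 0.42))
  expect_equal(node_average_ks(one), 0.42)
  ## three genes from one event: average linkage by hand gives 0.10 and
  ## mean(0.11, 0.12) = 0.115
  tri <- list(data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                         Ks = c(0.10, 0.11, 0.12)))
  expect_equal(sort(node_average_ks(tri)), c(0.10, 0.115))
  expect_equal(node_average_ks(list()), numeric(0))
})

test_that("EM log-likelihood is monotone and the single-component fit is the Normal MLE", {
  set.seed(8)
  x <- c(rnorm(150, 0.3, 0.08), rnorm(100, 1.2, 0.2))
  f <- fit_ks_gmm(x, seed = 2)
  expect_true(all(diff(f$trace) > -1e-6))
  expect_equal(sum(f$weights), 1, tolerance = 1e-9)
  expect_lte(f$k, 4)
  ## closed-form check of the k = 1 likelihood entering AIC
  mu <- mean(x); s <- sqrt(mean((x - mu)^2))
  ll1 <- sum(dnorm(x, mu, s, log = TRUE))
  expect_equal(unname(f$aic_by_k["k1"]), 2 * 2 - 2 * ll1, tolerance = 1e-2)
  expect_error(fit_ks_gmm(rnorm(20, 0.5, 0.1)), "at least 50")
})

test_that("planted WGD divergence is recovered by NG86 on simulated pairs", {
  sim <- simulate_wgd_genome(genome_sim_params(n_ancestral_genes = 60,
                                               seed = 23))
  truth <- sim$truth$pairs[sim$truth$pairs$relation == "wgd", ]
  ks <- ks_for_pairs(truth, sim$catalog)
  expect_lt(abs(median(ks$Ks, na.rm = TRUE) - 0.2) / 0.2, 0.2)
})

test_that("exon conservation counts matched exons with coverage and E-value rules", {
  set.seed(9)
  exons <- vapply(c(120, 150, 180, 140), function(n)
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""), character(1))
  ## identical sets
  ec <- exon_conservation(exons, exons)
  expect_equal(ec$n_matched, 4L)
  expect_equal(ec$shared_pct, 100)
  expect_equal(ec$gain_loss, 0L)
  ## one exon lost in copy B: shared = 2*3/7
  ec2 <- exon_conservation(exons, exons[1:3])
  expect_equal(ec2$n_matched, 3L)
  expect_equal(ec2$shared_pct, 100 * 6 / 7, tolerance = 1e-9)
  expect_equal(ec2$gain_loss, 1L)
  ## unrelated sequence does not match at E <= 1e-20
  other <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  ec3 <- exon_conservation(exons[1], other)
  expect_equal(ec3$n_matched, 0L)
  expect_warning(expect_null(exon_conservation(character(0), exons)),
                 "skipped")
})
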