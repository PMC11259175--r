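test_that("gene position parsing assigns ranks, lengths, and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc1\tsrc\tgene\t100\t400\t.\t+\t.\tID=gB",
    "sc1\tsrc\texon\t100\t189\t.\t+\t.\tParent=gB",
    "sc1\tsrc\texon\t250\t309\t.\t+\t.\tParent=gB",
    "sc1\tsrc\tgene\t50\t80\t.\t-\t.\tID=gA",
    "sc1\tsrc\tgene\t500\t600\t.\t+\t.\tID=gC",
    "sc1\tsrc\tgene\t700\t650\t.\t+\t.\tID=gBad"), path)
  expect_warning(cat1 <- parse_gene_positions(path), "malformed")
  g <- cat1$genes
  expect_equal(nrow(g), 3)
  expect_equal(g$rank[match(c("gA", "gB", "gC"), g$gene_id)], c(0L, 1L, 2L))
  expect_equal(g$length[g$gene_id == "gB"], 150L)  # 90 + 60
  expect_equal(g$length[g$gene_id == "gA"], 31L)   # no exon rows: span

  ## empty file -> empty catalog
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(parse_gene_positions(empty)$genes), 0)

  ## duplicate gene id -> hard error
  dup <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("sc1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1",
               "sc1\tsrc\tgene\t20\t30\t.\t+\t.\tID=g1"), dup)
  expect_error(parse_gene_positions(dup), "duplicate")
})

test_that("catalog write/parse round trip preserves coordinates, strands, ranks", {
  set.seed(42)
  sim <- simulate_wgd_genome(genome_sim_params(n_ancestral_genes = 30, seed = 4))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_positions(sim$catalog, path)
  back <- parse_gene_positions(path)
  a <- sim$catalog$genes[order(sim$catalog$genes$gene_id), ]
  b <- back$genes[order(back$genes$gene_id), ]
  for (col in c("gene_id", "scaffold", "start", "end", "strand", "rank"))
    expect_equal(a[[col]], b[[col]])
  ## rank is a permutation of 0..n-1 within every scaffold
  for (sc in unique(b$scaffold))
    expect_setequal(b$rank[b$scaffold == sc],
                    seq_len(sum(b$scaffold == sc)) - 1L)
})

test_that("hit filtering applies coverage, E-value and top-5 rules and is idempotent", {
  h <- hit_set(data.frame(
    query_id = c("q", "q", "q", rep("q", 7), "s"),
    subject_id = c("q", "badE", "badCov", paste0("t", 1:7), "s2"),
    identity = 90,
    evalue = c(1e-30, 1e-3, 1e-30, 10^-(30:24), 1e-30),
    query_coverage = c(90, 90, 40, rep(90, 7), 60),
    subject_coverage = c(90, 90, 40, rep(90, 7), 20),
    bitscore = 200))
  f <- filter_hits(h)
  expect_true(f$filtered)
  expect_false("q" %in% f$hits$subject_id[f$hits$query_id == "q"])  # self hit
  expect_false("badE" %in% f$hits$subject_id)    # E = 1e-3 removed
  expect_false("badCov" %in% f$hits$subject_id)  # both coverages 40 removed
  ## 7 passing candidates -> the 5 smallest E-values kept
  kept <- f$hits[f$hits$query_id == "q", ]
  expect_equal(nrow(kept), 5)
  expect_setequal(kept$subject_id, paste0("t", 1:5))
  ## coverage rule is OR: query 60 / subject 20 passes
  expect_true("s2" %in% f$hits$subject_id)
  ## idempotent
  f2 <- filter_hits(f)
  expect_equal(f2$hits, f$hits)
})

test_that("count parsing enforces integer counts and sample sheet coverage", {
  sheet <- toy_samples(1)[1:4, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- data.frame(gene = c("g1", "g2"), matrix(1:8, 2,
                  dimnames = list(NULL, sheet$sample[1:4])), check.names = FALSE)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pc <- parse_counts(path, sheet)
  expect_equal(dim(pc$counts), c(2L, 4L))
  expect_identical(pc$samples$sample, colnames(pc$counts))

  ## sheet missing a column's metadata -> error
  expect_error(parse_counts(path, sheet[1:3, ]), "absent from sheet")

  ## float count -> error naming the cell
  m$free_28_r1[1] <- 3.7
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_counts(path, sheet), "g1")
})
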