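test_that("normalization follows median-of-ratios and the FPKM formula", {
  counts <- matrix(c(10L, 100L, 10L, 100L, 20L, 200L), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  nm <- normalize_counts(counts, gene_lengths = c(g1 = 1000, g2 = 500))
  ## equal libraries -> equal size factors; doubled column -> doubled factor
  expect_equal(nm$size_factors[["s1"]], nm$size_factors[["s2"]])
  expect_equal(nm$size_factors[["s3"]], 2 * nm$size_factors[["s1"]])
  ## formula check: 1 kb gene, 10 counts, 1e6 effective library -> FPKM 10
  big <- matrix(c(10L, 999990L), nrow = 2,
                dimnames = list(c("g1", "gBig"), "s1"))
  nb <- normalize_counts(big, gene_lengths = c(g1 = 1000, gBig = 1e6))
  expect_equal(nb$effective_lib_sizes[["s1"]], 1e6)
  expect_equal(nb$fpkm["g1", "s1"], 10)
  expect_error(normalize_counts(matrix(0L, 2, 2)), "all-zero")
})

test_that("DE status thresholds and contrast naming follow the design", {
  samples <- toy_samples(3)
  set.seed(31)
  G <- 400
  mu <- 2^rnorm(G, 7, 0.8)
  Y <- matrix(rnbinom(G * 12, mu = rep(mu, 12), size = 10), nrow = G,
              dimnames = list(sprintf("g%03d", 1:G), samples$sample))
  ## plant 20 strong up genes in symbiotic at 28
  sel <- samples$lifestyle == "symbiotic" & samples$temperature == 28
  Y[1:20, sel] <- matrix(rnbinom(20 * 3, mu = mu[1:20] * 10, size = 10), 20)
  de <- test_de(Y, samples, "L-28")
  planted <- de[match(sprintf("g%03d", 1:20), de$gene_id), ]
  expect_gt(mean(planted$status == "up", na.rm = TRUE), 0.8)
  ## status consistent with its own fdr/log2fc fields
  expect_true(all((de$status == "up") ==
                    (de$fdr < 0.01 & de$log2fc > 1), na.rm = TRUE))
  expect_true(all((de$status == "down") ==
                    (de$fdr < 0.01 & de$log2fc < -1), na.rm = TRUE))
  expect_error(test_de(Y, samples, "L-99"), "unknown contrast")
})

test_that("DE fold changes agree with an independent engine on strong signals", {
  samples <- toy_samples(3)
  set.seed(32)
  G <- 300
  mu <- 2^rnorm(G, 7, 0.8)
  Y <- matrix(rnbinom(G * 12, mu = rep(mu, 12), size = 10), nrow = G,
              dimnames = list(sprintf("g%03d", 1:G), samples$sample))
  sel <- samples$lifestyle == "symbiotic" & samples$temperature == 28
  Y[1:30, sel] <- matrix(rnbinom(30 * 3, mu = mu[1:30] * 8, size = 10), 30)
  de <- test_de(Y, samples, "L-28")

  grp <- factor(samples$condition)
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- levels(grp)
  y <- edgeR::DGEList(Y)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmFit(y, design)
  ctr <- numeric(4); names(ctr) <- levels(grp)
  ctr["symbiotic_28"] <- 1; ctr["free_28"] <- -1
  lrt <- edgeR::glmLRT(fit, contrast = ctr)
  lfc_edger <- lrt$table$logFC[match(de$gene_id, rownames(lrt$table))]
  expect_gt(cor(de$log2fc, lfc_edger), 0.98)
  ## the two engines call the same strong genes
  top_ours <- de$gene_id[de$status != "ns"]
  top_edger <- rownames(edgeR::topTags(lrt, n = length(top_ours))$table)
  expect_gt(length(intersect(top_ours, top_edger)) /
              max(length(top_ours), 1), 0.8)
})

test_that("expressed-pair filter requires both copies above threshold", {
  counts <- rbind(
    ok_a = rep(15L, 12), ok_b = rep(20L, 12),
    half = c(rep(15L, 6), rep(0L, 6)),       # exactly 50% of samples
    low = rep(3L, 12), zero = rep(0L, 12))
  colnames(counts) <- toy_samples(3)$sample
  pairs <- data.frame(gene_a = c("ok_a", "ok_a", "ok_a", "ok_a"),
                      gene_b = c("ok_b", "half", "low", "zero"))
  kept <- filter_expressed_pairs(counts, pairs)
  expect_equal(kept$gene_b, c("ok_b", "half"))  # >= 10 in >= 50% passes
  ## hand-evaluated toy: dropping the threshold to 16 removes ok_a pairs
  expect_equal(nrow(filter_expressed_pairs(counts, pairs, min_count = 16)), 0L)
})

test_that("pair group rules partition pairs as specified", {
  contrasts <- c("L-28", "L-34", "T-Fr", "T-Sy")
  mk_de <- function(...) {
    spec <- list(...)
    rows <- lapply(names(spec), function(g) {
      st <- rep("ns", 4)
      for (nm in names(spec[[g]])) st[match(nm, contrasts)] <- spec[[g]][[nm]]
      data.frame(gene_id = g, contrast = contrasts, log2fc = 0, pvalue = 1,
                 fdr = 1, status = st)
    })
    do.call(rbind, rows)
  }
  de <- mk_de(
    a1 = list(), b1 = list(),
    a2 = list("L-28" = "up"), b2 = list(),
    a3 = list("T-Sy" = "up"), b3 = list("T-Sy" = "up"),
    a4 = list("T-Fr" = "up"), b4 = list("L-28" = "down"),
    a5 = list("L-34" = "up"), b5 = list("L-34" = "down"),
    a53 = list("L-34" = "up", "T-Fr" = "up"),
    b53 = list("L-34" = "down", "T-Fr" = "up"))
  pairs <- data.frame(gene_a = c("a1", "a2", "a3", "a4", "a5", "a53"),
                      gene_b = c("b1", "b2", "b3", "b4", "b5", "b53"))
  got <- classify_pair_groups(de, pairs)
  ## the mixed case has both an opposing and a same-direction contrast:
  ## opposing wins (group 5)
  expect_equal(got$group, c(1L, 2L, 3L, 4L, 5L, 5L))
  expect_error(classify_pair_groups(de, data.frame(gene_a = "zz", gene_b = "a1")),
               "missing DE rows")
})

test_that("pair correlation matches the hand formula and flags degenerate profiles", {
  expr <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                c = c(4, 3, 2, 1), d = c(2, 2, 2, 2),
                e = c(1, 3, 2, 5))
  pairs <- data.frame(gene_a = c("a", "a", "a", "a"),
                      gene_b = c("b", "c", "d", "e"))
  r <- pair_correlation(expr, pairs)
  expect_equal(r[1], 1)
  expect_equal(r[2], -1)
  expect_true(is.na(r[3]))
  expect_equal(r[4], cor(c(1, 2, 3, 4), c(1, 3, 2, 5)))
})

test_that("tau boundary and hand-computed cases behave as defined", {
  samples <- toy_samples(2)
  conds <- samples$condition
  mk_fpkm <- function(cond_means) {
    ## FPKM values whose log2(FPKM+1) condition means equal cond_means
    v <- 2^cond_means[match(conds, names(cond_means))] - 1
    matrix(v, nrow = 1, dimnames = list("g", samples$sample))
  }
  cm <- setNames(c(3, 0, 0, 0),
                 c("free_28", "free_34", "symbiotic_28", "symbiotic_34"))
  tau1 <- tau_index(mk_fpkm(cm), samples)
  expect_equal(tau1$tau, 1)
  expect_equal(tau1$peak_condition, "free_28")

  uni <- tau_index(mk_fpkm(cm * 0 + 3), samples)
  expect_equal(uni$tau, 0)

  ## condition means (1, 0.5, 0, 0) -> 2.5/3; below eligibility (max = 1)
  t3 <- tau_index(mk_fpkm(setNames(c(1, 0.5, 0, 0), names(cm))), samples)
  expect_false(t3$eligible)
  t3b <- tau_index(mk_fpkm(setNames(c(2, 1, 0, 0), names(cm))), samples)
  expect_equal(t3b$tau, (0 + 0.5 + 1 + 1) / 3)

  ## scale invariance on the log-mean scale and zero expression
  t0 <- tau_index(mk_fpkm(cm * 0), samples)
  expect_false(t0$eligible)
  expect_true(is.na(t0$tau))
})

test_that("tau class comparisons reject strongly shifted classes", {
  set.seed(33)
  tau <- data.frame(gene_id = sprintf("g%03d", 1:120),
                    tau = c(runif(60, 0.1, 0.5), runif(60, 0.1, 0.5) + 0.45),
                    eligible = TRUE, peak_condition = "free_28")
  classes <- data.frame(gene_id = tau$gene_id,
                        category = rep(c("singleton", "wgd_segmental"), each = 60))
  res <- tau_class_tests(tau, classes)
  expect_lt(res$kruskal_p, 1e-5)
  ## two classes: Kruskal-Wallis and Wilcoxon agree at alpha = 0.05
  expect_lt(res$pairwise_p["wgd_segmental", "singleton"], 0.05)
  classes$category[1] <- "lonely"
  expect_warning(tau_class_tests(tau, classes), "excluded")
})

test_that("chi-square preference test matches hand computation with residual p-values", {
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  res <- categorical_preference(tab)
  expect_equal(res$chi2, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-9)
  expect_equal(dim(res$residuals), dim(tab))
  ## proportional table: residuals 0, cell p-values 1
  prop <- matrix(c(10, 20, 20, 40), 2, byrow = TRUE)
  rp <- categorical_preference(prop)
  expect_equal(max(abs(rp$residuals)), 0, tolerance = 1e-9)
  expect_equal(unname(rp$cell_pvalues), matrix(1, 2, 2))
  expect_error(categorical_preference(matrix(1:3, 1)), ">= 2 rows")
})
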