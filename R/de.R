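#' Differential expression across lifestyle and temperature contrasts
#'
#' Per-gene negative-binomial GLM on the 2x2 (lifestyle x temperature)
#' design, parameterised by condition means with log size-factor offsets.
#' Gene-wise dispersions are estimated by Cox-Reid adjusted profile
#' likelihood on a grid and shrunk 50/50 (log scale) toward a lowess
#' mean-dispersion trend; the contrast coefficient is tested with a Wald
#' test and Benjamini-Hochberg adjusted within each contrast. A gene is
#' called `up` when fdr < `fdr_level` and log2 fold change > `lfc_threshold`
#' (`down` for the negative side), otherwise `ns`.
#'
#' The four contrasts are `L-28` (symbiotic vs free-living at 28 C), `L-34`
#' (symbiotic vs free-living at 34 C), `T-Fr` (34 vs 28 C, free-living) and
#' `T-Sy` (34 vs 28 C, symbiotic).
#'
#' @param counts integer gene-by-sample matrix.
#' @param samples sample sheet (see [read_sample_sheet()]); at least two
#'   replicates per condition entering a contrast.
#' @param contrast one or more of `"L-28"`, `"L-34"`, `"T-Fr"`, `"T-Sy"`.
#' @param min_count,min_prop expression prefilter: keep genes with counts at
#'   least `min_count` in at least `min_prop` of samples (defaults 5, 0.25).
#' @param fdr_level,lfc_threshold the DE call thresholds (defaults 0.01, 1).
#' @return data.frame with columns `gene_id`, `contrast`, `log2fc`,
#'   `pvalue`, `fdr`, `status` (one block of rows per requested contrast).
#' @export
test_de <- function(counts, samples, contrast,
                    min_count = 5, min_prop = 0.25,
                    fdr_level = 0.01, lfc_threshold = 1) {
  samples <- validate_sample_sheet(samples)
  if (!identical(colnames(counts), samples$sample))
    samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  if (anyNA(samples$sample)) stop("count columns missing from sample sheet")
  cmap <- list("L-28" = c("symbiotic_28", "free_28"),
               "L-34" = c("symbiotic_34", "free_34"),
               "T-Fr" = c("free_34", "free_28"),
               "T-Sy" = c("symbiotic_34", "symbiotic_28"))
  bad <- setdiff(contrast, names(cmap))
  if (length(bad)) stop("unknown contrast: ", paste(bad, collapse = ", "))

  keep <- rowMeans(counts >= min_count) >= min_prop
  Y <- counts[keep, , drop = FALSE]
  if (!nrow(Y)) stop("no genes pass the expression prefilter")
  cond <- samples$condition
  for (cn in contrast) {
    reps <- table(cond)[cmap[[cn]]]
    if (anyNA(reps) || any(reps < 2))
      stop("contrast ", cn, " needs >= 2 replicates per condition")
  }

  sf <- .size_factors(Y)
  w <- sf * mean(colSums(Y) / sf)   # effective library sizes
  fit <- .nb_fit_dispersions(Y, w, cond)

  out <- lapply(contrast, function(cn) {
    tr <- cmap[[cn]]
    bt <- fit$beta[, tr[1]]; br <- fit$beta[, tr[2]]
    it <- fit$info[, tr[1]]; ir <- fit$info[, tr[2]]
    se <- sqrt(1 / it + 1 / ir)
    z <- (bt - br) / se
    ## t reference with moderated df: residual df (samples minus fitted
    ## condition means) plus an equal prior df for the trend half of the
    ## 50/50 dispersion shrinkage. A plain normal reference is
    ## anti-conservative at 2-3 replicates per condition.
    df_res <- length(cond) - length(unique(cond))
    p <- 2 * stats::pt(-abs(z), df = 2 * df_res)
    p[!is.finite(p)] <- 1
    fdr <- p.adjust(p, method = "BH")
    lfc <- (bt - br) / log(2)
    status <- ifelse(fdr < fdr_level & lfc > lfc_threshold, "up",
              ifelse(fdr < fdr_level & lfc < -lfc_threshold, "down", "ns"))
    data.frame(gene_id = rownames(Y), contrast = cn, log2fc = lfc,
               pvalue = p, fdr = fdr, status = status,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

## Newton solve of per-condition NB means for all genes at once.
## Returns beta (genes x conditions, natural log) and Fisher information.
.nb_group_beta <- function(Y, w, cond, phi, iters = 8) {
  conds <- sort(unique(cond))
  G <- nrow(Y)
  beta <- matrix(NA_real_, G, length(conds), dimnames = list(NULL, conds))
  info <- beta
  for (cc in conds) {
    j <- which(cond == cc)
    yj <- Y[, j, drop = FALSE]
    wj <- w[j]
    b <- log((rowSums(yj) + 0.5) / sum(wj))
    for (it in seq_len(iters)) {
      mu <- exp(b) %o% wj
      f <- rowSums((yj - mu) / (1 + phi * mu))
      fp <- -rowSums(mu * (1 + phi * yj) / (1 + phi * mu)^2)
      step <- f / fp
      step[!is.finite(step)] <- 0
      b <- pmin(pmax(b - step, -30), 30)
    }
    mu <- exp(b) %o% wj
    beta[, cc] <- b
    info[, cc] <- rowSums(mu / (1 + phi * mu))
  }
  list(beta = beta, info = info)
}

.nb_loglik <- function(Y, mu, phi) {
  a <- 1 / phi
  rowSums(lgamma(Y + a) - lgamma(a) - lgamma(Y + 1) +
            Y * log(phi * mu / (1 + phi * mu)) - a * log1p(phi * mu))
}

## Cox-Reid APL dispersion on a log grid, lowess trend, 50/50 log shrinkage,
## then the final group fit at the shrunk dispersions.
.nb_fit_dispersions <- function(Y, w, cond,
                                phi_grid = exp(seq(log(1e-4), log(4),
                                                   length.out = 25))) {
  G <- nrow(Y)
  apl <- matrix(-Inf, G, length(phi_grid))
  for (g in seq_along(phi_grid)) {
    phi <- rep(phi_grid[g], G)
    fit <- .nb_group_beta(Y, w, cond, phi)
    mu <- exp(fit$beta[, cond, drop = FALSE]) * rep(w, each = G)
    cr <- 0.5 * rowSums(log(pmax(fit$info, 1e-12)))
    apl[, g] <- .nb_loglik(Y, pmax(mu, 1e-12), phi_grid[g]) - cr
  }
  phi_gene <- phi_grid[max.col(apl, ties.method = "first")]
  xm <- log(rowMeans(sweep(Y, 2, w / mean(w), "/")) + 0.5)
  lo <- lowess(xm, log(phi_gene), f = 0.5)
  phi_trend <- exp(approx(lo$x, lo$y, xout = xm, rule = 2, ties = mean)$y)
  phi <- exp(0.5 * log(phi_gene) + 0.5 * log(phi_trend))
  fit <- .nb_group_beta(Y, w, cond, phi, iters = 12)
  list(beta = fit$beta, info = fit$info, phi = phi, phi_gene = phi_gene,
       phi_trend = phi_trend)
}
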