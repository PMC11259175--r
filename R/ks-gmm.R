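#' Cluster homologous genes from a filtered hit set
#'
#' Connected components of the undirected homology graph; used to group
#' paralogs before node-averaging the Ks distribution.
#'
#' @param hits a filtered [hit_set].
#' @return A list of character vectors of gene ids (components of size >= 2).
#' @export
cluster_homologs <- function(hits) {
  p <- .hit_pairs(hits)
  if (!nrow(p)) return(list())
  g <- igraph::graph_from_data_frame(p, directed = FALSE)
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

#' Node-averaged Ks values per homologous cluster
#'
#' Within each cluster of paralogs, pairwise Ks values are consolidated by
#' average-linkage hierarchical clustering on the Ks distance: each internal
#' node of the dendrogram contributes one value, the mean Ks over the gene
#' pairs it joins. This removes the redundancy of a single duplication event
#' being counted once per gene pair rather than once per event.
#'
#' @param clusters a list of data.frames, each with columns `gene_a`,
#'   `gene_b`, `Ks` (one cluster of homologs per element). Saturated or
#'   missing Ks should be removed beforehand.
#' @return Numeric vector of node-averaged Ks values (the union over
#'   clusters).
#' @export
node_average_ks <- function(clusters) {
  vals <- lapply(clusters, function(cl) {
    cl <- cl[is.finite(cl$Ks), , drop = FALSE]
    if (!nrow(cl)) return(numeric(0))
    genes <- sort(unique(c(cl$gene_a, cl$gene_b)))
    if (length(genes) == 2) return(cl$Ks[1])
    m <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
    m[cbind(cl$gene_a, cl$gene_b)] <- cl$Ks
    m[cbind(cl$gene_b, cl$gene_a)] <- cl$Ks
    if (anyNA(m[upper.tri(m)])) m[is.na(m)] <- mean(cl$Ks)
    diag(m) <- 0
    hc <- hclust(stats::as.dist(m), method = "average")
    members <- lapply(seq_along(genes), function(i) genes[i])
    node_vals <- numeric(nrow(hc$merge))
    groups <- vector("list", nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
      pick <- function(j) if (j < 0) members[[-j]] else groups[[j]]
      left <- pick(hc$merge[i, 1]); right <- pick(hc$merge[i, 2])
      cross <- expand.grid(a = left, b = right, stringsAsFactors = FALSE)
      node_vals[i] <- mean(m[cbind(cross$a, cross$b)])
      groups[[i]] <- c(left, right)
    }
    node_vals
  })
  out <- unlist(vals, use.names = FALSE)
  if (is.null(out)) numeric(0) else out
}

#' Fit a Gaussian mixture to a Ks distribution
#'
#' EM fits with k-means initialisation (fixed seed, `n_restarts` restarts)
#' for k = 1..`k_max` components; the component count minimising
#' AIC = 2(3k - 1) - 2 logL is selected. Values outside
#' `[ks_min, ks_max_cut]` are excluded before fitting; fewer than 50 usable
#' values is an error. A low-Ks component capturing an appreciable mixture
#' weight is the classical signature of a recent WGD.
#'
#' @param ks_values numeric Ks values (node-averaged recommended).
#' @param k_max maximum number of components (default 4).
#' @param ks_min,ks_max_cut fitting window (defaults 0.001 and 3.0).
#' @param seed RNG seed for initialisation.
#' @param n_restarts k-means restarts per k (default 10).
#' @return An object of class `gmm_fit`: `k`, `weights`, `means`, `sds`
#'   (sorted by mean), `loglik`, `aic_by_k`, `n_points`, and the
#'   log-likelihood `trace` of the selected fit.
#' @export
fit_ks_gmm <- function(ks_values, k_max = 4, ks_min = 0.001,
                       ks_max_cut = 3.0, seed = 1, n_restarts = 10) {
  x <- ks_values[is.finite(ks_values) & ks_values >= ks_min &
                   ks_values <= ks_max_cut]
  n <- length(x)
  if (n < 50)
    stop("only ", n, " usable Ks values in [", ks_min, ", ", ks_max_cut,
         "]; at least 50 are needed - provide more pairs")
  fits <- vector("list", k_max)
  aic <- setNames(numeric(k_max), paste0("k", seq_len(k_max)))
  for (k in seq_len(k_max)) {
    best <- NULL
    for (r in seq_len(if (k == 1) 1 else n_restarts)) {
      set.seed(seed * 1000L + k * 100L + r)
      init <- if (k == 1) list(mu = mean(x), sd = sd(x), w = 1) else {
        km <- suppressWarnings(kmeans(x, centers = k, nstart = 1, iter.max = 50))
        list(mu = as.numeric(km$centers),
             sd = pmax(sqrt(km$withinss / pmax(km$size, 1)), 1e-3),
             w = km$size / n)
      }
      fit <- .gmm_em(x, init$w, init$mu, init$sd)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    fits[[k]] <- best
    aic[k] <- 2 * (3 * k - 1) - 2 * best$loglik
  }
  k_sel <- unname(which.min(aic))
  f <- fits[[k_sel]]
  ord <- order(f$mu)
  structure(list(k = k_sel, weights = f$w[ord], means = f$mu[ord],
                 sds = f$sd[ord], loglik = f$loglik, aic_by_k = aic,
                 n_points = n, trace = f$trace),
            class = "gmm_fit")
}

## EM with variance regularisation and the convergence rule of standard
## mixture implementations (stop when the per-observation log-likelihood
## gain drops below `tol`); both choices mirror the reference tooling used
## for Ks mixtures in this field.
.gmm_em <- function(x, w, mu, s, max_iter = 100, tol = 1e-3,
                    reg_var = 1e-6) {
  n <- length(x); k <- length(mu)
  s <- sqrt(pmax(s^2, reg_var))
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    trace <- c(trace, ll)
    if ((ll - ll_old) / n < tol && it > 1) break
    ll_old <- ll
    g <- dens / rs
    nk <- colSums(g)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(g * x) / nk
    s <- sqrt(colSums(g * (x - rep(mu, each = n))^2) / nk + reg_var)
  }
  list(w = w, mu = mu, sd = s, loglik = ll, trace = trace)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("gmm_fit: k =", x$k, "components over", x$n_points, "Ks values\n")
  comp <- data.frame(weight = round(x$weights, 4),
                     mean = round(x$means, 4), sd = round(x$sds, 4))
  print(comp)
  cat("AIC by k:", paste(sprintf("%s=%.1f", names(x$aic_by_k), x$aic_by_k),
                         collapse = ", "), "\n")
  invisible(x)
}
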