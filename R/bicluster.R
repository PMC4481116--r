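# Bi-dimensional hierarchical clustering with correlation distance and
# optimal leaf ordering.

#' Pearson correlation distance between matrix rows
#'
#' Distance `1 - r` between the rows of `x`. Rows with zero variance
#' have no defined correlation; they are assigned the maximal distance
#' 2 to every other row (with a warning) so that clustering can
#' proceed.
#'
#' @param x Numeric matrix; distances are between rows.
#' @return A `dist` object over the rows.
#' @export
cor_dist <- function(x) {
  sds <- apply(x, 1, stats::sd)
  const <- sds == 0
  d <- matrix(2, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  if (sum(!const) >= 2L) {
    r <- stats::cor(t(x[!const, , drop = FALSE]))
    d[!const, !const] <- 1 - r
  }
  if (any(const)) {
    warning(sum(const), " zero-variance rows assigned maximal correlation distance 2",
            call. = FALSE)
  }
  diag(d) <- 0
  stats::as.dist(d)
}

# Optimal leaf ordering (Bar-Joseph dynamic program): among all 2^(n-1)
# orderings compatible with the dendrogram, find one minimizing the sum
# of distances between adjacent leaves. For each internal node and each
# admissible pair of end leaves (u, w) the minimal cost is computed
# bottom-up; the combine step is a min-plus product over the children's
# tables and the cross-distance block.
olo_order <- function(hc, dmat) {
  n <- nrow(dmat)
  if (n <= 2L) return(hc$order)
  merges <- hc$merge
  nodes <- vector("list", nrow(merges))

  node_leaves <- function(id) if (id < 0) -id else nodes[[id]]$leaves
  # full symmetric end-pair cost matrix of a child (Inf where both ends
  # fall in the same grandchild and thus cannot be the two extremes)
  node_full <- function(id) {
    if (id < 0) return(matrix(0, 1, 1))
    nd <- nodes[[id]]
    na <- length(nd$la); nb <- length(nd$lb)
    f <- matrix(Inf, na + nb, na + nb)
    f[seq_len(na), na + seq_len(nb)] <- nd$M
    f[na + seq_len(nb), seq_len(na)] <- t(nd$M)
    f
  }

  for (v in seq_len(nrow(merges))) {
    ia <- merges[v, 1]; ib <- merges[v, 2]
    la <- node_leaves(ia); lb <- node_leaves(ib)
    na <- length(la); nb <- length(lb)
    fa <- node_full(ia); fb <- node_full(ib)
    dab <- dmat[la, lb, drop = FALSE]

    # H[m, w] = min_k dab[m, k] + fb[k, w]
    H <- matrix(Inf, na, nb); K <- matrix(1L, na, nb)
    for (k in seq_len(nb)) {
      cand <- outer(dab[, k], fb[k, ], "+")
      upd <- cand < H
      if (any(upd)) { H[upd] <- cand[upd]; K[upd] <- k }
    }
    # M[u, w] = min_m fa[u, m] + H[m, w]
    M <- matrix(Inf, na, nb); Pm <- matrix(1L, na, nb)
    for (m in seq_len(na)) {
      cand <- outer(fa[, m], H[m, ], "+")
      upd <- cand < M
      if (any(upd)) { M[upd] <- cand[upd]; Pm[upd] <- m }
    }
    Pk <- matrix(K[cbind(as.vector(Pm), rep(seq_len(nb), each = na))], na, nb)
    nodes[[v]] <- list(leaves = c(la, lb), la = la, lb = lb,
                       ca = ia, cb = ib, M = M, Pm = Pm, Pk = Pk)
  }

  build <- function(id, u, w) {
    if (id < 0) return(-id)
    nd <- nodes[[id]]
    if (u %in% nd$la) {
      i <- match(u, nd$la); j <- match(w, nd$lb)
      m <- nd$la[nd$Pm[i, j]]; k <- nd$lb[nd$Pk[i, j]]
      c(build(nd$ca, u, m), build(nd$cb, k, w))
    } else {
      rev(build(id, w, u))
    }
  }

  root <- nodes[[nrow(merges)]]
  best <- which(root$M == min(root$M), arr.ind = TRUE)[1, ]
  build(nrow(merges), root$la[best[1]], root$lb[best[2]])
}

#' Bi-dimensional hierarchical clustering of a fingerprint matrix
#'
#' Agglomerative clustering of both axes of a genes-by-samples
#' fingerprint matrix with Pearson correlation distance (`1 - r`) and
#' average linkage, followed by optimal leaf ordering: among all
#' orderings compatible with each dendrogram, the one minimizing the
#' sum of distances between adjacent leaves. A flat sample partition is
#' cut at `k_samples` clusters.
#'
#' Leaf-order optimization is exact (a dynamic program over the
#' dendrogram) and is intended for panel-scale matrices; on thousands
#' of genes it dominates the runtime and can be disabled.
#'
#' @param m Numeric matrix, genes x samples, >= 2 of each.
#' @param k_samples Number of flat sample clusters (default 2).
#' @param optimize_leaves Optimize leaf order on both axes (default
#'   `TRUE`).
#' @return A list of class `bicluster`: `gene_hclust`, `sample_hclust`
#'   (with optimized `$order`), `gene_order`, `sample_order` (label
#'   vectors), `sample_partition` (named integer vector of cluster
#'   memberships).
#' @export
bicluster <- function(m, k_samples = 2, optimize_leaves = TRUE) {
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 genes and 2 samples", call. = FALSE)
  }
  if (k_samples < 1L || k_samples > ncol(m)) {
    stop("k_samples must be between 1 and the number of samples", call. = FALSE)
  }
  dg <- cor_dist(m)
  ds <- cor_dist(t(m))
  hg <- stats::hclust(dg, method = "average")
  hs <- stats::hclust(ds, method = "average")
  if (optimize_leaves) {
    hg$order <- olo_order(hg, as.matrix(dg))
    hs$order <- olo_order(hs, as.matrix(ds))
  }
  part <- stats::cutree(hs, k = k_samples)
  structure(list(gene_hclust = hg, sample_hclust = hs,
                 gene_order = rownames(m)[hg$order],
                 sample_order = colnames(m)[hs$order],
                 sample_partition = part),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat("bicluster:", length(x$gene_order), "genes x", length(x$sample_order),
      "samples; sample order:", paste(x$sample_order, collapse = ", "), "\n")
  invisible(x)
}
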