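#' Density-based cluster validity (DBCV)
#'
#' Implements the density-based clustering validation index: all-points core
#' distances (inverse-distance means with exponent equal to the embedding
#' dimension), mutual reachability distances, per-cluster density sparseness
#' (largest internal MST edge) versus density separation (smallest mutual
#' reachability to any other cluster), combined into a per-cluster validity in
#' \[-1, 1\] and a size-weighted overall index. Clusters with validity above
#' `valid_above` (0.25 by default) are flagged valid; label 0 is treated as
#' noise and enters only the overall weighting denominator.
#'
#' @param embedding a `meth_embedding` or coordinate matrix.
#' @param labels integer vector of cluster labels (0 = noise), aligned with
#'   the embedding's samples.
#' @param valid_above validity threshold for the `valid` flag.
#' @return list with `per_cluster` (tibble `label`, `size`, `sparseness`,
#'   `separation`, `validity`, `valid`) and `overall` (numeric).
#' @export
dbcv <- function(embedding, labels, valid_above = 0.25) {
  X <- embedding_coords(embedding)
  stopifnot(nrow(X) == length(labels))
  dim_d <- ncol(X)
  n_all <- nrow(X)
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) == 0) {
    return(list(per_cluster = tibble::tibble(label = integer(),
                                             size = integer(),
                                             sparseness = numeric(),
                                             separation = numeric(),
                                             validity = numeric(),
                                             valid = logical()),
                overall = 0))
  }
  d_all <- as.matrix(stats::dist(X))
  if (any(d_all[upper.tri(d_all)] < 1e-12)) {
    warning("coincident points; distances floored at 1e-12")
    d_all[d_all < 1e-12] <- 1e-12
    diag(d_all) <- 0
  }

  # all-points core distance within each point's own cluster
  apts <- rep(NA_real_, n_all)
  for (L in labs) {
    idx <- which(labels == L)
    if (length(idx) < 2) stop("cluster ", L, " has < 2 points")
    for (i in idx) {
      inv <- (1 / d_all[i, setdiff(idx, i)])^dim_d
      apts[i] <- (sum(inv) / (length(idx) - 1))^(-1 / dim_d)
    }
  }
  mr <- function(i, j) pmax(d_all[i, j, drop = FALSE],
                            outer(apts[i], apts[j], pmax))

  sparseness <- separation <- numeric(length(labs))
  internal_sets <- vector("list", length(labs))
  for (k in seq_along(labs)) {
    idx <- which(labels == labs[k])
    m <- mr(idx, idx)
    diag(m) <- 0
    mst <- prim_mst(m)
    deg <- tabulate(c(mst[, 1], mst[, 2]), nbins = length(idx))
    internal <- which(deg > 1)
    int_edges <- mst[deg[mst[, 1]] > 1 & deg[mst[, 2]] > 1, 3]
    sparseness[k] <- if (length(int_edges)) max(int_edges) else max(mst[, 3])
    internal_sets[[k]] <- if (length(internal)) idx[internal] else idx
  }
  for (k in seq_along(labs)) {
    seps <- vapply(seq_along(labs)[-k], function(j) {
      min(mr(internal_sets[[k]], internal_sets[[j]]))
    }, numeric(1))
    separation[k] <- if (length(seps)) min(seps) else Inf
  }

  validity <- vapply(seq_along(labs), function(k) {
    if (!is.finite(separation[k])) return(1)
    (separation[k] - sparseness[k]) / max(separation[k], sparseness[k])
  }, numeric(1))
  sizes <- vapply(labs, function(L) sum(labels == L), integer(1))
  overall <- sum(sizes / n_all * validity)
  list(per_cluster = tibble::tibble(label = labs, size = sizes,
                                    sparseness = sparseness,
                                    separation = separation,
                                    validity = validity,
                                    valid = validity > valid_above),
       overall = overall)
}
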