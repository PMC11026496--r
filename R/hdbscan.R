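#' HDBSCAN clustering of an embedding
#'
#' Hierarchical density-based clustering: mutual-reachability distances from
#' k-nearest-neighbor core distances, a minimum spanning tree, the condensed
#' cluster tree at `min_cluster_size`, and excess-of-mass cluster selection.
#' Noise points get label 0; clusters are renumbered 1..K by decreasing size.
#'
#' @param embedding a `meth_embedding` from [embed()], or a numeric matrix of
#'   coordinates (rows = samples).
#' @param min_cluster_size smallest cluster size considered real.
#' @param min_samples neighborhood size for core distances; defaults to
#'   `min_cluster_size`.
#' @param allow_single_cluster whether the tree root may be selected.
#' @return an object of class `cluster_assignment`: list with `labels`
#'   (tibble `sample_id`, `label`), `n_clusters`, and the `min_cluster_size`
#'   used.
#' @export
cluster <- function(embedding, min_cluster_size = 4,
                    min_samples = min_cluster_size,
                    allow_single_cluster = FALSE) {
  X <- embedding_coords(embedding)
  n <- nrow(X)
  if (n < min_cluster_size) stop("fewer points than min_cluster_size")
  d <- as.matrix(stats::dist(X))
  core <- apply(d, 1, function(r) sort(r)[min(min_samples, n)])
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0

  mst <- prim_mst(mreach)
  tree <- single_linkage_tree(mst, n)
  cond <- condense_tree(tree, n, min_cluster_size)
  sel <- select_clusters_eom(cond, allow_single_cluster)
  raw <- label_points(cond, sel, n)

  sizes <- table(raw[raw > 0])
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- ifelse(raw > 0, remap[as.character(raw)], 0L)
  ids <- rownames(X) %||% as.character(seq_len(n))
  structure(list(labels = tibble::tibble(sample_id = ids,
                                         label = as.integer(labels)),
                 n_clusters = length(sizes),
                 min_cluster_size = min_cluster_size),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("HDBSCAN: %d clusters, %d noise points of %d samples\n",
              x$n_clusters, sum(x$labels$label == 0), nrow(x$labels)))
  invisible(x)
}

embedding_coords <- function(embedding) {
  if (inherits(embedding, "meth_embedding")) {
    X <- as.matrix(embedding$coords[, c("x", "y")])
    rownames(X) <- embedding$coords$sample_id
    X
  } else {
    as.matrix(embedding)
  }
}

# Prim's algorithm on a full distance matrix; returns edges (i, j, w).
prim_mst <- function(d) {
  n <- nrow(d)
  in_tree <- rep(FALSE, n)
  in_tree[1] <- TRUE
  best_w <- d[1, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]
    edges[k, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & d[j, ] < best_w
    best_from[upd] <- j
    best_w[upd] <- d[j, upd]
  }
  edges[order(edges[, 3]), , drop = FALSE]
}

# Union-find single-linkage dendrogram from sorted MST edges.
# Returns merge list: each row (left_node, right_node, height); leaf nodes are
# 1..n, internal nodes n+1 .. 2n-1 in merge order.
single_linkage_tree <- function(edges, n) {
  parent <- seq_len(2 * n - 1)
  node_of <- seq_len(n)           # current tree node of each root component
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  merges <- matrix(0, n - 1, 3)
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    nxt <- nxt + 1L
    merges[e, ] <- c(node_of[a], node_of[b], edges[e, 3])
    parent[a] <- nxt; parent[b] <- nxt
    parent[nxt] <- nxt
    node_of <- c(node_of, 0)
    node_of[nxt] <- nxt
  }
  merges
}

tree_points <- function(merges, n) {
  pts <- vector("list", 2 * n - 1)
  for (i in seq_len(n)) pts[[i]] <- i
  for (e in seq_len(nrow(merges))) {
    l <- merges[e, 1]; r <- merges[e, 2]
    pts[[n + e]] <- c(pts[[l]], pts[[r]])
  }
  pts
}

# Condensed tree: walk the binary dendrogram top-down. A split is real when
# both sides have >= min_cluster_size points; otherwise the small side's
# points fall out of the running cluster at that split's lambda = 1/height.
condense_tree <- function(merges, n, mcs) {
  pts <- tree_points(merges, n)
  node_height <- c(rep(0, n), merges[, 3])
  children_of <- function(node) {
    if (node <= n) return(NULL)
    merges[node - n, 1:2]
  }
  clusters <- list()
  new_cluster <- function(parent, lambda_birth, size) {
    clusters[[length(clusters) + 1]] <<- list(
      id = length(clusters) + 1, parent = parent,
      lambda_birth = lambda_birth, size = size,
      children = integer(), fallen = integer(), fallen_lambda = numeric())
    length(clusters)
  }
  root <- new_cluster(0L, 0, n)
  # stack of (cluster id, binary node)
  stack <- list(list(cid = root, node = 2 * n - 1))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cid <- fr$cid
    node <- fr$node
    repeat {
      ch <- children_of(node)
      if (is.null(ch)) {
        # cluster reduced to a single point; it falls out when alone
        lam <- 1 / max(node_height[node], .Machine$double.xmin)
        clusters[[cid]]$fallen <- c(clusters[[cid]]$fallen, pts[[node]])
        clusters[[cid]]$fallen_lambda <- c(clusters[[cid]]$fallen_lambda, lam)
        break
      }
      h <- node_height[node]
      lam <- if (h <= 0) Inf else 1 / h
      sizes <- c(length(pts[[ch[1]]]), length(pts[[ch[2]]]))
      big_both <- sizes >= mcs
      if (all(big_both)) {
        for (s in 1:2) {
          kid <- new_cluster(cid, lam, sizes[s])
          clusters[[cid]]$children <- c(clusters[[cid]]$children, kid)
          stack[[length(stack) + 1]] <- list(cid = kid, node = ch[s])
        }
        break
      } else if (!any(big_both)) {
        fall <- c(pts[[ch[1]]], pts[[ch[2]]])
        clusters[[cid]]$fallen <- c(clusters[[cid]]$fallen, fall)
        clusters[[cid]]$fallen_lambda <- c(clusters[[cid]]$fallen_lambda,
                                           rep(lam, length(fall)))
        break
      } else {
        small <- which(!big_both)
        fall <- pts[[ch[small]]]
        clusters[[cid]]$fallen <- c(clusters[[cid]]$fallen, fall)
        clusters[[cid]]$fallen_lambda <- c(clusters[[cid]]$fallen_lambda,
                                           rep(lam, length(fall)))
        node <- ch[which(big_both)]
      }
    }
  }
  clusters
}

cluster_stability <- function(cl, clusters) {
  lam0 <- cl$lambda_birth
  s <- sum(pmin(cl$fallen_lambda, 1e12) - lam0)
  for (kid in cl$children) {
    s <- s + clusters[[kid]]$size * (clusters[[kid]]$lambda_birth - lam0)
  }
  s
}

select_clusters_eom <- function(clusters, allow_single_cluster) {
  nc <- length(clusters)
  stability <- vapply(clusters, cluster_stability, numeric(1),
                      clusters = clusters)
  score <- numeric(nc)
  selected <- logical(nc)
  # process children before parents: ids are created parent-first, so reverse
  for (i in rev(seq_len(nc))) {
    kids <- clusters[[i]]$children
    child_sum <- sum(score[kids])
    is_root <- clusters[[i]]$parent == 0
    if (length(kids) == 0) {
      score[i] <- stability[i]
      selected[i] <- TRUE
    } else if (stability[i] > child_sum && (!is_root || allow_single_cluster)) {
      score[i] <- stability[i]
      selected[i] <- TRUE
      selected[unlist_descendants(clusters, i)] <- FALSE
    } else {
      score[i] <- child_sum
    }
    if (is_root && !allow_single_cluster && length(kids) == 0) {
      selected[i] <- FALSE  # everything is noise
    }
  }
  selected
}

unlist_descendants <- function(clusters, i) {
  out <- integer()
  stack <- clusters[[i]]$children
  while (length(stack)) {
    j <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, j)
    stack <- c(stack, clusters[[j]]$children)
  }
  out
}

cluster_point_set <- function(clusters, i) {
  ids <- c(i, unlist_descendants(clusters, i))
  unique(unlist(lapply(ids, function(j) clusters[[j]]$fallen)))
}

label_points <- function(clusters, selected, n) {
  raw <- rep(0L, n)
  k <- 0L
  for (i in seq_along(clusters)) {
    if (!selected[i]) next
    k <- k + 1L
    raw[cluster_point_set(clusters, i)] <- k
  }
  raw
}
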