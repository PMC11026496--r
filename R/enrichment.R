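#' Probe-bias-aware gene-set enrichment (Wallenius test)
#'
#' Genes carrying more array CpGs are more likely to enter a
#' methylation-derived gene list. Each term is therefore tested with a
#' Wallenius noncentral hypergeometric upper tail whose odds equal the mean
#' CpG-count bias of the term's genes divided by the mean bias of the
#' remaining universe; with uniform bias this reduces exactly to the central
#' hypergeometric test. Benjamini-Hochberg correction is applied across
#' terms.
#'
#' @param query_genes character vector of selected genes (subset of
#'   `universe`).
#' @param genesets tibble with `term` and list-column `genes`
#'   (see [read_gmt()]).
#' @param bias named numeric vector of per-gene CpG counts (>= 1) covering
#'   the universe (see [gene_cpg_counts()]).
#' @param universe character vector of background genes.
#' @return tibble `term`, `n_term`, `overlap`, `odds`, `p`, `q`, list-column
#'   `overlap_genes`, `universe_size`, sorted by `p`.
#' @export
wallenius_test <- function(query_genes, genesets, bias, universe) {
  stopifnot(all(query_genes %in% universe))
  if (!all(universe %in% names(bias))) stop("bias missing for universe genes")
  b <- bias[universe]
  if (any(b < 1)) stop("bias must be >= 1 for every universe gene")
  n_draw <- length(unique(query_genes))
  query <- unique(query_genes)
  rows <- list()
  for (i in seq_len(nrow(genesets))) {
    members <- intersect(genesets$genes[[i]], universe)
    if (length(members) == 0) {
      warning("term ", genesets$term[i], " disjoint from universe; skipped")
      next
    }
    m1 <- length(members)
    m2 <- length(universe) - m1
    x <- length(intersect(query, members))
    odds <- mean(b[members]) / mean(b[setdiff(universe, members)])
    p <- wallenius_upper_tail(x, m1, m2, n_draw, odds)
    rows[[length(rows) + 1]] <- tibble::tibble(
      term = genesets$term[i], n_term = m1, overlap = x, odds = odds,
      p = p, overlap_genes = list(intersect(query, members)),
      universe_size = length(universe))
  }
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  dplyr::arrange(out[, c("term", "n_term", "overlap", "odds", "p", "q",
                         "overlap_genes", "universe_size")], .data$p)
}

#' Wallenius noncentral hypergeometric upper tail
#'
#' `P(X >= x)` for the number of "white" genes among `n` draws without
#' replacement from `m1` white and `m2` black genes, white genes weighted by
#' `odds`. Point masses use the integral representation of the Wallenius
#' density, evaluated by adaptive quadrature; `odds = 1` reduces to the
#' central hypergeometric tail.
#'
#' @param x observed overlap.
#' @param m1,m2 white/black universe sizes.
#' @param n number of draws.
#' @param odds weight of white genes relative to black.
#' @return upper-tail probability.
#' @export
wallenius_upper_tail <- function(x, m1, m2, n, odds) {
  if (x <= 0) return(1)
  support <- max(0, n - m2):min(n, m1)
  ks <- support[support >= x]
  if (length(ks) == 0) return(0)
  sum(vapply(ks, dwallenius, numeric(1), m1 = m1, m2 = m2, n = n,
             odds = odds))
}

# Wallenius point mass via the Fog (2008) integral:
# P(X = k) = C(m1,k) C(m2,n-k) * Int_0^1 (1 - t^(w/D))^k (1 - t^(1/D))^(n-k) dt
# with D = w (m1 - k) + (m2 - (n - k)).
dwallenius <- function(k, m1, m2, n, odds) {
  if (k < max(0, n - m2) || k > min(n, m1)) return(0)
  D <- odds * (m1 - k) + (m2 - (n - k))
  if (D <= 0) {  # everything drawn; degenerate point
    return(as.numeric(k == min(n, m1)))
  }
  lchoose_term <- lchoose(m1, k) + lchoose(m2, n - k)
  # substitute t = u^D so the integrand is smooth on [0, 1]:
  # D * u^(D-1) * (1 - u^odds)^k * (1 - u)^(n-k)
  integrand <- function(u) {
    exp(log(D) + (D - 1) * log(u) + k * log1p(-u^odds) +
          (n - k) * log1p(-u))
  }
  int <- stats::integrate(integrand, 0, 1, rel.tol = 1e-12,
                          abs.tol = 1e-14, subdivisions = 1000L)$value
  exp(lchoose_term + log(int))
}

#' Over-representation analysis by Fisher's exact test
#'
#' One-sided (enrichment) Fisher exact test per term with Benjamini-Hochberg
#' correction.
#'
#' @inheritParams wallenius_test
#' @return tibble like [wallenius_test()] (without `odds`), sorted by `p`.
#' @export
ora_fisher <- function(query_genes, genesets, universe) {
  query <- unique(query_genes)
  if (length(query) == 0) stop("empty query")
  stopifnot(all(query %in% universe))
  rows <- list()
  for (i in seq_len(nrow(genesets))) {
    members <- intersect(genesets$genes[[i]], universe)
    if (length(members) == 0) {
      warning("term ", genesets$term[i], " disjoint from universe; skipped")
      next
    }
    m1 <- length(members)
    x <- length(intersect(query, members))
    # upper tail of the central hypergeometric, P(X >= x)
    p <- stats::phyper(x - 1, m1, length(universe) - m1, length(query),
                       lower.tail = FALSE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      term = genesets$term[i], n_term = m1, overlap = x, p = p,
      overlap_genes = list(intersect(query, members)),
      universe_size = length(universe))
  }
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  dplyr::arrange(out[, c("term", "n_term", "overlap", "p", "q",
                         "overlap_genes", "universe_size")], .data$p)
}

#' Reduce redundant enriched terms by gene-set overlap
#'
#' Greedy by ascending p-value: a term is kept unless its Jaccard similarity
#' (on member genes) with an already-kept term exceeds `cutoff`. A set-overlap
#' stand-in for ontology-based semantic-similarity reduction.
#'
#' @param results enrichment tibble with `term`, `p`.
#' @param genesets tibble with `term` and list-column `genes`.
#' @param cutoff Jaccard similarity above which a term is redundant.
#' @return the kept subset of `results`, in ascending p order.
#' @export
reduce_redundancy <- function(results, genesets, cutoff = 0.3) {
  if (nrow(results) == 0) return(results)
  ord <- order(results$p)
  res <- results[ord, ]
  sets <- genesets$genes[match(res$term, genesets$term)]
  keep <- logical(nrow(res))
  kept_sets <- list()
  for (i in seq_len(nrow(res))) {
    red <- any(vapply(kept_sets, function(s) jaccard(s, sets[[i]]) > cutoff,
                      logical(1)))
    if (!red) {
      keep[i] <- TRUE
      kept_sets[[length(kept_sets) + 1]] <- sets[[i]]
    }
  }
  res[keep, ]
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Intersect hypomethylated gene lists across contrasts
#'
#' @param lists named list (contrast label -> character vector of genes),
#'   at least 2 entries.
#' @return list with `shared` (genes in every list) and `overlap_counts`, a
#'   tibble of intersection sizes for every combination of 2 or more lists.
#' @export
intersect_hypo <- function(lists) {
  stopifnot(length(lists) >= 2)
  if (any(lengths(lists) == 0)) {
    warning("empty gene list; intersection is empty")
  }
  shared <- Reduce(intersect, lists)
  labels <- names(lists) %||% as.character(seq_along(lists))
  combos <- list()
  for (k in 2:length(lists)) {
    cmb <- utils::combn(length(lists), k, simplify = FALSE)
    for (cc in cmb) {
      n_shared <- length(Reduce(intersect, lists[cc]))
      combos[[length(combos) + 1]] <- tibble::tibble(
        lists = paste(labels[cc], collapse = "&"),
        k = k, n_shared = n_shared)
    }
  }
  list(shared = shared, overlap_counts = dplyr::bind_rows(combos))
}
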