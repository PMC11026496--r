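#' PCA-initialized t-SNE embedding of a methylation cohort
#'
#' Reduces the beta matrix to `pca_components` principal components, then runs
#' t-SNE on the component scores, initializing the map from the first two PCA
#' axes scaled to sd 1e-4 so that the global structure of the data seeds the
#' embedding. Gradients are computed exactly (O(n^2) per iteration); at cohort
#' sizes of a few hundred samples this matches the Barnes-Hut approximation
#' whose `theta` parameter is recorded in the result for provenance. No
#' feature selection is applied; the full probe set enters the PCA.
#'
#' @param beta probes x samples beta matrix.
#' @param perplexity t-SNE perplexity (effective neighborhood size).
#' @param theta Barnes-Hut accuracy parameter, recorded in the result.
#' @param eei number of early-exaggeration iterations.
#' @param pca_components number of PCA components fed to t-SNE.
#' @param seed integer seed, recorded in the result (the optimization is
#'   deterministic given the PCA initialization).
#' @param max_iter total gradient-descent iterations.
#' @param eta learning rate; `NULL` (default) uses the openTSNE-style
#'   automatic rate `max(n / exaggeration, 50)`.
#' @param exaggeration early-exaggeration factor.
#' @return an object of class `meth_embedding`: list with `coords`
#'   (tibble `sample_id`, `x`, `y`), `params`, `pca_components`.
#' @export
embed <- function(beta, perplexity = 15, theta = 0.5, eei = 200,
                  pca_components = 20, seed = 1, max_iter = 750,
                  eta = NULL, exaggeration = 12) {
  X <- t(beta)
  n <- nrow(X)
  if (is.null(eta)) eta <- max(n / exaggeration, 50)
  if (perplexity >= (n - 1) / 3) {
    stop("perplexity ", perplexity, " too large for n = ", n,
         "; need perplexity < (n - 1)/3, e.g. ",
         max(2, floor((n - 1) / 3) - 1))
  }
  if (n < 3 * perplexity) {
    warning("fewer than 3 * perplexity samples; embedding may be unstable")
  }
  k <- min(pca_components, n - 1, ncol(X))
  pc <- stats::prcomp(X, rank. = k, center = TRUE, scale. = FALSE)
  S <- pc$x

  P <- perplexity_calibrate(as.matrix(stats::dist(S))^2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  init <- S[, 1:2, drop = FALSE]
  init <- sweep(init, 2, apply(init, 2, stats::sd), "/") * 1e-4
  Y <- tsne_descent(P, init, eei = eei, max_iter = max_iter, eta = eta,
                    exaggeration = exaggeration)

  structure(list(
    coords = tibble::tibble(sample_id = colnames(beta) %||%
                              as.character(seq_len(n)),
                            x = Y[, 1], y = Y[, 2]),
    params = list(perplexity = perplexity, theta = theta, eei = eei,
                  seed = seed, max_iter = max_iter, eta = eta),
    pca_components = k
  ), class = "meth_embedding")
}

#' @export
print.meth_embedding <- function(x, ...) {
  cat(sprintf("t-SNE embedding of %d samples (perplexity %g, %d PCA components)\n",
              nrow(x$coords), x$params$perplexity, x$pca_components))
  print(x$coords, n = 5)
  invisible(x)
}

# Per-row binary search for the bandwidth matching log2(perplexity) entropy.
perplexity_calibrate <- function(D2, perplexity, tol = 1e-5, maxit = 60) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta_i <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(maxit)) {
      w <- exp(-di * beta_i)
      sw <- sum(w)
      if (sw < 1e-300) {
        H <- 0
      } else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {  # entropy too high -> sharpen
        lo <- beta_i
        beta_i <- if (is.finite(hi)) (beta_i + hi) / 2 else beta_i * 2
      } else {
        hi <- beta_i
        beta_i <- if (is.finite(lo)) (beta_i + lo) / 2 else beta_i / 2
      }
    }
    w <- exp(-di * beta_i)
    P[i, -i] <- w / sum(w)
  }
  P
}

tsne_descent <- function(P, Y, eei, max_iter, eta, exaggeration) {
  n <- nrow(Y)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  P_run <- P * exaggeration
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    if (iter == eei + 1) P_run <- P
    if (iter == 251) momentum <- 0.8
    D2 <- as.matrix(stats::dist(Y))^2
    W <- 1 / (1 + D2)
    diag(W) <- 0
    Q <- W / sum(W)
    Q[Q < 1e-12] <- 1e-12
    L <- (P_run - Q) * W
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Grid utility over t-SNE hyperparameters
#'
#' Convenience sweep mirroring the protocol of exploring perplexity, theta and
#' early-exaggeration settings before fixing final values; returns one
#' embedding per grid row.
#'
#' @param beta probes x samples beta matrix.
#' @param grid data frame with any of the columns `perplexity`, `theta`,
#'   `eei`.
#' @param ... passed to [embed()].
#' @return list of `meth_embedding` objects, one per grid row.
#' @export
embed_grid <- function(beta, grid, ...) {
  lapply(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, , drop = FALSE])
    do.call(embed, c(list(beta = beta), args, list(...)))
  })
}
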