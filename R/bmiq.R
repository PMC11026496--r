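#' BMIQ normalization of type II probes
#'
#' Beta-mixture quantile dilation: per sample, a three-state
#' (unmethylated / hemimethylated / methylated) beta mixture is fitted by EM
#' separately to type I and type II probes. Type II probes classified
#' unmethylated or methylated are mapped state-wise onto the type I scale via
#' the fitted beta CDF and inverse CDF; hemimethylated probes are dilated
#' linearly between the two mapped state boundaries. Type I probes are
#' returned bit-identical, and the mapping is monotone within each sample's
#' type II probes.
#'
#' @param beta probes x samples beta matrix.
#' @param design_types per-probe character vector, `"I"` or `"II"`.
#' @param seed kept for interface symmetry; the fit is deterministic
#'   (fixed-center initialization), so it is unused.
#' @param em_tol EM log-likelihood convergence tolerance.
#' @param em_maxit maximum EM iterations.
#' @return beta matrix of the same shape; attribute `"bmiq_log"` lists
#'   samples where the EM failed and the identity fallback was used.
#' @export
bmiq <- function(beta, design_types, seed = 1, em_tol = 1e-4, em_maxit = 100) {
  stopifnot(length(design_types) == nrow(beta),
            all(design_types %in% c("I", "II")))
  i1 <- design_types == "I"
  i2 <- design_types == "II"
  if (sum(i1) < 50 || sum(i2) < 50) {
    stop("need >= 50 probes of each design type")
  }
  out <- beta
  fallback <- character()
  for (s in seq_len(ncol(beta))) {
    mapped <- tryCatch(
      bmiq_sample(beta[i1, s], beta[i2, s], em_tol, em_maxit),
      error = function(e) NULL)
    if (is.null(mapped)) {
      fallback <- c(fallback, colnames(beta)[s] %||% as.character(s))
    } else {
      out[i2, s] <- mapped
    }
  }
  if (length(fallback)) {
    warning("BMIQ identity fallback for samples: ",
            paste(fallback, collapse = ", "))
  }
  attr(out, "bmiq_log") <- fallback
  out
}

# Map one sample's type II values onto its type I scale.
bmiq_sample <- function(b1, b2, em_tol, em_maxit) {
  fit1 <- fit_beta_mixture3(b1, em_tol, em_maxit)
  fit2 <- fit_beta_mixture3(b2, em_tol, em_maxit)
  if (!fit1$converged || !fit2$converged) stop("EM did not converge")

  state2 <- classify_states(b2, fit2)
  if (!any(state2 == 1) || !any(state2 == 3)) stop("degenerate state fit")
  tU <- max(b2[state2 == 1])
  tM <- min(b2[state2 == 3])
  if (tU >= tM) stop("state boundaries overlap")

  map_state <- function(x, k) {
    p <- stats::pbeta(pmin(pmax(x, 1e-6), 1 - 1e-6),
                      fit2$shape1[k], fit2$shape2[k])
    stats::qbeta(p, fit1$shape1[k], fit1$shape2[k])
  }
  out <- b2
  out[state2 == 1] <- map_state(b2[state2 == 1], 1)
  out[state2 == 3] <- map_state(b2[state2 == 3], 3)
  fU <- map_state(tU, 1)
  fM <- map_state(tM, 3)
  if (fU >= fM) stop("mapped boundaries overlap")
  mid <- state2 == 2
  if (any(mid)) {
    out[mid] <- fU + (b2[mid] - tU) * (fM - fU) / (tM - tU)
  }
  pmin(pmax(out, 0), 1)
}

# Three-component beta mixture via EM with weighted moment-matching M-step;
# components ordered by mean (1 = unmethylated, 3 = methylated).
fit_beta_mixture3 <- function(b, tol = 1e-4, maxit = 100) {
  x <- pmin(pmax(b, 1e-4), 1 - 1e-4)
  n <- length(x)
  centers <- c(0.1, 0.5, 0.85)
  assign0 <- apply(abs(outer(x, centers, "-")), 1, which.min)
  pi_k <- pmax(tabulate(assign0, 3) / n, 0.01)
  mom <- function(w) {
    m <- sum(w * x) / sum(w)
    v <- sum(w * (x - m)^2) / sum(w)
    v <- min(max(v, 1e-6), m * (1 - m) * 0.95)
    nu <- m * (1 - m) / v - 1
    c(m * nu, (1 - m) * nu)
  }
  par <- t(vapply(1:3, function(k) mom(as.numeric(assign0 == k)),
                  numeric(2)))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    dens <- vapply(1:3, function(k)
      pi_k[k] * stats::dbeta(x, par[k, 1], par[k, 2]), numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < 1e-300] <- 1e-300
    gamma <- dens / rowsum_d
    ll <- sum(log(rowsum_d))
    pi_k <- pmax(colMeans(gamma), 1e-6)
    pi_k <- pi_k / sum(pi_k)
    par <- t(vapply(1:3, function(k) mom(gamma[, k]), numeric(2)))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  means <- par[, 1] / rowSums(par)
  ord <- order(means)
  list(shape1 = par[ord, 1], shape2 = par[ord, 2], pi = pi_k[ord],
       means = means[ord], converged = converged)
}

classify_states <- function(x, fit) {
  xx <- pmin(pmax(x, 1e-6), 1 - 1e-6)
  post <- vapply(1:3, function(k)
    fit$pi[k] * stats::dbeta(xx, fit$shape1[k], fit$shape2[k]),
    numeric(length(xx)))
  cls <- max.col(post, ties.method = "first")
  # enforce contiguity in beta order so the state-wise maps cannot interleave
  bU <- suppressWarnings(max(xx[cls == 1], -Inf))
  bM <- suppressWarnings(min(xx[cls == 3], Inf))
  cls[cls == 2 & xx <= bU] <- 1L
  cls[cls == 2 & xx >= bM] <- 3L
  cls
}
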