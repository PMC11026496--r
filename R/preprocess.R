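#' Probe quality filtering
#'
#' Removes probes in four ordered, mutually exclusive steps: (1) detection
#' p-value above `detp_max` in at least one sample; (2) bead count below
#' `bead_min` in at least a fraction `bead_frac` of samples; (3) blacklisted
#' probes (SNP/cross-reactive proxies); (4) sex-chromosome probes. A probe
#' failing several rules is counted once, under the first rule it hits.
#'
#' @param intensities list of aligned matrices `M`, `U`, `detection_p`,
#'   `beadcount` (as from [simulate_cohort()]).
#' @param manifest manifest tibble, row-aligned with the matrices.
#' @param detp_max detection p-value ceiling.
#' @param bead_min minimum bead count.
#' @param bead_frac fraction of samples allowed below `bead_min` before the
#'   probe is dropped (a probe is removed when the failing fraction is
#'   >= `bead_frac`).
#' @return list with `mask` (logical, TRUE = probe retained) and `report`, a
#'   list holding `removed_probes` (tibble `probe_id`, `reason`) and
#'   `n_retained`.
#' @export
filter_probes <- function(intensities, manifest, detp_max = 0.01,
                          bead_min = 3, bead_frac = 0.05) {
  detp <- intensities$detection_p
  beads <- intensities$beadcount
  assert_matrix_aligned(detp, beads, what = "detection_p/beadcount")
  stopifnot(nrow(detp) == nrow(manifest))

  fail_detp <- rowSums(detp > detp_max) >= 1
  fail_beads <- rowMeans(beads < bead_min) >= bead_frac
  reason <- rep(NA_character_, nrow(manifest))
  reason[manifest$sex_chrom_flag] <- "sexchrom"
  reason[manifest$blacklist_flag] <- "blacklist"
  reason[fail_beads] <- "beads"
  reason[fail_detp] <- "detection"
  mask <- is.na(reason)
  if (!any(mask)) stop("no probes survive QC")
  removed <- tibble::tibble(probe_id = manifest$probe_id[!mask],
                            reason = reason[!mask])
  list(mask = mask,
       report = list(removed_probes = removed,
                     n_retained = sum(mask)))
}

#' Beta values from channel intensities
#'
#' `beta = M / (M + U + offset)`, the standard Illumina definition; the
#' offset regularizes low-intensity probes and keeps beta strictly below 1.
#'
#' @param intensities list with matrices `M` and `U` (or a list as from
#'   [simulate_cohort()]).
#' @param offset additive constant in the denominator.
#' @return probes x samples beta matrix in \[0, 1\].
#' @export
compute_beta <- function(intensities, offset = 100) {
  M <- intensities$M
  U <- intensities$U
  assert_matrix_aligned(M, U, what = "M/U")
  if (any(M < 0) || any(U < 0)) stop("negative intensities")
  M / (M + U + offset)
}

#' M-values from beta values
#'
#' `M = log2(b / (1 - b))` with `b` clipped to `[eps, 1 - eps]`; the
#' variance-stabilized scale used for differential statistics.
#'
#' @param beta beta matrix in \[0, 1\].
#' @param eps clipping bound.
#' @return M-value matrix.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' MDS outlier check on the most variable probes
#'
#' Classical multidimensional scaling of Euclidean sample distances over the
#' `top_k` most variable probes; samples with a robust z-score above 3 on
#' either of the first two axes are flagged.
#'
#' @param beta beta matrix (probes x samples).
#' @param top_k number of most-variable probes used.
#' @return list with `coordinates` (tibble `sample_id`, `mds1`, `mds2`) and
#'   `outliers` (character vector of flagged sample ids).
#' @export
mds_outlier_check <- function(beta, top_k = 1000) {
  if (ncol(beta) < 3) stop("need at least 3 samples")
  v <- apply(beta, 1, stats::var)
  if (top_k > nrow(beta)) {
    warning("top_k exceeds probe count; using all probes")
    top_k <- nrow(beta)
  }
  sel <- order(v, decreasing = TRUE)[seq_len(top_k)]
  d <- stats::dist(t(beta[sel, , drop = FALSE]))
  if (max(d) < .Machine$double.eps) {
    coords <- matrix(0, ncol(beta), 2)
  } else {
    coords <- stats::cmdscale(d, k = 2)
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
  }
  z1 <- robust_z(coords[, 1])
  z2 <- robust_z(coords[, 2])
  out <- colnames(beta)[abs(z1) > 3 | abs(z2) > 3]
  list(coordinates = tibble::tibble(sample_id = colnames(beta),
                                    mds1 = coords[, 1], mds2 = coords[, 2]),
       outliers = out)
}

#' SVD scan for technical and biological covariates
#'
#' Singular value decomposition of the row-centered beta matrix; each of the
#' leading components is tested for association with each covariate
#' (Kruskal-Wallis for categorical covariates, Spearman correlation for
#' numeric ones).
#'
#' @param beta beta matrix (probes x samples).
#' @param covariates data frame, rows aligned with samples; constant
#'   covariates are dropped with a warning.
#' @param n_components number of leading components tested (capped at
#'   samples - 1).
#' @param alpha significance threshold for the `significant` flag.
#' @return tibble with `component`, `covariate`, `p`, `significant`.
#' @export
svd_covariate_scan <- function(beta, covariates, n_components = 6,
                               alpha = 0.01) {
  stopifnot(nrow(covariates) == ncol(beta))
  keep <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) > 1,
                 logical(1))
  if (any(!keep)) {
    warning("dropping constant covariates: ",
            paste(names(covariates)[!keep], collapse = ", "))
  }
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0) stop("no usable covariates")
  n_components <- min(n_components, ncol(beta) - 1)
  centered <- beta - rowMeans(beta)
  sv <- svd(centered, nu = 0, nv = n_components)
  scores <- sv$v  # samples x components

  rows <- list()
  for (k in seq_len(n_components)) {
    for (cv in names(covariates)) {
      x <- covariates[[cv]]
      ok <- !is.na(x)
      p <- if (is.numeric(x)) {
        suppressWarnings(stats::cor.test(scores[ok, k], x[ok],
                                         method = "spearman")$p.value)
      } else {
        suppressWarnings(stats::kruskal.test(scores[ok, k],
                                             factor(x[ok]))$p.value)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        component = k, covariate = cv, p = p)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p < alpha
  out
}
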