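#' Per-probe copy-number log2 ratios against copy-neutral controls
#'
#' The combined intensity `t = M + U` of each probe tracks local DNA copy
#' number. The sample's log2 intensities are regressed (intercept + slope, by
#' least squares) on the mean control log2 intensity per probe; the residual,
#' median-centered per sample, is the per-probe log2R. A global rescaling of
#' the sample's intensities is absorbed by the intercept, so log2R is
#' invariant to it.
#'
#' @param sample list with vectors/1-column matrices `M`, `U` for one sample,
#'   or a numeric vector of combined intensities.
#' @param controls list with matrices `M`, `U` of at least 3 copy-neutral
#'   control samples (probes x controls), or a combined-intensity matrix.
#' @return numeric vector of per-probe log2R values.
#' @export
probe_log2r <- function(sample, controls) {
  t_s <- combined_intensity(sample)
  t_c <- combined_intensity(controls)
  if (is.null(dim(t_c)) || ncol(t_c) < 3) stop("need >= 3 control samples")
  stopifnot(length(t_s) == nrow(t_c))
  ref <- rowMeans(log2(pmax(t_c, 1)))
  ok <- t_s > 0
  y <- log2(t_s[ok])
  fit <- stats::lm.fit(cbind(1, ref[ok]), y)
  res <- rep(NA_real_, length(t_s))
  res[ok] <- fit$residuals
  res[!ok] <- stats::median(res[ok])
  res - stats::median(res, na.rm = TRUE)
}

combined_intensity <- function(x) {
  if (is.list(x) && !is.null(x$M)) x$M + x$U else x
}

#' Genomic bins with minimum span and probe count
#'
#' Greedy left-to-right binning per chromosome: probes accumulate until the
#' bin spans at least `min_size` bp and holds at least `min_probes` probes,
#' then the bin closes. The trailing remainder of each chromosome is merged
#' into its last bin. Chromosomes with fewer than `min_probes` probes yield a
#' single bin flagged undersized (excluded from similarity correlations).
#'
#' @param manifest manifest tibble (positions sorted within chromosome).
#' @param min_size minimum bin span in bp.
#' @param min_probes minimum probes per bin.
#' @return tibble `bin_id`, `chrom`, `start`, `end` (1-based inclusive probe
#'   span), `n_probes`, `undersized`, plus a list-column `probe_idx` of
#'   manifest row indices.
#' @export
make_bins <- function(manifest, min_size = 50000, min_probes = 15) {
  out <- list()
  for (ch in unique(manifest$chrom)) {
    rows <- which(manifest$chrom == ch)
    pos <- manifest$pos[rows]
    if (is.unsorted(pos, strictly = TRUE)) stop("manifest not sorted on ", ch)
    if (length(rows) < min_probes) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, start = min(pos), end = max(pos),
        n_probes = length(rows), undersized = TRUE, probe_idx = list(rows))
      next
    }
    start_i <- 1L
    bins_ch <- list()
    i <- 1L
    while (i <= length(rows)) {
      span <- pos[i] - pos[start_i]
      count <- i - start_i + 1L
      if (span >= min_size && count >= min_probes) {
        bins_ch[[length(bins_ch) + 1]] <- c(start_i, i)
        start_i <- i + 1L
      }
      i <- i + 1L
    }
    if (length(bins_ch) == 0) {
      bins_ch[[1]] <- c(1L, length(rows))
    } else if (start_i <= length(rows)) {
      # merge trailing remainder into the last bin
      bins_ch[[length(bins_ch)]][2] <- length(rows)
    }
    for (b in bins_ch) {
      idx <- rows[b[1]:b[2]]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, start = manifest$pos[idx[1]],
        end = manifest$pos[idx[length(idx)]],
        n_probes = length(idx), undersized = FALSE, probe_idx = list(idx))
    }
  }
  bins <- dplyr::bind_rows(out)
  bins$bin_id <- sprintf("bin_%04d", seq_len(nrow(bins)))
  bins[, c("bin_id", "chrom", "start", "end", "n_probes", "undersized",
           "probe_idx")]
}

#' Bin-level CNV profile from per-probe log2R
#'
#' @param log2r per-probe log2R vector aligned with the manifest the bins
#'   were built from.
#' @param bins tibble from [make_bins()].
#' @param sample_id optional sample id recorded in the result.
#' @return tibble `bin_id`, `chrom`, `start`, `end`, `undersized`, `log2r`,
#'   `sample_id`.
#' @export
bin_profile <- function(log2r, bins, sample_id = NA_character_) {
  vals <- vapply(bins$probe_idx, function(idx) mean(log2r[idx]), numeric(1))
  tibble::tibble(bin_id = bins$bin_id, chrom = bins$chrom,
                 start = bins$start, end = bins$end,
                 undersized = bins$undersized, log2r = vals,
                 sample_id = sample_id)
}

#' Cell-versus-tissue CNV similarity with cohort tertiles
#'
#' Pearson (or Spearman) correlation between the two profiles' bin values
#' (undersized bins excluded), categorized by where the correlation falls
#' among the whole cohort of evaluated pairs: lower tertile `different`,
#' middle `similar`, top `coincident`. Boundaries are the 1/3 and 2/3
#' quantiles (type 7); values at a boundary go to the lower category.
#'
#' @param cell,tissue profiles from [bin_profile()] over the same bins.
#' @param cohort_correlations numeric vector of correlations for all
#'   evaluated pairs in the cohort (must contain this pair's value).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return one-row tibble `cell_id`, `tissue_id`, `r`, `category`, `flag`.
#' @export
similarity <- function(cell, tissue, cohort_correlations,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  r <- profile_correlation(cell, tissue, method)
  flag <- attr(r, "flag") %||% NA_character_
  tibble::tibble(cell_id = cell$sample_id[1], tissue_id = tissue$sample_id[1],
                 r = as.numeric(r),
                 category = tertile_category(as.numeric(r),
                                             cohort_correlations),
                 flag = flag)
}

profile_correlation <- function(cell, tissue,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(identical(cell$bin_id, tissue$bin_id))
  keep <- !cell$undersized
  x <- cell$log2r[keep]
  y <- tissue$log2r[keep]
  if (stats::sd(x) < .Machine$double.eps ||
      stats::sd(y) < .Machine$double.eps) {
    r <- 0
    attr(r, "flag") <- "flat_profile"
    return(r)
  }
  stats::cor(x, y, method = method)
}

tertile_category <- function(r, cohort) {
  q <- stats::quantile(cohort, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  if (r <= q[1]) "different" else if (r <= q[2]) "similar" else "coincident"
}

#' Number of altered regions in a CNV profile
#'
#' Counts maximal runs of consecutive bins whose |log2R| strictly exceeds
#' `thresh` — the number of altered regions, not altered bins.
#'
#' @param profile tibble from [bin_profile()] (or numeric log2R vector).
#' @param thresh absolute log2R threshold (strict).
#' @return integer count of altered regions.
#' @export
alteration_burden <- function(profile, thresh = 0.1) {
  v <- if (is.numeric(profile)) profile else profile$log2r
  stopifnot(all(is.finite(v)))
  hit <- abs(v) > thresh
  sum(hit & !c(FALSE, hit[-length(hit)]))
}

#' Compare alteration burdens between two groups
#'
#' Two-sided exact Wilcoxon rank-sum test on the per-sample region counts.
#' For small groups the permutation distribution of the rank-sum statistic is
#' enumerated exactly (midranks, so ties are handled); larger groups fall
#' back to the normal approximation of `stats::wilcox.test`.
#'
#' @param groupA,groupB numeric vectors of burdens.
#' @param max_enum enumerate exactly while `choose(nA + nB, nA)` is at most
#'   this.
#' @return tibble `mean_a`, `mean_b`, `statistic` (rank-sum of group A), `p`.
#' @export
burden_comparison <- function(groupA, groupB, max_enum = 200000) {
  n1 <- length(groupA); n2 <- length(groupB)
  stopifnot(n1 > 0, n2 > 0)
  out <- function(stat, p) {
    tibble::tibble(mean_a = mean(groupA), mean_b = mean(groupB),
                   statistic = stat, p = p)
  }
  if (stats::sd(c(groupA, groupB)) < .Machine$double.eps) {
    return(out(NA_real_, 1))
  }
  ranks <- rank(c(groupA, groupB))
  W <- sum(ranks[seq_len(n1)])
  EW <- n1 * (n1 + n2 + 1) / 2
  if (choose(n1 + n2, n1) <= max_enum) {
    combs <- utils::combn(n1 + n2, n1)
    Ws <- colSums(matrix(ranks[combs], nrow = n1))
    p <- mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(groupA, groupB, alternative = "two.sided",
                         exact = FALSE, correct = FALSE)$p.value)
  }
  out(W, p)
}

#' Cumulative gain/loss fractions across profiles
#'
#' Per bin, the fraction of samples gained (`log2r > gain_thresh`) and lost
#' (`log2r < loss_thresh`), plus a flatness summary (mean |log2R| over all
#' bins and samples) useful for comparing divergent cells with their tissues.
#'
#' @param profiles list of [bin_profile()] tibbles over shared bins.
#' @param gain_thresh,loss_thresh log2R thresholds.
#' @return list with `per_bin` (tibble `bin_id`, `chrom`, `start`, `end`,
#'   `frac_gain`, `frac_loss`) and `flatness` (numeric).
#' @export
cumulative_profile <- function(profiles, gain_thresh = 0.1,
                               loss_thresh = -0.1) {
  stopifnot(length(profiles) >= 1)
  mat <- vapply(profiles, function(p) p$log2r, numeric(nrow(profiles[[1]])))
  mat <- matrix(mat, nrow = nrow(profiles[[1]]))
  b <- profiles[[1]]
  list(per_bin = tibble::tibble(bin_id = b$bin_id, chrom = b$chrom,
                                start = b$start, end = b$end,
                                frac_gain = rowMeans(mat > gain_thresh),
                                frac_loss = rowMeans(mat < loss_thresh)),
       flatness = mean(abs(mat)))
}
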