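#' Define a two-group contrast
#'
#' @param test,reference character vectors of sample ids (disjoint, each with
#'   at least 2 samples).
#' @param label contrast label (e.g. `"DCA1"`).
#' @return object of class `group_contrast`.
#' @export
group_contrast <- function(test, reference, label = "contrast") {
  stopifnot(length(test) >= 2, length(reference) >= 2,
            length(intersect(test, reference)) == 0)
  structure(list(test = test, reference = reference, label = label),
            class = "group_contrast")
}

#' Moderated per-CpG two-sample statistics on M-values
#'
#' Pooled-variance t statistics with empirical-Bayes shrinkage of the
#' per-CpG variance toward the global mean variance: the shrunk variance is
#' `(d0 * mean(s2) + df * s2) / (d0 + df)` with `d0` pseudo-observations, and
#' p-values come from the t distribution on `df + d0` degrees of freedom.
#' With `d0 = 0` this is the ordinary pooled two-sample t test.
#'
#' @param mvals M-value matrix (CpGs x samples), CpGs in genome order.
#' @param contrast a [group_contrast()].
#' @param d0 prior degrees of freedom for the variance shrinkage.
#' @return tibble `probe_id`, `t`, `p`, `df`, `flag_zero_var`.
#' @export
cpg_stats <- function(mvals, contrast, d0 = 4) {
  stopifnot(inherits(contrast, "group_contrast"))
  a <- mvals[, contrast$test, drop = FALSE]
  b <- mvals[, contrast$reference, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2); v2 <- rowSums((b - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (v1 + v2) / df
  zero <- s2 < .Machine$double.eps
  s2_bar <- mean(s2[!zero])
  if (!is.finite(s2_bar)) s2_bar <- 0
  s2_mod <- if (d0 > 0) (d0 * s2_bar + df * s2) / (d0 + df) else s2
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, (m1 - m2) / se, 0)
  df_mod <- df + d0
  p <- 2 * stats::pt(abs(t_stat), df_mod, lower.tail = FALSE)
  t_stat[zero] <- 0
  p[zero] <- 1
  tibble::tibble(probe_id = rownames(mvals) %||%
                   as.character(seq_len(nrow(mvals))),
                 t = unname(t_stat), p = unname(p), df = df_mod,
                 flag_zero_var = unname(zero))
}

#' Call differentially methylated regions by kernel smoothing
#'
#' Squared t statistics are smoothed along the genome with a Gaussian kernel
#' of bandwidth `lambda / 2` (within chromosome). Each CpG's smoothed
#' statistic gets a p-value from a scaled chi-square null matched to its
#' first two moments (Satterthwaite), assuming the unsmoothed squared t
#' statistics are independent t-squared draws. After Benjamini-Hochberg
#' correction across CpGs, significant CpGs (`q < fdr`) are grouped into
#' regions, splitting where consecutive significant CpGs are more than
#' `lambda` bp apart; regions with fewer than `min_cpgs` significant CpGs are
#' discarded.
#'
#' @param stats tibble from [cpg_stats()] (needs columns `t`, `df`,
#'   `probe_id`).
#' @param positions tibble/data frame with `chrom`, `pos` aligned to `stats`
#'   rows (sorted within chromosome).
#' @param lambda gap parameter in bp; also sets the kernel bandwidth
#'   `lambda / 2`.
#' @param min_cpgs minimum significant CpGs per region.
#' @param fdr FDR threshold.
#' @return tibble of regions: `chrom`, `start`, `end`, `n_cpgs`, `min_q`,
#'   plus list-column `probe_ids` of member significant CpGs.
#' @export
call_dmrs <- function(stats, positions, lambda = 1000, min_cpgs = 7,
                      fdr = 0.05) {
  stopifnot(nrow(stats) == nrow(positions))
  sigma <- lambda / 2
  df <- stats$df[1]
  # moments of a squared t_df variate
  mu_y <- df / (df - 2)
  var_y <- 2 * df^2 * (df - 1) / ((df - 2)^2 * (df - 4))

  smoothed <- numeric(nrow(stats))
  wsq <- numeric(nrow(stats))
  support <- 4 * sigma  # kernel truncated beyond 4 sd
  for (ch in unique(positions$chrom)) {
    idx <- which(positions$chrom == ch)
    pos <- positions$pos[idx]
    y <- stats$t[idx]^2
    lo <- findInterval(pos - support, pos) + 1L
    hi <- findInterval(pos + support, pos)
    for (i in seq_along(idx)) {
      j <- lo[i]:hi[i]
      w <- exp(-(pos[j] - pos[i])^2 / (2 * sigma^2))
      w <- w / sum(w)
      smoothed[idx[i]] <- sum(w * y[j])
      wsq[idx[i]] <- sum(w^2)
    }
  }
  scale_c <- (var_y * wsq) / (2 * mu_y)
  dof_k <- 2 * mu_y^2 / (var_y * wsq)
  p_sm <- stats::pchisq(smoothed / scale_c, dof_k, lower.tail = FALSE)
  q <- stats::p.adjust(p_sm, method = "BH")

  sig <- which(q < fdr)
  if (length(sig) < min_cpgs) return(empty_dmr_table())
  regions <- list()
  run <- sig[1]
  for (i in sig[-1]) {
    prev <- run[length(run)]
    same <- positions$chrom[i] == positions$chrom[prev] &&
      positions$pos[i] - positions$pos[prev] <= lambda
    if (same) {
      run <- c(run, i)
    } else {
      regions[[length(regions) + 1]] <- run
      run <- i
    }
  }
  regions[[length(regions) + 1]] <- run
  regions <- regions[lengths(regions) >= min_cpgs]
  if (length(regions) == 0) return(empty_dmr_table())
  dplyr::bind_rows(lapply(regions, function(idx) {
    tibble::tibble(chrom = positions$chrom[idx[1]],
                   start = min(positions$pos[idx]),
                   end = max(positions$pos[idx]),
                   n_cpgs = length(idx),
                   min_q = min(q[idx]),
                   probe_ids = list(stats$probe_id[idx]))
  }))
}

empty_dmr_table <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 n_cpgs = integer(), min_q = numeric(), probe_ids = list())
}

#' Per-region methylation difference (delta-beta)
#'
#' For each test sample, the difference between its beta values and the
#' reference-group mean, averaged over the region's probes and then over test
#' samples; algebraically the test-group mean minus the reference-group mean
#' over region probes.
#'
#' @param beta beta matrix (probes x samples), rownames = probe ids.
#' @param region one row of a [call_dmrs()] table (needs `probe_ids`).
#' @param contrast a [group_contrast()].
#' @return numeric delta-beta in \[-1, 1\].
#' @export
delta_beta <- function(beta, region, contrast) {
  probes <- intersect(region$probe_ids[[1]], rownames(beta))
  if (length(probes) == 0) stop("region has no surviving probes")
  test <- beta[probes, contrast$test, drop = FALSE]
  ref <- beta[probes, contrast$reference, drop = FALSE]
  ref_mean <- rowMeans(ref)
  mean(colMeans(test - ref_mean))
}

#' Annotate DMRs with delta-beta, genes, region classes and direction
#'
#' @param dmrs tibble from [call_dmrs()].
#' @param beta beta matrix.
#' @param contrast a [group_contrast()].
#' @param manifest manifest tibble for gene / region-class annotation.
#' @param thresh |delta-beta| threshold for the hypo/hyper direction (strict).
#' @return `dmrs` with columns `delta_beta`, `direction`, list-columns
#'   `genes`, `region_classes` added.
#' @export
annotate_dmrs <- function(dmrs, beta, contrast, manifest, thresh = 0.10) {
  if (nrow(dmrs) == 0) {
    dmrs$delta_beta <- numeric()
    dmrs$direction <- character()
    dmrs$genes <- list()
    dmrs$region_classes <- list()
    return(dmrs)
  }
  db <- vapply(seq_len(nrow(dmrs)), function(i)
    delta_beta(beta, dmrs[i, ], contrast), numeric(1))
  ann <- lapply(dmrs$probe_ids, function(p) {
    rows <- match(p, manifest$probe_id)
    list(genes = setdiff(unique(manifest$gene[rows]), ""),
         classes = unique(manifest$region_class[rows]))
  })
  dmrs$delta_beta <- db
  dmrs$direction <- ifelse(db < -thresh, "hypo",
                           ifelse(db > thresh, "hyper", "none"))
  dmrs$genes <- lapply(ann, `[[`, "genes")
  dmrs$region_classes <- lapply(ann, `[[`, "classes")
  dmrs
}

#' Keep promoter-proximal DMRs
#'
#' Retains DMRs with at least one member CpG in TSS200, TSS1500 or 1stExon.
#'
#' @param dmrs annotated DMR tibble (with `region_classes`).
#' @param manifest manifest tibble (used if `region_classes` is absent).
#' @return the promoter subset of `dmrs`.
#' @export
promoter_filter <- function(dmrs, manifest = NULL) {
  if (nrow(dmrs) == 0) return(dmrs)
  promoter <- c("TSS200", "TSS1500", "1stExon")
  if (!"region_classes" %in% names(dmrs)) {
    stopifnot(!is.null(manifest))
    dmrs$region_classes <- lapply(dmrs$probe_ids, function(p)
      unique(manifest$region_class[match(p, manifest$probe_id)]))
  }
  keep <- vapply(dmrs$region_classes,
                 function(cl) any(cl %in% promoter), logical(1))
  dmrs[keep, ]
}

#' Split DMR genes into hypo- and hypermethylated sets
#'
#' Hypo if `delta_beta < -thresh`, hyper if `delta_beta > thresh`
#' (strict inequalities); genes are collected from member-CpG annotations.
#'
#' @param dmrs annotated DMR tibble (needs `delta_beta`, `genes`).
#' @param thresh |delta-beta| threshold.
#' @return list with character vectors `hypo` and `hyper`.
#' @export
split_hypo_hyper <- function(dmrs, thresh = 0.10) {
  hypo <- unique(unlist(dmrs$genes[dmrs$delta_beta < -thresh]))
  hyper <- unique(unlist(dmrs$genes[dmrs$delta_beta > thresh]))
  list(hypo = hypo %||% character(), hyper = hyper %||% character())
}
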