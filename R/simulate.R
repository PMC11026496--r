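#' Simulate an Infinium-style cohort with known ground truth
#'
#' Generates methylated/unmethylated channel intensities, detection p-values
#' and bead counts for every sample in a [cohort_design()].
#'
#' The generative model: each probe draws a baseline beta from a bimodal
#' logit-normal mixture (low mode near 0.1, high mode near 0.85). Class
#' signatures, the shared divergence signature of unfaithful cells, planted
#' DMRs and the panel-gene promoter hypomethylation shift the per-sample mean
#' on the beta scale (clipped to \[0.01, 0.99\]); logit-scale Gaussian noise
#' of sd `noise_sd` is then added per probe and sample. Betas become channel
#' intensities through a single total-intensity draw `T` per probe and sample
#' (lognormal, median 3000): `M = T * beta`, `U = T * (1 - beta)`. Planted
#' CNV segments multiply `T` by `1 + purity * (copies/2 - 1)`, so copy number
#' lives in the combined intensity and methylation in the channel ratio.
#' Copy-neutral controls carry baseline betas and no CNV. Detection p-values
#' are small (< 0.01) and bead counts at least 3 except at planted failures.
#'
#' @param manifest manifest tibble from [build_manifest()].
#' @param design a [cohort_design()].
#' @return a list with elements
#'   * `intensities`: list of probes x samples matrices `M`, `U`,
#'     `detection_p`, `beadcount` (shared dimnames);
#'   * `sheet`: sample sheet tibble (`sample_id`, `role`, `class`,
#'     `tissue_id`, `divergence`, `serum`, `time`, `dimension`);
#'   * `truth`: ground-truth list (`true_class`, `true_fidelity`,
#'     `dmr_regions`, `cnv_segments`).
#' @export
simulate_cohort <- function(manifest, design) {
  stopifnot(inherits(design, "cohort_design"))
  sheet <- build_sample_sheet(design)
  n_probes <- nrow(manifest)
  n_samples <- nrow(sheet)

  with_seed(design$seed, {
    # --- baseline beta per probe: bimodal logit-normal mixture ---
    high <- stats::runif(n_probes) < 0.5
    base_mu_logit <- ifelse(high,
                            stats::rnorm(n_probes, logit(0.85), 0.4),
                            stats::rnorm(n_probes, logit(0.10), 0.4))
    base_beta <- clip01(expit(base_mu_logit))

    # panel-gene promoter probes start methylated so hypomethylation can show
    panel_prom <- manifest$gene %in% design$divergence_panel &
      manifest$region_class %in% c("TSS200", "TSS1500", "1stExon")
    base_beta[panel_prom] <- design$panel_baseline_beta

    # --- per-sample mean beta ---
    mu <- matrix(base_beta, n_probes, n_samples,
                 dimnames = list(manifest$probe_id, sheet$sample_id))
    pid <- manifest$probe_id

    for (cl in names(design$signatures)) {
      sig <- design$signatures[[cl]]
      rows <- match(sig$probe_id, pid)
      full <- sheet$sample_id[sheet$class == cl &
                                (sheet$role == "tumor" |
                                   (sheet$role == "cell" &
                                      sheet$divergence == "faithful"))]
      mu[rows, full] <- sig$target_beta
      att <- sheet$sample_id[sheet$class == cl & sheet$role == "cell" &
                               sheet$divergence == "unfaithful"]
      if (length(att)) {
        resid <- 1 - design$signature_attenuation
        mu[rows, att] <- base_beta[rows] +
          resid * (sig$target_beta - base_beta[rows])
      }
    }

    unf <- sheet$sample_id[sheet$role == "cell" &
                             sheet$divergence == "unfaithful"]
    if (length(unf)) {
      if (nrow(design$divergence_signature)) {
        rows <- match(design$divergence_signature$probe_id, pid)
        mu[rows, unf] <- design$divergence_signature$target_beta
      }
      if (any(panel_prom)) {
        shifted <- mu[panel_prom, unf, drop = FALSE] + design$divergence_delta
        if (any(shifted < 0 | shifted > 1)) {
          warning("planted divergence shift clipped to [0.01, 0.99]")
        }
        mu[panel_prom, unf] <- clip01(shifted)
      }
    }

    if (nrow(design$planted_dmrs)) {
      for (i in seq_len(nrow(design$planted_dmrs))) {
        reg <- design$planted_dmrs[i, ]
        rows <- which(manifest$chrom == reg$chrom & manifest$pos >= reg$start &
                        manifest$pos <= reg$end)
        cols <- match(reg$samples[[1]], sheet$sample_id)
        shifted <- mu[rows, cols, drop = FALSE] + reg$delta_beta
        if (any(shifted < 0 | shifted > 1)) {
          warning("planted DMR shift clipped to [0.01, 0.99]")
        }
        mu[rows, cols] <- clip01(shifted)
      }
    }

    # --- logit-scale noise, realized beta ---
    eps <- matrix(stats::rnorm(n_probes * n_samples, 0, design$noise_sd),
                  n_probes, n_samples)
    beta_raw <- expit(logit(clip01(mu)) + eps)

    # --- total intensity, CNV scaling, channels ---
    # per-probe affinity shared across samples (median 3000) times a small
    # per-observation lognormal; the shared affinity is what the copy-neutral
    # control fit removes downstream
    affinity <- stats::rlnorm(n_probes, log(3000), 0.5)
    total <- affinity * matrix(stats::rlnorm(n_probes * n_samples, 0, 0.15),
                               n_probes, n_samples,
                               dimnames = dimnames(mu))
    cnv_truth <- list()
    if (nrow(design$planted_cnvs)) {
      for (i in seq_len(nrow(design$planted_cnvs))) {
        seg <- design$planted_cnvs[i, ]
        rows <- which(manifest$chrom == seg$chrom & manifest$pos >= seg$start &
                        manifest$pos <= seg$end)
        carriers <- intersect(seg$samples[[1]], sheet$sample_id)
        if (length(rows) && length(carriers)) {
          scale <- 1 + design$purity * (seg$copies / 2 - 1)
          total[rows, carriers] <- total[rows, carriers] * scale
        }
        cnv_truth[[i]] <- tibble::tibble(
          chrom = seg$chrom, start = seg$start, end = seg$end,
          copies = seg$copies, log2_ratio = log2(seg$copies / 2),
          samples = list(carriers))
      }
    }

    M <- total * beta_raw
    U <- total * (1 - beta_raw)

    detection_p <- matrix(stats::runif(n_probes * n_samples, 0, 0.005),
                          n_probes, n_samples, dimnames = dimnames(mu))
    beadcount <- matrix(3L + stats::rpois(n_probes * n_samples, 11),
                        n_probes, n_samples, dimnames = dimnames(mu))

    if (nrow(design$planted_failures)) {
      for (i in seq_len(nrow(design$planted_failures))) {
        pf <- design$planted_failures[i, ]
        r <- match(pf$probe_id, pid)
        s <- match(pf$sample_id, sheet$sample_id)
        if (is.na(r) || is.na(s)) stop("planted failure refers to unknown probe/sample")
        if (pf$mode == "detp") detection_p[r, s] <- 0.5 else beadcount[r, s] <- 1L
      }
    }

    truth <- list(
      true_class = tibble::tibble(sample_id = sheet$sample_id,
                                  class = sheet$class),
      true_fidelity = build_true_fidelity(design),
      dmr_regions = design$planted_dmrs,
      cnv_segments = if (length(cnv_truth)) dplyr::bind_rows(cnv_truth) else
        tibble::tibble(chrom = character(), start = integer(), end = integer(),
                       copies = integer(), log2_ratio = numeric(),
                       samples = list())
    )

    list(intensities = list(M = M, U = U, detection_p = detection_p,
                            beadcount = beadcount),
         sheet = sheet, truth = truth)
  })
}

build_sample_sheet <- function(design) {
  tumors <- dplyr::bind_rows(lapply(seq_len(nrow(design$classes)), function(i) {
    cl <- design$classes$class[i]
    n <- design$classes$n_tumors[i]
    tibble::tibble(sample_id = sprintf("%s_T%d", cl, seq_len(n)),
                   role = "tumor", class = cl, tissue_id = NA_character_,
                   divergence = NA_character_, serum = NA_character_,
                   time = NA_character_, dimension = NA_character_)
  }))
  pc <- design$paired_cells
  cells <- tibble::tibble(sample_id = pc$cell_id, role = "cell",
                          class = pc$class, tissue_id = pc$tissue_id,
                          divergence = pc$divergence, serum = pc$serum,
                          time = pc$time, dimension = pc$dimension)
  bad <- setdiff(stats::na.omit(cells$tissue_id), tumors$sample_id)
  if (length(bad)) stop("paired_cells reference unknown tissues: ",
                        paste(bad, collapse = ", "))
  controls <- if (design$n_controls > 0) {
    tibble::tibble(sample_id = sprintf("CTRL_%d", seq_len(design$n_controls)),
                   role = "control", class = NA_character_,
                   tissue_id = NA_character_, divergence = NA_character_,
                   serum = NA_character_, time = NA_character_,
                   dimension = NA_character_)
  } else {
    NULL
  }
  dplyr::bind_rows(tumors, cells, controls)
}

build_true_fidelity <- function(design) {
  pc <- design$paired_cells
  dnam <- ifelse(pc$divergence == "faithful", "maintained", "unfaithful")
  cond <- ifelse(pc$cnv_fate %in% c("coincident", "similar", "different"),
                 (as.integer(dnam == "unfaithful") * 3L +
                    match(pc$cnv_fate, c("coincident", "similar", "different"))),
                 NA_integer_)
  tibble::tibble(cell_id = pc$cell_id, tissue_id = pc$tissue_id,
                 class = pc$class, divergence = pc$divergence,
                 dnam_status = dnam, cnv_fate = pc$cnv_fate,
                 condition = cond)
}
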