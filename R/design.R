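#' Specify a synthetic cohort design
#'
#' A cohort design fixes everything [simulate_cohort()] needs to generate a
#' cohort with known ground truth: histology classes with their signature CpG
#' sets, paired tumor/cell samples with a designed fidelity fate, planted DMRs
#' and CNV segments, and copy-neutral controls.
#'
#' @param classes tibble with columns `class`, `n_tumors`.
#' @param signatures named list (one entry per class) of tibbles with columns
#'   `probe_id`, `target_beta`; class samples are pushed to `target_beta` at
#'   these CpGs.
#' @param paired_cells tibble with columns `cell_id`, `tissue_id`, `class`,
#'   `divergence` (`"faithful"` or `"unfaithful"`), `cnv_fate` (`"coincident"`,
#'   `"similar"` or `"different"`), `serum` (`"serum"`/`"serum_free"`),
#'   `time` (`"early"`/`"late"`), `dimension` (`"2D"`/`"3D"`).
#' @param planted_dmrs tibble (possibly empty) with columns `chrom`, `start`,
#'   `end`, `delta_beta`, and a list-column `samples` of affected sample ids.
#' @param planted_cnvs tibble (possibly empty) with columns `chrom`, `start`,
#'   `end`, `copies` (0-4; 2 is neutral) and a list-column `samples`.
#' @param divergence_panel character vector of genes whose promoters are
#'   hypomethylated in every unfaithful cell.
#' @param divergence_delta beta-scale shift applied to panel promoters in
#'   unfaithful cells (negative = hypomethylation).
#' @param divergence_signature tibble (`probe_id`, `target_beta`) of CpGs that
#'   all unfaithful cells share, emulating the convergent culture-adapted
#'   profile that makes divergent cells co-cluster away from every tumor class.
#' @param planted_failures tibble (`probe_id`, `sample_id`,
#'   `mode` in `"detp"`/`"beads"`) of probe x sample QC failures to plant.
#' @param panel_baseline_beta baseline methylation level given to panel-gene
#'   promoter probes so that hypomethylation has room to show.
#' @param signature_attenuation fraction of the class-signature shift that
#'   unfaithful cells lose (1 = signature fully erased).
#' @param n_controls number of copy-neutral control samples.
#' @param noise_sd per-sample logit-scale noise standard deviation.
#' @param purity tumor purity in (0, 1]; attenuates planted CNV log-ratios.
#' @param seed integer seed for the simulation.
#'
#' @return an object of class `cohort_design` (a named list).
#' @export
cohort_design <- function(classes, signatures, paired_cells,
                          planted_dmrs = empty_regions(delta_beta = TRUE),
                          planted_cnvs = empty_regions(copies = TRUE),
                          divergence_panel = character(),
                          divergence_delta = -0.35,
                          panel_baseline_beta = 0.75,
                          divergence_signature = tibble::tibble(
                            probe_id = character(), target_beta = numeric()),
                          signature_attenuation = 0.9,
                          planted_failures = tibble::tibble(
                            probe_id = character(), sample_id = character(),
                            mode = character()),
                          n_controls = 6, noise_sd = 0.3, purity = 1.0,
                          seed = 1) {
  stopifnot(all(c("class", "n_tumors") %in% names(classes)),
            all(classes$class %in% names(signatures)),
            all(c("cell_id", "tissue_id", "class", "divergence", "cnv_fate",
                  "serum", "time", "dimension") %in% names(paired_cells)),
            all(paired_cells$divergence %in% c("faithful", "unfaithful")),
            all(paired_cells$cnv_fate %in%
                  c("coincident", "similar", "different", "none")),
            n_controls >= 0, noise_sd >= 0, purity > 0, purity <= 1)
  structure(list(classes = classes, signatures = signatures,
                 paired_cells = paired_cells, planted_dmrs = planted_dmrs,
                 planted_cnvs = planted_cnvs,
                 divergence_panel = divergence_panel,
                 divergence_delta = divergence_delta,
                 panel_baseline_beta = panel_baseline_beta,
                 divergence_signature = divergence_signature,
                 signature_attenuation = signature_attenuation,
                 planted_failures = planted_failures,
                 n_controls = n_controls, noise_sd = noise_sd,
                 purity = purity, seed = seed),
            class = "cohort_design")
}

empty_regions <- function(delta_beta = FALSE, copies = FALSE) {
  out <- tibble::tibble(chrom = character(), start = integer(),
                        end = integer())
  if (delta_beta) out$delta_beta <- numeric()
  if (copies) out$copies <- integer()
  out$samples <- list()
  out
}

#' Default study-scale cohort design
#'
#' Builds the design used throughout the package's examples and validation: a
#' four-class cohort (medulloblastoma-like MB, low/high-grade glioma-like
#' LGG/HGG, diffuse midline glioma-like DMG) with `n_per_class` tumors each,
#' 24 paired cell lines spread evenly over the six DNAm-by-CNV fidelity
#' conditions (four per condition), and copy-neutral controls. Tumors carry
#' two planted CNV segments (one gain, one loss); cells inherit them
#' according to their designed CNV fate (coincident: all, similar: one shared
#' plus one private, different: none). Unfaithful cells share a promoter
#' hypomethylation panel of `panel_size` genes and lose most of their class
#' signature.
#'
#' @param manifest manifest tibble from [build_manifest()].
#' @param n_per_class tumors per histology class.
#' @param n_cells_per_condition paired cell lines per fidelity condition 1-6.
#' @param sig_size signature CpGs per class.
#' @param div_size CpGs in the shared divergence signature of unfaithful cells.
#' @param panel_size genes in the shared divergence panel.
#' @param seg_mb planted CNV segment length in Mb.
#' @param seed integer seed (drives both the design draw and the simulation).
#' @inheritParams cohort_design
#' @return a `cohort_design`.
#' @export
default_cohort_design <- function(manifest, n_per_class = 6,
                                  n_cells_per_condition = 4, sig_size = 250,
                                  div_size = 400, panel_size = 30, seg_mb = 4,
                                  n_controls = 6, noise_sd = 0.3,
                                  purity = 1.0, seed = 1) {
  # MB/LGG/HGG/DMG contribute tumors and derived cells; MNG is a small
  # tumor-only class whose signature coincides with the divergence signature,
  # so drifted cultures classify there (wrong class) rather than hovering
  # near the score threshold of their own class
  class_names <- c("MB", "LGG", "HGG", "DMG")
  with_seed(seed + 1000L, {
    usable <- which(!manifest$blacklist_flag & !manifest$sex_chrom_flag &
                      manifest$region_class %in% c("Body", "IGR"))
    need <- sig_size * length(class_names) + div_size
    if (length(usable) < need) stop("manifest too small for requested signatures")
    picks <- sample(usable, need)
    signatures <- lapply(seq_along(class_names), function(i) {
      idx <- picks[((i - 1) * sig_size + 1):(i * sig_size)]
      tibble::tibble(probe_id = manifest$probe_id[idx],
                     target_beta = ifelse(stats::runif(sig_size) < 0.5, 0.10, 0.90))
    })
    names(signatures) <- class_names
    div_idx <- picks[(sig_size * length(class_names) + 1):need]
    divergence_signature <- tibble::tibble(
      probe_id = manifest$probe_id[div_idx],
      target_beta = ifelse(stats::runif(div_size) < 0.5, 0.10, 0.90))
    signatures$MNG <- divergence_signature

    panel <- dense_promoter_genes(manifest, min_cpgs = 7)
    if (length(panel) < panel_size) {
      stop("manifest has only ", length(panel),
           " genes with dense promoters; need ", panel_size)
    }
    panel <- sample(panel, panel_size)

    classes <- tibble::tibble(class = c(class_names, "MNG"),
                              n_tumors = c(rep(n_per_class,
                                               length(class_names)), 4L))
    tissue_ids <- unlist(lapply(seq_len(nrow(classes)), function(i)
      sprintf("%s_T%d", classes$class[i], seq_len(classes$n_tumors[i]))))

    # 6 conditions x n_cells_per_condition cells, classes round-robin,
    # each cell paired with a distinct tissue of its class where possible
    n_cells <- 6 * n_cells_per_condition
    cond <- rep(1:6, each = n_cells_per_condition)
    cls <- rep_len(class_names, n_cells)
    cells <- tibble::tibble(
      condition = cond,
      class = cls,
      divergence = ifelse(cond <= 3, "faithful", "unfaithful"),
      cnv_fate = c("coincident", "similar", "different")[(cond - 1) %% 3 + 1]
    )
    # deterministic pairing: cycle through that class's tissues
    cells <- dplyr::group_by(cells, .data$class)
    cells <- dplyr::mutate(cells,
      tissue_id = sprintf("%s_T%d", .data$class,
                          ((seq_along(.data$class) - 1) %% n_per_class) + 1))
    cells <- dplyr::ungroup(cells)
    cells$cell_id <- sprintf("%s_C%d", cells$class,
                             stats::ave(seq_len(n_cells), cells$class,
                                        FUN = seq_along))
    # culture metadata: unfaithful cells are mostly serum / late / 2D,
    # mirroring the direction of divergence seen in patient-derived cultures
    unf <- cells$divergence == "unfaithful"
    cells$serum <- ifelse(stats::runif(n_cells) < ifelse(unf, 0.75, 0.2),
                          "serum", "serum_free")
    cells$time <- ifelse(stats::runif(n_cells) < ifelse(unf, 0.65, 0.35),
                         "late", "early")
    cells$dimension <- ifelse(stats::runif(n_cells) < ifelse(unf, 0.7, 0.3),
                              "2D", "3D")

    # two planted segments per tumor on a 6 Mb grid, inherited by cells
    chroms <- unique(manifest$chrom[!manifest$sex_chrom_flag])
    seg_len <- as.integer(seg_mb * 1e6)
    grid <- dplyr::bind_rows(lapply(chroms, function(ch) {
      maxpos <- max(manifest$pos[manifest$chrom == ch])
      starts <- seq(1e6, maxpos - seg_len - 1e6, by = 6e6)
      if (length(starts) == 0) return(NULL)
      tibble::tibble(chrom = ch, start = as.integer(starts),
                     end = as.integer(starts + seg_len - 1L))
    }))
    segs <- list()
    for (t in tissue_ids) {
      pick <- sample(nrow(grid), 4)
      tum_segs <- grid[pick[1:3], ]
      tum_segs$copies <- c(3L, 1L, sample(c(1L, 3L), 1))
      priv <- grid[pick[4], ]
      priv$copies <- sample(c(1L, 3L), 1)
      paired <- cells$cell_id[cells$tissue_id == t]
      for (s in seq_len(nrow(tum_segs))) {
        seg <- tum_segs[s, ]
        carriers <- t
        for (cid in paired) {
          fate <- cells$cnv_fate[cells$cell_id == cid]
          # coincident cells keep every tumor segment; similar keep 2 of 3
          if (fate == "coincident" || (fate == "similar" && s <= 2)) {
            carriers <- c(carriers, cid)
          }
        }
        seg$samples <- list(carriers)
        segs[[length(segs) + 1]] <- seg
      }
      # similar cells additionally carry a private segment the tumor lacks
      for (cid in paired[cells$cnv_fate[match(paired, cells$cell_id)] == "similar"]) {
        priv2 <- priv
        priv2$samples <- list(cid)
        segs[[length(segs) + 1]] <- priv2
      }
    }
    planted_cnvs <- dplyr::bind_rows(segs)

    cohort_design(
      classes = classes, signatures = signatures,
      paired_cells = cells[, c("cell_id", "tissue_id", "class", "divergence",
                               "cnv_fate", "serum", "time", "dimension")],
      planted_cnvs = planted_cnvs,
      divergence_panel = panel,
      divergence_signature = divergence_signature,
      n_controls = n_controls, noise_sd = noise_sd, purity = purity,
      seed = seed)
  })
}
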