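#' Run the full fidelity pipeline on a synthetic cohort
#'
#' Convenience wrapper chaining every stage on a simulated cohort: manifest
#' and cohort generation, probe QC and BMIQ normalization, MDS/SVD cohort QC,
#' t-SNE + HDBSCAN + DBCV, CNV profiles with similarity tertiles and burden,
#' classifier-surrogate scores with the faithful/useful/unfaithful categories
#' and the six-condition taxonomy, DMR calling between unfaithful cells and
#' tumors, and gene-set enrichment of the hypomethylated promoter genes.
#'
#' @param seed integer seed driving manifest, design and simulation.
#' @param n_probes probes in the synthetic manifest.
#' @param chrom_sizes named chromosome sizes for the synthetic genome.
#' @param design optional [cohort_design()]; defaults to
#'   [default_cohort_design()] on the generated manifest.
#' @param run_embedding compute the t-SNE/HDBSCAN/DBCV stage (the slowest).
#' @param outdir optional directory for TSV/JSON outputs.
#' @return a list with the intermediate results of every stage (see the
#'   vignette for a walk-through).
#' @export
run_fidelity_pipeline <- function(seed = 1, n_probes = 18000,
                                  chrom_sizes = c(chr1 = 40e6, chr2 = 35e6,
                                                  chr3 = 30e6, chr4 = 25e6,
                                                  chrX = 10e6),
                                  design = NULL, run_embedding = TRUE,
                                  outdir = NULL) {
  manifest <- build_manifest(n_probes, chrom_sizes, seed = seed)
  if (is.null(design)) design <- default_cohort_design(manifest, seed = seed)
  cohort <- simulate_cohort(manifest, design)
  sheet <- cohort$sheet

  qc <- filter_probes(cohort$intensities, manifest)
  mask <- qc$mask
  mf <- manifest[mask, ]
  beta_raw <- compute_beta(cohort$intensities)[mask, , drop = FALSE]
  beta <- bmiq(beta_raw, mf$design_type)

  mds <- mds_outlier_check(beta)
  covs <- data.frame(role = sheet$role,
                     class = ifelse(is.na(sheet$class), "none", sheet$class))
  svd_scan <- svd_covariate_scan(beta, covs)

  embedding <- clusters <- validity <- NULL
  if (run_embedding) {
    non_control <- sheet$sample_id[sheet$role != "control"]
    embedding <- embed(beta[, non_control, drop = FALSE],
                       perplexity = min(15, floor((length(non_control) - 1) / 3) - 1),
                       seed = seed)
    clusters <- cluster(embedding, min_cluster_size = 4)
    validity <- dbcv(embedding, clusters$labels$label)
  }

  # --- CNV ---
  controls <- sheet$sample_id[sheet$role == "control"]
  bins <- make_bins(mf)
  ctrl_int <- list(M = cohort$intensities$M[mask, controls, drop = FALSE],
                   U = cohort$intensities$U[mask, controls, drop = FALSE])
  profiles <- list()
  for (s in sheet$sample_id[sheet$role != "control"]) {
    smp <- list(M = cohort$intensities$M[mask, s],
                U = cohort$intensities$U[mask, s])
    profiles[[s]] <- bin_profile(probe_log2r(smp, ctrl_int), bins,
                                 sample_id = s)
  }
  pairs <- design$paired_cells
  pair_r <- vapply(seq_len(nrow(pairs)), function(i)
    as.numeric(profile_correlation(profiles[[pairs$cell_id[i]]],
                                   profiles[[pairs$tissue_id[i]]])),
    numeric(1))
  similarity_calls <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i)
    similarity(profiles[[pairs$cell_id[i]]], profiles[[pairs$tissue_id[i]]],
               pair_r)))
  burdens <- tibble::tibble(
    sample_id = names(profiles),
    burden = vapply(profiles, alteration_burden, numeric(1)))

  # --- classifier surrogate + fidelity ---
  tumors <- sheet[sheet$role == "tumor", ]
  reference <- build_class_centroids(beta, tumors$sample_id, tumors$class)
  cells <- sheet[sheet$role == "cell", ]
  scores <- centroid_scores(beta, reference, cells$sample_id)
  records <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    cid <- cells$sample_id[i]
    sc <- scores[scores$sample_id == cid, ]
    ma <- match_assessment(sc, cells$class[i])
    cnv_cat <- similarity_calls$category[similarity_calls$cell_id == cid]
    cnv_cat <- if (length(cnv_cat)) cnv_cat[1] else NA_character_
    tibble::tibble(cell_id = cid, tissue_id = cells$tissue_id[i],
                   class = cells$class[i],
                   assigned_class = sc$assigned_class[1],
                   max_score = sc$max_score[1],
                   category = ma$category,
                   histology_match = ma$histology_match,
                   dnam_status = ma$dnam_status,
                   cnv_category = cnv_cat,
                   condition = assign_condition(ma$dnam_status, cnv_cat),
                   serum = cells$serum[i], time = cells$time[i],
                   dimension = cells$dimension[i])
  }))
  report <- fidelity_report(records)

  # --- DMRs: unfaithful cells versus tumor tissues ---
  unf <- sheet$sample_id[sheet$role == "cell" &
                           sheet$divergence == "unfaithful"]
  dmrs <- dmr_table <- NULL
  hypo_hyper <- list(hypo = character(), hyper = character())
  enrichment <- NULL
  if (length(unf) >= 2) {
    contrast <- group_contrast(unf, tumors$sample_id, "divergent_vs_tumor")
    mv <- beta_to_m(beta)
    st <- cpg_stats(mv, contrast)
    dmrs <- call_dmrs(st, mf[, c("chrom", "pos")])
    dmr_table <- annotate_dmrs(dmrs, beta, contrast, mf)
    dmr_table <- promoter_filter(dmr_table)
    hypo_hyper <- split_hypo_hyper(dmr_table)
    genesets <- make_genesets(manifest,
                              target_panel = design$divergence_panel,
                              seed = seed)
    universe <- names(gene_cpg_counts(mf))
    bias <- gene_cpg_counts(mf)
    query <- intersect(hypo_hyper$hypo, universe)
    if (length(query)) {
      wall <- wallenius_test(query, genesets, bias, universe)
      fisher <- ora_fisher(query, genesets, universe)
      enrichment <- list(wallenius = wall, fisher = fisher,
                         reduced = reduce_redundancy(wall, genesets))
    }
  }

  result <- list(manifest = manifest, design = design, cohort = cohort,
                 qc = qc, beta = beta, mds = mds, svd_scan = svd_scan,
                 embedding = embedding, clusters = clusters,
                 validity = validity, bins = bins, profiles = profiles,
                 similarity = similarity_calls, burdens = burdens,
                 scores = scores, records = records, report = report,
                 dmrs = dmr_table, hypo_hyper = hypo_hyper,
                 enrichment = enrichment)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$qc$report$removed_probes, "qc_removed_probes.tsv")
  wt(result$mds$coordinates, "mds.tsv")
  wt(result$svd_scan, "svd_table.tsv")
  if (!is.null(result$embedding)) {
    wt(result$embedding$coords, "embedding.tsv")
    wt(result$clusters$labels, "clusters.tsv")
    wt(result$validity$per_cluster, "validity.tsv")
  }
  wt(result$similarity, "similarity.tsv")
  wt(result$burdens, "burden.tsv")
  wt(result$records, "fidelity_records.tsv")
  if (!is.null(result$dmrs)) {
    d <- result$dmrs
    d$genes <- vapply(d$genes, paste, character(1), collapse = ",")
    d$region_classes <- vapply(d$region_classes, paste, character(1),
                               collapse = ",")
    d$probe_ids <- NULL
    wt(d, "dmrs.tsv")
  }
  if (!is.null(result$enrichment)) {
    wt(result$enrichment$wallenius, "enrichment_wallenius.tsv")
    wt(result$enrichment$fisher, "enrichment_fisher.tsv")
  }
  invisible(outdir)
}
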