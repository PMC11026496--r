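test_that("manifest construction is valid, deterministic and seed-sensitive", {
  mf <- build_manifest(1000, c(chr1 = 1e7), seed = 1)
  expect_equal(nrow(mf), 1000)
  expect_false(any(duplicated(mf$probe_id)))
  expect_false(is.unsorted(mf$pos, strictly = TRUE))
  expect_true(all(mf$region_class %in%
                    c("TSS200", "TSS1500", "1stExon", "Body", "IGR")))
  expect_true(all(mf$design_type %in% c("I", "II")))

  expect_identical(mf, build_manifest(1000, c(chr1 = 1e7), seed = 1))
  mf2 <- build_manifest(1000, c(chr1 = 1e7), seed = 2)
  expect_false(identical(sort(mf$pos), sort(mf2$pos)))

  expect_error(build_manifest(1000, c(chr1 = 5e3), seed = 1), "too small")
})

test_that("simulated cohorts reproduce planted signals and are deterministic", {
  fx <- fixture_cohort()
  co <- fx$cohort
  mf <- fx$manifest
  design <- fx$design
  sheet <- co$sheet

  beta <- compute_beta(co$intensities)
  expect_true(all(beta >= 0 & beta <= 1))

  # bimodality of baseline (control) probe means
  ctrl <- sheet$sample_id[sheet$role == "control"]
  bm <- rowMeans(beta[, ctrl])
  expect_gt(mean(bm <= 0.2 | bm >= 0.8), 0.6)

  # divergence panel promoters: unfaithful cells hypomethylated by ~delta
  panel_rows <- mf$gene %in% design$divergence_panel &
    mf$region_class %in% c("TSS200", "TSS1500", "1stExon")
  unf <- sheet$sample_id[sheet$role == "cell" &
                           sheet$divergence == "unfaithful"]
  fai <- sheet$sample_id[sheet$role == "cell" &
                           sheet$divergence == "faithful"]
  observed_delta <- mean(beta[panel_rows, unf]) - mean(beta[panel_rows, fai])
  expect_lt(abs(observed_delta - design$divergence_delta), 0.05)

  # 3-copy segment: combined intensity ~1.5x controls over segment probes
  segs <- co$truth$cnv_segments
  g <- segs[segs$copies == 3, ][1, ]
  carrier <- g$samples[[1]][1]
  rows <- mf$chrom == g$chrom & mf$pos >= g$start & mf$pos <= g$end
  tot <- co$intensities$M + co$intensities$U
  ratio <- mean(tot[rows, carrier]) / mean(tot[rows, ctrl])
  expect_lt(abs(ratio - 1.5), 0.15)

  # full determinism
  co2 <- simulate_cohort(mf, design)
  expect_identical(co$intensities, co2$intensities)
  expect_identical(co$sheet, co2$sheet)
})

test_that("planted DMR shifts are recovered at the designed delta-beta", {
  mf <- fixture_manifest()
  region <- tibble::tibble(chrom = "chr1", start = 1e6L, end = 3e6L,
                           delta_beta = -0.3,
                           samples = list(c("A_T1", "A_T2")))
  design <- cohort_design(
    classes = tibble::tibble(class = "A", n_tumors = 4),
    signatures = list(A = tibble::tibble(probe_id = character(),
                                         target_beta = numeric())),
    paired_cells = tibble::tibble(cell_id = character(),
                                  tissue_id = character(),
                                  class = character(), divergence = character(),
                                  cnv_fate = character(), serum = character(),
                                  time = character(), dimension = character()),
    planted_dmrs = region, n_controls = 0, noise_sd = 0.2, seed = 5)
  co <- NULL
  expect_warning(co <- simulate_cohort(mf, design), "clipped")
  beta <- compute_beta(co$intensities)
  rows <- which(mf$chrom == "chr1" & mf$pos >= 1e6 & mf$pos <= 3e6)
  affected <- c("A_T1", "A_T2")
  others <- setdiff(colnames(beta), affected)
  # low-baseline probes clip at the 0.01 floor (warned above); judge the
  # planted shift where there is room for the full -0.3
  room <- rows[rowMeans(beta[rows, others, drop = FALSE]) >= 0.4]
  diff <- mean(beta[room, affected]) - mean(beta[room, others])
  expect_lt(abs(diff - (-0.3)), 0.05)
})

test_that("planted QC failures land where designed", {
  mf <- fixture_manifest()
  fails <- tibble::tibble(probe_id = mf$probe_id[c(3, 7)],
                          sample_id = c("A_T1", "A_T2"),
                          mode = c("detp", "beads"))
  design <- cohort_design(
    classes = tibble::tibble(class = "A", n_tumors = 2),
    signatures = list(A = tibble::tibble(probe_id = character(),
                                         target_beta = numeric())),
    paired_cells = tibble::tibble(cell_id = character(),
                                  tissue_id = character(),
                                  class = character(), divergence = character(),
                                  cnv_fate = character(), serum = character(),
                                  time = character(), dimension = character()),
    planted_failures = fails, n_controls = 0, seed = 2)
  co <- simulate_cohort(mf, design)
  expect_gt(co$intensities$detection_p[3, "A_T1"], 0.01)
  expect_lt(co$intensities$beadcount[7, "A_T2"], 3)
  expect_true(all(co$intensities$detection_p[-3, "A_T1"] < 0.01))
  expect_true(all(co$intensities$beadcount[-7, "A_T2"] >= 3))
})

test_that("write_dataset round-trips and refuses bad targets", {
  fx <- fixture_cohort()
  outdir <- withr::local_tempdir()
  target <- file.path(outdir, "ds")
  write_dataset(target, fx$cohort, fx$manifest)
  back <- read_dataset(target)
  expect_equal(back$intensities$M, fx$cohort$intensities$M,
               tolerance = 1e-9)
  expect_equal(back$intensities$detection_p,
               fx$cohort$intensities$detection_p, tolerance = 1e-9)
  expect_equal(back$sheet$sample_id, fx$cohort$sheet$sample_id)
  expect_equal(nrow(back$truth$cnv_segments),
               nrow(fx$cohort$truth$cnv_segments))
  expect_equal(back$manifest$pos, fx$manifest$pos)

  # refuse non-empty outdir without overwrite
  expect_error(write_dataset(target, fx$cohort, fx$manifest), "non-empty")
  expect_silent(write_dataset(target, fx$cohort, fx$manifest,
                              overwrite = TRUE))

  # empty cohort errors
  empty <- list(intensities = list(M = matrix(numeric(), 0, 0)))
  expect_error(write_dataset(file.path(outdir, "e"), empty, fx$manifest),
               "empty cohort")
})

test_that("gmt files round-trip and synthetic collections hit their panel", {
  mf <- fixture_manifest()
  panel <- dense_promoter_genes(mf)[1:5]
  gs <- make_genesets(mf, n_terms = 20, target_panel = panel,
                      n_target_terms = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  back <- read_gmt(path)
  expect_equal(back$term, gs$term)
  expect_equal(back$genes, gs$genes)
  hits <- vapply(gs$genes[1:3], function(g) length(intersect(g, panel)),
                 integer(1))
  expect_true(all(hits >= 1))
})
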