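make_ctrl <- function(n_probes = 500, n_ctrl = 4, seed = 30) {
  set.seed(seed)
  aff <- stats::rlnorm(n_probes, log(3000), 0.5)
  t_c <- aff * matrix(stats::rlnorm(n_probes * n_ctrl, 0, 0.1), n_probes)
  list(affinity = aff, controls = t_c)
}

test_that("probe_log2r vanishes for control-like samples and ignores global
           scale", {
  cc <- make_ctrl()
  # baseline is the mean control log-intensity, i.e. the geometric mean scale
  ref_sample <- 2^rowMeans(log2(cc$controls))
  lr <- probe_log2r(ref_sample, cc$controls)
  expect_lt(max(abs(lr)), 1e-8)

  lr2 <- probe_log2r(ref_sample * 2, cc$controls)
  expect_lt(max(abs(lr2)), 1e-8)

  set.seed(31)
  noisy <- cc$affinity * stats::rlnorm(500, 0, 0.1)
  a <- probe_log2r(noisy, cc$controls)
  b <- probe_log2r(noisy * 37.5, cc$controls)
  expect_equal(a, b, tolerance = 1e-10)

  expect_error(probe_log2r(noisy, cc$controls[, 1:2]), "3 control")
})

test_that("a planted 3-copy segment shifts segment log2R by ~log2(1.5)", {
  cc <- make_ctrl()
  set.seed(32)
  smp <- cc$affinity * stats::rlnorm(500, 0, 0.1)
  seg <- 101:150
  smp[seg] <- smp[seg] * 1.5
  lr <- probe_log2r(smp, cc$controls)
  expect_lt(abs((mean(lr[seg]) - mean(lr[-seg])) - log2(1.5)), 0.1)

  # zero-intensity probe excluded and imputed at the median
  smp2 <- smp
  smp2[7] <- 0
  lr2 <- probe_log2r(smp2, cc$controls)
  expect_equal(lr2[7], stats::median(lr2[-7]) , tolerance = 0.05)
})

test_that("make_bins follows the greedy both-minima rule", {
  mf <- tibble::tibble(probe_id = paste0("p", 1:100), chrom = "chr1",
                       pos = as.integer(seq(10000, 1000000, by = 10000)))
  bins <- make_bins(mf)
  expect_equal(nrow(bins), 6)
  expect_equal(bins$n_probes, c(rep(15L, 5), 25L))

  # 15 probes within 30 kb then a 100 kb gap: bin closes only at the far probe
  mf2 <- tibble::tibble(probe_id = paste0("p", 1:16), chrom = "chr1",
                        pos = as.integer(c(seq(1000, 30000, length.out = 15),
                                           130000)))
  bins2 <- make_bins(mf2)
  expect_equal(bins2$n_probes[1], 16L)

  # chromosome with too few probes -> single undersized bin
  mf3 <- tibble::tibble(probe_id = paste0("q", 1:5), chrom = "chr9",
                        pos = as.integer(1:5 * 1e4))
  bins3 <- make_bins(mf3)
  expect_true(bins3$undersized[1])
  expect_equal(nrow(bins3), 1)
})

test_that("bin_profile averages member probes", {
  mf <- tibble::tibble(probe_id = paste0("p", 1:30), chrom = "chr1",
                       pos = as.integer(seq(10000, 300000, by = 10000)))
  bins <- make_bins(mf)
  prof <- bin_profile(rep(0.2, 30), bins, "s")
  expect_true(all(abs(prof$log2r - 0.2) < 1e-12))
  vals <- c(rep(0.1, 5), rep(0.3, 5), rep(0.2, 20))  # first bin balanced
  expect_equal(bin_profile(vals, bins)$log2r[1], 0.2)
})

test_that("similarity handles identity, anti-correlation, flat profiles and
           tertiles", {
  mf <- tibble::tibble(probe_id = paste0("p", 1:60), chrom = "chr1",
                       pos = as.integer(seq(10000, 600000, by = 10000)))
  bins <- make_bins(mf)
  set.seed(33)
  x <- bin_profile(rnorm(60), bins, "cell")
  y <- x; y$sample_id <- "tissue"
  cohort <- c(0.2, 0.5, 1)
  s <- similarity(x, y, cohort)
  expect_equal(s$r, 1)
  expect_equal(s$category, "coincident")

  neg <- x
  neg$log2r <- -neg$log2r
  expect_equal(similarity(x, neg, cohort)$r, -1)

  flat <- x
  flat$log2r <- rep(0, nrow(flat))
  sf <- similarity(flat, y, cohort)
  expect_equal(sf$r, 0)
  expect_equal(sf$flag, "flat_profile")

  # 9 pairs at r = 0.1..0.9 split 3/3/3
  rs <- seq(0.1, 0.9, by = 0.1)
  cats <- vapply(rs, tertile_category, character(1), cohort = rs)
  expect_equal(unname(table(cats)[c("different", "similar", "coincident")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(cats[1:3], rep("different", 3))
  expect_equal(cats[7:9], rep("coincident", 3))
})

test_that("alteration_burden counts runs with a strict threshold", {
  expect_equal(alteration_burden(rep(0, 10)), 0)
  expect_equal(alteration_burden(c(0.2, 0.2, 0, -0.15)), 2)
  expect_equal(alteration_burden(c(0.1, 0.1)), 0)       # strictly greater
  expect_equal(alteration_burden(c(0.2, -0.2, 0.2)), 1) # one contiguous run
  expect_equal(alteration_burden(c(0, 0.3, 0, 0.3, 0)), 2)
})

test_that("burden_comparison is an exact two-sided rank-sum test", {
  same <- burden_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  r <- burden_comparison(c(0, 0, 0, 0), c(10, 12, 11, 13))
  expect_equal(r$p, 2 / choose(8, 4), tolerance = 1e-10)
  expect_equal(r$mean_a, 0)
  expect_equal(r$mean_b, 11.5)

  tied <- burden_comparison(c(2, 2), c(2, 2))
  expect_equal(tied$p, 1)
})

test_that("cumulative_profile reports gain/loss fractions and flatness", {
  mf <- tibble::tibble(probe_id = paste0("p", 1:30), chrom = "chr1",
                       pos = as.integer(seq(10000, 300000, by = 10000)))
  bins <- make_bins(mf)
  zero <- bin_profile(rep(0, 30), bins, "a")
  res <- cumulative_profile(list(zero, zero))
  expect_true(all(res$per_bin$frac_gain == 0))
  expect_equal(res$flatness, 0)

  gained <- bin_profile(c(rep(0.5, 15), rep(0, 15)), bins, "b")
  res2 <- cumulative_profile(list(zero, zero, zero, gained))
  expect_equal(res2$per_bin$frac_gain[1], 0.25)
  expect_gt(res2$flatness, res$flatness)
})

test_that("different-fate cells are flatter than their tissues on simulated
           cohorts", {
  fx <- fixture_cohort()
  co <- fx$cohort
  mf <- fx$manifest
  sheet <- co$sheet
  ctrl <- sheet$sample_id[sheet$role == "control"]
  ctrl_int <- list(M = co$intensities$M[, ctrl],
                   U = co$intensities$U[, ctrl])
  bins <- make_bins(mf)
  prof <- function(s) {
    bin_profile(probe_log2r(list(M = co$intensities$M[, s],
                                 U = co$intensities$U[, s]), ctrl_int),
                bins, s)
  }
  pc <- fx$design$paired_cells
  diff_cells <- pc$cell_id[pc$cnv_fate == "different"]
  their_tissues <- pc$tissue_id[pc$cnv_fate == "different"]
  flat_cells <- cumulative_profile(lapply(diff_cells, prof))$flatness
  flat_tissues <- cumulative_profile(lapply(their_tissues, prof))$flatness
  expect_lt(flat_cells, flat_tissues)
})
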