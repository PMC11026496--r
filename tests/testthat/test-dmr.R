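test_that("cpg_stats: identical groups give t = 0, p = 1; zero variance is
           flagged", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("cg", 1:10),
                              c("a1", "a2", "b1", "b2")))
  m[, 3:4] <- m[, 1:2]
  ct <- group_contrast(c("a1", "a2"), c("b1", "b2"))
  st <- cpg_stats(m, ct)
  expect_true(all(st$t == 0))
  expect_true(all(st$p == 1))

  m2 <- matrix(1, 5, 4, dimnames = list(paste0("cg", 1:5),
                                        c("a1", "a2", "b1", "b2")))
  st2 <- cpg_stats(m2, ct)
  expect_true(all(st2$flag_zero_var))
  expect_true(all(st2$p == 1))
})

test_that("cpg_stats with d0 = 0 equals the ordinary pooled t test", {
  set.seed(41)
  m <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(sprintf("cg%03d", 1:200),
                              c(paste0("a", 1:6), paste0("b", 1:6))))
  ct <- group_contrast(paste0("a", 1:6), paste0("b", 1:6))
  st <- cpg_stats(m, ct, d0 = 0)
  oracle <- apply(m, 1, function(row) {
    tt <- stats::t.test(row[1:6], row[7:12], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  })
  expect_equal(unname(st$t), unname(oracle[1, ]), tolerance = 1e-12)
  expect_equal(unname(st$p), unname(oracle[2, ]), tolerance = 1e-12)
})

test_that("cpg_stats power on a 2-sd shift at n = 8 matches the noncentral-t
           oracle", {
  hits <- 0
  for (s in 1:200) {
    set.seed(s)
    x <- matrix(c(rnorm(8, 0, 1), rnorm(8, 2, 1)), 1, 16,
                dimnames = list("cg1", c(paste0("a", 1:8), paste0("b", 1:8))))
    st <- cpg_stats(x, group_contrast(paste0("a", 1:8), paste0("b", 1:8)))
    if (abs(st$t) > 3) hits <- hits + 1
  }
  # with one CpG the shrinkage target equals the CpG's own variance, so the
  # statistic is the pooled t: |t| > 3 has power P(|T''(ncp = 4, df = 14)| > 3)
  ncp <- 2 / sqrt(2 / 8)
  power <- stats::pt(3, 14, ncp, lower.tail = FALSE) +
    stats::pt(-3, 14, ncp)
  mc_se <- sqrt(power * (1 - power) / 200)
  expect_lt(abs(hits / 200 - power), 3 * mc_se)
  expect_gt(hits / 200, 0.75)
})

test_that("call_dmrs recovers a planted 12-CpG island with tight boundaries", {
  recovered <- 0
  for (s in 1:20) {
    run <- simulate_dmr_run(s, island_len = 12)
    d <- run$dmrs
    ok <- nrow(d) >= 1 &&
      any(abs(d$start - run$island_range[1]) <= 400 &
            abs(d$end - run$island_range[2]) <= 400)
    if (ok) recovered <- recovered + 1
  }
  expect_gte(recovered, 18)
})

test_that("call_dmrs drops planted blocks below the minimum CpG count", {
  called <- vapply(1:20, function(s)
    nrow(simulate_dmr_run(s, island_len = 5)$dmrs), integer(1))
  expect_true(all(called == 0))
})

test_that("call_dmrs is quiet on null data", {
  spurious <- vapply(1:50, function(s)
    nrow(simulate_dmr_run(s + 500, delta = 0)$dmrs), integer(1))
  expect_lte(mean(spurious), 2)
})

test_that("called regions never overlap and respect the gap rule", {
  for (s in 1:5) {
    run <- simulate_dmr_run(s, island_len = 12)
    d <- run$dmrs
    if (nrow(d) < 2) next
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
  # member significant CpGs of one region are within lambda of each other
  run <- simulate_dmr_run(1, island_len = 12)
  for (i in seq_len(nrow(run$dmrs))) {
    pos <- run$positions$pos[match(run$dmrs$probe_ids[[i]],
                                   sprintf("cg%03d", 1:200))]
    expect_true(all(diff(sort(pos)) <= 1000))
  }
})

test_that("delta_beta equals the double average and is antisymmetric", {
  beta <- matrix(c(0.2, 0.2, 0.2,   # test sample 1
                   0.2, 0.2, 0.2,   # test sample 2
                   0.5, 0.5, 0.5,   # ref sample 1
                   0.5, 0.5, 0.5),  # ref sample 2
                 nrow = 3,
                 dimnames = list(c("cg1", "cg2", "cg3"),
                                 c("t1", "t2", "r1", "r2")))
  region <- tibble::tibble(probe_ids = list(c("cg1", "cg2", "cg3")))
  ct <- group_contrast(c("t1", "t2"), c("r1", "r2"))
  expect_equal(delta_beta(beta, region, ct), -0.3, tolerance = 1e-12)

  # probes {0.1, 0.3} in test vs {0.4, 0.6} in ref
  beta2 <- matrix(c(0.1, 0.3, 0.1, 0.3, 0.4, 0.6, 0.4, 0.6), nrow = 2,
                  dimnames = list(c("cg1", "cg2"),
                                  c("t1", "t2", "r1", "r2")))
  region2 <- tibble::tibble(probe_ids = list(c("cg1", "cg2")))
  expect_equal(delta_beta(beta2, region2, ct), -0.3, tolerance = 1e-12)

  # identity and antisymmetry
  beta_same <- beta
  beta_same[, c("r1", "r2")] <- beta[, c("t1", "t2")]
  expect_equal(delta_beta(beta_same, region, ct), 0)
  ct_rev <- group_contrast(c("r1", "r2"), c("t1", "t2"))
  set.seed(44)
  beta3 <- matrix(runif(12), 3,
                  dimnames = list(c("cg1", "cg2", "cg3"),
                                  c("t1", "t2", "r1", "r2")))
  expect_equal(delta_beta(beta3, region, ct),
               -delta_beta(beta3, region, ct_rev), tolerance = 1e-12)

  # missing probes error
  regionx <- tibble::tibble(probe_ids = list("cg99"))
  expect_error(delta_beta(beta, regionx, ct), "no surviving probes")
})

test_that("promoter_filter keeps DMRs with any promoter CpG", {
  mf <- tibble::tibble(probe_id = paste0("cg", 1:8),
                       region_class = c("TSS200", rep("Body", 7)))
  dmrs <- tibble::tibble(chrom = "chr1", start = 1L, end = 2L,
                         n_cpgs = c(7L, 7L), min_q = 0.01,
                         probe_ids = list(paste0("cg", 1:7),
                                          paste0("cg", 2:8)))
  kept <- promoter_filter(dmrs, mf)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$probe_ids[[1]], paste0("cg", 1:7))
  expect_equal(nrow(promoter_filter(dmrs[0, ], mf)), 0)
})

test_that("split_hypo_hyper applies strict 10% thresholds", {
  dmrs <- tibble::tibble(
    delta_beta = c(-0.15, 0.05, 0.10, 0.25, -0.10),
    genes = list("g1", "g2", "g3", "g4", "g5"))
  sets <- split_hypo_hyper(dmrs)
  expect_equal(sets$hypo, "g1")
  expect_equal(sets$hyper, "g4")
})
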