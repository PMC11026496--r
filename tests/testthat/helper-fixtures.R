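# Shared fixtures, memoized so expensive objects build once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

fixture_manifest <- function() {
  memo("manifest", build_manifest(
    6000, c(chr1 = 40e6, chr2 = 35e6, chrX = 8e6), seed = 11))
}

fixture_cohort <- function() {
  memo("cohort", {
    mf <- fixture_manifest()
    design <- default_cohort_design(mf, n_per_class = 2,
                                    n_cells_per_condition = 1,
                                    sig_size = 100, div_size = 150,
                                    panel_size = 8, seed = 11)
    list(manifest = mf, design = design,
         cohort = simulate_cohort(mf, design))
  })
}

fixture_pipeline <- function() {
  memo("pipeline", run_fidelity_pipeline(seed = 101))
}

# 200-CpG fixture: sparse 3 kb background with one dense 200 bp-spaced island,
# the geometry of promoter CpG islands on methylation arrays
dmr_positions <- function(island_len) {
  bg_n <- 200 - island_len
  bg1 <- seq(5000, by = 3000, length.out = 100)
  island <- seq(bg1[100] + 3000, by = 200, length.out = island_len)
  bg2 <- seq(island[island_len] + 3000, by = 3000,
             length.out = bg_n - 100)
  tibble::tibble(chrom = "chr1", pos = as.integer(c(bg1, island, bg2)),
                 in_island = c(rep(FALSE, 100), rep(TRUE, island_len),
                               rep(FALSE, bg_n - 100)))
}

simulate_dmr_run <- function(seed, island_len = 12, delta = -0.3, n = 8,
                             noise_sd = 0.3) {
  set.seed(seed)
  posd <- dmr_positions(island_len)
  mu <- matrix(0.5, 200, 2 * n)
  mu[posd$in_island, seq_len(n)] <- 0.5 + delta
  beta <- stats::plogis(stats::qlogis(mu) +
                          matrix(stats::rnorm(200 * 2 * n, 0, noise_sd), 200))
  rownames(beta) <- sprintf("cg%03d", 1:200)
  colnames(beta) <- c(paste0("t", seq_len(n)), paste0("r", seq_len(n)))
  contrast <- group_contrast(paste0("t", seq_len(n)), paste0("r", seq_len(n)))
  stats <- cpg_stats(beta_to_m(beta), contrast)
  list(dmrs = call_dmrs(stats, posd[, c("chrom", "pos")]),
       island_range = range(posd$pos[posd$in_island]),
       beta = beta, contrast = contrast, positions = posd)
}

# gaussian blobs in 2-D for clustering tests
make_blobs <- function(centers, n_per, sd, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    cbind(stats::rnorm(n_per, centers[k, 1], sd),
          stats::rnorm(n_per, centers[k, 2], sd))
  }))
}
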