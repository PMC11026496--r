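make_centroids <- function(p = 400, k = 3, seed = 60) {
  set.seed(seed)
  cent <- matrix(runif(p * k), p, k,
                 dimnames = list(sprintf("cg%03d", 1:p), LETTERS[1:k]))
  cent
}

test_that("centroid_scores is sharp for a centroid-equal sample and symmetric
           under equal correlation", {
  cent <- make_centroids()
  # sample equal to centroid A; other centroids anticorrelated with A
  cent[, 2] <- 1 - cent[, 1] + rnorm(400, 0, 0.01)
  cent[, 3] <- 1 - cent[, 1] + rnorm(400, 0, 0.01)
  beta <- matrix(cent[, 1], ncol = 1,
                 dimnames = list(rownames(cent), "s1"))
  sc <- centroid_scores(beta, cent, k = 10)
  expect_gt(sc$score[sc$class == "A"], 0.99)
  expect_equal(sc$assigned_class[1], "A")

  # equal correlation to all classes -> 1/k each
  cent2 <- make_centroids(seed = 61)
  beta2 <- matrix(0.5 + rnorm(400, 0, 0.2), ncol = 1,
                  dimnames = list(rownames(cent2), "s1"))
  r <- cor(beta2[, 1], cent2)
  sc2 <- centroid_scores(beta2, cent2, k = 0)  # k = 0 flattens the softmax
  expect_equal(sc2$score, rep(1 / 3, 3), tolerance = 1e-12)

  # score is monotone in r: increasing r_A raises score_A
  sc10 <- centroid_scores(beta, cent, k = 10)
  sA <- function(mix) {
    b <- matrix(mix * cent[, 1] + (1 - mix) * rowMeans(cent[, 2:3]),
                ncol = 1, dimnames = list(rownames(cent), "s"))
    centroid_scores(b, cent, k = 10)$score[1]
  }
  scores <- vapply(c(0.3, 0.6, 0.9), sA, numeric(1))
  expect_true(all(diff(scores) > 0))

  flat <- cent
  flat[, 2] <- 0.5
  expect_error(centroid_scores(beta, flat), "zero variance")
})

test_that("categorize applies the published score thresholds", {
  expect_equal(categorize(c(0.85, 0.5, 0.2)),
               c("faithful", "useful", "unfaithful"))
  expect_equal(categorize(0.84), "faithful")
  expect_equal(categorize(0.3), "useful")
  expect_error(categorize(1.2))
})

test_that("match_assessment combines class identity with score category", {
  sc <- tibble::tibble(sample_id = "c", class = c("MB", "LGG"),
                       score = c(0.9, 0.1),
                       assigned_class = "MB", max_score = 0.9)
  good <- match_assessment(sc, "MB")
  expect_true(good$histology_match)
  expect_equal(good$dnam_status, "maintained")

  # wrong class at a useful score is unfaithful
  sc$assigned_class <- "LGG"
  wrong <- match_assessment(sc, "MB")
  expect_false(wrong$histology_match)
  expect_equal(wrong$dnam_status, "unfaithful")

  # right class but unfaithful score
  sc$assigned_class <- "MB"
  sc$max_score <- 0.2
  low <- match_assessment(sc, "MB")
  expect_false(low$histology_match)
  expect_equal(low$dnam_status, "unfaithful")

  expect_error(match_assessment(sc, "XX"), "unknown histology")
})

test_that("assign_condition is a bijection over the 2x3 status grid", {
  grid <- expand.grid(dnam = c("maintained", "unfaithful"),
                      cnv = c("coincident", "similar", "different"),
                      stringsAsFactors = FALSE)
  codes <- assign_condition(grid$dnam, grid$cnv)
  expect_setequal(codes, 1:6)
  expect_equal(assign_condition("maintained", "coincident"), 1L)
  expect_equal(assign_condition("maintained", "similar"), 2L)
  expect_equal(assign_condition("maintained", "different"), 3L)
  expect_equal(assign_condition("unfaithful", "coincident"), 4L)
  expect_equal(assign_condition("unfaithful", "similar"), 5L)
  expect_equal(assign_condition("unfaithful", "different"), 6L)
  expect_true(is.na(assign_condition("maintained", NA)))
  expect_error(assign_condition("x", "similar"), "bad dnam_status")
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test and handles
           degenerate margins", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$odds_ratio, 1)

  set.seed(62)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 5), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ours <- fisher_exact_2x2(tab)$p
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }

  t19 <- matrix(c(1, 9, 9, 1), 2, 2)
  expect_equal(fisher_exact_2x2(t19)$p, stats::fisher.test(t19)$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(t19)$p, fisher_exact_2x2(t(t19))$p)

  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2))$p, 1)
})

test_that("chi_squared_test matches the Pearson formula and permutation
           invariance", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  res <- chi_squared_test(tab)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)

  expected_like <- matrix(c(10, 20, 5, 10), 2, 2)
  res2 <- chi_squared_test(expected_like)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)

  set.seed(63)
  tab3 <- matrix(rpois(6, 8) + 1, 2, 3)
  a <- chi_squared_test(tab3)$statistic
  b <- chi_squared_test(tab3[, c(2, 3, 1)])$statistic
  c_ <- chi_squared_test(tab3[c(2, 1), ])$statistic
  expect_equal(a, b)
  expect_equal(a, c_)

  expect_error(chi_squared_test(matrix(c(0, 0, 1, 2), 2, 2)), "zero row")
})

test_that("fidelity_report stratifies counts and detects a planted serum
           effect", {
  set.seed(64)
  n <- 15
  records <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:(2 * n)),
    category = c(rep("faithful", n), rep("unfaithful", n)),
    dnam_status = c(rep("maintained", n), rep("unfaithful", n)),
    condition = c(rep(1L, n), rep(6L, n)),
    serum = c(rep("serum_free", n), rep("serum", n)))
  rep_ <- fidelity_report(records, strata = "serum")
  expect_lt(rep_$tests$p[rep_$tests$stratum_var == "serum"], 0.01)

  cf <- rep_$counts[rep_$counts$stratum == "serum_free", ]
  expect_equal(cf$pct[cf$category == "faithful"], 100)

  # single stratum: counts only, no test
  rec2 <- records[records$serum == "serum", ]
  rep2 <- fidelity_report(rec2, strata = "serum")
  expect_equal(nrow(rep2$tests), 0)

  # whole-number percentages: 3 of 22
  rec3 <- tibble::tibble(cell_id = sprintf("c%02d", 1:22),
                         category = c(rep("faithful", 3),
                                      rep("unfaithful", 19)),
                         dnam_status = c(rep("maintained", 3),
                                         rep("unfaithful", 19)),
                         condition = NA_integer_,
                         serum = "serum")
  rep3 <- fidelity_report(rec3, strata = "serum")
  expect_equal(rep3$counts$pct[rep3$counts$category == "faithful"], 14)
})

test_that("cohort_match_summary reproduces whole-number percentages", {
  counts <- tibble::tibble(
    cohort = c("tissue", "tissue", "cell", "cell"),
    class = c("X", "Y", "X", "Y"),
    total = c(100, 55, 50, 36),
    matched = c(99, 54, 20, 21),
    faithful = c(NA, NA, 10, 15))
  s <- cohort_match_summary(counts)
  expect_equal(s$match_pct$pct[s$match_pct$cohort == "tissue"], 99)
  expect_equal(s$match_pct$pct[s$match_pct$cohort == "cell"], 48)
  expect_equal(s$faithful_pct$pct, c(20, 42))
})
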