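#' Class centroids from reference (tumor) samples
#'
#' Mean beta per class over the `top_n` most variable probes among the
#' reference samples; the centroid panel a [centroid_scores()] surrogate
#' classifier matches new samples against.
#'
#' @param beta beta matrix (probes x samples).
#' @param sample_ids reference sample ids (columns of `beta`).
#' @param classes class label per reference sample.
#' @param top_n number of most-variable probes retained.
#' @return list with `centroids` (probes x classes matrix) and `probes`.
#' @export
build_class_centroids <- function(beta, sample_ids, classes, top_n = 5000) {
  stopifnot(length(sample_ids) == length(classes),
            all(sample_ids %in% colnames(beta)))
  sub <- beta[, sample_ids, drop = FALSE]
  v <- apply(sub, 1, stats::var)
  top_n <- min(top_n, nrow(beta))
  probes <- rownames(beta)[order(v, decreasing = TRUE)[seq_len(top_n)]]
  cls <- sort(unique(classes))
  cent <- vapply(cls, function(cl)
    rowMeans(sub[probes, sample_ids[classes == cl], drop = FALSE]),
    numeric(length(probes)))
  list(centroids = cent, probes = probes)
}

#' Softmax class-membership scores against class centroids
#'
#' Pearson correlation of each sample with each class centroid, passed
#' through a softmax with sharpness `k`: higher correlation with one class
#' concentrates the score mass there. Scores per sample sum to 1. A stand-in
#' for an externally trained methylation classifier; externally produced
#' score tables can be supplied instead via [read_external_scores()].
#'
#' @param beta beta matrix including the samples to score.
#' @param reference list from [build_class_centroids()], or a probes x
#'   classes centroid matrix over rownames of `beta`.
#' @param sample_ids samples to score; default all columns of `beta`.
#' @param k softmax sharpness.
#' @return tibble `sample_id`, `class`, `r`, `score`, plus per-sample
#'   `assigned_class` and `max_score` repeated on each row; one row per
#'   sample x class.
#' @export
centroid_scores <- function(beta, reference, sample_ids = colnames(beta),
                            k = 10) {
  cent <- if (is.list(reference) && !is.null(reference$centroids)) {
    reference$centroids[, , drop = FALSE]
  } else {
    reference
  }
  probes <- if (is.list(reference) && !is.null(reference$probes)) {
    reference$probes
  } else {
    rownames(cent) %||% rownames(beta)
  }
  if (ncol(cent) < 2) stop("need >= 2 classes")
  if (any(apply(cent, 2, stats::sd) < .Machine$double.eps)) {
    stop("centroid with zero variance")
  }
  sub <- beta[probes, sample_ids, drop = FALSE]
  r <- stats::cor(sub, cent)  # samples x classes
  sc <- exp(k * r)
  sc <- sc / rowSums(sc)
  cls <- colnames(cent)
  out <- tibble::tibble(
    sample_id = rep(sample_ids, times = length(cls)),
    class = rep(cls, each = length(sample_ids)),
    r = as.vector(r), score = as.vector(sc))
  best <- dplyr::group_by(out, .data$sample_id)
  best <- dplyr::summarise(
    best,
    assigned_class = {
      mx <- max(.data$score)
      tied <- sort(.data$class[.data$score >= mx - 1e-12])
      tied[1]
    },
    max_score = max(.data$score),
    tie = sum(.data$score >= max(.data$score) - 1e-12) > 1,
    .groups = "drop")
  dplyr::left_join(out, best, by = "sample_id")
}

#' Read an external per-class score table
#'
#' Accepts a TSV with columns `sample_id`, `class`, `score` (one row per
#' sample x class) from an external classifier and normalizes it to the
#' [centroid_scores()] output shape.
#'
#' @param path TSV file path.
#' @return tibble like [centroid_scores()] (without `r`).
#' @export
read_external_scores <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("sample_id", "class", "score") %in% names(df)))
  best <- dplyr::group_by(df, .data$sample_id)
  best <- dplyr::summarise(
    best,
    assigned_class = sort(.data$class[.data$score >= max(.data$score) - 1e-12])[1],
    max_score = max(.data$score),
    tie = sum(.data$score >= max(.data$score) - 1e-12) > 1,
    .groups = "drop")
  dplyr::left_join(df, best, by = "sample_id")
}

#' Fidelity category from a classifier score
#'
#' Faithful for scores of at least 0.84, useful for scores in \[0.3, 0.84),
#' unfaithful below 0.3. The boundary convention (0.84 is faithful, 0.3 is
#' useful) is this package's documented resolution of the interval ambiguity.
#'
#' @param score maximum class score in \[0, 1\] (vectorized).
#' @return character vector in `{"faithful", "useful", "unfaithful"}`.
#' @export
categorize <- function(score) {
  stopifnot(all(score >= 0 & score <= 1))
  ifelse(score >= 0.84, "faithful",
         ifelse(score >= 0.3, "useful", "unfaithful"))
}

#' Histology match and DNAm status for one sample
#'
#' A sample's DNAm profile is maintained when it is assigned to its
#' histology's class with at least a useful score; a wrong class or a score
#' below 0.3 makes it unfaithful.
#'
#' @param scores one sample's rows of a [centroid_scores()] table (or any
#'   tibble with `assigned_class`, `max_score` for that sample).
#' @param histology the sample's histological class label.
#' @return list with `histology_match` (logical), `dnam_status`
#'   (`"maintained"`/`"unfaithful"`), `category`.
#' @export
match_assessment <- function(scores, histology) {
  if (!histology %in% scores$class) stop("unknown histology label: ", histology)
  assigned <- scores$assigned_class[1]
  category <- categorize(scores$max_score[1])
  match <- (assigned == histology) && category != "unfaithful"
  list(histology_match = match,
       dnam_status = if (match) "maintained" else "unfaithful",
       category = category)
}

#' Six-condition code from DNAm status and CNV category
#'
#' The 2x3 cross of DNAm status with CNV similarity: (maintained, coincident)
#' = 1, (maintained, similar) = 2, (maintained, different) = 3, (unfaithful,
#' coincident) = 4, (unfaithful, similar) = 5, (unfaithful, different) = 6.
#'
#' @param dnam_status `"maintained"` or `"unfaithful"` (vectorized).
#' @param cnv_category `"coincident"`, `"similar"` or `"different"`.
#' @return integer condition code 1-6, NA if either input is NA.
#' @export
assign_condition <- function(dnam_status, cnv_category) {
  d <- match(dnam_status, c("maintained", "unfaithful"))
  c_ <- match(cnv_category, c("coincident", "similar", "different"))
  if (any(is.na(d) & !is.na(dnam_status))) stop("bad dnam_status")
  if (any(is.na(c_) & !is.na(cnv_category))) stop("bad cnv_category")
  as.integer((d - 1) * 3 + c_)
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Two-sided p by the minimum-likelihood rule: the sum of hypergeometric
#' point probabilities no larger than the observed table's. The sample odds
#' ratio is reported.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return tibble `odds_ratio`, `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(table[, 2]) == 0) {
    p <- 1
  } else {
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(support, r1, r2, c1)
    p_obs <- stats::dhyper(a, r1, r2, c1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  tibble::new_tibble(list(odds_ratio = or, p = p), nrow = 1L)
}

#' Pearson chi-squared test for an r x c count table
#'
#' Without continuity correction by default; for 2x2 tables the Yates
#' correction can be switched on.
#'
#' @param table r x c matrix of counts.
#' @param correct apply the continuity correction (2x2 only).
#' @return tibble `statistic`, `df`, `p`.
#' @export
chi_squared_test <- function(table, correct = FALSE) {
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value)
}

#' Stratified fidelity summary tables and tests
#'
#' Per stratum of each metadata variable, counts and whole-number percentages
#' of faithful/useful/unfaithful cells and the condition distribution, plus a
#' Fisher (2x2) or chi-squared test of matched (faithful + useful with
#' correct class) versus unfaithful across strata.
#'
#' @param records tibble of per-cell fidelity records with columns
#'   `cell_id`, `category`, `dnam_status`, `condition`, and the metadata
#'   columns named in `strata`.
#' @param strata character vector of metadata column names to stratify by.
#' @return list with `counts` (tibble `stratum_var`, `stratum`, `category`,
#'   `n`, `pct`), `conditions` (tibble `stratum_var`, `stratum`, `condition`,
#'   `n`), and `tests` (tibble `stratum_var`, `test`, `p`).
#' @export
fidelity_report <- function(records,
                            strata = c("serum", "time", "dimension")) {
  strata <- intersect(strata, names(records))
  counts <- list(); conds <- list(); tests <- list()
  for (v in strata) {
    sub <- records[!is.na(records[[v]]), ]
    lv <- unique(sub[[v]])
    if (length(lv) == 0) next
    for (s in lv) {
      grp <- sub[sub[[v]] == s, ]
      if (nrow(grp) == 0) next
      tab <- table(factor(grp$category,
                          levels = c("faithful", "useful", "unfaithful")))
      counts[[length(counts) + 1]] <- tibble::tibble(
        stratum_var = v, stratum = s,
        category = names(tab), n = as.integer(tab),
        pct = round(100 * as.integer(tab) / nrow(grp)))
      ctab <- table(grp$condition)
      if (length(ctab)) {
        conds[[length(conds) + 1]] <- tibble::tibble(
          stratum_var = v, stratum = s,
          condition = as.integer(names(ctab)), n = as.integer(ctab))
      }
    }
    if (length(lv) >= 2) {
      maintained <- records$dnam_status == "maintained"
      tab <- table(factor(records[[v]], levels = lv), maintained)
      if (all(dim(tab) == c(2, 2))) {
        tests[[length(tests) + 1]] <- tibble::tibble(
          stratum_var = v, test = "fisher",
          p = fisher_exact_2x2(unclass(tab))$p)
      } else if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        tests[[length(tests) + 1]] <- tibble::tibble(
          stratum_var = v, test = "chisq",
          p = chi_squared_test(unclass(tab))$p)
      }
    }
  }
  list(counts = dplyr::bind_rows(counts),
       conditions = dplyr::bind_rows(conds),
       tests = dplyr::bind_rows(tests))
}
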