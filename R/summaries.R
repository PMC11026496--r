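#' Match and faithful percentages from a cohort count table
#'
#' Takes a per-class count table for a profiled cohort (tissues and cell
#' lines, with the number whose classifier call matched the histological
#' assessment and, where known, the number scoring faithful) and computes the
#' whole-number percentages used in cohort summaries: per-cohort match
#' percentage (matched / total) and per-class faithful percentage.
#'
#' A reference table for a published pediatric brain-tumor cohort ships as
#' `system.file("extdata", "cohort_counts.tsv", package = "methfidelity")`.
#'
#' @param counts tibble/data frame with columns `cohort` (`"tissue"` /
#'   `"cell"`), `class`, `total`, `matched`, `faithful` (NA where unknown).
#' @return list with `match_pct` (tibble `cohort`, `total`, `matched`,
#'   `pct`) and `faithful_pct` (tibble `cohort`, `class`, `total`,
#'   `faithful`, `pct`).
#' @export
cohort_match_summary <- function(counts) {
  stopifnot(all(c("cohort", "class", "total", "matched") %in% names(counts)))
  match_pct <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(counts), .data$cohort),
    total = sum(.data$total), matched = sum(.data$matched),
    .groups = "drop")
  match_pct$pct <- round(100 * match_pct$matched / match_pct$total)
  fa <- counts[!is.na(counts$faithful), c("cohort", "class", "total",
                                          "faithful")]
  fa$pct <- round(100 * fa$faithful / fa$total)
  list(match_pct = match_pct, faithful_pct = tibble::as_tibble(fa))
}
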