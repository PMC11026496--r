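#' Write a simulated cohort to plain-text files
#'
#' Writes the four intensity matrices as TSV, the manifest as TSV plus a
#' BED-compatible export (0-based half-open coordinates), the sample sheet as
#' TSV and the ground truth as JSON. Values round-trip through
#' [read_dataset()] to within 1e-9.
#'
#' @param outdir output directory; created if missing. An existing non-empty
#'   directory is refused unless `overwrite = TRUE`.
#' @param cohort a list as returned by [simulate_cohort()] (elements
#'   `intensities`, `sheet`, `truth`).
#' @param manifest the manifest the cohort was simulated from.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(outdir, cohort, manifest, overwrite = FALSE) {
  ints <- cohort$intensities
  if (is.null(dim(ints$M)) || nrow(ints$M) == 0 || ncol(ints$M) == 0) {
    stop("empty cohort: nothing to write")
  }
  assert_matrix_aligned(ints$M, ints$U, ints$detection_p, ints$beadcount,
                        what = "intensity matrices")
  stopifnot(nrow(ints$M) == nrow(manifest), ncol(ints$M) == nrow(cohort$sheet))
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !overwrite) {
    stop("outdir ", outdir, " is non-empty; pass overwrite = TRUE")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  write_mat <- function(m, f) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  files <- file.path(outdir, c("intensities_M.tsv", "intensities_U.tsv",
                               "intensities_detp.tsv", "intensities_beads.tsv",
                               "manifest.tsv", "manifest.bed",
                               "samplesheet.tsv", "truth.json"))
  write_mat(ints$M, files[1])
  write_mat(ints$U, files[2])
  write_mat(ints$detection_p, files[3])
  write_mat(ints$beadcount, files[4])
  utils::write.table(manifest, files[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(chrom = manifest$chrom, start = manifest$pos - 1L,
                    end = manifest$pos, name = manifest$probe_id)
  utils::write.table(bed, files[6], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$sheet, files[7], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- cohort$truth
  truth$dmr_regions$samples <- lapply(truth$dmr_regions$samples, identity)
  jsonlite::write_json(truth, files[8], auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(files)
}

#' Read a cohort written by [write_dataset()]
#'
#' @param indir directory written by [write_dataset()].
#' @return a list with `intensities`, `sheet`, `truth` (truth tables as
#'   tibbles) and `manifest`.
#' @export
read_dataset <- function(indir) {
  read_mat <- function(f, integer = FALSE) {
    df <- utils::read.delim(file.path(indir, f), check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$probe_id
    if (integer) storage.mode(m) <- "integer"
    m
  }
  manifest <- tibble::as_tibble(
    utils::read.delim(file.path(indir, "manifest.tsv"),
                      stringsAsFactors = FALSE))
  manifest$gene[is.na(manifest$gene)] <- ""
  sheet <- tibble::as_tibble(
    utils::read.delim(file.path(indir, "samplesheet.tsv"),
                      stringsAsFactors = FALSE))
  truth_raw <- jsonlite::read_json(file.path(indir, "truth.json"),
                                   simplifyVector = TRUE)
  truth <- list(
    true_class = tibble::as_tibble(truth_raw$true_class),
    true_fidelity = tibble::as_tibble(truth_raw$true_fidelity),
    dmr_regions = tibble::as_tibble(truth_raw$dmr_regions),
    cnv_segments = tibble::as_tibble(truth_raw$cnv_segments)
  )
  list(intensities = list(M = read_mat("intensities_M.tsv"),
                          U = read_mat("intensities_U.tsv"),
                          detection_p = read_mat("intensities_detp.tsv"),
                          beadcount = read_mat("intensities_beads.tsv",
                                               integer = TRUE)),
       sheet = sheet, truth = truth, manifest = manifest)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: tab-separated lines `term`, `description`, genes...
#' @return tibble with columns `term`, `description`, list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT: lines with fewer than 3 fields")
  tibble::tibble(
    term = vapply(parts, `[[`, character(1), 1),
    description = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write a GMT gene-set file
#'
#' @param genesets tibble as returned by [read_gmt()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(seq_len(nrow(genesets)), function(i) {
    paste(c(genesets$term[i], genesets$description[i],
            genesets$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic gene-set collection over a manifest's genes
#'
#' Draws `n_terms` gene sets from the manifest's gene universe. A configurable
#' number of terms is enriched for a target panel (e.g. the divergence panel)
#' so that enrichment analyses have planted positives.
#'
#' @param manifest manifest tibble.
#' @param n_terms number of gene sets.
#' @param size_range min/max genes per term.
#' @param target_panel genes to over-represent in the first
#'   `n_target_terms` terms.
#' @param n_target_terms how many terms are panel-enriched.
#' @param target_frac fraction of a panel-enriched term drawn from the panel.
#' @param seed integer seed.
#' @return tibble with `term`, `description`, list-column `genes`.
#' @export
make_genesets <- function(manifest, n_terms = 50, size_range = c(10, 40),
                          target_panel = character(), n_target_terms = 5,
                          target_frac = 0.5, seed = 1) {
  genes <- setdiff(unique(manifest$gene), "")
  with_seed(seed, {
    sets <- lapply(seq_len(n_terms), function(i) {
      size <- sample(size_range[1]:size_range[2], 1)
      if (i <= n_target_terms && length(target_panel)) {
        k <- min(length(target_panel), max(1, round(target_frac * size)))
        unique(c(sample(target_panel, k),
                 sample(setdiff(genes, target_panel), size - k)))
      } else {
        sample(genes, size)
      }
    })
    tibble::tibble(term = sprintf("TERM_%03d", seq_len(n_terms)),
                   description = ifelse(seq_len(n_terms) <= n_target_terms &
                                          length(target_panel) > 0,
                                        "panel-enriched", "random"),
                   genes = sets)
  })
}
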