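#' Build a synthetic Infinium-style probe manifest
#'
#' Lays out CpG probes along a small synthetic genome. Genes are tiled at
#' regular intervals along each chromosome; a fraction of probes is placed in
#' promoter bursts around gene transcription start sites (so that some genes,
#' as on real arrays, carry a dense promoter cluster of 7+ CpGs), the rest
#' uniformly. Region classes follow the probe's offset from the TSS:
#' `TSS200` (within 200 bp upstream), `TSS1500` (200-1500 bp upstream),
#' `1stExon` (up to 800 bp downstream), `Body` (inside the gene span) and
#' `IGR` (intergenic, no gene). Positions are 1-based and strictly increasing
#' within each chromosome.
#'
#' @param n_probes number of probes to place (>= 100).
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#'   Chromosomes named `"chrX"`/`"chrY"` (or `"X"`/`"Y"`) are flagged as sex
#'   chromosomes.
#' @param gene_spacing distance in bp between consecutive gene TSSs.
#' @param seed integer seed; the manifest is deterministic given the seed.
#' @param promoter_frac fraction of probes placed in promoter bursts.
#' @param type1_frac fraction of probes assigned Infinium design type I.
#' @param blacklist_frac fraction of probes flagged as SNP/cross-reactive
#'   proxies.
#' @param gene_conc gamma concentration for how unevenly promoter probes are
#'   spread over genes; smaller means burstier promoters.
#'
#' @return A tibble with columns `probe_id`, `chrom`, `pos`, `gene`,
#'   `region_class`, `design_type`, `blacklist_flag`, `sex_chrom_flag`.
#' @export
#' @examples
#' mf <- build_manifest(1000, c(chr1 = 1e7), seed = 1)
#' table(mf$region_class)
build_manifest <- function(n_probes, chrom_sizes, gene_spacing = 60000,
                           seed = 1, promoter_frac = 0.12, type1_frac = 0.15,
                           blacklist_frac = 0.01, gene_conc = 0.3) {
  stopifnot(n_probes >= 100, length(chrom_sizes) >= 1)
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector")
  }
  with_seed(seed, {
    # probes per chromosome, proportional to size
    alloc <- round(n_probes * chrom_sizes / sum(chrom_sizes))
    alloc[1] <- alloc[1] + (n_probes - sum(alloc))
    if (any(alloc > chrom_sizes / 10)) {
      stop("chromosome sizes too small to place probes at plausible density")
    }
    per_chrom <- lapply(names(chrom_sizes), function(ch) {
      size <- chrom_sizes[[ch]]
      n <- alloc[[ch]]
      if (n == 0L) return(NULL)
      tss <- seq(gene_spacing, size - gene_spacing, by = gene_spacing)
      if (length(tss) < 1L) stop("chromosome ", ch, " too small for gene_spacing")
      genes <- sprintf("G%s_%03d", sub("^chr", "", ch), seq_along(tss))
      gene_len <- round(0.4 * gene_spacing)

      n_prom <- round(promoter_frac * n)
      n_unif <- n - n_prom
      # bursty promoter coverage: gamma weights per gene
      w <- stats::rgamma(length(tss), shape = gene_conc, rate = 1)
      gene_of_prom <- sample.int(length(tss), n_prom, replace = TRUE,
                                 prob = w / sum(w))
      off <- round(stats::runif(n_prom, -1500, 800))
      pos_prom <- tss[gene_of_prom] + off
      pos_unif <- round(stats::runif(n_unif, 1, size))
      pos <- c(pos_prom, pos_unif)
      pos <- pmin(pmax(pos, 1), size)

      ord <- order(pos)
      pos <- pos[ord]
      # enforce strictly increasing positions
      while (any(dup <- duplicated(pos))) {
        pos[dup] <- pos[dup] + 1L
        pos <- sort(pos)
      }

      # annotate by offset from nearest TSS
      gi <- pmin(pmax(round(pos / gene_spacing), 1L), length(tss))
      offset <- pos - tss[gi]
      region <- rep("IGR", length(pos))
      gene <- rep("", length(pos))
      in_prom <- offset >= -1500 & offset <= 800
      in_body <- offset > 800 & offset <= gene_len
      region[in_body] <- "Body"
      region[in_prom & offset >= -200 & offset <= 0] <- "TSS200"
      region[in_prom & offset < -200] <- "TSS1500"
      region[in_prom & offset > 0] <- "1stExon"
      gene[in_prom | in_body] <- genes[gi[in_prom | in_body]]

      tibble::tibble(chrom = ch, pos = as.integer(pos), gene = gene,
                     region_class = region)
    })
    mf <- dplyr::bind_rows(per_chrom)
    n <- nrow(mf)
    mf$probe_id <- sprintf("cg%08d", seq_len(n))
    mf$design_type <- ifelse(stats::runif(n) < type1_frac, "I", "II")
    mf$blacklist_flag <- stats::runif(n) < blacklist_frac
    mf$sex_chrom_flag <- mf$chrom %in% c("chrX", "chrY", "X", "Y")
    mf[, c("probe_id", "chrom", "pos", "gene", "region_class",
           "design_type", "blacklist_flag", "sex_chrom_flag")]
  })
}

#' Gene-level CpG counts from a manifest
#'
#' Number of manifest probes annotated to each gene; used as the probe-number
#' bias term in [wallenius_test()].
#'
#' @param manifest a manifest tibble from [build_manifest()].
#' @return named integer vector, one entry per gene.
#' @export
gene_cpg_counts <- function(manifest) {
  g <- manifest$gene[manifest$gene != ""]
  counts <- table(g)
  stats::setNames(as.integer(counts), names(counts))
}

# genes whose promoter (TSS200/TSS1500/1stExon) cluster has >= min_cpgs probes
dense_promoter_genes <- function(manifest, min_cpgs = 7) {
  prom <- manifest[manifest$region_class %in% c("TSS200", "TSS1500", "1stExon") &
                     manifest$gene != "" & !manifest$sex_chrom_flag &
                     !manifest$blacklist_flag, ]
  counts <- table(prom$gene)
  names(counts)[counts >= min_cpgs]
}
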