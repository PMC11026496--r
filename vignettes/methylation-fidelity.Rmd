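---
title: "Assessing epigenomic fidelity of tumor-derived cell cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing epigenomic fidelity of tumor-derived cell cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient-derived cell cultures are the workhorse of functional tumor biology,
but a culture is only useful as a model if it still resembles the tumor it
came from. Genome-wide DNA methylation is a sensitive readout of that
resemblance: methylation classes distinguish tumor entities, and the same
array also encodes copy-number information in its probe intensities.
`methfidelity` implements a complete, testable pipeline for grading cultures
against their parental tissues on both axes:

1. **DNAm class membership** — a per-sample score against reference class
   centroids, thresholded into *faithful* (score ≥ 0.84), *useful*
   (0.3 ≤ score < 0.84, correct class) and *unfaithful* (wrong class or
   score < 0.3) categories;
2. **CNV similarity** — per-bin log2 copy-number ratios correlated between
   cell line and paired tissue, categorized by cohort tertiles into
   *coincident* / *similar* / *different*;
3. the **six-condition taxonomy** crossing DNAm status
   (maintained/unfaithful) with CNV similarity;
4. **DMR calling and gene-set enrichment** to characterize *what* changed in
   drifted cultures.

Because raw patient array data cannot ship with a package, every stage is
exercised end-to-end on a synthetic Infinium-style cohort generator with
known ground truth. The generator is first-class, tested code: its planted
signals define what "recovered correctly" means in the test suite and the
acceptance script.

## The synthetic cohort generator

`build_manifest()` lays out probes on a small genome. Genes are tiled at
regular spacing; a fraction of probes (12%) falls in promoter bursts around
transcription start sites — with a gamma-weighted gene choice so that, as on
real arrays, some genes carry dense promoter clusters of 7+ CpGs while most
carry a couple. Region classes (TSS200/TSS1500/1stExon/Body/IGR) follow the
offset from the TSS; ~15% of probes are design type I, ~1% carry a
SNP/cross-reactivity proxy flag, and chrX probes carry the sex-chromosome
flag.

`simulate_cohort()` draws, per probe, a baseline beta from a bimodal
logit-normal mixture (modes near 0.1 and 0.85, logit-sd 0.4), which yields
the characteristic bimodal beta distribution (≥ 60% of probe means in
[0, 0.2] ∪ [0.8, 1]). On top of the baseline:

* **class signatures** — each histology class fixes ~250 designated CpGs at
  class-specific target levels (0.1 or 0.9); tumors and faithful cells of
  the class follow them;
* **divergence** — unfaithful cells lose 90% of their class signature and
  acquire (i) a shared 400-CpG divergence signature and (ii) promoter
  hypomethylation (Δβ = −0.35) over a 30-gene panel whose promoters start at
  beta 0.75. The default design also includes a small tumor-only MNG class
  whose signature coincides with the divergence signature, so drifted
  cultures classify *there* — the wrong class — rather than hovering near
  their own class's score threshold. This mirrors the observed behavior of
  divergent cultures converging on a common off-target methylation class;
* **noise** — i.i.d. logit-scale Gaussian noise, sd 0.3 per observation, a
  realistic per-probe technical scatter for array betas.

Betas become channel intensities through a single total-intensity draw per
probe and sample: `M = T·β`, `U = T·(1−β)`, with
`T = affinity[probe] · lognormal(0, 0.15)` and the per-probe affinity shared
across samples (lognormal, median 3000). The shared affinity matters: it is
exactly what regression on copy-neutral controls removes, and it is why
methylation-array CNV calling works on real data. Planted CNV segments
multiply `T` by `1 + purity·(copies/2 − 1)`; purity defaults to 1. Detection
p-values are < 0.01 and bead counts ≥ 3 except at planted failures.

The default study design (`default_cohort_design()`) is fixed at a scale a
desk validation can afford: 4 cell-contributing classes × 6 tumors, 24
paired cultures spread evenly over the six fidelity conditions (4 each), 4
MNG tumors, 6 copy-neutral controls — 58 samples over 18,000 probes. Tumors
carry three planted segments (a 3-copy gain, a 1-copy loss, one random);
*coincident* cells inherit all three, *similar* cells two plus one private
segment, *different* cells none. Culture metadata (serum/time/2D-3D) is
biased toward serum/late/2D among unfaithful cells, mirroring the direction
reported for patient-derived cultures.

**What the generator does not emulate:** probe chemistry (out-of-band
signal, dye bias), FFPE degradation, cell-composition mixtures, multi-gene
probes, and the correlation structure of real methylomes beyond the planted
signals. Passing tests therefore demonstrate that the *algorithms* recover
what they are specified to recover under controlled conditions — not that
any particular biological cohort would behave identically.

## Preprocessing

`filter_probes()` applies the standard ordered filters: detection p > 0.01
in any sample; bead count < 3 in ≥ 5% of samples; blacklist; sex
chromosomes. Reasons are exclusive first-match, so the removed-probe ledger
sums to the manifest size. The any-sample detection rule is the conservative
reading of the usual QC recipe (no sample fraction is standard for this
rule).

Betas use the Illumina definition `M/(M + U + 100)`; M-values are
`log2(β/(1−β))` with betas clipped at 1e-6.

**BMIQ.** Type II probes are mapped onto the type I scale by beta-mixture
quantile dilation: per sample, three-state beta mixtures are fitted by EM to
each design type (moment-matching M-step, tolerance 1e-4, 100 iterations,
fixed-center initialization so the fit is deterministic); unmethylated and
methylated type II probes are mapped through the fitted CDFs
(`qbeta(pbeta(·))`), and hemimethylated probes are dilated linearly between
the two mapped state boundaries. State classification is made contiguous in
beta order before mapping, which guarantees a monotone overall transform.
Samples whose EM fails fall back to identity and are flagged. Type I values
are returned bit-identical.

**Cohort QC.** `mds_outlier_check()` runs classical MDS on the top-1000
most-variable probes and flags samples with robust z > 3 on either leading
axis — an operational rule, deliberately aggressive: in a structured cohort
it will flag whole minority clusters, so its output is a prompt for
inspection, not an automatic exclusion. `svd_covariate_scan()` associates
the leading components of the row-centered beta matrix (up to 6) with sample
covariates — Kruskal–Wallis for categorical, Spearman for numeric — at a
0.01 significance threshold.

## Embedding, clustering, validity

`embed()` follows the PCA-initialized t-SNE protocol: 20-component PCA, map
initialized from the first two PCA axes scaled to sd 1e-4, perplexity 15,
early exaggeration (factor 12) for 200 iterations, 750 iterations total.
Gradients are computed exactly; at cohort sizes of tens-to-hundreds of
samples this equals the Barnes–Hut approximation whose `theta` (0.5) is
recorded in the result's metadata for provenance. The learning rate defaults
to the openTSNE-style automatic rate `max(n/12, 50)` — a fixed large rate
diverges on near-duplicate clusters. The optimization is deterministic given
the data, so identical inputs give identical maps. `embed_grid()` exposes
the hyperparameter sweep (perplexity/theta/early exaggeration) as a
utility without re-running it by default.

`cluster()` is a full HDBSCAN implementation: k-NN core distances
(`min_samples` defaults to `min_cluster_size` = 4, the size of the smallest
tumor group), mutual-reachability minimum spanning tree, condensed tree at
`min_cluster_size`, excess-of-mass cluster selection (root excluded unless
`allow_single_cluster`). Noise is label 0; clusters are renumbered by
decreasing size — published cluster numbers are not reproducible
identifiers, only the partition is.

`dbcv()` implements density-based cluster validation: all-points core
distances (inverse-distance mean with exponent = embedding dimension),
mutual reachability, density sparseness (largest internal MST edge) versus
density separation (smallest mutual reachability between clusters' internal
nodes), per-cluster validity in [−1, 1], size-weighted overall index.
Clusters above 0.25 are flagged valid. Coincident points are floored at
1e-12 with a warning.

## CNV from probe intensities

`probe_log2r()` regresses a sample's log2 combined intensity (`M + U`) on
the mean control log2 intensity (intercept + slope, least squares) and
median-centers the residual: one fit against the control average, rather
than a fitted combination of individual controls — a documented
simplification of the reference approach, validated on planted segments
(recovered gain ≈ log2(1.5) = 0.585). The fit makes log2R exactly invariant
to global rescaling of the sample. Zero-intensity probes are excluded from
the fit and imputed at the median.

`make_bins()` builds bins greedily per chromosome: accumulate probes until
span ≥ 50 kb *and* count ≥ 15, then close; the trailing remainder merges
into the last bin; undersized chromosomes yield one flagged bin excluded
from correlations. `bin_profile()` takes the per-bin mean (no shrinkage —
documented simplification). `similarity()` correlates cell and tissue bins
(Pearson by default, Spearman by option) and categorizes by the cohort's
tertile boundaries (type-7 quantiles at 1/3 and 2/3, boundary values to the
lower category); flat profiles get r = 0 with a `flat_profile` flag.
`alteration_burden()` counts maximal runs of bins with |log2R| strictly
above 0.1 — regions, not bins. `burden_comparison()` is an exact two-sided
rank-sum test (full enumeration with midranks for small groups).
`cumulative_profile()` reports per-bin gain/loss fractions and a flatness
summary (mean |log2R|), under which divergent cells are measurably flatter
than their tissues in the synthetic cohort.

## DMRs and Δβ

`cpg_stats()` computes per-CpG moderated t statistics on M-values: pooled
variance shrunk toward the global mean variance with d0 = 4
pseudo-observations, p-values on df + d0 degrees of freedom; d0 = 0 recovers
the ordinary pooled t exactly. CpGs with zero variance in both groups get
t = 0, p = 1, and a flag.

`call_dmrs()` smooths squared t statistics along the genome with a Gaussian
kernel (bandwidth λ/2 with λ = 1000 bp, truncated at 4 sd), assigns each
CpG a p-value from a Satterthwaite-matched scaled chi-square (treating the
unsmoothed squared statistics as independent t² draws), applies
Benjamini–Hochberg across CpGs, groups significant CpGs (q < 0.05) into
regions split at gaps > λ, and discards regions with fewer than 7
significant CpGs. This follows the kernel-smoothing architecture of
established DMR callers as a reimplementation, not a port: validation is
planted-signal recovery (a 12-CpG island at Δβ = −0.3 is recovered with
boundaries within ±2 CpGs in 20/20 seeded runs; a 5-CpG island is never
called; null runs average ≤ 2 spurious regions), not output-identity with
any reference tool. Region bounds are the min/max positions of member
significant CpGs.

`delta_beta()` is computed on normalized betas (statistics are on M-values;
Δβ on the beta scale — the two-scale split is intentional): for each test
sample, the difference from the reference-group mean, averaged over region
probes and then over test samples; algebraically the test mean minus
reference mean over the region. `promoter_filter()` keeps regions with ≥ 1
CpG in TSS200/TSS1500/1stExon; `split_hypo_hyper()` applies the strict
|Δβ| > 0.10 thresholds. Enrichment defaults to the promoter-restricted DMR
set (the restriction can be disabled by passing the unfiltered table) —
where the upstream protocol is ambiguous about which set feeds enrichment,
promoter-restricted is the default here.

## Enrichment

`wallenius_test()` weights each term by the probe-number bias: odds = mean
CpG count of term genes / mean CpG count of the rest of the universe, with
the tail probability of the Wallenius noncentral hypergeometric computed by
adaptive quadrature of its integral representation (substituted to be
polynomial-smooth; odds = 1 reproduces the central hypergeometric to
machine precision). Collapsing per-gene biases to a single odds is the
field-standard approximation; with strongly dispersed CpG counts it can
deviate from per-gene-weight urn sampling by ~0.01–0.04 in absolute p — a
characterized limitation tested explicitly. `ora_fisher()` is the one-sided
Fisher/hypergeometric ORA. `reduce_redundancy()` replaces semantic-
similarity reduction with a greedy Jaccard rule (keep by ascending p unless
similarity with a kept term exceeds 0.3) — ontology topology is out of
scope, and the published similarity cutoff is reused as the Jaccard cutoff.
`intersect_hypo()` intersects hypomethylated gene lists across contrasts
and tabulates all k-way overlaps.

## Fidelity calls

`centroid_scores()` is a documented surrogate for an external trained
classifier, which is out of scope: class centroids are mean betas of
reference tumors over the top-5000 most-variable probes, a sample's scores
are a softmax (sharpness k = 10) over its Pearson correlations with the
centroids, and externally produced score tables can be supplied instead via
`read_external_scores()`. `categorize()` applies the 0.3/0.84 thresholds;
the published interval notation is open at both ends, so the boundary
convention here — 0.84 counts as faithful, 0.3 as useful — is documented
rather than inherited. `match_assessment()` declares DNAm maintained only
for a correct-class assignment at a non-unfaithful score.
`assign_condition()` maps the 2×3 grid (maintained/unfaithful ×
coincident/similar/different) to conditions 1–6. "Maintained" is
faithful-or-useful with the correct class, consistent with aggregating
faithful + useful as matches in cohort tables.

`fisher_exact_2x2()` uses the minimum-likelihood two-sided rule (sum of
point probabilities ≤ observed), which is what exhaustive enumeration
validates; the doubling method would differ near small p.
`chi_squared_test()` is Pearson's test without continuity correction by
default. `fidelity_report()` produces per-stratum category counts with
whole-number percentages and the matched-versus-unfaithful tests per
stratification.

## Numerical choices and degenerate inputs

* Clipping: planted beta shifts clip to [0.01, 0.99] with a warning; beta
  values clip at 1e-6 before logit.
* BMIQ EM: moment-matching M-step with variance capped below m(1−m);
  identity fallback on non-convergence.
* t-SNE: perplexity ≥ (n−1)/3 is an error; optimization is deterministic.
* HDBSCAN: all-noise output (K = 0) is valid; single-cluster roots are
  noise unless `allow_single_cluster`.
* DBCV: clusters lacking internal MST nodes fall back to all nodes; single
  evaluated cluster has validity 1 by convention (no separation defined).
* Tertiles: ties at a boundary go to the lower category; cohorts whose size
  is not divisible by 3 split with sizes differing by ≤ 1.
* Wallenius: degenerate D ≤ 0 returns the point mass at the support edge.
* Exact rank-sum enumeration caps at choose(n, nA) ≤ 2e5, then the normal
  approximation takes over.

## Problem sizes used in validation

The shipped validation uses 18,000 probes × 58 samples for the end-to-end
cohort, 200-CpG fixtures over 20 (recovery) and 50 (null) seeds for DMR
calling, 5,000 type II probes for BMIQ, a 30-gene universe with 10,000 urn
draws for Wallenius, and exhaustive enumeration of all 2×2 tables with
N ≤ 30 for the Fisher test. These sizes were chosen so the whole validation
runs comfortably on a laptop while leaving every recovery margin wide.

## Known limitations

* The classifier surrogate is not a trained classifier; its scores are
  calibrated only by the softmax sharpness, and absolute score values on
  real data would differ from a production classifier's calibrated scores.
* The CNV baseline uses one regressor (the control mean); highly variable
  control sets would benefit from the reference tool's fitted combinations.
* The Wallenius odds collapse is first-order in the bias spread.
* No segmentation (CBS/HMM) and no focal-amplification calling; burden is a
  run count over fixed bins.
* GO-style semantic similarity is replaced by set overlap; terms with
  disjoint gene sets are never merged however related their concepts.
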