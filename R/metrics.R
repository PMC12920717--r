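#' Diversity-decay metric lambda
#'
#' The sum of variant allele frequencies over all variants retained by the
#' tip-variant filter: lambda = sum_k mu_k.  Because every variant belongs
#' to exactly one subclonal cluster, this equals the cluster-based decay
#' metric gamma computed with exact member-mean cluster frequencies, but
#' needs no clustering step.  Tip variants must be excluded first; the
#' filter at `threshold` is (re-)applied internally and is idempotent.
#'
#' @param x a [vfs] object.
#' @param threshold tip-variant VAF threshold (default 0.01).
#' @return Non-negative scalar; 0 for an empty post-filter spectrum.
#' @seealso [gamma_metric()], [filter_tip_variants()]
#' @export
lambda_metric <- function(x, threshold = 0.01) {
  stopifnot(inherits(x, "vfs"))
  f <- filter_tip_variants(x, threshold)
  sum(f$records$vaf)
}

#' Largest retained VAF
#'
#' The maximum VAF among retained variants, a proxy for the single most
#' expanded clone.
#' @param x a [vfs] object (already tip-filtered, or pass `threshold`).
#' @param threshold optional VAF threshold to apply first.
#' @return Scalar VAF.
#' @export
largest_vaf <- function(x, threshold = NULL) {
  stopifnot(inherits(x, "vfs"))
  if (!is.null(threshold)) x <- filter_tip_variants(x, threshold)
  if (!nrow(x$records)) stop_input("empty VFS: largest VAF undefined")
  max(x$records$vaf)
}

#' Nucleotide diversity (pi) from a VFS
#'
#' Within-population average heterozygosity summed over variant sites.
#' Somatic variants are heterozygous in carrier lineages, so the carrier
#' (cell-level) frequency of a variant is twice its VAF; each site
#' contributes 2 p (1 - p) with the unbiased n/(n-1) small-sample
#' correction, which makes the result identical to the mean pairwise
#' Hamming distance between lineages.
#'
#' @param x a [vfs] object.
#' @param n_lineages number of sampled lineages (>= 2).
#' @return Expected pairwise differences across all variant sites.
#' @seealso [pi_from_matrix()] for the genotype-matrix route.
#' @export
pi_metric <- function(x, n_lineages) {
  stopifnot(inherits(x, "vfs"))
  if (!is.numeric(n_lineages) || n_lineages < 2)
    stop_input("n_lineages must be >= 2")
  if (!nrow(x$records)) return(0)
  p <- pmin(1, 2 * x$records$vaf)
  sum(2 * p * (1 - p)) * n_lineages / (n_lineages - 1)
}

#' Nucleotide diversity from a genotype matrix
#'
#' Mean pairwise difference count computed site-wise with pairwise deletion
#' of missing calls: each site contributes 2 c (n_s - c) / (n_s (n_s - 1))
#' where c is the carrier count and n_s the non-missing lineages at that
#' site.
#'
#' @param matrix binary lineages-by-variants matrix (NA = missing).
#' @return Scalar pi.
#' @export
pi_from_matrix <- function(matrix) {
  x <- as.matrix(matrix)
  c_i <- colSums(x == 1, na.rm = TRUE)
  n_i <- colSums(!is.na(x))
  use <- n_i >= 2
  sum(2 * c_i[use] * (n_i[use] - c_i[use]) / (n_i[use] * (n_i[use] - 1)))
}

#' Tajima's D on a binary somatic alignment
#'
#' Compares pairwise diversity against Watterson's estimator on the binary
#' presence/absence alignment of somatic variants across sampled lineages,
#' normalized by the standard variance under neutrality.  The reference
#' state is ancestral (somatic variants are derived by construction).
#' Missing calls are handled by per-site pairwise deletion in the diversity
#' term; the normalizing constants use the full lineage count.
#'
#' @param matrix binary lineages-by-variants matrix (NA = missing), >= 4
#'   lineages.
#' @return Scalar D.
#' @export
tajimas_d <- function(matrix) {
  x <- as.matrix(matrix)
  n <- nrow(x)
  if (n < 4) stop_input("Tajima's D needs at least 4 lineages")
  c_i <- colSums(x == 1, na.rm = TRUE)
  n_i <- colSums(!is.na(x))
  seg <- c_i > 0 & c_i < n_i
  S <- sum(seg)
  if (S == 0) stop_input("no segregating sites: Tajima's D undefined")
  th_pi <- sum(2 * c_i[seg] * (n_i[seg] - c_i[seg]) / (n_i[seg] * (n_i[seg] - 1)))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (th_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fay and Wu's H on a binary somatic alignment
#'
#' H = theta_pi - theta_H, where theta_H = sum_sites 2 c^2 / (n (n - 1))
#' weights sites by the square of their derived-allele count.  Negative H
#' signals an excess of high-frequency derived variants, the footprint of
#' clonal expansion.  Polarization is by construction: the reference allele
#' is ancestral, so no outgroup is needed.  Fixed sites (c = n) are not
#' segregating and are skipped.
#'
#' @inheritParams tajimas_d
#' @return Scalar H.
#' @export
fay_wu_h <- function(matrix) {
  x <- as.matrix(matrix)
  n <- nrow(x)
  if (n < 4) stop_input("Fay & Wu's H needs at least 4 lineages")
  c_i <- colSums(x == 1, na.rm = TRUE)
  n_i <- colSums(!is.na(x))
  seg <- c_i > 0 & c_i < n_i
  if (!any(seg)) stop_input("no segregating sites: Fay & Wu's H undefined")
  th_pi <- sum(2 * c_i[seg] * (n_i[seg] - c_i[seg]) / (n_i[seg] * (n_i[seg] - 1)))
  th_h <- sum(2 * c_i[seg]^2 / (n_i[seg] * (n_i[seg] - 1)))
  th_pi - th_h
}

#' Shannon diversity from a lineages-through-time plateau cut
#'
#' HSC phylogenies diversify explosively during embryogenesis and then
#' plateau; clades founded before the plateau are the individual's primary
#' HSC lineages.  This statistic locates the plateau on the
#' log-lineage-count versus time curve, cuts the tree there, and returns the
#' Shannon index -sum c_i log c_i over the tip fractions c_i of the
#' resulting clades.
#'
#' The plateau is located on the discrete slope of log lineage count against
#' time (tied event times collapsed first): the chosen changepoint is the
#' interior split event with the largest *proportional* drop between the
#' incoming and outgoing slope.  The proportional form matters because the
#' near-simultaneous embryonic splits give steep but slowly decaying raw
#' slopes, whose absolute second differences would swamp the
#' embryonic-to-adult transition.  The cut falls midway between the chosen
#' event and the next one (any time in that open interval yields the same
#' clade decomposition).  When no interior event exists, the cut falls back
#' to 2.5 years (midpoint of the typical 2--3 year diversification
#' plateau), clamped to half the tree height for very young trees.
#'
#' @param tree a rooted, time-calibrated `ape::phylo` tree (branch lengths
#'   in years; a `root.edge` is honoured) or an `"hsc_tree"` from
#'   [simulate_individual()].
#' @return Shannon diversity of post-embryonic clade sizes.
#' @export
shannon_ltt <- function(tree) {
  phy <- if (inherits(tree, "hsc_tree")) tree$phylo else tree
  if (!inherits(phy, "phylo")) stop_input("tree must be a phylo or hsc_tree")
  ntip <- length(phy$tip.label)
  if (ntip < 2) stop_input("tree must have at least 2 tips")
  root_edge <- phy$root.edge %||% 0
  depth <- ape::node.depth.edgelength(phy) + root_edge
  height <- max(depth)
  internal <- (ntip + 1):(ntip + phy$Nnode)
  split_times <- sort(round(depth[internal], 12))  # collapse tied event times
  u <- unique(split_times)
  counts <- vapply(u, function(t) 1 + sum(split_times <= t), numeric(1))
  t_cut <- NA_real_
  if (length(u) >= 3) {
    logn <- log(counts)
    j <- 2:(length(u) - 1)
    s_before <- (logn[j] - logn[j - 1]) / (u[j] - u[j - 1])
    s_after <- (logn[j + 1] - logn[j]) / (u[j + 1] - u[j])
    drop <- log(s_after) - log(s_before)  # slopes are positive: counts increase
    if (any(drop < 0)) {
      jstar <- j[which.min(drop)]
      t_cut <- (u[jstar] + u[jstar + 1]) / 2
    }
  }
  if (is.na(t_cut)) t_cut <- min(2.5, height / 2)
  # clades = edges crossing the cut time
  if (t_cut < root_edge) return(0)  # a single stem lineage holds every tip
  ntips_below <- ape::node.depth(phy)  # number of descendant tips per node
  parent <- phy$edge[, 1]; child <- phy$edge[, 2]
  crossing <- depth[parent] <= t_cut & depth[child] > t_cut
  sizes <- ntips_below[child[crossing]]
  # tips that sit exactly at or before the cut (degenerate zero-length case)
  if (!length(sizes)) return(0)
  c_i <- sizes / sum(sizes)
  -sum(c_i * log(c_i))
}

#' One-row summary of all diversity metrics for an individual
#'
#' Computes lambda and the comparison statistics that the available inputs
#' allow: gamma and Hill numbers need a cluster set (inferred from the
#' filtered spectrum when not supplied), pi needs the number of sampled
#' lineages, Tajima's D and Fay & Wu's H need the genotype matrix, and the
#' LTT Shannon diversity needs the time-calibrated tree.  Missing inputs
#' yield NA for the corresponding statistics.
#'
#' @param x a [vfs] object.
#' @param matrix optional binary genotype matrix (lineages x variants).
#' @param tree optional `phylo` or `"hsc_tree"`.
#' @param clusters optional `"cluster_set"`; computed by [cluster_vafs()]
#'   on the filtered spectrum when `NULL` and at least one variant remains.
#' @param threshold tip-variant threshold (default 0.01).
#' @param n_lineages lineage count for pi; taken from `nrow(matrix)` when a
#'   matrix is given.
#' @param seed seed forwarded to [cluster_vafs()].
#' @return One-row data.frame of metrics.
#' @export
metric_report <- function(x, matrix = NULL, tree = NULL, clusters = NULL,
                          threshold = 0.01, n_lineages = NULL, seed = 1L) {
  stopifnot(inherits(x, "vfs"))
  filt <- filter_tip_variants(x, threshold)
  lam <- sum(filt$records$vaf)
  if (is.null(n_lineages) && !is.null(matrix)) n_lineages <- nrow(matrix)
  if (is.null(clusters) && nrow(filt$records) >= 1)
    clusters <- cluster_vafs(filt, seed = seed)
  has_cl <- !is.null(clusters) && nrow(clusters$clusters) > 0 &&
    length(setdiff(clusters$clusters$cluster_id, clusters$excluded_cluster_ids)) > 0
  seg_ok <- function(m) {
    c_i <- colSums(as.matrix(m) == 1, na.rm = TRUE)
    n_i <- colSums(!is.na(as.matrix(m)))
    any(c_i > 0 & c_i < n_i)
  }
  data.frame(
    sample_id = x$sample_id,
    age = x$age,
    lambda = lam,
    gamma = if (has_cl) gamma_metric(clusters) else NA_real_,
    pi = if (!is.null(matrix)) pi_from_matrix(matrix)
         else if (!is.null(n_lineages)) pi_metric(x, n_lineages) else NA_real_,
    tajimas_d = if (!is.null(matrix) && nrow(matrix) >= 4 && seg_ok(matrix))
      tajimas_d(matrix) else NA_real_,
    fay_wu_h = if (!is.null(matrix) && nrow(matrix) >= 4 && seg_ok(matrix))
      fay_wu_h(matrix) else NA_real_,
    hill_q0 = if (has_cl) hill_numbers(clusters, 0) else NA_real_,
    hill_q1 = if (has_cl) hill_numbers(clusters, 1) else NA_real_,
    hill_q2 = if (has_cl) hill_numbers(clusters, 2) else NA_real_,
    shannon_ltt = if (!is.null(tree)) shannon_ltt(tree) else NA_real_,
    largest_vaf = if (nrow(filt$records)) max(filt$records$vaf) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Regress comparison metrics against lambda across individuals
#'
#' Ordinary least-squares R-squared of each metric against the reference
#' metric across individuals (one [metric_report()] row each).  Metrics with
#' fewer than 3 complete pairs or zero variance are reported as NA.
#'
#' @param reports data.frame of stacked [metric_report()] rows.
#' @param reference name of the reference column (default `"lambda"`).
#' @return data.frame with columns `metric`, `r_squared`, `n`.
#' @export
metric_correlations <- function(reports, reference = "lambda") {
  if (!is.data.frame(reports) || !reference %in% names(reports))
    stop_input("reports must be a data.frame containing a '", reference, "' column")
  if (nrow(reports) < 3)
    stop_input("at least 3 individuals are required for regression")
  metrics <- setdiff(names(reports), c("sample_id", "age", reference))
  metrics <- metrics[vapply(reports[metrics], is.numeric, logical(1))]
  out <- lapply(metrics, function(mcol) {
    ok <- complete.cases(reports[[mcol]], reports[[reference]])
    n <- sum(ok)
    r2 <- NA_real_
    if (n >= 3 && var(reports[[mcol]][ok]) > 0 && var(reports[[reference]][ok]) > 0)
      r2 <- suppressWarnings(
        summary(lm(reports[[mcol]][ok] ~ reports[[reference]][ok])))$r.squared
    data.frame(metric = mcol, r_squared = r2, n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
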