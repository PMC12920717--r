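#' Cluster VAFs into subclonal groups
#'
#' Groups variants by the fraction of reads (or colony cells) supporting the
#' alternate allele, as a fast stand-in for full Dirichlet-process subclone
#' inference: a one-dimensional binomial mixture over (mutant count, total
#' count) pairs is fitted by expectation--maximization for 1..`k_max`
#' components, the component count is selected by BIC (ties broken toward
#' fewer components), and variants are hard-assigned by maximum posterior.
#' Initial component locations come from a k-means++ style seeding on the
#' observed count fractions, so the whole procedure is deterministic given
#' `seed`.
#'
#' The input is expected to be tip-filtered already (see
#' [filter_tip_variants()]); clustering an unfiltered spectrum mostly
#' recovers one huge cluster of tip variants.  After fitting, the spurious
#' low-frequency cluster exclusion is applied (see Details).
#'
#' @details
#' Subclone inference on somatic spectra typically recovers one very large
#' cluster of rare variants that actually sit on distinct phylogenetic tips;
#' its mean VAF is characteristically below ~4%.  The default rule
#' (`exclude = "largest"`) flags the single largest cluster by member count
#' if and only if its mean VAF is below `exclude_below`; `"all_below"` flags
#' every cluster with mean VAF below the cutoff; `"none"` disables the rule.
#' Flagged clusters stay in the object (`excluded_cluster_ids`) and are
#' skipped by [gamma_metric()] and [hill_numbers()].
#'
#' @param x a tip-filtered [vfs] object.
#' @param k_max maximum number of mixture components (default 20).
#' @param seed integer seed controlling initialization.
#' @param exclude spurious-cluster rule: `"largest"`, `"all_below"`, `"none"`.
#' @param exclude_below mean-VAF cutoff for the rule (default 0.04).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return An object of class `"cluster_set"`: list with `clusters`
#'   (data.frame `cluster_id`, `size`, `mean_vaf`), `assignment` (named
#'   integer vector variant -> cluster), `excluded_cluster_ids`, `seed`,
#'   `method_tag`.
#' @export
cluster_vafs <- function(x, k_max = 20L, seed = 1L,
                         exclude = c("largest", "all_below", "none"),
                         exclude_below = 0.04, max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(x, "vfs"))
  exclude <- match.arg(exclude)
  rec <- x$records
  if (nrow(rec) < 1)
    return(structure(list(clusters = data.frame(cluster_id = integer(),
                                                size = integer(),
                                                mean_vaf = numeric()),
                          assignment = setNames(integer(), character()),
                          excluded_cluster_ids = integer(),
                          seed = seed, method_tag = "binmix_em_bic"),
                     class = "cluster_set"))
  m <- rec$mutant_count
  d <- rec$mutant_count + rec$nonmutant_count
  frac <- m / d
  n <- length(m)
  k_cap <- min(k_max, length(unique(frac)))
  best <- NULL
  for (k in seq_len(k_cap)) {
    fit <- binmix_em(m, d, k, seed = seed, max_iter = max_iter, tol = tol)
    bic <- -2 * fit$loglik + (2 * k - 1) * log(n)
    # strict improvement required, so BIC ties resolve to fewer components
    if (is.null(best) || bic < best$bic - 1e-8) best <- c(fit, list(bic = bic, k = k))
  }
  post <- best$post
  assign_raw <- max.col(post, ties.method = "first")
  # drop empty components, renumber by decreasing mean member VAF
  used <- sort(unique(assign_raw))
  means <- vapply(used, function(c) mean(rec$vaf[assign_raw == c]), numeric(1))
  ord <- used[order(means, decreasing = TRUE)]
  assignment <- match(assign_raw, ord)
  names(assignment) <- rec$variant_id
  cs <- clusters_from_assignment(x, assignment, seed = seed,
                                 method_tag = "binmix_em_bic")
  cl <- cs$clusters
  excluded <- integer()
  if (exclude == "largest" && nrow(cl)) {
    big <- cl$cluster_id[which.max(cl$size)]
    if (cl$mean_vaf[cl$cluster_id == big] < exclude_below) excluded <- big
  } else if (exclude == "all_below") {
    excluded <- cl$cluster_id[cl$mean_vaf < exclude_below]
  }
  cs$excluded_cluster_ids <- excluded
  cs
}

# binomial mixture EM for fixed k; deterministic given seed
binmix_em <- function(m, d, k, seed, max_iter = 500L, tol = 1e-8) {
  frac <- m / d
  p <- with_seed(seed, kmeanspp_centers(frac, k))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logdens <- vapply(seq_len(k), function(c)
      log(w[c]) + dbinom(m, d, p[c], log = TRUE), numeric(length(m)))
    logdens <- matrix(logdens, nrow = length(m))
    mx <- apply(logdens, 1, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    post <- exp(logdens - lse)
    w <- colMeans(post)
    p <- as.numeric(crossprod(post, m) / crossprod(post, d))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(loglik = ll, p = p, w = w, post = post)
}

# k-means++ seeding followed by a few Lloyd iterations, on 1-d values;
# caller controls the RNG state
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(x, function(v) min((v - centers[1:(j - 1)])^2), numeric(1))
      if (all(d2 == 0)) centers[j] <- x[sample.int(length(x), 1)]
      else centers[j] <- x[sample.int(length(x), 1, prob = d2)]
    }
  }
  for (it in 1:10) {
    cl <- apply(outer(x, centers, function(a, b) (a - b)^2), 1, which.min)
    for (j in seq_len(k)) if (any(cl == j)) centers[j] <- mean(x[cl == j])
  }
  sort(centers)
}

#' Build a cluster set from an explicit assignment
#'
#' Constructs a `"cluster_set"` whose per-cluster mean VAF is the exact
#' arithmetic mean of its members' VAFs, with no exclusions.  Under exact
#' member means, the cluster-sum identity sum_i f_i * n_i = sum_k mu_k holds,
#' so [gamma_metric()] on the result equals [lambda_metric()] on the same
#' spectrum.
#'
#' @param x a [vfs] object.
#' @param assignment integer vector of cluster labels, one per record (or a
#'   named vector keyed by `variant_id`).
#' @param seed,method_tag provenance fields.
#' @return A `"cluster_set"` object.
#' @export
clusters_from_assignment <- function(x, assignment, seed = NA_integer_,
                                     method_tag = "assignment") {
  stopifnot(inherits(x, "vfs"))
  rec <- x$records
  if (!is.null(names(assignment))) assignment <- assignment[rec$variant_id]
  if (length(assignment) != nrow(rec) || anyNA(assignment))
    stop_input("assignment must label every variant exactly once")
  assignment <- as.integer(assignment)
  ids <- sort(unique(assignment))
  cl <- data.frame(
    cluster_id = ids,
    size = vapply(ids, function(c) sum(assignment == c), integer(1)),
    mean_vaf = vapply(ids, function(c) mean(rec$vaf[assignment == c]), numeric(1)))
  structure(list(clusters = cl,
                 assignment = setNames(assignment, rec$variant_id),
                 excluded_cluster_ids = integer(),
                 seed = seed, method_tag = method_tag),
            class = "cluster_set")
}

#' @method print cluster_set
#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s), %d variant(s)%s [%s]\n",
              nrow(x$clusters), length(x$assignment),
              if (length(x$excluded_cluster_ids))
                sprintf(", %d excluded", length(x$excluded_cluster_ids)) else "",
              x$method_tag))
  print(x$clusters)
  invisible(x)
}

#' Export a cluster table
#'
#' Mirrors the subclone-caller cluster table layout: columns `cluster_id`,
#' `size`, `mean`.
#' @param x a `"cluster_set"`.
#' @param path output TSV.
#' @export
write_cluster_set <- function(x, path) {
  tab <- x$clusters
  names(tab) <- c("cluster_id", "size", "mean")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cluster-based diversity-decay metric (gamma)
#'
#' Sums cluster frequency times cluster size over all non-excluded clusters:
#' gamma = sum_i f_i * n_i.  Each clonal expansion removes phylogenetic
#' diversity in proportion to the fraction of cells it converted (f) times
#' the number of variants its founding lineage carried (n), so gamma
#' accumulates the total decay across expansions.
#'
#' @param clusters a `"cluster_set"` (see [cluster_vafs()]).
#' @return Non-negative scalar.
#' @export
gamma_metric <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  cl <- clusters$clusters
  keep <- !(cl$cluster_id %in% clusters$excluded_cluster_ids)
  if (!any(keep)) return(0)
  sum(cl$mean_vaf[keep] * cl$size[keep])
}

#' Hill numbers of the inferred clonal structure
#'
#' Treats the non-excluded cluster mean frequencies, normalized to sum to
#' one, as clonal abundances and returns the Hill number of order `q`:
#' richness (q = 0), the exponential of Shannon entropy (q = 1), or the
#' inverse Simpson concentration (q = 2).  The family is non-increasing in
#' q for any abundance vector.
#'
#' @param clusters a `"cluster_set"`.
#' @param q order, one of 0, 1, 2.
#' @return Diversity of order `q`.
#' @export
hill_numbers <- function(clusters, q = c(0, 1, 2)) {
  stopifnot(inherits(clusters, "cluster_set"))
  q <- match.arg(as.character(q[1]), c("0", "1", "2"))
  cl <- clusters$clusters
  keep <- !(cl$cluster_id %in% clusters$excluded_cluster_ids)
  f <- cl$mean_vaf[keep]
  if (!length(f)) stop_input("no non-excluded clusters: Hill numbers undefined")
  p <- f / sum(f)
  switch(q,
         "0" = length(p),
         "1" = exp(-sum(p * log(p))),
         "2" = 1 / sum(p^2))
}
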