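test_that("lambda sums the surviving VAFs and responds monotonically", {
  v <- make_vfs(c(0.10, 0.20, 0.005))
  expect_equal(lambda_metric(v, 0.01), 0.30)
  empty <- vfs(data.frame(variant_id = character(), mutant_count = numeric(),
                          nonmutant_count = numeric(), source = character()))
  expect_equal(lambda_metric(empty), 0)
  # adding a retained variant raises lambda by exactly its VAF
  v2 <- make_vfs(c(0.10, 0.20, 0.005, 0.07))
  expect_equal(lambda_metric(v2, 0.01) - lambda_metric(v, 0.01), 0.07)
  # colony bound: lambda <= 0.5 * retained count
  set.seed(11)
  for (rep in 1:20) {
    vv <- make_vfs(runif(30, 0, 0.5), depth = 10000)
    lam <- lambda_metric(vv, 0.01)
    kept <- sum(vfs_records(vv)$vaf >= 0.01)
    expect_lte(lam, 0.5 * kept + 1e-12)
    expect_gte(lam, 0)
  }
})

test_that("VAF clustering separates well-spaced groups deterministically", {
  v <- make_vfs(c(rep(0.30, 5), rep(0.10, 4)) + c(seq(-2e-3, 2e-3, length.out = 5),
                                                  seq(-1e-3, 2e-3, length.out = 4)),
                source = "bulk_reads", depth = 500)
  cs <- cluster_vafs(v, seed = 5)
  expect_equal(nrow(cs$clusters), 2)
  expect_equal(cs$clusters$size, c(5, 4))
  expect_equal(cs$clusters$mean_vaf, c(0.30, 0.10), tolerance = 0.02)
  # every variant maps to exactly one cluster
  expect_equal(sort(names(cs$assignment)), sort(vfs_records(v)$variant_id))
  # determinism
  cs2 <- cluster_vafs(v, seed = 5)
  expect_identical(cs$clusters, cs2$clusters)
  expect_identical(cs$assignment, cs2$assignment)
  # single variant: one cluster of size 1 at its VAF
  one <- make_vfs(0.23, source = "bulk_reads", depth = 200)
  cs1 <- cluster_vafs(one, seed = 1)
  expect_equal(cs1$clusters$size, 1)
  expect_equal(cs1$clusters$mean_vaf, vfs_records(one)$vaf)
  # empty input: empty cluster set
  empty <- vfs(data.frame(variant_id = character(), mutant_count = numeric(),
                          nonmutant_count = numeric(), source = character()))
  expect_equal(nrow(cluster_vafs(empty, seed = 1)$clusters), 0)
})

test_that("the spurious low-frequency cluster rule flags the big rare cluster", {
  # 40 rare variants near 2% plus a clean clone at 30%
  set.seed(2)
  v <- make_vfs(c(runif(40, 0.012, 0.03), rep(0.30, 6)), source = "bulk_reads",
                depth = 2000)
  cs <- cluster_vafs(v, seed = 2)
  expect_true(length(cs$excluded_cluster_ids) >= 1)
  big <- cs$clusters$cluster_id[which.max(cs$clusters$size)]
  expect_true(big %in% cs$excluded_cluster_ids)
  expect_lt(cs$clusters$mean_vaf[cs$clusters$cluster_id == big], 0.04)
  # gamma skips the excluded cluster
  kept <- !(cs$clusters$cluster_id %in% cs$excluded_cluster_ids)
  expect_equal(gamma_metric(cs),
               sum(cs$clusters$mean_vaf[kept] * cs$clusters$size[kept]))
})

test_that("gamma follows the cluster-sum formula and matches lambda exactly", {
  cs <- structure(list(clusters = data.frame(cluster_id = 1:2, size = c(3L, 5L),
                                             mean_vaf = c(0.2, 0.1)),
                       assignment = setNames(rep(1:2, c(3, 5)), paste0("v", 1:8)),
                       excluded_cluster_ids = integer(),
                       seed = 1L, method_tag = "manual"),
                  class = "cluster_set")
  expect_equal(gamma_metric(cs), 0.2 * 3 + 0.1 * 5)
  cs$excluded_cluster_ids <- 1:2
  expect_equal(gamma_metric(cs), 0)
  # identity: exact member-mean clusters reproduce lambda
  set.seed(31)
  for (rep in 1:10) {
    v <- filter_tip_variants(make_vfs(runif(25, 0.005, 0.5), depth = 5000), 0.01)
    grp <- sample(1:4, nrow(vfs_records(v)), replace = TRUE)
    expect_equal(gamma_metric(clusters_from_assignment(v, grp)),
                 lambda_metric(v, 0.01), tolerance = 1e-12)
  }
})

test_that("pi agrees with direct substitution and the pairwise oracle", {
  # single variant carried by 1 of 2 lineages
  v <- vfs(data.frame(variant_id = "a", mutant_count = 1, nonmutant_count = 1,
                      source = "colony_cells"))
  expect_equal(pi_metric(v, 2), 1.0)
  empty <- vfs(data.frame(variant_id = character(), mutant_count = numeric(),
                          nonmutant_count = numeric(), source = character()))
  expect_equal(pi_metric(empty, 10), 0)
  expect_error(pi_metric(v, 1), ">= 2")
  # random genotype matrices: both package routes equal the brute-force oracle
  set.seed(7)
  for (rep in 1:10) {
    mat <- random_binary_matrix(6, 10)
    expect_equal(pi_from_matrix(mat), oracle_pi(mat), tolerance = 1e-9)
    expect_equal(pi_metric(genotype_matrix_to_vfs(mat), 6), oracle_pi(mat),
                 tolerance = 1e-9)
  }
  # pairwise deletion with missing data still matches the oracle
  mat <- random_binary_matrix(8, 12)
  mat[sample(length(mat), 6)] <- NA
  expect_equal(pi_from_matrix(mat), oracle_pi(mat), tolerance = 1e-9)
})

test_that("Tajima's D and Fay & Wu's H match brute-force oracles", {
  # 4 lineages, 3 singleton sites
  mat <- matrix(0L, 4, 3, dimnames = list(paste0("t", 1:4), paste0("v", 1:3)))
  diag(mat[1:3, ]) <- 1L
  expect_equal(tajimas_d(mat), oracle_tajima(mat), tolerance = 1e-9)
  # every site a singleton: theta_H = S * 2 / (n (n - 1))
  expect_equal(fay_wu_h(mat), oracle_faywu(mat), tolerance = 1e-9)
  th_pi <- 3 * 2 * 1 * 3 / (4 * 3)
  expect_equal(fay_wu_h(mat), th_pi - 3 * 2 / (4 * 3), tolerance = 1e-9)
  # no segregating sites is an error
  zero <- matrix(0L, 4, 3)
  expect_error(tajimas_d(zero), "segregating")
  expect_error(fay_wu_h(zero), "segregating")
  expect_error(tajimas_d(random_binary_matrix(3, 5)), "4 lineages")
})

test_that("Hill numbers follow the entropy formulas and their ordering", {
  two <- clusters_from_assignment(make_vfs(c(0.2, 0.2), source = "bulk_reads",
                                           depth = 100), 1:2)
  expect_equal(hill_numbers(two, 0), 2)
  expect_equal(hill_numbers(two, 1), 2)
  expect_equal(hill_numbers(two, 2), 2)
  one <- clusters_from_assignment(make_vfs(0.3, source = "bulk_reads"), 1)
  expect_equal(hill_numbers(one, 0), 1)
  expect_equal(hill_numbers(one, 1), 1)
  expect_equal(hill_numbers(one, 2), 1)
  skew <- clusters_from_assignment(make_vfs(c(0.8, 0.2), source = "bulk_reads",
                                            depth = 100), 1:2)
  expect_equal(hill_numbers(skew, 1), exp(-0.8 * log(0.8) - 0.2 * log(0.2)),
               tolerance = 1e-9)
  empty <- cluster_vafs(vfs(data.frame(variant_id = character(),
                                       mutant_count = numeric(),
                                       nonmutant_count = numeric(),
                                       source = character())), seed = 1)
  expect_error(hill_numbers(empty, 0), "undefined|no non-excluded")
  # ordering q0 >= q1 >= q2 across random cluster sets
  set.seed(13)
  for (rep in 1:15) {
    k <- sample(2:6, 1)
    v <- make_vfs(runif(k, 0.02, 0.5), depth = 5000)
    cs <- clusters_from_assignment(v, seq_len(k))
    h <- vapply(c(0, 1, 2), function(q) hill_numbers(cs, q), numeric(1))
    expect_true(h[1] >= h[2] - 1e-12 && h[2] >= h[3] - 1e-12)
  }
})

test_that("LTT Shannon diversity recovers clade structure at the plateau", {
  # star tree: every post-cut clade is a singleton
  star <- ape::read.tree(text = "(t1:10,(t2:10,(t3:10,t4:10):0):0);")
  expect_equal(shannon_ltt(star), log(4), tolerance = 1e-9)
  # stem tree: a single clade holds every tip
  stem <- ape::read.tree(text = "(t1:4,(t2:3,t3:3):1):5;")
  expect_equal(shannon_ltt(stem), 0)
  expect_error(shannon_ltt(ape::read.tree(text = "(t1:1);")), "2 tips")
  # simulated individual: matches the oracle from known clade memberships
  ind <- simulate_individual(55, small_params(), seed = 99)
  ev <- ind$ch_events
  n <- ind$tree$n_lineages
  sizes <- c(rep(1, n - sum(ev$size)), ev$size)
  expect_equal(shannon_ltt(ind$tree), -sum(sizes / n * log(sizes / n)),
               tolerance = 1e-9)
})

test_that("largest VAF reports the maximum retained frequency", {
  v <- make_vfs(c(0.02, 0.31, 0.11), source = "bulk_reads")
  expect_equal(largest_vaf(v), 0.31)
  expect_equal(largest_vaf(make_vfs(0.04, source = "bulk_reads")), 0.04)
  expect_error(largest_vaf(make_vfs(c(0.005, 0.004)), threshold = 0.01), "empty")
})

test_that("metric correlations report OLS R-squared against lambda", {
  set.seed(21)
  lam <- runif(50, 0.5, 30)
  reports <- data.frame(sample_id = paste0("s", 1:50), age = 1:50,
                        lambda = lam,
                        linear = 2 * lam + 1,
                        permuted = sample(lam),
                        constant = 3)
  tab <- metric_correlations(reports)
  expect_equal(tab$r_squared[tab$metric == "linear"], 1.0, tolerance = 1e-12)
  expect_lt(tab$r_squared[tab$metric == "permuted"], 0.1)
  expect_true(is.na(tab$r_squared[tab$metric == "constant"]))
  expect_error(metric_correlations(reports[1:2, ]), "3 individuals")
})

test_that("metric_report assembles all statistics for a simulated individual", {
  ind <- simulate_individual(50, small_params(), seed = 17)
  rep1 <- metric_report(ind$vfs, matrix = as.matrix(ind$matrix),
                        tree = ind$tree, seed = 3)
  expect_equal(rep1$lambda, ind$true_decay, tolerance = 1e-9)
  expect_false(anyNA(rep1[c("pi", "tajimas_d", "fay_wu_h", "shannon_ltt")]))
  expect_true(rep1$hill_q0 >= rep1$hill_q1 && rep1$hill_q1 >= rep1$hill_q2)
})
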