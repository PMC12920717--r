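test_that("VAF conversions follow the cell- and read-count rules", {
  expect_equal(vaf_from_cell_counts(100, 200), 1 / 6)
  expect_equal(vaf_from_cell_counts(0, 250), 0)
  expect_equal(vaf_from_cell_counts(300, 0), 0.5)
  expect_equal(vaf_from_read_counts(15, 85), 0.15)
  expect_equal(vaf_from_read_counts(0, 30), 0)
  expect_equal(vaf_from_read_counts(30, 0), 1)
  expect_error(vaf_from_cell_counts(0, 0), "zero total")
  expect_error(vaf_from_read_counts(0, 0), "zero total")
  # bounds hold across random inputs
  m <- sample(0:50, 100, replace = TRUE); d <- sample(1:50, 100, replace = TRUE)
  expect_true(all(vaf_from_cell_counts(m, d) <= 0.5))
  expect_true(all(vaf_from_read_counts(m, d) <= 1))
})

test_that("depth rescaling uses the target-depth divisor and preserves VAF", {
  got <- rescale_counts_to_depth(100, 300, 30)
  expect_equal(got$scaled_mutant, 10)
  expect_equal(got$scaled_nonmutant, 20)
  expect_equal(rescale_counts_to_depth(0, 300, 30)$scaled_nonmutant, 30)
  ident <- rescale_counts_to_depth(30, 30, 30)
  expect_equal(ident$scaled_mutant, 30)
  expect_equal(ident$scaled_nonmutant, 0)
  expect_error(rescale_counts_to_depth(5, 20, 30), "upscaling")
  expect_error(rescale_counts_to_depth(40, 30, 30), "exceed")
  # real-valued output preserves the VAF exactly
  tot <- sample(30:5000, 50)
  mut <- vapply(tot, function(t) sample(0:t, 1), numeric(1))
  sc <- rescale_counts_to_depth(mut, tot, 30)
  expect_equal(sc$scaled_mutant / 30, mut / tot, tolerance = 1e-12)
  expect_true(all(rescale_counts_to_depth(25, 299, 30, integerize = TRUE)$scaled_mutant %% 1 == 0))
})

test_that("tip-variant filter is inclusive, idempotent and composable", {
  v <- make_vfs(c(0.005, 0.010, 0.20))
  f <- filter_tip_variants(v, 0.01)
  expect_equal(vfs_records(f)$vaf, c(0.010, 0.20))
  expect_equal(f$vaf_threshold_applied, 0.01)
  expect_identical(vfs_records(filter_tip_variants(f, 0.01)),
                   vfs_records(f))
  # filtering at t1 then t2 >= t1 equals filtering at t2 directly
  v2 <- make_vfs(seq(0.002, 0.40, length.out = 40))
  expect_identical(
    vfs_records(filter_tip_variants(filter_tip_variants(v2, 0.01), 0.05)),
    vfs_records(filter_tip_variants(v2, 0.05)))
  empty <- filter_tip_variants(make_vfs(c(0.004, 0.005)), 0.01)
  expect_equal(nrow(vfs_records(empty)), 0)
  expect_equal(empty$vaf_threshold_applied, 0.01)
})

test_that("cohort germline filter removes known and recurrent variants", {
  target <- make_vfs(c(0.1, 0.2, 0.3, 0.4), sample_id = "me")
  tr <- vfs_records(target)
  other <- function(ids, nm) {
    vfs(data.frame(variant_id = ids, mutant_count = 10, nonmutant_count = 90,
                   source = "colony_cells"), sample_id = nm)
  }
  cohort <- list(other(c("v1", "v9"), "a"), other(c("v1", "v2"), "b"),
                 other("v2", "c"), other("v8", "d"), other("v7", "e"))
  out <- cohort_germline_filter(target, cohort, known_germline_sites = "v3")
  expect_setequal(vfs_records(out)$variant_id, "v4")
  removed <- attr(out, "removed")
  expect_equal(removed$reason[removed$variant_id == "v3"], "known_germline")
  expect_equal(removed$reason[removed$variant_id == "v1"], "cohort_recurrent")
  # a stricter (smaller) recurrence cutoff removes a superset
  loose <- vfs_records(cohort_germline_filter(target, cohort, min_other_samples = 3))
  strict <- vfs_records(cohort_germline_filter(target, cohort, min_other_samples = 1))
  expect_true(all(strict$variant_id %in% loose$variant_id))
  # the target's own sample never counts toward recurrence
  self_in <- c(cohort, list(make_vfs(c(0.1, 0.2, 0.3, 0.4), sample_id = "me")))
  expect_identical(
    vfs_records(cohort_germline_filter(target, self_in))$variant_id,
    vfs_records(cohort_germline_filter(target, cohort))$variant_id)
})

test_that("tabular VFS round-trip is lossless", {
  v <- make_vfs(c(0.01, 0.15, 0.32), sample_id = "rt", age = 41.5)
  path <- temp_path("roundtrip.tsv")
  write_vfs(v, path)
  back <- read_vfs(path)
  expect_equal(vfs_records(back), vfs_records(v), tolerance = 1e-12)
  expect_equal(back$sample_id, "rt")
  expect_equal(back$age, 41.5)
})

test_that("malformed tabular rows are rejected with their line number", {
  path <- temp_path("bad.tsv")
  writeLines(c("sample_id\tvariant_id\tref_count\talt_count\tvaf\tsource",
               "s\tv1\t90\t10\t0.1\tbulk_reads",
               "s\tv2\t90\t10"), path)
  expect_error(read_vfs(path), "line 3")
  writeLines(c("sample_id\tvariant_id\tref_count\talt_count\tvaf\tsource",
               "s\tv1\tninety\t10\t0.1\tbulk_reads"), path)
  expect_error(read_vfs(path), "non-numeric")
  # stored vaf inconsistent with counts
  writeLines(c("sample_id\tvariant_id\tref_count\talt_count\tvaf\tsource",
               "s\tv1\t90\t10\t0.5\tbulk_reads"), path)
  expect_error(read_vfs(path), "disagrees")
})

test_that("VCF input yields read-backed VAFs and clear errors", {
  path <- temp_path("ok.vcf")
  write_test_vcf(path)
  v <- read_vfs(path, format = "vcf")
  rec <- vfs_records(v)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$vaf[rec$variant_id == "var1"], 0.15)
  expect_equal(rec$mutant_count[rec$variant_id == "var2"], 40)
  expect_true(all(rec$source == "bulk_reads"))
  expect_equal(rec$pos[rec$variant_id == "var3"], 75)

  bad <- temp_path("noad.vcf")
  write_test_vcf(bad, drop_ad = TRUE)
  expect_error(read_vfs(bad, format = "vcf"), "var1")

  multi <- temp_path("multi.vcf")
  write_test_vcf(multi, multiallelic = TRUE)
  expect_error(read_vfs(multi, format = "vcf"), "var2")
})

test_that("genotype matrices convert via the half cell-fraction rule", {
  mat <- matrix(0L, nrow = 200, ncol = 2,
                dimnames = list(NULL, c("rare", "shared")))
  mat[1, "rare"] <- 1L
  mat[1:80, "shared"] <- 1L
  v <- genotype_matrix_to_vfs(mat)
  rec <- vfs_records(v)
  expect_equal(rec$vaf[rec$variant_id == "rare"], 0.0025)
  expect_equal(rec$vaf[rec$variant_id == "shared"], 0.5 * 80 / 200)
  # NA cells drop out of both counts
  mat[2, "rare"] <- NA
  v2 <- genotype_matrix_to_vfs(mat)
  rec2 <- vfs_records(v2)
  expect_equal(rec2$mutant_count[rec2$variant_id == "rare"] +
                 rec2$nonmutant_count[rec2$variant_id == "rare"], 199)
  # matrix TSV round trip
  path <- temp_path("geno.tsv")
  rownames(mat) <- paste0("t", 1:200)
  write_genotype_matrix(mat, path)
  expect_equal(read_genotype_matrix(path), mat)
})

test_that("vfs construction enforces its invariants", {
  expect_error(vfs(data.frame(variant_id = c("a", "a"), mutant_count = 1,
                              nonmutant_count = 9, source = "bulk_reads")),
               "unique")
  expect_error(vfs(data.frame(variant_id = "a", mutant_count = 0,
                              nonmutant_count = 0, source = "bulk_reads")),
               "zero total")
  expect_error(vfs(data.frame(variant_id = "a", mutant_count = 1,
                              nonmutant_count = 9, source = "whole_genome")),
               "source")
})
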