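# Independent brute-force oracles and fixture builders for the test suite.
# Oracles are deliberately written from first principles (pairwise loops,
# explicit histograms) so they share no code path with the package.

# mean pairwise difference count, summed over sites, pairwise deletion
oracle_pi <- function(mat) {
  n <- nrow(mat)
  total <- 0
  for (s in seq_len(ncol(mat))) {
    col <- mat[, s]
    diffs <- 0; pairs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (is.na(col[i]) || is.na(col[j])) next
      pairs <- pairs + 1
      if (col[i] != col[j]) diffs <- diffs + 1
    }
    if (pairs > 0) total <- total + diffs / pairs
  }
  total
}

# Tajima's D from explicit pairwise diversity and Watterson's estimator
oracle_tajima <- function(mat) {
  n <- nrow(mat)
  th_pi <- oracle_pi(mat)
  derived <- colSums(mat == 1)
  S <- sum(derived > 0 & derived < n)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (th_pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Fay & Wu's H via the unfolded site-frequency histogram
oracle_faywu <- function(mat) {
  n <- nrow(mat)
  derived <- colSums(mat == 1)
  sfs <- tabulate(derived[derived > 0 & derived < n], nbins = n - 1)
  i <- seq_len(n - 1)
  th_pi <- sum(2 * sfs * i * (n - i)) / (n * (n - 1))
  th_h <- sum(2 * sfs * i^2) / (n * (n - 1))
  th_pi - th_h
}

# random binary genotype matrix with at least one segregating site
random_binary_matrix <- function(n, s, p = 0.3) {
  repeat {
    mat <- matrix(rbinom(n * s, 1, p), nrow = n,
                  dimnames = list(paste0("t", seq_len(n)),
                                  paste0("v", seq_len(s))))
    derived <- colSums(mat)
    if (any(derived > 0 & derived < n)) return(mat)
  }
}

make_vfs <- function(vafs, source = "colony_cells", depth = 1000,
                     sample_id = "s", age = NA_real_) {
  if (source == "colony_cells") {
    mut <- round(2 * vafs * depth)
    nonmut <- depth - mut
  } else {
    mut <- round(vafs * depth)
    nonmut <- depth - mut
  }
  vfs(data.frame(variant_id = paste0("v", seq_along(vafs)),
                 mutant_count = mut, nonmutant_count = nonmut,
                 source = source), sample_id = sample_id, age = age)
}

# small, fast simulator settings that keep tip variants below the threshold
small_params <- function(...) {
  sim_params(n_lineages = 60L, ch_rate = 2e-4, ...)
}

write_test_vcf <- function(path, drop_ad = FALSE, multiallelic = FALSE) {
  ad <- if (drop_ad) c("GT", "0/1") else c("GT:AD:DP", "0/1:85,15:100")
  alt2 <- if (multiallelic) "A,G" else "A"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    sprintf("chr1\t100\tvar1\tC\tT\t.\tPASS\t.\t%s\t%s", ad[1], ad[2]),
    sprintf("chr1\t250\tvar2\tG\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:60,40:100", alt2),
    "chr2\t75\tvar3\tT\tC\t.\tPASS\t.\tGT:AD:DP\t0/1:97,3:100")
  writeLines(lines, path)
  path
}

write_test_bed <- function(path) {
  # 0-based half-open: covers chr1:101-200 and chr2:51-80 in 1-based terms
  writeLines(c("chr1\t100\t200", "chr2\t50\t80"), path)
  path
}

# scratch file path in the session tempdir (cleaned up with the session)
temp_path <- function(name) file.path(tempdir(), name)
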