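#' Target sequencing-depth profile
#'
#' Bundles the parameters of a stochastic read-depth resampling: the mean
#' depth of the emulated design, the root seed, and the tip-variant
#' threshold to re-apply after resampling.
#'
#' @param mean_depth mean read depth of the target design (> 0).
#' @param seed root seed; every variant draws from its own substream derived
#'   from `(seed, variant_id)`, so subsetting a spectrum never shifts the
#'   draws of the remaining variants.
#' @param reapply_threshold VAF threshold re-applied after resampling
#'   (default 0.01).
#' @return An object of class `"depth_profile"`.
#' @export
depth_profile <- function(mean_depth, seed = 1L, reapply_threshold = 0.01) {
  if (!is.numeric(mean_depth) || length(mean_depth) != 1 || mean_depth <= 0)
    stop_input("mean_depth must be a single positive number")
  structure(list(mean_depth = mean_depth, seed = as.integer(seed),
                 reapply_threshold = reapply_threshold),
            class = "depth_profile")
}

#' Resample a VFS to a target read depth
#'
#' Emulates re-sequencing the same variants under a finite-coverage design:
#' each variant draws a depth r ~ Poisson(`mean_depth`) and a mutant read
#' count m ~ Binomial(r, VAF); the observed VAF becomes m / r.  Variants
#' drawing r = 0 are unobserved and dropped; variants observed with m = 0
#' (VAF 0) are retained up to the threshold re-application, which then
#' removes them together with any draw below the threshold.  Output records
#' carry `source = "bulk_reads"`.  Deterministic given the profile's seed.
#'
#' Note that resampling preserves each variant's VAF in expectation
#' (E\[m/r\] equals the input VAF for r > 0); what changes with depth is the
#' dispersion of the observed VAFs and which variants clear the re-applied
#' threshold.
#'
#' @param x a [vfs] object; typically tip-filtered first, since resampling
#'   an unfiltered spectrum floods the threshold with noise-inflated tip
#'   variants at low depth.
#' @param profile a [depth_profile()].
#' @return Resampled [vfs]; attribute `unobserved` lists the variant ids
#'   dropped with r = 0.
#' @export
simulate_depth <- function(x, profile) {
  stopifnot(inherits(x, "vfs"), inherits(profile, "depth_profile"))
  rec <- x$records
  out <- x
  if (!nrow(rec)) {
    attr(out, "unobserved") <- character()
    return(filter_tip_variants(out, profile$reapply_threshold))
  }
  seeds <- substream_seed(profile$seed, rec$variant_id)
  draws <- vapply(seq_len(nrow(rec)), function(k) {
    set.seed(seeds[k])
    r <- rpois(1, profile$mean_depth)
    m <- if (r > 0) rbinom(1, r, rec$vaf[k]) else 0L
    c(r, m)
  }, numeric(2))
  r <- draws[1, ]; m <- draws[2, ]
  observed <- r > 0
  rec2 <- rec[observed, , drop = FALSE]
  rec2$mutant_count <- m[observed]
  rec2$nonmutant_count <- r[observed] - m[observed]
  rec2$source <- "bulk_reads"
  rec2$vaf <- rec2$mutant_count / (rec2$mutant_count + rec2$nonmutant_count)
  out$records <- rec2
  out$vaf_threshold_applied <- NA_real_
  out <- filter_tip_variants(out, profile$reapply_threshold)
  attr(out, "unobserved") <- rec$variant_id[!observed]
  out
}

#' Restrict a VFS to a panel
#'
#' Keeps the records whose locus falls inside a set of genomic regions
#' (BED convention: 0-based half-open intervals, converted on import) or
#' whose gene annotation is in a gene list, emulating a targeted design.
#'
#' @param x a [vfs] object.  Region panels require `chrom` and `pos`
#'   (1-based) columns on the records; gene panels require a `gene` column.
#' @param panel a `GenomicRanges::GRanges` of regions, a path to a BED file
#'   (read via [read_panel_bed()]), or a character vector of gene names.
#' @return The restricted [vfs].
#' @export
restrict_panel <- function(x, panel) {
  stopifnot(inherits(x, "vfs"))
  rec <- x$records
  out <- x
  if (is.character(panel) && length(panel) == 1 && file.exists(panel))
    panel <- read_panel_bed(panel)
  if (is.character(panel)) {
    if (is.null(rec$gene)) {
      stop_input("records lack gene annotations; cannot apply a gene panel (",
                 paste(head(rec$variant_id, 5), collapse = ", "),
                 if (nrow(rec) > 5) ", ..." else "", ")")
    }
    keep <- rec$gene %in% panel
  } else if (methods::is(panel, "GRanges")) {
    if (!length(panel)) {
      keep <- rep(FALSE, nrow(rec))
    } else {
      missing_ann <- is.null(rec$chrom) || is.null(rec$pos)
      if (!missing_ann) missing_ann_ids <- rec$variant_id[is.na(rec$chrom) | is.na(rec$pos)]
      if (missing_ann || length(missing_ann_ids))
        stop_input("records lack chrom/pos annotations; cannot apply a region ",
                   "panel (", if (missing_ann) "all records"
                   else paste(head(missing_ann_ids, 5), collapse = ", "), ")")
      loci <- GenomicRanges::GRanges(rec$chrom,
                                     IRanges::IRanges(rec$pos, rec$pos))
      keep <- IRanges::overlapsAny(loci, panel)
    }
  } else {
    stop_input("panel must be a GRanges, a BED path, or a gene-name vector")
  }
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Read a BED panel
#'
#' Imports BED regions (0-based half-open) into a 1-based `GRanges` via
#' rtracklayer.
#' @param path BED file.
#' @return `GRanges` of panel regions.
#' @export
read_panel_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read a gene-list panel (one gene name per line, `#` comments allowed)
#' @param path text file.
#' @return character vector of gene names.
#' @export
read_panel_genes <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !grepl("^#", lines)]
}
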