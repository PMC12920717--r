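#' Construct a variant frequency spectrum (VFS)
#'
#' A VFS collects one individual's somatic variants together with the counts
#' supporting them.  Counts are either sequencing reads (`source =
#' "bulk_reads"`: `mutant_count` alt-supporting reads, `nonmutant_count`
#' reference reads) or colony-sequencing cell counts (`source =
#' "colony_cells"`: mutant and non-mutant HSC lineages).  The variant allele
#' frequency (VAF) is the raw read fraction for bulk data and half the mutant
#' cell fraction for colony data, because a heterozygous somatic variant
#' contributes one of two alleles in every carrier cell; colony-derived VAFs
#' are therefore bounded by 0.5.
#'
#' @param records data.frame with columns `variant_id`, `mutant_count`,
#'   `nonmutant_count`, `source` (one of `"bulk_reads"`, `"colony_cells"`),
#'   and optionally `vaf` (recomputed and checked when present), `chrom`,
#'   `pos`, `gene`.
#' @param sample_id sample identifier.
#' @param age chronological age in years, or `NA` when unknown.
#' @param vaf_threshold_applied the tip-variant VAF threshold already applied
#'   to these records, or `NA` when the spectrum is unfiltered.
#' @return An object of class `"vfs"`.
#' @seealso [filter_tip_variants()], [lambda_metric()], [read_vfs()]
#' @examples
#' v <- vfs(data.frame(variant_id = c("a", "b"),
#'                     mutant_count = c(30, 5), nonmutant_count = c(270, 95),
#'                     source = "colony_cells"))
#' vfs_records(v)$vaf
#' @export
vfs <- function(records, sample_id = "sample", age = NA_real_,
                vaf_threshold_applied = NA_real_) {
  required <- c("variant_id", "mutant_count", "nonmutant_count", "source")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop_input("records is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  records$variant_id <- as.character(records$variant_id)
  if (anyDuplicated(records$variant_id))
    stop_input("variant_id must be unique within a VFS; duplicated: ",
               paste(unique(records$variant_id[duplicated(records$variant_id)]),
                     collapse = ", "))
  if (!all(records$source %in% c("bulk_reads", "colony_cells")))
    stop_input("source must be 'bulk_reads' or 'colony_cells'")
  if (!is_count(records$mutant_count) || !is_count(records$nonmutant_count))
    stop_input("counts must be non-negative finite numbers")
  total <- records$mutant_count + records$nonmutant_count
  if (any(total <= 0))
    stop_input("zero total count for variant(s): ",
               paste(records$variant_id[total <= 0], collapse = ", "))
  vaf <- ifelse(records$source == "colony_cells",
                0.5 * records$mutant_count / total,
                records$mutant_count / total)
  if (!is.null(records$vaf)) {
    bad <- abs(records$vaf - vaf) > 1e-9
    if (any(bad))
      stop_input("stored vaf disagrees with counts for variant(s): ",
                 paste(records$variant_id[bad], collapse = ", "))
  }
  records$vaf <- vaf
  if (!is.na(vaf_threshold_applied) && any(vaf < vaf_threshold_applied))
    stop_input("records contain VAFs below the declared applied threshold")
  canonical <- c("variant_id", "mutant_count", "nonmutant_count", "vaf", "source")
  records <- records[, c(canonical, setdiff(names(records), canonical)),
                     drop = FALSE]
  rownames(records) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 age = as.numeric(age),
                 records = records,
                 vaf_threshold_applied = as.numeric(vaf_threshold_applied)),
            class = "vfs")
}

#' @method print vfs
#' @export
print.vfs <- function(x, ...) {
  cat(sprintf("VFS for sample '%s'%s: %d variant(s)%s\n",
              x$sample_id,
              if (is.na(x$age)) "" else sprintf(" (age %.4g y)", x$age),
              nrow(x$records),
              if (is.na(x$vaf_threshold_applied)) " (unfiltered)"
              else sprintf(", VAF >= %g", x$vaf_threshold_applied)))
  invisible(x)
}

#' Access the record table of a VFS
#' @param x a [vfs] object.
#' @return The records data.frame.
#' @export
vfs_records <- function(x) {
  stopifnot(inherits(x, "vfs"))
  x$records
}

#' @method as.data.frame vfs
#' @export
as.data.frame.vfs <- function(x, ...) {
  out <- x$records
  out$sample_id <- x$sample_id
  out[, c("sample_id", setdiff(names(out), "sample_id"))]
}

#' VAF from colony cell counts
#'
#' Converts mutant/non-mutant cell counts from colony sequencing into a
#' variant allele frequency.  Every mutant cell is heterozygous for a somatic
#' variant, so the allele fraction is half the cell fraction:
#' VAF = mutant / (2 * (mutant + nonmutant)), bounded by 0.5.
#'
#' @param mutant_cells,nonmutant_cells non-negative cell counts (vectorised).
#' @return VAF values in \[0, 0.5\].
#' @examples
#' vaf_from_cell_counts(100, 200)  # 1/6
#' @export
vaf_from_cell_counts <- function(mutant_cells, nonmutant_cells) {
  if (!is_count(mutant_cells) || !is_count(nonmutant_cells))
    stop_input("cell counts must be non-negative finite numbers")
  total <- mutant_cells + nonmutant_cells
  if (any(total <= 0))
    stop_input("VAF undefined: zero total cell count")
  0.5 * mutant_cells / total
}

#' VAF from read counts
#'
#' Bulk sequencing reads sample alleles directly, so the VAF is the raw
#' alt-read fraction (no 1/2 factor).
#'
#' @param alt_reads,ref_reads non-negative read counts (vectorised).
#' @return VAF values in \[0, 1\].
#' @export
vaf_from_read_counts <- function(alt_reads, ref_reads) {
  if (!is_count(alt_reads) || !is_count(ref_reads))
    stop_input("read counts must be non-negative finite numbers")
  total <- alt_reads + ref_reads
  if (any(total <= 0))
    stop_input("VAF undefined: zero total read count")
  alt_reads / total
}

#' Deterministically rescale counts to a target depth
#'
#' Scales an observed (mutant, total) count pair down to a nominal total
#' depth: the mutant count is divided by `total_count / target_total` and the
#' non-mutant count is the remainder to `target_total`.  With real-valued
#' output the VAF is preserved exactly; `integerize = TRUE` rounds the scaled
#' mutant count half-away-from-zero for consumers that need integer counts.
#'
#' @param mutant_count,total_count observed counts, `mutant_count <=
#'   total_count` (vectorised).
#' @param target_total nominal depth to scale down to (default 30).
#' @param integerize round the scaled mutant count to an integer.
#' @return data.frame with columns `scaled_mutant`, `scaled_nonmutant`.
#' @examples
#' rescale_counts_to_depth(100, 300)  # divisor 10 -> (10, 20)
#' @export
rescale_counts_to_depth <- function(mutant_count, total_count,
                                    target_total = 30, integerize = FALSE) {
  if (!is_count(mutant_count) || !is_count(total_count))
    stop_input("counts must be non-negative finite numbers")
  if (target_total <= 0) stop_input("target_total must be positive")
  if (any(total_count < target_total))
    stop_input("total_count below target_total: upscaling is undefined")
  if (any(mutant_count > total_count))
    stop_input("mutant_count cannot exceed total_count")
  scaled <- mutant_count / (total_count / target_total)
  if (integerize) scaled <- floor(scaled + 0.5)
  data.frame(scaled_mutant = scaled, scaled_nonmutant = target_total - scaled)
}

#' Remove tip variants from a VFS
#'
#' Somatic variants private to a single sampled HSC lineage ("tip variants")
#' have VAFs at or below roughly 1/(2 * lineages sampled) and carry no signal
#' of clonal expansion.  This filter keeps records with `vaf >= threshold`
#' (inclusive) and records the threshold on the returned VFS.  The operation
#' is idempotent and order-preserving.
#'
#' @param x a [vfs] object.
#' @param threshold VAF threshold in (0, 1); default 0.01.
#' @return The filtered [vfs] with `vaf_threshold_applied` set.
#' @export
filter_tip_variants <- function(x, threshold = 0.01) {
  stopifnot(inherits(x, "vfs"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop_input("threshold must be a single value in (0, 1)")
  keep <- x$records$vaf >= threshold
  out <- x
  out$records <- x$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$vaf_threshold_applied <- threshold
  out
}

#' Filter probable germline variants against a cohort
#'
#' Removes records whose `variant_id` appears in a known germline site list,
#' and records seen in at least `min_other_samples` *other* members of the
#' cohort (a recurrence pattern expected for shared germline variation, not
#' for private somatic mutations).  The removed ids and the reason for each
#' removal are attached as the `"removed"` attribute of the result.
#'
#' @param target the [vfs] to filter.
#' @param cohort list of [vfs] objects; any member sharing `target`'s
#'   `sample_id` is ignored in the recurrence count.
#' @param known_germline_sites character vector of variant ids known to be
#'   germline (e.g. population-database sites).
#' @param min_other_samples recurrence count triggering removal (default 2).
#' @return Filtered [vfs] with attribute `removed` (data.frame of
#'   `variant_id`, `reason`).
#' @export
cohort_germline_filter <- function(target, cohort,
                                   known_germline_sites = character(),
                                   min_other_samples = 2L) {
  stopifnot(inherits(target, "vfs"))
  others <- Filter(function(v) {
    stopifnot(inherits(v, "vfs"))
    !identical(v$sample_id, target$sample_id)
  }, cohort)
  seen <- table(unlist(lapply(others, function(v) unique(v$records$variant_id))))
  ids <- target$records$variant_id
  n_other <- as.integer(seen[ids])
  n_other[is.na(n_other)] <- 0L
  known <- ids %in% known_germline_sites
  recurrent <- n_other >= min_other_samples
  drop <- known | recurrent
  removed <- data.frame(
    variant_id = ids[drop],
    reason = ifelse(known[drop], "known_germline", "cohort_recurrent"))
  out <- target
  out$records <- target$records[!drop, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "removed") <- removed
  out
}
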