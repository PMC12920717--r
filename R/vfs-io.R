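#' Read a VFS from disk
#'
#' Two formats are supported.  The tabular format is a UTF-8 TSV with header
#' `sample_id  variant_id  ref_count  alt_count  vaf  source` (optional
#' additional columns `chrom`, `pos`, `gene` are preserved); `ref_count` maps
#' to the non-mutant count and `alt_count` to the mutant count, and the
#' stored `vaf` is recomputed on read and checked at 1e-9.  Comment lines
#' start with `#`; a line of the form `# age=40` carries the individual's
#' chronological age.  The VCF format consumes biallelic SNV records with a
#' standard `AD` (allele depth) genotype field, 1-based coordinates per the
#' VCF standard.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample for VCF input with several genotype columns, which sample to
#'   take allele depths from (default: the first).
#' @return A [vfs] object.
#' @export
read_vfs <- function(path, format = c("tsv", "vcf"), sample = NULL) {
  format <- match.arg(format)
  if (format == "tsv") read_vfs_tsv(path) else read_vfs_vcf(path, sample)
}

read_vfs_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop_input("empty VFS file: ", path)
  comment <- grepl("^#", lines)
  age <- NA_real_
  m <- regmatches(lines[comment], regexec("age\\s*=\\s*([0-9.]+)", lines[comment]))
  m <- Filter(function(x) length(x) == 2, m)
  if (length(m)) age <- as.numeric(m[[1]][2])
  body <- lines[!comment]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  required <- c("sample_id", "variant_id", "ref_count", "alt_count", "vaf", "source")
  if (!all(required %in% header))
    stop_input("VFS TSV header must contain: ", paste(required, collapse = ", "))
  rows <- body[-1]
  if (!length(rows))
    return(vfs(data.frame(variant_id = character(), mutant_count = numeric(),
                          nonmutant_count = numeric(), source = character()),
               sample_id = "sample", age = age))
  fields <- strsplit(rows, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    # line number in the original file, counting comments and the header
    stop_input(sprintf("malformed row at line %d of %s: expected %d fields, got %d",
                       which(!comment)[bad + 1], path, length(header), nf[bad]))
  }
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- header
  for (col in c("ref_count", "alt_count", "vaf")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      stop_input(sprintf("malformed row at line %d of %s: non-numeric %s",
                         which(!comment)[bad + 1], path, col))
    }
    tab[[col]] <- val
  }
  if ("pos" %in% names(tab)) tab$pos <- as.numeric(tab$pos)
  rec <- data.frame(variant_id = tab$variant_id,
                    mutant_count = tab$alt_count,
                    nonmutant_count = tab$ref_count,
                    vaf = tab$vaf,
                    source = tab$source, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "gene")) if (col %in% names(tab)) rec[[col]] <- tab[[col]]
  vfs(rec, sample_id = tab$sample_id[1], age = age)
}

read_vfs_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) stop_input("no records in VCF: ", path)
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               paste0(fix$CHROM, ":", fix$POS, "_", fix$REF, ">", fix$ALT),
               fix$ID)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop_input("multi-allelic record(s) not supported (split upstream): ",
               paste(id[multi], collapse = ", "))
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (any(!snv))
    stop_input("non-SNV record(s) not supported: ", paste(id[!snv], collapse = ", "))
  gt_format <- v@gt[, 1]
  if (!all(grepl("(^|:)AD(:|$)", gt_format)))
    stop_input("record(s) lacking an AD allele-depth field: ",
               paste(id[!grepl("(^|:)AD(:|$)", gt_format)], collapse = ", "))
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  sample <- sample %||% samples[1]
  if (!sample %in% samples) stop_input("no sample '", sample, "' in VCF")
  ad <- ad[, sample]
  bad <- is.na(ad) | !grepl("^[0-9]+,[0-9]+$", ad)
  if (any(bad))
    stop_input("missing or malformed AD value for record(s): ",
               paste(id[bad], collapse = ", "))
  parts <- do.call(rbind, strsplit(ad, ",", fixed = TRUE))
  ref_d <- as.numeric(parts[, 1]); alt_d <- as.numeric(parts[, 2])
  zero <- ref_d + alt_d == 0
  if (any(zero))
    stop_input("zero allele depth for record(s): ", paste(id[zero], collapse = ", "))
  vfs(data.frame(variant_id = id, mutant_count = alt_d, nonmutant_count = ref_d,
                 source = "bulk_reads", chrom = fix$CHROM, pos = as.numeric(fix$POS),
                 stringsAsFactors = FALSE),
      sample_id = sample)
}

#' Write a VFS to the tabular format
#'
#' Writes the TSV layout documented in [read_vfs()]; the write/read
#' round-trip is lossless for the record table and the age metadata.
#'
#' @param x a [vfs] object.
#' @param path output file.
#' @export
write_vfs <- function(x, path) {
  stopifnot(inherits(x, "vfs"))
  rec <- x$records
  out <- data.frame(sample_id = rep(x$sample_id, nrow(rec)),
                    variant_id = rec$variant_id,
                    ref_count = rec$nonmutant_count,
                    alt_count = rec$mutant_count,
                    vaf = rec$vaf,
                    source = rec$source, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "gene")) if (col %in% names(rec)) out[[col]] <- rec[[col]]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.na(x$age)) writeLines(sprintf("# age=%.10g", x$age), con)
  write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a VFS from a binary genotype matrix
#'
#' Colony sequencing yields one genotype per sampled HSC lineage.  Given a
#' lineages-by-variants matrix of 0/1 carrier states (NA allowed for missing
#' calls), each variant's VAF is half its carrier cell fraction, via
#' [vaf_from_cell_counts()] applied column-wise.
#'
#' @param matrix binary matrix (base matrix or a `Matrix` sparse matrix),
#'   rows = lineages, columns = variants; column names are the variant ids.
#' @param sample_id,age metadata for the resulting [vfs].
#' @return A [vfs] with `source = "colony_cells"`.
#' @export
genotype_matrix_to_vfs <- function(matrix, sample_id = "sample", age = NA_real_) {
  if (is.null(colnames(matrix)))
    colnames(matrix) <- paste0("v", seq_len(ncol(matrix)))
  if (inherits(matrix, "Matrix")) {
    mut <- Matrix::colSums(matrix != 0)
    nonmut <- nrow(matrix) - mut
  } else {
    vals <- matrix
    if (!all(vals %in% c(0, 1, NA)))
      stop_input("genotype matrix entries must be 0, 1 or NA")
    mut <- colSums(vals == 1, na.rm = TRUE)
    nonmut <- colSums(vals == 0, na.rm = TRUE)
  }
  vfs(data.frame(variant_id = colnames(matrix),
                 mutant_count = as.numeric(mut),
                 nonmutant_count = as.numeric(nonmut),
                 source = "colony_cells", stringsAsFactors = FALSE),
      sample_id = sample_id, age = age)
}

#' Read a genotype matrix from TSV
#'
#' Rows are lineages, columns variants, entries 0/1/NA; first column holds
#' lineage ids.
#' @param path file to read.
#' @return base matrix with dimnames.
#' @export
read_genotype_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1)
  as.matrix(tab)
}

#' @rdname read_genotype_matrix
#' @param x matrix to write.
#' @export
write_genotype_matrix <- function(x, path) {
  df <- data.frame(lineage = rownames(x) %||% paste0("t", seq_len(nrow(x))),
                   as.data.frame(as.matrix(x), check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
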