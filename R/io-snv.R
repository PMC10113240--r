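#' Validate a somatic SNV table
#'
#' An SNV table is a data.frame with one row per somatic single-nucleotide
#' variant and columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `tumor_coverage`, `tumor_alt_reads`, `normal_alt_reads`,
#' `allelic_fraction`, `gene`, `impact`. `impact` uses the standard
#' annotation tiers `HIGH`, `MODERATE`, `LOW`, `MODIFIER`.
#'
#' Invariants checked: `tumor_alt_reads <= tumor_coverage` and
#' `allelic_fraction` consistent with `tumor_alt_reads / tumor_coverage`
#' within rounding. If `allelic_fraction` is absent it is computed from the
#' read counts. Duplicate `(chrom, pos, ref, alt)` keys are collapsed with a
#' warning.
#'
#' @param calls A data.frame of SNV calls.
#' @return The validated (possibly deduplicated) data.frame.
#' @export
validate_snv_table <- function(calls) {
  req <- c("chrom", "pos", "ref", "alt", "tumor_coverage", "tumor_alt_reads",
           "normal_alt_reads", "gene", "impact")
  miss <- setdiff(req, names(calls))
  if (length(miss) > 0)
    stop("SNV table is missing column(s): ", paste(miss, collapse = ", "))
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  calls$chrom <- as.character(calls$chrom)
  calls$ref <- as.character(calls$ref)
  calls$alt <- as.character(calls$alt)
  calls$gene <- as.character(calls$gene)
  calls$impact <- as.character(calls$impact)
  bad <- which(calls$tumor_alt_reads > calls$tumor_coverage)
  if (length(bad) > 0)
    stop("SNV row ", bad[1], ": tumor_alt_reads exceeds tumor_coverage")
  if (!"allelic_fraction" %in% names(calls)) {
    calls$allelic_fraction <- ifelse(calls$tumor_coverage > 0,
                                     calls$tumor_alt_reads / calls$tumor_coverage, 0)
  } else {
    expected <- ifelse(calls$tumor_coverage > 0,
                       calls$tumor_alt_reads / calls$tumor_coverage, 0)
    off <- which(abs(calls$allelic_fraction - expected) > 0.011)
    if (length(off) > 0)
      stop("SNV row ", off[1], ": allelic_fraction inconsistent with ",
           "tumor_alt_reads / tumor_coverage")
  }
  key <- snv_key(calls)
  if (anyDuplicated(key)) {
    warning("removed ", sum(duplicated(key)), " duplicate SNV record(s)")
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  rownames(calls) <- NULL
  calls
}

snv_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Read somatic SNV calls from TSV or VCF
#'
#' The primary dialect is a tab-separated table with the [validate_snv_table()]
#' columns (`allelic_fraction` optional; computed from read counts when
#' absent). VCF v4.x input is supported when the vcfR package is available:
#' the first genotype column is taken as the tumor sample (`FORMAT/AD`
#' required for depths), the second, if present, as the matched normal, and
#' gene/impact annotations are read from `INFO/GENE` and `INFO/IMPACT`.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A validated SNV data.frame (plus a `sample_id` column if the TSV
#'   carries one).
#' @export
read_snvs <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") return(read_snvs_vcf(path))
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  keep_sample <- "sample_id" %in% names(tab)
  if (keep_sample && length(unique(tab$sample_id)) > 1) {
    parts <- lapply(split(tab, tab$sample_id), validate_snv_table)
    out <- do.call(rbind, unname(parts[unique(tab$sample_id)]))
    rownames(out) <- NULL
    return(out)
  }
  validate_snv_table(tab)
}

read_snvs_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package; supply a TSV instead")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)  # single-record VCF returns a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) stop("VCF ", path, " contains no records")
  if (any(nchar(fix$REF) != 1 | nchar(fix$ALT) != 1))
    stop("only single-nucleotide records are supported; split or drop ",
         "indel/multi-allelic records upstream")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad) || ncol(ad) < 1 || anyNA(ad[, 1]))
    stop("VCF record lacks FORMAT/AD depths for the tumor sample")
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  }
  tum <- split_ad(ad[, 1])
  norm_alt <- if (ncol(ad) >= 2) split_ad(ad[, 2])[, 2] else rep(0, n)
  gene <- vcfR::extract.info(v, element = "GENE")
  impact <- vcfR::extract.info(v, element = "IMPACT")
  if (is.null(gene) || is.null(impact) || anyNA(gene) || anyNA(impact))
    stop("VCF records must carry INFO/GENE and INFO/IMPACT annotations")
  validate_snv_table(data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, tumor_coverage = tum[, 1] + tum[, 2],
    tumor_alt_reads = tum[, 2], normal_alt_reads = norm_alt,
    gene = gene, impact = impact, stringsAsFactors = FALSE))
}

#' Write an SNV table to TSV
#'
#' @param calls A validated SNV data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snvs <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
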