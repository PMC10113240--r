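#' Allele-specific copy-number segment profile
#'
#' A `segment_profile` holds one sample's allele-specific copy-number
#' segmentation together with sample metadata. Segments carry the major
#' (`cnA`) and minor (`cnB`) allele copy numbers, with `cnA >= cnB >= 0` by
#' definition. Coordinates are stored internally as 0-based half-open
#' intervals; on-disk SEG-like tables use the 1-based inclusive convention
#' (see [read_segments()]).
#'
#' @param sample_id Sample identifier (scalar character).
#' @param segments A data.frame with columns `chrom`, `start`, `end`, `cnA`,
#'   `cnB`. `start`/`end` are interpreted as 0-based half-open.
#' @param sample_class `"PT"` (parental tumor), `"PDO"` (organoid) or `NA`.
#' @param tumor_class One of `"NMIBC_LG"`, `"NMIBC_HG"`, `"MIBC"` (ordered
#'   from low-grade non-muscle-invasive to muscle-invasive) or `NA`.
#' @param purity Tumor purity in `[0, 1]`, or `NA` if unknown.
#'
#' @return An object of class `segment_profile`.
#' @seealso [read_segments()], [compute_asP()], [compute_gb()]
#' @export
segment_profile <- function(sample_id, segments, sample_class = NA_character_,
                            tumor_class = NA_character_, purity = NA_real_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!is.na(sample_class) && !sample_class %in% c("PT", "PDO"))
    stop("sample_class must be 'PT', 'PDO' or NA, got: ", sample_class)
  if (!is.na(tumor_class) && !tumor_class %in% tumor_class_levels())
    stop("tumor_class must be one of ", paste(tumor_class_levels(), collapse = ", "))
  if (!is.na(purity) && (purity < 0 || purity > 1))
    stop("purity must lie in [0, 1], got: ", purity)
  segments <- validate_segments(segments)
  structure(
    list(sample_id = sample_id, sample_class = sample_class,
         tumor_class = tumor_class, purity = purity, segments = segments),
    class = "segment_profile")
}

#' Ordered tumor-class levels
#'
#' Low-grade non-muscle-invasive, high-grade non-muscle-invasive, and
#' muscle-invasive bladder cancer, in order of increasing aggressiveness.
#' This ordering is what [ordinal_trend()] correlates against.
#'
#' @return Character vector of the three ordered levels.
#' @export
tumor_class_levels <- function() c("NMIBC_LG", "NMIBC_HG", "MIBC")

validate_segments <- function(segments) {
  req <- c("chrom", "start", "end", "cnA", "cnB")
  miss <- setdiff(req, names(segments))
  if (length(miss) > 0)
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  segments <- as.data.frame(segments)[req]
  segments$chrom <- as.character(segments$chrom)
  for (col in c("start", "end", "cnA", "cnB")) {
    v <- segments[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop("segment column '", col, "' must be numeric and complete")
  }
  bad <- which(segments$start >= segments$end)
  if (length(bad) > 0)
    stop("segment row ", bad[1], ": start must be < end")
  bad <- which(segments$cnB < 0)
  if (length(bad) > 0)
    stop("segment row ", bad[1], ": cnB must be >= 0")
  bad <- which(segments$cnA < segments$cnB)
  if (length(bad) > 0)
    stop("segment row ", bad[1], ": cnA < cnB violates the major/minor ",
         "allele convention")
  # non-overlap within chromosome (0-based half-open: touching is fine)
  ord <- order(segments$chrom, segments$start)
  segments <- segments[ord, , drop = FALSE]
  rownames(segments) <- NULL
  by_chrom <- split(seq_len(nrow(segments)), segments$chrom)
  for (idx in by_chrom) {
    if (length(idx) < 2) next
    s <- segments$start[idx]; e <- segments$end[idx]
    if (any(s[-1] < e[-length(e)]))
      stop("overlapping segments on chromosome ", segments$chrom[idx[1]])
  }
  segments
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("segment_profile:", x$sample_id,
      sprintf("(%s, %s, purity %s)\n", x$sample_class, x$tumor_class,
              format(x$purity, digits = 3)))
  cat("  ", nrow(x$segments), "segments on",
      length(unique(x$segments$chrom)), "chromosome(s);",
      sprintf("asP %.3f, GB %.3f\n", compute_asP(x), compute_gb(x)))
  invisible(x)
}

seg_to_disk <- function(segments) {
  segments$start <- segments$start + 1L  # 0-based half-open -> 1-based inclusive
  # fixed notation so canonical files round-trip byte-identically
  segments$start <- format(segments$start, scientific = FALSE, trim = TRUE)
  segments$end <- format(segments$end, scientific = FALSE, trim = TRUE)
  segments
}

seg_from_disk <- function(segments) {
  segments$start <- segments$start - 1L  # 1-based inclusive -> 0-based half-open
  segments
}

#' Read allele-specific copy-number segments (SEG-like TSV)
#'
#' Reads a tab-separated segment table with header columns
#' `sample_id` (optional for single-sample files), `chrom`, `start`, `end`,
#' `cnA`, `cnB`. On disk, coordinates follow the SEG convention: 1-based,
#' inclusive. They are converted to 0-based half-open internally. Rows with
#' `cnA < cnB` are rejected (major/minor allele convention), as are
#' overlapping segments on the same chromosome.
#'
#' @param path Path to the TSV file.
#' @param metadata Optional data.frame with columns `sample_id` and any of
#'   `sample_class`, `tumor_class`, `purity`, attached to each profile.
#'
#' @return A list of [segment_profile()] objects (empty for a header-only
#'   file).
#' @export
read_segments <- function(path, metadata = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = NA, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "cnA", "cnB")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("segment file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("start", "end", "cnA", "cnB")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v) && nrow(tab) > 0) {
      line <- which(is.na(v))[1] + 1L  # +1 for the header line
      stop("malformed value in column '", col, "' at line ", line,
           " of ", path)
    }
    tab[[col]] <- v
  }
  if (nrow(tab) == 0) return(list())
  if (!"sample_id" %in% names(tab)) tab$sample_id <- "sample"
  profiles <- lapply(split(tab, tab$sample_id), function(sub) {
    id <- sub$sample_id[1]
    meta <- list(sample_class = NA_character_, tumor_class = NA_character_,
                 purity = NA_real_)
    if (!is.null(metadata)) {
      row <- metadata[metadata$sample_id == id, , drop = FALSE]
      if (nrow(row) == 1) {
        for (f in names(meta)) if (f %in% names(row)) meta[[f]] <- row[[f]]
      }
    }
    segment_profile(id, seg_from_disk(sub[req]),
                    sample_class = meta$sample_class,
                    tumor_class = meta$tumor_class, purity = meta$purity)
  })
  unname(profiles[unique(tab$sample_id)])
}

#' Write segment profiles to a SEG-like TSV
#'
#' Inverse of [read_segments()]: coordinates are converted back to the
#' 1-based inclusive on-disk convention. `write_segments()` followed by
#' `read_segments()` round-trips exactly for canonical files.
#'
#' @param profiles A list of [segment_profile()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    cbind(sample_id = p$sample_id, seg_to_disk(p$segments))
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
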