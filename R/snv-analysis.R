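#' Quality-filter thresholds for somatic SNVs
#'
#' The four high-quality SNV conditions, all applied inclusively: tumor
#' coverage >= 20 reads, tumor allelic fraction >= 0.08, tumor alternative
#' reads >= 5, and normal alternative reads equal to at most
#' `max_normal_alt` (0: no support in the matched normal).
#'
#' @param min_tumor_coverage Minimum tumor coverage (default 20).
#' @param min_af Minimum tumor allelic fraction (default 0.08).
#' @param min_alt_reads Minimum tumor alternative reads (default 5).
#' @param max_normal_alt Maximum normal alternative reads (default 0).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_tumor_coverage = 20, min_af = 0.08,
                              min_alt_reads = 5, max_normal_alt = 0) {
  vals <- c(min_tumor_coverage, min_af, min_alt_reads, max_normal_alt)
  if (any(vals < 0)) stop("all thresholds must be non-negative")
  structure(list(min_tumor_coverage = min_tumor_coverage, min_af = min_af,
                 min_alt_reads = min_alt_reads,
                 max_normal_alt = max_normal_alt),
            class = "filter_thresholds")
}

#' Select high-quality SNVs
#'
#' Keeps calls meeting all four [filter_thresholds()] conditions. The
#' operation is idempotent and its output is always a subset of its input.
#'
#' @param calls A validated SNV data.frame.
#' @param thresholds A [filter_thresholds()].
#' @return The filtered data.frame.
#' @export
filter_snvs <- function(calls, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  keep <- calls$tumor_coverage >= thresholds$min_tumor_coverage &
    calls$allelic_fraction >= thresholds$min_af &
    calls$tumor_alt_reads >= thresholds$min_alt_reads &
    calls$normal_alt_reads <= thresholds$max_normal_alt
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor mutational burden
#'
#' Number of (already quality-filtered) SNVs per megabase of sequenced
#' territory.
#'
#' @param filtered Filtered SNV data.frame.
#' @param territory_mb Size of the sequenced territory in megabases
#'   (e.g. the exome capture design size).
#' @return SNVs per Mb.
#' @export
compute_tmb <- function(filtered, territory_mb) {
  if (!is.numeric(territory_mb) || length(territory_mb) != 1 ||
      territory_mb <= 0)
    stop("territory_mb must be a positive number")
  nrow(filtered) / territory_mb
}

#' Select deleterious SNVs
#'
#' Keeps variants whose annotated impact on protein function is `HIGH` or
#' `MODERATE` (the standard annotation tier for "medium" impact). Unknown
#' impact labels are an error.
#'
#' @param calls A validated SNV data.frame with populated `impact`.
#' @return The deleterious subset.
#' @export
select_deleterious <- function(calls) {
  known <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  bad <- setdiff(unique(calls$impact), known)
  if (length(bad) > 0)
    stop("unknown impact label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(known, collapse = "/"), ")")
  out <- calls[calls$impact %in% c("HIGH", "MODERATE"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared/private SNV partition for a matched pair
#'
#' Partitions the deleterious SNVs of a matched tumor (PT) / organoid (PDO)
#' pair by the identity key `(chrom, pos, ref, alt)` into shared and
#' private sets, reports per-side shared/private proportions, and tests the
#' shared-vs-private counts of the two sides with a 2x2 chi-squared test
#' (no continuity correction).
#'
#' @param pt,pdo Filtered, deleterious SNV data.frames for the two sides.
#' @return An object of class `pair_concordance`: list with the three key
#'   sets (`shared`, `private_pt`, `private_pdo`), per-side proportions and
#'   `chi2_p`.
#' @export
partition_pair <- function(pt, pdo) {
  if (nrow(pt) == 0 && nrow(pdo) == 0)
    stop("both SNV tables are empty; nothing to partition")
  kp <- snv_key(pt); ko <- snv_key(pdo)
  shared <- intersect(kp, ko)
  private_pt <- setdiff(kp, shared)
  private_pdo <- setdiff(ko, shared)
  prop <- function(n_shared, n_private) {
    tot <- n_shared + n_private
    if (tot == 0) c(shared = NA_real_, private = NA_real_)
    else c(shared = n_shared / tot, private = n_private / tot)
  }
  tab <- rbind(PT = c(shared = length(shared), private = length(private_pt)),
               PDO = c(shared = length(shared), private = length(private_pdo)))
  chi2_p <- if (any(rowSums(tab) == 0)) NA_real_ else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  structure(list(shared = shared, private_pt = private_pt,
                 private_pdo = private_pdo,
                 proportions_pt = prop(length(shared), length(private_pt)),
                 proportions_pdo = prop(length(shared), length(private_pdo)),
                 counts = tab, chi2_p = chi2_p),
            class = "pair_concordance")
}

#' @export
print.pair_concordance <- function(x, ...) {
  cat("pair_concordance:", length(x$shared), "shared,",
      length(x$private_pt), "PT-private,", length(x$private_pdo),
      "PDO-private SNVs\n")
  cat(sprintf("  shared fraction: PT %.3f, PDO %.3f; chi-squared p = %s\n",
              x$proportions_pt["shared"], x$proportions_pdo["shared"],
              format(x$chi2_p, digits = 3)))
  invisible(x)
}

#' Clonality (cancer cell fraction) of somatic SNVs
#'
#' Corrects observed allelic fractions for tumor purity, local
#' allele-specific copy number and mutation multiplicity. With `p` the
#' purity, `CNt = cnA + cnB` the local tumor copy number and `AF` the
#' allelic fraction, the multiplicity is
#' `m = clamp(round(AF * (p * CNt + (1 - p) * 2) / p), 1, max(cnA, cnB))`
#' and the cancer cell fraction is
#' `CCF = AF * (p * CNt + (1 - p) * 2) / (p * m)`. The raw CCF is retained
#' (capped at 1.25); the reported `ccf` is truncated at 1. A fully clonal
#' heterozygous SNV in a pure diploid sample (AF = 0.5, p = 1) has CCF 1.
#'
#' @param calls SNV data.frame (one row per SNV).
#' @param purity Tumor purity in `(0, 1]`.
#' @param cnA,cnB Local discrete allele-specific copy numbers at each SNV
#'   (recycled if scalar). Their sum must be >= 1.
#' @return A data.frame with columns `key`, `ccf`, `ccf_raw`,
#'   `multiplicity`, `purity`, `cn_total`.
#' @export
compute_clonality <- function(calls, purity, cnA = 1L, cnB = 1L) {
  if (!is.numeric(purity) || length(purity) != 1 || purity <= 0 ||
      purity > 1)
    stop("purity must lie in (0, 1]")
  n <- nrow(calls)
  cnA <- rep_len(cnA, n); cnB <- rep_len(cnB, n)
  cn_t <- cnA + cnB
  if (any(cn_t < 1)) stop("total copy number at an SNV locus must be >= 1")
  af <- calls$allelic_fraction
  scale <- purity * cn_t + (1 - purity) * 2
  m <- pmin(pmax(round_cn(af * scale / purity), 1L), pmax(cnA, cnB))
  ccf_raw <- pmin(af * scale / (purity * m), 1.25)
  data.frame(key = snv_key(calls), ccf = pmin(ccf_raw, 1),
             ccf_raw = ccf_raw, multiplicity = m, purity = purity,
             cn_total = cn_t, stringsAsFactors = FALSE)
}

#' Compare allelic-fraction distributions of shared and private SNVs
#'
#' Two-sided rank-sum test between the allelic fractions of SNVs shared by
#' a matched pair and those private to one side. Private mutations confined
#' to minor subclones sit at depressed allelic fractions, so a low p
#' indicates the shared mutations are the clonal backbone.
#'
#' @param shared,private Numeric vectors of allelic fractions.
#' @return Two-sided p-value.
#' @export
compare_af_distributions <- function(shared, private) {
  if (length(shared) == 0 || length(private) == 0)
    stop("both allelic-fraction vectors must be non-empty")
  rank_sum_test(shared, private)
}

#' Clonality correlation between matched samples
#'
#' Pearson correlation (with two-sided correlation-test p) between the
#' cancer cell fractions of SNVs shared by a matched tumor/organoid pair.
#'
#' @param ccf_pt,ccf_pdo CCF values for the shared SNVs, aligned by key.
#' @return List with `r`, `p` and `n`.
#' @export
clonality_correlation <- function(ccf_pt, ccf_pdo) {
  stopifnot(length(ccf_pt) == length(ccf_pdo))
  if (length(ccf_pt) < 3)
    stop("need at least 3 shared SNVs for a correlation")
  ct <- stats::cor.test(ccf_pt, ccf_pdo, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value), n = length(ccf_pt))
}

#' Longitudinal clonality shift between baseline and relapse
#'
#' For two longitudinal samples of one patient, tests (i) whether clonality
#' changed between baseline and relapse - paired over shared SNVs when any
#' exist (two-sided paired rank test), otherwise unpaired with a warning -
#' and (ii) whether the SNVs lost at relapse were more subclonal at
#' baseline than the conserved ones (two-sided rank-sum test).
#'
#' @param baseline,relapse Clonality data.frames from [compute_clonality()]
#'   (columns `key` and `ccf`).
#' @return List with `p_shift`, `paired` (logical), `lost_snvs` (keys
#'   present only at baseline), and `p_lost_vs_kept` (NA if either side is
#'   empty).
#' @export
longitudinal_clonality_shift <- function(baseline, relapse) {
  if (nrow(baseline) == 0 || nrow(relapse) == 0)
    stop("both clonality tables must be non-empty")
  shared <- intersect(baseline$key, relapse$key)
  if (length(shared) > 0) {
    b <- baseline$ccf[match(shared, baseline$key)]
    r <- relapse$ccf[match(shared, relapse$key)]
    p_shift <- rank_sum_test(r, b, paired = TRUE)
    paired <- TRUE
  } else {
    warning("no shared SNVs between baseline and relapse; ",
            "reporting an unpaired test")
    p_shift <- rank_sum_test(relapse$ccf, baseline$ccf)
    paired <- FALSE
  }
  lost <- setdiff(baseline$key, relapse$key)
  kept <- baseline$key %in% shared
  p_lost_vs_kept <- if (length(lost) > 0 && any(kept))
    rank_sum_test(baseline$ccf[baseline$key %in% lost],
                  baseline$ccf[kept]) else NA_real_
  list(p_shift = p_shift, paired = paired, lost_snvs = lost,
       p_lost_vs_kept = p_lost_vs_kept)
}
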