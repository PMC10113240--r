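#' Build a binary genomic feature matrix
#'
#' Assembles per-sample binary indicators for pharmacogenomic association:
#' \describe{
#'   \item{`<gene>_snv`}{gene carries at least one deleterious SNV}
#'   \item{`<gene>_homo_del`}{discrete `(cnA, cnB) = (0, 0)`}
#'   \item{`<gene>_hemi_del`}{discrete `(cnA, cnB) = (1, 0)`}
#'   \item{`<gene>_gain`}{total copy number above the sample's rounded
#'     allele-specific ploidy baseline}
#'   \item{`<gene>_amp`}{total copy number at least baseline + 3
#'     (amplification)}
#'   \item{`<set>_enriched`}{the sample's enrichment q-value for the set is
#'     below `q_cut`}
#' }
#' A sample missing from an input block gets NA (missing, not 0) for that
#' block's features.
#'
#' @param snv_tables Named list (by sample) of deleterious SNV data.frames.
#' @param cn_matrix A `gene_cn_matrix` from [project_to_genes()], or NULL.
#' @param asP Named numeric vector of per-sample allele-specific ploidy
#'   (required with `cn_matrix`; defines the gain baseline).
#' @param enrichment List of [overrepresentation()] results, or NULL.
#' @param samples Character vector fixing the row order (default: union of
#'   input samples).
#' @param q_cut Enrichment q-value cutoff (default 0.2).
#' @param amp_offset Total copies above baseline that define amplification
#'   (default 3).
#' @param drop_constant Drop features with no variation among non-missing
#'   samples (default TRUE).
#' @return Integer matrix samples x features with entries 0/1/NA.
#' @export
build_features <- function(snv_tables = NULL, cn_matrix = NULL, asP = NULL,
                           enrichment = NULL, samples = NULL, q_cut = 0.2,
                           amp_offset = 3L, drop_constant = TRUE) {
  blocks <- list()
  if (!is.null(snv_tables)) {
    genes <- sort(unique(unlist(lapply(snv_tables, function(t) t$gene))))
    if (length(genes) > 0) {
      m <- t(vapply(snv_tables, function(t) as.integer(genes %in% t$gene),
                    integer(length(genes))))
      dimnames(m) <- list(names(snv_tables), paste0(genes, "_snv"))
      blocks$snv <- m
    }
  }
  if (!is.null(cn_matrix)) {
    stopifnot(inherits(cn_matrix, "gene_cn_matrix"))
    if (is.null(asP) || is.null(names(asP)))
      stop("cn features need a named per-sample asP vector for the ",
           "gain/amplification baseline")
    base <- round_cn(asP[cn_matrix$samples])
    tot <- cn_matrix$cnA + cn_matrix$cnB
    mk <- function(m, tag) {
      colnames(m) <- paste0(cn_matrix$genes, "_", tag)
      rownames(m) <- cn_matrix$samples
      m
    }
    blocks$cn <- cbind(
      mk((cn_matrix$cnA == 0 & cn_matrix$cnB == 0) + 0L, "homo_del"),
      mk((cn_matrix$cnA == 1 & cn_matrix$cnB == 0) + 0L, "hemi_del"),
      mk((tot > base) + 0L, "gain"),
      mk((tot >= base + amp_offset) + 0L, "amp"))
  }
  if (!is.null(enrichment)) {
    ids <- vapply(enrichment, function(r) attr(r, "sample_id"), character(1))
    sets <- sort(unique(unlist(lapply(enrichment, function(r) r$set_name))))
    m <- t(vapply(enrichment, function(r)
      as.integer(sets %in% r$set_name[r$q < q_cut]), integer(length(sets))))
    dimnames(m) <- list(ids, paste0(sets, "_enriched"))
    blocks$enrich <- m
  }
  if (length(blocks) == 0) stop("no feature inputs supplied")
  samples <- samples %||% unique(unlist(lapply(blocks, rownames)))
  out <- do.call(cbind, lapply(blocks, function(b) {
    full <- matrix(NA_integer_, length(samples), ncol(b),
                   dimnames = list(samples, colnames(b)))
    present <- intersect(samples, rownames(b))
    full[present, ] <- b[present, , drop = FALSE]
    full
  }))
  if (drop_constant) {
    keep <- apply(out, 2, function(x) length(unique(x[!is.na(x)])) > 1)
    out <- out[, keep, drop = FALSE]
  }
  out
}

#' Linear mixed-model association of a genomic feature with drug response
#'
#' Fits replicate-level z-scores against a binary genomic feature with a
#' per-sample random intercept: `z ~ feature + (1 | sample)`. The effect is
#' the fixed-effect coefficient (z-score units; negative means carriers are
#' more sensitive) and the p-value is the two-sided Wald-type t test on
#' that coefficient with Satterthwaite denominator degrees of freedom,
#' which keeps the type-I error calibrated at cohort sizes of tens of
#' samples. With one replicate per sample the model reduces to an ordinary
#' linear model, whose coefficient is the two-group mean difference; the
#' same fallback is used if the mixed fit is singular or fails.
#'
#' @param feature Named 0/1 vector over samples (NA allowed; those samples
#'   are dropped).
#' @param z_by_sample Named list mapping sample id to the replicate
#'   z-score vector of one drug.
#' @param feature_name,drug Labels carried into the result.
#' @return A one-row data.frame (class `association_result`) with columns
#'   `feature`, `drug`, `effect`, `p`, `n_mutated`, `n_wildtype`,
#'   `method`, or NULL (with a message) if the feature is constant or a
#'   group has fewer than 2 samples.
#' @export
lmm_association <- function(feature, z_by_sample,
                            feature_name = "feature", drug = "drug") {
  common <- intersect(names(feature)[!is.na(feature)], names(z_by_sample))
  feature <- feature[common]
  z_by_sample <- z_by_sample[common]
  n1 <- sum(feature == 1); n0 <- sum(feature == 0)
  if (n1 < 2 || n0 < 2) {
    message("untestable feature '", feature_name, "' for ", drug,
            ": needs >= 2 samples per level (has ", n1, "/", n0, ")")
    return(NULL)
  }
  long <- data.frame(
    z = unlist(z_by_sample, use.names = FALSE),
    feature = rep(feature, lengths(z_by_sample)),
    sample = factor(rep(common, lengths(z_by_sample))))
  res <- NULL
  if (max(lengths(z_by_sample)) >= 2) {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(z ~ feature + (1 | sample),
                                      data = long, REML = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4)) {
      co <- stats::coef(summary(fit))
      res <- list(effect = co["feature", "Estimate"],
                  p = co["feature", "Pr(>|t|)"], method = "lmm")
    }
  }
  if (is.null(res)) {
    # per-sample means: ordinary two-group linear model
    means <- vapply(z_by_sample, mean, 1)
    fit <- stats::lm(means ~ feature)
    co <- stats::coef(summary(fit))
    res <- list(effect = co["feature", "Estimate"],
                p = co["feature", "Pr(>|t|)"], method = "lm_sample_means")
    if (max(lengths(z_by_sample)) >= 2)
      warning("singular mixed fit for '", feature_name, "' x ", drug,
              "; fell back to the per-sample-mean linear model")
  }
  out <- data.frame(feature = feature_name, drug = drug,
                    effect = res$effect, p = res$p,
                    n_mutated = n1, n_wildtype = n0, method = res$method,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Screen all features against one drug
#'
#' Convenience wrapper running [lmm_association()] for every column of a
#' feature matrix against one drug's replicate z-scores, then adjusting the
#' per-drug family with [adjust_fdr()].
#'
#' @param features Feature matrix from [build_features()].
#' @param z_by_sample Named list of replicate z-score vectors for the drug.
#' @param drug Drug label.
#' @return An `association_result` data.frame (possibly 0 rows), FDR
#'   adjusted.
#' @export
associate_drug <- function(features, z_by_sample, drug = "drug") {
  rows <- lapply(colnames(features), function(f)
    suppressMessages(
      lmm_association(features[, f], z_by_sample, feature_name = f,
                      drug = drug)))
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    out <- data.frame(feature = character(0), drug = character(0),
                      effect = numeric(0), p = numeric(0),
                      n_mutated = integer(0), n_wildtype = integer(0),
                      method = character(0), fdr = numeric(0),
                      significant = logical(0))
    class(out) <- c("association_result", "data.frame")
    return(out)
  }
  adjust_fdr(do.call(rbind, rows))
}

#' Benjamini-Hochberg adjustment of association results
#'
#' Adjusts the p-values of one testing family (per drug across features)
#' with the Benjamini-Hochberg step-up procedure and flags significance at
#' `fdr <= fdr_cut`. The output is invariant under permutation of the
#' input rows.
#'
#' @param results An `association_result` data.frame.
#' @param fdr_cut FDR threshold for the `significant` flag (default 0.10).
#' @return The input with `fdr` and `significant` columns.
#' @export
adjust_fdr <- function(results, fdr_cut = 0.10) {
  if (nrow(results) == 0) {
    results$fdr <- numeric(0); results$significant <- logical(0)
    return(results)
  }
  results$fdr <- stats::p.adjust(results$p, method = "BH")
  results$significant <- results$fdr <= fdr_cut
  results
}
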