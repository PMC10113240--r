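#' Gene-set over-representation for one sample
#'
#' One-sided hypergeometric test per gene set: with `N` background genes of
#' which `n` carry a deleterious mutation in the sample, and a set covering
#' `K` background genes of which `k` are mutated, the p-value is the upper
#' hypergeometric tail `P(X >= k)`. Q-values are Benjamini-Hochberg
#' adjusted p-values across the sets tested within the sample.
#'
#' @param mutated_genes Character vector of genes carrying at least one
#'   deleterious mutation in the sample. Genes absent from the background
#'   are dropped with a warning.
#' @param collection A [gene_set_collection()]; if its background is NULL,
#'   the union of all set members is used.
#' @param sample_id Optional label carried into the result.
#' @return An object of class `enrichment_result`: data.frame with columns
#'   `set_name`, `k`, `K`, `n`, `N`, `p`, `q` and attribute `sample_id`.
#' @export
overrepresentation <- function(mutated_genes, collection,
                               sample_id = NA_character_) {
  stopifnot(inherits(collection, "gene_set_collection"))
  mutated_genes <- unique(as.character(mutated_genes))
  if (length(mutated_genes) == 0) stop("mutated gene set is empty")
  bg <- collection$background %||% unique(unlist(collection$sets))
  outside <- setdiff(mutated_genes, bg)
  if (length(outside) > 0) {
    warning("dropping ", length(outside),
            " mutated gene(s) absent from the background")
    mutated_genes <- intersect(mutated_genes, bg)
  }
  N <- length(bg)
  n <- length(mutated_genes)
  rows <- lapply(names(collection$sets), function(nm) {
    set_bg <- intersect(collection$sets[[nm]], bg)
    K <- length(set_bg)
    k <- length(intersect(mutated_genes, set_bg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  attr(res, "sample_id") <- sample_id
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Recurrently enriched terms across a cohort
#'
#' Shortlists gene sets that are enriched (`q < q_cut`) in at least
#' `ceiling(recurrence * n_included)` of the included samples. Excluded
#' samples (e.g. longitudinal relapse samples, which would double-count a
#' patient) are removed from both numerator and denominator.
#'
#' @param results List of [overrepresentation()] results (with sample ids).
#' @param q_cut Q-value cutoff within each sample (default 0.2, strict
#'   inequality).
#' @param recurrence Minimum fraction of included samples (default 0.20);
#'   the count threshold is rounded up.
#' @param excluded_samples Character vector of sample ids to exclude.
#' @return Data.frame with `set_name`, `n_enriched`, `n_included`,
#'   `fraction`, sorted by decreasing recurrence, containing only retained
#'   terms. The count threshold is in attribute `min_samples`.
#' @export
recurrent_terms <- function(results, q_cut = 0.2, recurrence = 0.20,
                            excluded_samples = character(0)) {
  ids <- vapply(results, function(r) attr(r, "sample_id"), character(1))
  if (anyNA(ids)) stop("every enrichment result needs a sample_id")
  keep <- !ids %in% excluded_samples
  if (!any(keep)) stop("all samples are excluded")
  results <- results[keep]
  n_included <- sum(keep)
  min_samples <- ceiling(recurrence * n_included)
  hits <- lapply(results, function(r) r$set_name[r$q < q_cut])
  counts <- table(unlist(hits))
  out <- data.frame(set_name = names(counts),
                    n_enriched = as.integer(counts),
                    n_included = n_included,
                    fraction = as.integer(counts) / n_included,
                    stringsAsFactors = FALSE)
  out <- out[out$n_enriched >= min_samples, , drop = FALSE]
  out <- out[order(-out$n_enriched, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_samples") <- min_samples
  out
}
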