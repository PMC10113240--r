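#' Project segment copy numbers onto a gene panel
#'
#' Each gene takes the discrete `(cnA, cnB)` state of the segment containing
#' its midpoint (deterministic and order-independent; a gene spanning a
#' breakpoint is assigned by where its midpoint falls). Continuous copy
#' numbers are discretized by rounding half away from zero, floored at 0.
#' Genes not covered by any segment in at least one sample are dropped for
#' the whole cohort (complete-case), so every retained gene is comparable
#' across all samples.
#'
#' @param profiles List of [segment_profile()] objects.
#' @param panel A [gene_panel()].
#' @return An object of class `gene_cn_matrix`: list with `samples`,
#'   `genes`, integer matrices `cnA` and `cnB` (samples x genes), and
#'   `dropped_genes`.
#' @export
project_to_genes <- function(profiles, panel) {
  panel <- gene_panel(panel)
  if (nrow(panel) == 0) stop("gene panel is empty")
  samples <- vapply(profiles, function(p) p$sample_id, character(1))
  # gene midpoint in internal 0-based coordinates
  mid <- floor((panel$start + panel$end) / 2) - 1L
  lookup <- function(profile) {
    seg <- profile$segments
    cn <- matrix(NA_integer_, nrow = nrow(panel), ncol = 2)
    for (chrom in unique(panel$chrom)) {
      gi <- which(panel$chrom == chrom)
      sc <- seg[seg$chrom == chrom, , drop = FALSE]
      if (nrow(sc) == 0) next
      idx <- findInterval(mid[gi], sc$start)
      hit <- idx >= 1 & ifelse(idx >= 1, mid[gi] < sc$end[pmax(idx, 1)], FALSE)
      cn[gi[hit], 1] <- round_cn(sc$cnA[idx[hit]])
      cn[gi[hit], 2] <- round_cn(sc$cnB[idx[hit]])
    }
    cn
  }
  per_sample <- lapply(profiles, lookup)
  cnA <- do.call(rbind, lapply(per_sample, function(m) m[, 1]))
  cnB <- do.call(rbind, lapply(per_sample, function(m) m[, 2]))
  dimnames(cnA) <- dimnames(cnB) <- list(samples, panel$gene)
  complete <- colSums(is.na(cnA)) == 0
  if (!any(complete))
    warning("no gene is covered by segments in every sample; ",
            "returning an empty matrix")
  structure(list(samples = samples, genes = panel$gene[complete],
                 cnA = cnA[, complete, drop = FALSE],
                 cnB = cnB[, complete, drop = FALSE],
                 dropped_genes = panel$gene[!complete]),
            class = "gene_cn_matrix")
}

#' @export
print.gene_cn_matrix <- function(x, ...) {
  cat("gene_cn_matrix:", length(x$samples), "samples x", length(x$genes),
      "genes (", length(x$dropped_genes), "dropped )\n")
  invisible(x)
}

cn_feature_matrix <- function(mat) {
  # concatenated (cnA, cnB) gene vectors, one row per sample
  cbind(mat$cnA, mat$cnB)
}

#' Euclidean copy-number distance between two samples
#'
#' Distance between the concatenated `(cnA, cnB)` gene-wise copy-number
#' vectors of two samples.
#'
#' @param mat A `gene_cn_matrix` from [project_to_genes()].
#' @param k1,k2 Sample identifiers.
#' @return Euclidean distance (scalar).
#' @export
cn_distance <- function(mat, k1, k2) {
  stopifnot(inherits(mat, "gene_cn_matrix"))
  for (k in c(k1, k2)) if (!k %in% mat$samples)
    stop("sample not present in matrix: ", k)
  if (length(mat$genes) == 0)
    stop("no genes shared across samples; distance undefined")
  x <- cn_feature_matrix(mat)
  sqrt(sum((x[k1, ] - x[k2, ])^2))
}

#' Cohort-wide copy-number similarity
#'
#' Computes all pairwise Euclidean distances `d` between concatenated
#' gene-wise `(cnA, cnB)` vectors, min-max rescales them over all
#' off-diagonal pairs (`d' = (d - min d) / (max d - min d)`) and reports the
#' similarity `s = 1 - d'`. The closest pair in the cohort therefore has
#' s = 1 and the most dissimilar pair s = 0.
#'
#' @param mat A `gene_cn_matrix`.
#' @param matched_pairs Optional data.frame with columns `pt` and `pdo`
#'   naming matched tumor/organoid pairs, carried through for
#'   [matched_vs_random_test()].
#' @return An object of class `cn_similarity`: list with matrices `d`,
#'   `d_prime`, `s` (NA diagonal for the rescaled forms) and
#'   `matched_pairs`.
#' @export
similarity <- function(mat, matched_pairs = NULL) {
  stopifnot(inherits(mat, "gene_cn_matrix"))
  if (length(mat$samples) < 2) stop("need at least 2 samples")
  if (length(mat$genes) == 0) stop("no genes shared across samples")
  d <- as.matrix(stats::dist(cn_feature_matrix(mat)))
  off <- d[upper.tri(d)]
  rng <- range(off)
  if (rng[1] == rng[2])
    stop("all pairwise distances are equal; min-max rescaling is undefined")
  d_prime <- (d - rng[1]) / (rng[2] - rng[1])
  diag(d_prime) <- NA_real_
  s <- 1 - d_prime
  if (!is.null(matched_pairs)) {
    matched_pairs <- as.data.frame(matched_pairs)
    stopifnot(all(c("pt", "pdo") %in% names(matched_pairs)))
    known <- c(matched_pairs$pt, matched_pairs$pdo) %in% mat$samples
    if (!all(known)) stop("matched pair sample(s) absent from matrix")
  }
  structure(list(d = d, d_prime = d_prime, s = s,
                 matched_pairs = matched_pairs),
            class = "cn_similarity")
}

#' @export
print.cn_similarity <- function(x, ...) {
  cat("cn_similarity over", nrow(x$d), "samples;",
      if (is.null(x$matched_pairs)) "no matched pairs recorded"
      else paste(nrow(x$matched_pairs), "matched pairs"), "\n")
  invisible(x)
}

#' Matched versus randomly-paired similarity test
#'
#' Tests whether matched tumor/organoid pairs are more similar than
#' arbitrary cross-sample pairings: a two-sided rank-sum test of the
#' matched-pair similarities against the similarities of all remaining
#' sample pairs (`choose(n, 2) - n_matched` of them; e.g. 26 samples with 13
#' matched pairs give 312 random pairings).
#'
#' @param result A `cn_similarity` with `matched_pairs` set.
#' @return List with `p`, `n_matched`, `n_random`, and the two similarity
#'   vectors `matched_s`, `random_s`.
#' @export
matched_vs_random_test <- function(result) {
  stopifnot(inherits(result, "cn_similarity"))
  mp <- result$matched_pairs
  if (is.null(mp) || nrow(mp) == 0)
    stop("no matched pairs recorded in the similarity result")
  if (nrow(mp) < 2)
    stop("need at least 2 matched pairs")
  s <- result$s
  ids <- rownames(s)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  matched_keys <- pair_key(mp$pt, mp$pdo)
  ut <- which(upper.tri(s), arr.ind = TRUE)
  keys <- pair_key(ids[ut[, 1]], ids[ut[, 2]])
  matched_s <- s[upper.tri(s)][keys %in% matched_keys]
  random_s <- s[upper.tri(s)][!keys %in% matched_keys]
  list(p = rank_sum_test(matched_s, random_s),
       n_matched = length(matched_s), n_random = length(random_s),
       matched_s = matched_s, random_s = random_s)
}

#' Hierarchical clustering of copy-number profiles
#'
#' Agglomerative clustering with average linkage on the pairwise
#' copy-number distance matrix. Duplicated profiles merge first at height
#' 0; merge heights are non-decreasing (average linkage is monotone).
#'
#' @param result A `cn_similarity`.
#' @return An [stats::hclust] dendrogram with samples as leaves.
#' @seealso [export_dendrogram()] for Newick output.
#' @export
cluster_profiles <- function(result) {
  stopifnot(inherits(result, "cn_similarity"))
  if (nrow(result$d) < 3) stop("need at least 3 samples to cluster")
  hc <- stats::hclust(stats::as.dist(result$d), method = "average")
  hc$method.note <- "average linkage on gene-wise allele-specific CN distance"
  hc
}

#' Export a dendrogram in Newick format
#'
#' @param hc An [stats::hclust] object from [cluster_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Ordinal trend of a genomic index across tumor classes
#'
#' Kendall tau-b (tie-corrected) correlation between a per-sample numeric
#' index (e.g. tumor mutational burden or genomic burden) and the ordered
#' tumor classes low-grade NMIBC < high-grade NMIBC < MIBC, with a
#' two-sided p-value from the tie-corrected normal approximation.
#'
#' @param values Per-sample numeric values.
#' @param classes Per-sample tumor classes (character or factor using the
#'   [tumor_class_levels()] ordering, or any ordered factor).
#' @return List with `tau_b` and `p`.
#' @export
ordinal_trend <- function(values, classes) {
  stopifnot(length(values) == length(classes))
  if (is.ordered(classes)) {
    rank_cls <- as.integer(classes)
  } else {
    cls <- as.character(classes)
    if (!all(cls %in% tumor_class_levels()))
      stop("classes must use levels ", paste(tumor_class_levels(), collapse = " < "),
           " or be an ordered factor")
    rank_cls <- match(cls, tumor_class_levels())
  }
  if (length(unique(rank_cls)) < 2)
    stop("need at least 2 distinct classes")
  if (length(unique(values)) < 2)
    stop("values are constant; tau is undefined")
  ct <- suppressWarnings(
    stats::cor.test(rank_cls, values, method = "kendall", exact = FALSE))
  list(tau_b = unname(ct$estimate), p = unname(ct$p.value))
}
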