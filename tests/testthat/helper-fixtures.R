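# fixtures are built in code; nothing is stored on disk

# profile from a matrix of (cnA, cnB) states and segment lengths (bp),
# laid end to end on one chromosome (internal 0-based half-open coords)
make_profile <- function(states, lengths, sample_id = "S1", chrom = "chr1",
                         ...) {
  stopifnot(nrow(states) == length(lengths))
  ends <- cumsum(lengths)
  segment_profile(sample_id, data.frame(
    chrom = chrom, start = c(0, ends[-length(ends)]), end = ends,
    cnA = states[, 1], cnB = states[, 2]), ...)
}

uniform_profile <- function(cnA, cnB, sample_id = "S1", n_seg = 4,
                            seg_len = 1e6) {
  make_profile(cbind(rep(cnA, n_seg), rep(cnB, n_seg)),
               rep(seg_len, n_seg), sample_id = sample_id)
}

make_snvs <- function(n = 5, pos = seq_len(n) * 100, cov = 40, alt = 10,
                      normal_alt = 0, gene = "G001", impact = "MODERATE",
                      chrom = "chr1") {
  validate_snv_table(data.frame(
    chrom = chrom, pos = pos, ref = "C", alt = "T",
    tumor_coverage = cov, tumor_alt_reads = alt,
    normal_alt_reads = normal_alt, gene = gene, impact = impact,
    stringsAsFactors = FALSE))
}

make_plate <- function(sample_id = "S1",
                       vehicle = c(90, 100, 110),
                       drugs = list(drugA = c(80, 85, 75)),
                       vehicle_class = "DMSO") {
  rows <- list(data.frame(condition = vehicle_class,
                          vehicle_class = vehicle_class,
                          replicate = seq_along(vehicle),
                          readout = vehicle))
  for (d in names(drugs)) {
    rows[[d]] <- data.frame(condition = d, vehicle_class = vehicle_class,
                            replicate = seq_along(drugs[[d]]),
                            readout = drugs[[d]])
  }
  plate_data(sample_id, do.call(rbind, rows))
}

# exhaustive two-sided rank-sum p by enumeration of all rank assignments
# (the independent oracle for small two-sample configurations)
enumerate_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  ranks <- rank(c(x, y))
  obs <- sum(ranks[seq_len(m)])
  splits <- utils::combn(m + n, m)
  stats_all <- apply(splits, 2, function(idx) sum(ranks[idx]))
  # two-sided: double the smaller tail of the permutation distribution
  p_low <- mean(stats_all <= obs)
  p_high <- mean(stats_all >= obs)
  min(1, 2 * min(p_low, p_high))
}

# direct-summation hypergeometric upper tail (oracle for enrichment tests)
enumerate_hyper_p <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# one shared small cohort reused across test files
shared_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(cohort_config(n_pairs = 6,
                                                            seed = 101))
    coh
  }
})
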