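test_that("asP matches closed forms and hand-computed weighted means", {
  expect_equal(compute_asP(uniform_profile(1, 1)), 2)
  expect_equal(compute_asP(make_profile(cbind(2, 1), 1e6)), 3)
  # (2,1) over 1 Mb and (1,1) over 3 Mb: (3*1 + 2*3) / 4
  p <- make_profile(rbind(c(2, 1), c(1, 1)), c(1e6, 3e6))
  expect_equal(compute_asP(p), 2.25)
  expect_error(compute_asP(segment_profile("x", data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    cnA = numeric(0), cnB = numeric(0)))), "empty")
})

test_that("genomic burden is the length-weighted non-wild-type fraction", {
  expect_equal(compute_gb(uniform_profile(1, 1)), 0)
  expect_equal(compute_gb(uniform_profile(2, 1)), 1)  # uniform triploid
  p <- make_profile(rbind(c(2, 1), c(1, 1)), c(2e6, 2e6))
  expect_equal(compute_gb(p), 0.5)
})

test_that("asP decomposes over wild-type and aberrant territory", {
  # asP = 2 * (1 - GB) + (mean total CN over aberrant territory) * GB
  coh <- shared_cohort()
  for (p in coh$profiles[1:6]) {
    gb <- compute_gb(p)
    seg <- p$segments
    w <- seg$end - seg$start
    ab <- seg$cnA != 1 | seg$cnB != 1
    mean_ab <- if (any(ab)) sum((seg$cnA + seg$cnB)[ab] * w[ab]) / sum(w[ab])
    else 0
    expect_equal(compute_asP(p), 2 * (1 - gb) + mean_ab * gb)
  }
})

test_that("gene projection uses the midpoint rule and complete-case drop", {
  panel <- gene_panel(data.frame(
    gene = c("A", "B", "C"), chrom = "chr1",
    start = c(101, 1801, 5001), end = c(300, 2200, 5200)))
  # sample 1: gene B spans the 2 Mb..? breakpoint scaled down: segments
  # [0,2000) at (3,1) and [2000,4000) at (1,1); B's midpoint 2000 (1-based)
  # -> internal 1999 falls in the first segment
  s1 <- segment_profile("S1", data.frame(
    chrom = "chr1", start = c(0, 2000), end = c(2000, 4000),
    cnA = c(3, 1), cnB = c(1, 1)))
  # sample 2 covers genes A and B but not C either
  s2 <- segment_profile("S2", data.frame(
    chrom = "chr1", start = 0, end = 4000, cnA = 2, cnB = 2))
  mat <- project_to_genes(list(s1, s2), panel)
  expect_setequal(mat$genes, c("A", "B"))      # C uncovered in both -> dropped
  expect_equal(mat$dropped_genes, "C")
  expect_equal(unname(mat$cnA["S1", ]), c(3, 3))  # midpoint rule picks (3,1)
  expect_equal(unname(mat$cnB["S1", ]), c(1, 1))
  # continuous copy numbers are rounded half away from zero
  s3 <- segment_profile("S3", data.frame(
    chrom = "chr1", start = 0, end = 4000, cnA = 2.5, cnB = 0.4))
  mat3 <- project_to_genes(list(s3), panel[panel$gene != "C", ])
  expect_equal(unname(mat3$cnA["S3", ]), c(3, 3))
  expect_equal(unname(mat3$cnB["S3", ]), c(0, 0))
})

test_that("copy-number distance is Euclidean on concatenated alleles", {
  panel <- gene_panel(data.frame(gene = c("A", "B", "C"), chrom = "chr1",
                                 start = c(1, 1001, 2001),
                                 end = c(500, 1500, 2500)))
  base <- segment_profile("S1", data.frame(
    chrom = "chr1", start = 0, end = 3000, cnA = 2, cnB = 1))
  same <- segment_profile("S2", data.frame(
    chrom = "chr1", start = 0, end = 3000, cnA = 2, cnB = 1))
  # one allele of one gene differs by 1
  one_off <- segment_profile("S3", data.frame(
    chrom = "chr1", start = c(0, 500), end = c(500, 3000),
    cnA = c(3, 2), cnB = c(1, 1)))
  # cnA differs at gene A and cnB at gene B
  two_off <- segment_profile("S4", data.frame(
    chrom = "chr1", start = c(0, 1000, 2000), end = c(1000, 2000, 3000),
    cnA = c(3, 2, 2), cnB = c(1, 2, 1)))
  mat <- project_to_genes(list(base, same, one_off, two_off), panel)
  expect_equal(cn_distance(mat, "S1", "S2"), 0)
  expect_equal(cn_distance(mat, "S1", "S3"), 1)
  expect_equal(cn_distance(mat, "S1", "S4"), sqrt(2))
  expect_error(cn_distance(mat, "S1", "S9"), "not present")
})

test_that("similarity anchors the closest pair at 1 and the farthest at 0", {
  coh <- shared_cohort()
  profiles <- coh$profiles
  # append an exact duplicate of the first sample
  dup <- profiles[[1]]
  dup$sample_id <- "DUP"
  mat <- project_to_genes(c(profiles, list(dup)), coh$panel)
  sim <- similarity(mat)
  s_off <- sim$s[upper.tri(sim$s)]
  expect_true(all(s_off >= 0 & s_off <= 1))
  expect_equal(sim$s["P01_PT", "DUP"], 1)        # min distance pair
  expect_equal(min(s_off), 0)                    # max distance pair
  expect_equal(sim$s, t(sim$s))
  # a pair at the midpoint distance rescales to similarity 0.5
  d_off <- sim$d[upper.tri(sim$d)]
  mid_d <- (min(d_off) + max(d_off)) / 2
  expect_equal(1 - (mid_d - min(d_off)) / (max(d_off) - min(d_off)), 0.5)
})

test_that("similarity is invariant under sample reordering", {
  coh <- shared_cohort()
  mat1 <- project_to_genes(coh$profiles, coh$panel)
  mat2 <- project_to_genes(rev(coh$profiles), coh$panel)
  s1 <- similarity(mat1)$s
  s2 <- similarity(mat2)$s
  expect_equal(s1, s2[rownames(s1), colnames(s1)])
})

test_that("equal-distance cohorts are rejected", {
  panel <- gene_panel(data.frame(gene = "A", chrom = "chr1", start = 1,
                                 end = 100))
  profs <- lapply(c("S1", "S2"), function(id) segment_profile(id,
    data.frame(chrom = "chr1", start = 0, end = 100, cnA = 1, cnB = 1)))
  mat <- project_to_genes(profs, panel)
  expect_error(similarity(mat), "rescaling is undefined")
})

test_that("matched pairs test against all remaining cross-sample pairs", {
  coh <- shared_cohort()
  mat <- project_to_genes(coh$profiles, coh$panel)
  sim <- similarity(mat, matched_pairs = coh$matched_pairs)
  res <- matched_vs_random_test(sim)
  n <- length(coh$profiles)
  expect_equal(res$n_matched, 6)
  expect_equal(res$n_random, choose(n, 2) - 6)
  # matched organoid/tumor pairs share a segment backbone: strongly similar
  expect_lt(res$p, 0.01)
  expect_gt(mean(res$matched_s), mean(res$random_s))
})

test_that("fully separated matched pairs attain the exact minimal p", {
  # 4 matched above 6 random similarities: p = 2 / choose(10, 4)
  matched_s <- c(0.9, 0.92, 0.95, 0.97)
  random_s <- c(0.1, 0.2, 0.3, 0.15, 0.25, 0.05)
  p <- rank_sum_test(matched_s, random_s)
  expect_equal(p, 2 / choose(10, 4), tolerance = 1e-12)
  expect_equal(p, enumerate_ranksum_p(matched_s, random_s),
               tolerance = 1e-10)
  # one matched pair vs one random pair carries no resolution
  expect_equal(rank_sum_test(0.9, 0.1), 1)
})

test_that("matched-vs-random p is calibrated under the null", {
  # matched and random similarities drawn from one distribution
  set.seed(99)
  pvals <- replicate(200, {
    s <- runif(40)
    rank_sum_test(s[1:6], s[7:40])
  })
  expect_gt(mean(pvals > 0.05), 0.85)     # ~5% false positives
  expect_lt(abs(mean(pvals) - 0.5), 0.08) # roughly uniform
})

test_that("clustering recovers planted structure and linkage properties", {
  coh <- shared_cohort()
  mat <- project_to_genes(coh$profiles, coh$panel)
  dup <- coh$profiles[[1]]
  dup$sample_id <- "DUP"
  mat_dup <- project_to_genes(c(coh$profiles, list(dup)), coh$panel)
  hc <- cluster_profiles(similarity(mat_dup))
  expect_equal(min(hc$height), 0)                  # duplicate merges first
  expect_true(all(diff(hc$height) >= -1e-9))       # monotone linkage
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("P01_PT", "DUP"))
  # two planted blocks (diploid vs polyploid backbones) separate at k = 2
  blocks <- generate_cohort(cohort_config(n_pairs = 4, seed = 17,
                                          polyploid_fraction = 0.5))
  poly <- blocks$truth$pairs$polyploid
  if (length(unique(poly)) == 2) {
    matb <- project_to_genes(blocks$profiles, blocks$panel)
    hcb <- cluster_profiles(similarity(matb))
    cut <- stats::cutree(hcb, k = 2)
    truth_block <- rep(poly, each = 2)
    expect_true(all(tapply(truth_block, cut, mean) %in% c(0, 1)))
  }
  two_sample <- structure(list(d = matrix(c(0, 1, 1, 0), 2, 2)),
                          class = "cn_similarity")
  expect_error(cluster_profiles(two_sample), "at least 3")
})

test_that("ordinal trend returns tie-corrected Kendall tau-b", {
  inc <- ordinal_trend(c(1, 2, 3), c("NMIBC_LG", "NMIBC_HG", "MIBC"))
  expect_equal(inc$tau_b, 1)
  dec <- ordinal_trend(c(3, 2, 1), c("NMIBC_LG", "NMIBC_HG", "MIBC"))
  expect_equal(dec$tau_b, -1)
  # brute-force concordant/discordant enumeration with tie correction
  classes <- c("NMIBC_LG", "NMIBC_LG", "NMIBC_HG", "NMIBC_HG", "MIBC",
               "MIBC")
  values <- c(1.2, 3.0, 2.5, 2.5, 4.1, 3.9)
  x <- match(classes, tumor_class_levels())
  C <- 0; D <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    s <- sign(x[j] - x[i]) * sign(values[j] - values[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- choose(6, 2)
  tx <- table(x); ty <- table(values)
  tau_oracle <- (C - D) / sqrt((n0 - sum(tx * (tx - 1) / 2)) *
                                 (n0 - sum(ty * (ty - 1) / 2)))
  expect_equal(ordinal_trend(values, classes)$tau_b, tau_oracle)
  expect_error(ordinal_trend(c(1, 1), c("NMIBC_LG", "MIBC")), "constant")
  expect_error(ordinal_trend(c(1, 2), c("MIBC", "MIBC")), "distinct")
})
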