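test_that("quality filters are inclusive at the stated boundaries", {
  calls <- validate_snv_table(data.frame(
    chrom = "chr1", pos = 1:5, ref = "C", alt = "T",
    tumor_coverage = c(20, 19, 100, 100, 100),
    tumor_alt_reads = c(5, 9, 4, 50, 8),
    normal_alt_reads = c(0, 0, 0, 1, 0),
    gene = "G", impact = "HIGH"))
  # row 1: exactly at every boundary (cov 20, AF 0.25, alt 5, normal 0)
  # row 2: coverage below 20; row 3: alt reads below 5; row 4: normal
  # support; row 5: passes
  kept <- filter_snvs(calls)
  expect_equal(kept$pos, c(1, 5))
  af_boundary <- validate_snv_table(data.frame(
    chrom = "chr1", pos = 1:2, ref = "C", alt = "T",
    tumor_coverage = 100, tumor_alt_reads = c(8, 7),
    normal_alt_reads = 0, gene = "G", impact = "HIGH"))
  expect_equal(filter_snvs(af_boundary)$pos, 1)  # AF 0.08 kept, 0.07 not
})

test_that("filtering is idempotent and returns a subset", {
  snv <- shared_cohort()$snvs[[1]]
  f1 <- filter_snvs(validate_snv_table(snv))
  expect_identical(filter_snvs(f1), f1)
  expect_true(all(pdoscreen:::snv_key(f1) %in%
                    pdoscreen:::snv_key(snv)))
})

test_that("TMB is the per-megabase count of filtered SNVs", {
  expect_equal(compute_tmb(make_snvs(n = 300, pos = 1:300), 30), 10)
  expect_equal(compute_tmb(make_snvs(n = 300, pos = 1:300), 60), 5)
  expect_equal(compute_tmb(make_snvs(2)[0, ], 30), 0)
  expect_error(compute_tmb(make_snvs(2), 0), "positive")
})

test_that("deleterious selection keeps HIGH and MODERATE impacts", {
  calls <- make_snvs(4, impact = c("HIGH", "MODERATE", "LOW", "MODIFIER"))
  kept <- select_deleterious(calls)
  expect_setequal(kept$impact, c("HIGH", "MODERATE"))
  expect_equal(nrow(kept), 2)
  bad <- make_snvs(1, impact = "medium")
  expect_error(select_deleterious(bad), "medium")
})

test_that("pair partition counts, proportions and symmetry", {
  pt <- make_snvs(9, pos = 1:9, impact = "HIGH")
  pdo <- make_snvs(8, pos = c(1:7, 100), impact = "HIGH")
  pc <- partition_pair(pt, pdo)
  expect_length(pc$shared, 7)
  expect_length(pc$private_pt, 2)
  expect_length(pc$private_pdo, 1)
  expect_equal(unname(pc$proportions_pt["shared"]), 7 / 9)
  expect_equal(unname(pc$proportions_pdo["shared"]), 7 / 8)
  # swapping sides swaps the private labels but not the shared set
  sw <- partition_pair(pdo, pt)
  expect_setequal(sw$shared, pc$shared)
  expect_setequal(sw$private_pt, pc$private_pdo)
  expect_setequal(sw$private_pdo, pc$private_pt)
  expect_equal(sw$chi2_p, pc$chi2_p)
  # identical and disjoint sets
  same <- partition_pair(pt, pt)
  expect_equal(unname(same$proportions_pt["shared"]), 1)
  expect_length(same$private_pt, 0)
  disj <- partition_pair(make_snvs(3, pos = 1:3),
                         make_snvs(3, pos = 11:13))
  expect_length(disj$shared, 0)
  expect_equal(unname(disj$proportions_pt["shared"]), 0)
  expect_error(partition_pair(pt[0, ], pdo[0, ]), "empty")
})

test_that("clonality correction recovers cancer cell fractions", {
  mk <- function(af) validate_snv_table(data.frame(
    chrom = "chr1", pos = 1, ref = "C", alt = "T", tumor_coverage = 1000,
    tumor_alt_reads = round(af * 1000), normal_alt_reads = 0,
    gene = "G", impact = "HIGH"))
  # fully clonal het in a pure diploid sample
  r <- compute_clonality(mk(0.5), purity = 1, cnA = 1, cnB = 1)
  expect_equal(r$multiplicity, 1)
  expect_equal(r$ccf, 1)
  # AF 0.25 at purity 0.5: (0.25 * 2) / (0.5 * 1) = 1
  expect_equal(compute_clonality(mk(0.25), 0.5, 1, 1)$ccf, 1)
  # AF 0.125 at purity 0.5: ccf 0.5
  expect_equal(compute_clonality(mk(0.125), 0.5, 1, 1)$ccf, 0.5)
  expect_error(compute_clonality(mk(0.5), 0), "purity")
  # diploid limit: ccf * purity / 2 reproduces AF for m = 1
  af <- c(0.1, 0.2, 0.3)
  tab <- validate_snv_table(data.frame(
    chrom = "chr1", pos = 1:3, ref = "C", alt = "T",
    tumor_coverage = 1000, tumor_alt_reads = af * 1000,
    normal_alt_reads = 0, gene = "G", impact = "HIGH"))
  r2 <- compute_clonality(tab, purity = 0.8, cnA = 1, cnB = 1)
  expect_equal(r2$ccf * 0.8 / 2, af, tolerance = 1e-12)
  # multiplicity is clamped by the major allele copy number
  r3 <- compute_clonality(mk(0.9), purity = 1, cnA = 2, cnB = 1)
  expect_lte(r3$multiplicity, 2)
  expect_gte(r3$multiplicity, 1)
})

test_that("shared/private allelic-fraction comparison", {
  expect_equal(compare_af_distributions(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compare_af_distributions(c(.5, .52, .48, .51),
                                        c(.1, .12, .08, .11)),
               0.0286, tolerance = 1e-3)
  expect_error(compare_af_distributions(numeric(0), 1), "non-empty")
  # planted one-SD shift is detected at n = 50 per group
  set.seed(42)
  shared <- rnorm(50, 0.4, 0.1)
  private <- rnorm(50, 0.3, 0.1)
  expect_lt(compare_af_distributions(shared, private), 0.05)
})

test_that("clonality correlation over shared SNVs", {
  x <- c(0.2, 0.5, 0.9, 1)
  expect_equal(clonality_correlation(x, x)$r, 1)
  expect_equal(clonality_correlation(x, 1 - x + 0.1)$r, -1)
  expect_error(clonality_correlation(x[1:2], x[1:2]), "at least 3")
  set.seed(7)
  n <- 200
  pt <- runif(n, 0.1, 1)
  pdo <- 0.8 * scale(pt)[, 1] + sqrt(1 - 0.64) * rnorm(n)
  est <- clonality_correlation(pt, pdo)
  expect_lt(abs(est$r - 0.8), 0.1)
  expect_lt(est$p, 1e-10)
})

test_that("longitudinal clonality shift and lost-SNV subclonality", {
  base <- data.frame(key = paste0("k", 1:6),
                     ccf = c(1, 0.9, 0.8, 0.3, 0.2, 0.25))
  # relapse identical to baseline
  shift0 <- longitudinal_clonality_shift(base, base)
  expect_equal(shift0$p_shift, 1)
  expect_length(shift0$lost_snvs, 0)
  expect_true(shift0$paired)
  # disjoint 4v4, baseline strictly subclonal: exact unpaired p
  b <- data.frame(key = paste0("a", 1:4), ccf = c(.1, .2, .15, .25))
  r <- data.frame(key = paste0("b", 1:4), ccf = c(.9, .95, 1, .85))
  expect_warning(sh <- longitudinal_clonality_shift(b, r), "unpaired")
  expect_false(sh$paired)
  expect_equal(sh$p_shift, 0.0286, tolerance = 1e-3)
  # planted: lost SNVs subclonal (CCF 0.2) vs conserved clonal (0.8)
  set.seed(3)
  n <- 100
  kept_keys <- paste0("s", 1:n)
  lost_keys <- paste0("l", 1:n)
  base2 <- data.frame(key = c(kept_keys, lost_keys),
                      ccf = c(pmin(rnorm(n, 0.8, 0.1), 1),
                              pmax(rnorm(n, 0.2, 0.1), 0)))
  rel2 <- data.frame(key = kept_keys, ccf = pmin(rnorm(n, 0.85, 0.1), 1))
  sh2 <- longitudinal_clonality_shift(base2, rel2)
  expect_setequal(sh2$lost_snvs, lost_keys)
  expect_lt(sh2$p_lost_vs_kept, 0.01)
})
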