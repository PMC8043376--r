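test_that("expected counts distribute the focal total in reference proportions", {
  expect_equal(expected_counts(c(298, 44), c(61000, 24500)), c(244, 98))
  expect_equal(expected_counts(c(100, 0), c(50, 50)), c(50, 50))
  expect_equal(expected_counts(c(0, 0), c(10, 10)), c(0, 0))
  expect_error(expected_counts(c(1, 2), c(0, 0)), "no reference population")
  expect_error(expected_counts(c(1, 2, 3), c(1, 2)), "same length")
})

test_that("expected counts conserve the focal total", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    f <- sample(0:500, k, replace = TRUE)
    o <- sample(1:100000, k, replace = TRUE)
    expect_equal(sum(expected_counts(f, o)), sum(f), tolerance = 1e-12)
  }
})

test_that("2x2 exact test matches hand-enumerated and degenerate cases", {
  # margins (4,4)/(4,4): 5 tables, those at least as extreme sum to 34/70
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3))), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(10, 10), c(10, 10))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(7, 0))), 1)   # zero column
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(7, 2))), 1)   # zero row
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))), "negative")
})

test_that("2x2 exact test agrees with dhyper and fisher.test oracles", {
  set.seed(42)
  for (i in 1:200) {
    pr <- runif(1, 0.05, 0.95)
    tab <- random_table(sample(1:40, 1), sample(1:40, 1), 2, c(pr, 1 - pr))
    p <- fisher_exact_2x2(tab)
    expect_equal(p, oracle_fisher_2x2(tab), tolerance = 1e-9)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  # large reference margins must not overflow
  big <- rbind(c(298, 44), c(610000, 245000))
  expect_equal(fisher_exact_2x2(big), oracle_fisher_2x2(big),
               tolerance = 1e-9)
})

test_that("2x2 p-value is largest when focal matches the reference proportion", {
  for (others in list(c(50, 50), c(90, 10), c(500, 1500))) {
    n1 <- 20
    p <- vapply(0:n1, function(k) {
      fisher_exact_2x2(rbind(c(k, n1 - k), others))
    }, numeric(1))
    modal <- round(n1 * others[1] / sum(others))
    # p never decreases as the focal cell moves toward the modal cell
    expect_true(all(diff(p[seq_len(modal + 1)]) >= -1e-12))
    expect_true(all(diff(p[(modal + 1):(n1 + 1)]) <= 1e-12))
  }
})

test_that("2xK exact test handles ties, degeneracy, and reduces to 2x2", {
  expect_equal(fisher_exact_2xk(rbind(c(1, 1, 1), c(1, 1, 1))), 1)
  expect_equal(fisher_exact_2xk(rbind(c(0, 0, 0), c(3, 2, 2))), 1)
  expect_error(fisher_exact_2xk(rbind(c(1, -1, 0), c(1, 1, 1))), "negative")
  set.seed(7)
  for (i in 1:50) {
    tab <- random_table(sample(1:30, 1), sample(1:30, 1), 2)
    expect_equal(fisher_exact_2xk(tab), fisher_exact_2x2(tab),
                 tolerance = 1e-12)
  }
})

test_that("2x3 exact test matches the brute-force enumeration oracle", {
  expect_equal(fisher_exact_2xk(rbind(c(5, 0, 0), c(0, 5, 5))),
               oracle_fisher_2x3(rbind(c(5, 0, 0), c(0, 5, 5))),
               tolerance = 1e-9)
  set.seed(99)
  for (i in 1:40) {
    pr <- as.vector(stats::rmultinom(1, 30, rep(1 / 3, 3)) + 1) / 33
    tab <- random_table(sample(1:20, 1), sample(1:5000, 1), 3, pr)
    expect_equal(fisher_exact_2xk(tab), oracle_fisher_2x3(tab),
                 tolerance = 1e-9)
  }
})

test_that("BH step-up reproduces the reported significance calls", {
  tab <- t2d_snp_table()
  allele <- benjamini_hochberg(tab$p_allele_reported, q = 0.05)
  expect_identical(allele, tab$sig_allele_reported)
  expect_identical(sum(allele), 6L)
  geno <- benjamini_hochberg(tab$p_genotype_reported, q = 0.05)
  expect_identical(geno, tab$sig_genotype_reported)
  expect_identical(sum(geno), 4L)
  # borderline p-values excluded by the step-up rule
  expect_false(geno[tab$rsid == "rs1799999"])   # p = 0.039
  expect_false(geno[tab$rsid == "rs2076026"])   # p = 0.016
})

test_that("BH decision properties: order, ties, Bonferroni containment", {
  expect_identical(benjamini_hochberg(rep(1, 10)), rep(FALSE, 10))
  expect_identical(benjamini_hochberg(numeric(0)), logical(0))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:50) {
    p <- round(runif(sample(1:40, 1))^3, 2)   # rounding forces ties
    q <- runif(1, 0.01, 0.2)
    got <- benjamini_hochberg(p, q)
    expect_identical(got, oracle_bh(p, q))
    expect_true(all(got[p <= q / length(p)]))  # contains Bonferroni set
    for (v in unique(p)) expect_length(unique(got[p == v]), 1L)
  }
})

test_that("adjusted residuals satisfy the 2x2 chi-square identity", {
  o <- rbind(c(30, 10), c(10, 30))
  r <- adjusted_residuals(o)
  expect_equal(abs(r), matrix(sqrt(20), 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sign(r), rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  set.seed(21)
  for (i in 1:50) {
    o <- matrix(sample(1:60, 4, replace = TRUE), 2)
    r <- adjusted_residuals(o)
    chi2 <- suppressWarnings(stats::chisq.test(o, correct = FALSE))
    expect_equal(r^2, matrix(chi2$statistic, 2, 2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(r, chi2$stdres, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("adjusted residuals: exact fit, zero-expected cells, sign contract", {
  o <- rbind(c(20, 20), c(20, 20))
  expect_equal(adjusted_residuals(o), matrix(0, 2, 2), ignore_attr = TRUE)
  # zero-expected cells are undefined
  r <- adjusted_residuals(rbind(c(5, 0), c(7, 0)))
  expect_true(all(is.na(r[, 2])))
  expect_error(adjusted_residuals(rbind(c(1, 2), c(3, 4)), matrix(1, 2, 3)),
               "dimension mismatch")
  # focal allele row of the strongest risk-factor SNP: REF excess, ALT deficit
  o <- rbind(focal = c(298, 44),
             expected = round(expected_counts(c(298, 44), c(244, 98))))
  r <- adjusted_residuals(o)
  expect_gt(r["focal", 1], 0)
  expect_lt(r["focal", 2], 0)
})

test_that("genotype residuals of a 2x3 table flag the deviating cells", {
  set.seed(33)
  o <- rbind(c(130, 38, 3), c(88, 68, 15))
  r <- adjusted_residuals(o)
  expect_gt(r[1, 1], 0)   # homozygous-REF excess in the focal row
  expect_lt(r[1, 2], 0)
  # residuals are margin-antisymmetric across the two rows
  expect_equal(r[1, ], -r[2, ], tolerance = 1e-9)
})

test_that("allele-frequency spectrum bins are half-open with closed top bin", {
  keys <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G")
  m <- make_merged(keys,
                   vcf_counts = list(p1 = matrix(c(1, 2, 1), 1)),
                   gme_counts = list(r1 = matrix(c(4, 0, 0), 1)))
  sp <- allele_frequency_spectrum(m, labels = "p1", n_bins = 2)
  expect_equal(unname(sp$counts["p1", ]), c(0, 1))   # AF 0.5 -> upper bin
  sp2 <- allele_frequency_spectrum(m, n_bins = 4, focal = "p1")
  expect_true("others(pooled)" %in% rownames(sp2$counts))
  expect_equal(unname(sp2$counts["others(pooled)", ]), c(1, 0, 0, 0))
})

test_that("spectrum counts sum to the variants with non-absent data", {
  cfg <- sim_config(n_variants = 120, seed = 301, missing_rate = 0.2)
  paths <- simulate_cohort(cfg, tempfile("spec"))
  gn <- read_gnomad_vcf(paths$vcf, default_populations())
  gm <- read_gme_table(paths$gme, default_regions())
  m <- merge_by_key(gn, gm)
  sp <- allele_frequency_spectrum(m, n_bins = 25)
  present <- colSums(!is.na(m$homref))
  expect_equal(rowSums(sp$counts)[m$labels], present[m$labels])
})
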