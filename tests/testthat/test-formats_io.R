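test_that("gnomAD-dialect VCF parsing extracts per-population allele info", {
  p <- write_mini_vcf(c(
    "8\t118184783\trs13266634\tC\tT\t.\t.\tAN_ap=342;AC_ap=44;nhomalt_ap=3",
    "1\t100\trs1\tA\tT\t.\t.\t.",
    "1\t200\trs2\tG\tA,T\t.\t.\tAN_ap=10;AC_ap=1;nhomalt_ap=0",
    "1\t300\trs3\tG\tGA\t.\t.\tAN_ap=10;AC_ap=1;nhomalt_ap=0"
  ))
  cat <- read_gnomad_vcf(p, populations = "ap")
  expect_s3_class(cat, "gnomad_catalog")
  i <- which(cat$keys$rsid == "rs13266634")
  expect_equal(cat$keys$chrom[i], "8")
  expect_equal(cat$keys$pos[i], 118184783L)
  expect_equal(unname(cat$an[i, "ap"]), 342)
  expect_equal(unname(cat$ac[i, "ap"]), 44)
  expect_equal(unname(cat$nhomalt[i, "ap"]), 3)
  # INFO-less line is kept with an absent marker
  expect_true(is.na(cat$an[cat$keys$rsid == "rs1", "ap"]))
  # multi-allelic and indel lines are skipped with counters
  expect_equal(cat$n_records, 2L)
  expect_equal(cat$n_skipped_multiallelic, 1L)
  expect_equal(cat$n_skipped_indel, 1L)
  expect_equal(cat$n_records + cat$n_skipped_multiallelic +
                 cat$n_skipped_indel + cat$n_skipped_other,
               cat$n_data_lines)
})

test_that("VCF allele-info invariants are enforced with the variant named", {
  p <- write_mini_vcf(
    "2\t50\trsX\tC\tT\t.\t.\tAN_ap=342;AC_ap=400;nhomalt_ap=0")
  expect_error(read_gnomad_vcf(p, "ap"), "AC exceeds AN.*2:50:C:T")
  p2 <- write_mini_vcf(
    "2\t50\trsX\tC\tT\t.\t.\tAN_ap=341;AC_ap=10;nhomalt_ap=0")
  expect_error(read_gnomad_vcf(p2, "ap"), "odd AN")
  p3 <- write_mini_vcf(
    "2\t50\trsX\tC\tT\t.\t.\tAN_ap=342;AC_ap=10;nhomalt_ap=8")
  expect_error(read_gnomad_vcf(p3, "ap"), "nhomalt")
})

test_that("genotype reconstruction from allele-level fields", {
  expect_equal(genotype_counts_from_allele_info(342, 44, 3),
               data.frame(homref = 130, het = 38, homalt = 3))
  expect_equal(genotype_counts_from_allele_info(342, 272, 113),
               data.frame(homref = 12, het = 46, homalt = 113))
  expect_equal(genotype_counts_from_allele_info(0, 0, 0),
               data.frame(homref = 0, het = 0, homalt = 0))
  expect_error(genotype_counts_from_allele_info(7, 2, 1), "odd AN")
  expect_error(genotype_counts_from_allele_info(10, 12, 1), "AC exceeds")
})

test_that("genotype reconstruction round-trips the implied allele counts", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(1:500, 1)
    p <- runif(1)
    g <- as.vector(stats::rmultinom(1, n, c((1 - p)^2, 2 * p * (1 - p),
                                            p^2)))
    an <- 2 * n; ac <- 2 * g[3] + g[2]
    got <- genotype_counts_from_allele_info(an, ac, g[3])
    expect_equal(unlist(got, use.names = FALSE), g)
    expect_equal(2 * got$homalt + got$het, ac)                 # ALT
    expect_equal(2 * got$homref + got$het, an - ac)            # REF
  }
})

test_that("genotype-table parsing handles triplets, absent cells and errors", {
  regions <- c("ap", "r2")
  p <- write_mini_gme(c("8\t118184783\tC\tT\t130,38,3\t.",
                        "1\t5\tA\tG\t.\t10,0,0"), regions)
  cat <- read_gme_table(p, regions)
  expect_s3_class(cat, "gme_catalog")
  expect_equal(unname(cat$homref[1, "ap"]), 130)
  expect_equal(unname(cat$het[1, "ap"]), 38)
  expect_equal(unname(cat$homalt[1, "ap"]), 3)
  expect_true(is.na(cat$homref[1, "r2"]))
  expect_true(is.na(cat$homref[2, "ap"]))

  bad2 <- write_mini_gme("1\t5\tA\tG\t10,3\t.", regions)
  expect_error(read_gme_table(bad2, regions), "triplet")
  badneg <- write_mini_gme("1\t5\tA\tG\t10,-1,0\t.", regions)
  expect_error(read_gme_table(badneg, regions), "negative")
  badint <- write_mini_gme("1\t5\tA\tG\t10,x,0\t.", regions)
  expect_error(read_gme_table(badint, regions), "non-integer")
  expect_error(read_gme_table(p, c("ap", "missing_region")),
               "missing column")
})

test_that("clinical-annotation parsing keeps labels verbatim and duplicates", {
  p <- write_mini_clinvar(c(
    "8\t118184783\tC\tT\trs13266634\tSLC30A8\tc.973C>T (p.Arg325Trp)\trisk factor",
    "11\t17409572\tT\tC\trs5219\tKCNJ11\tc.67A>G (p.Lys23Glu)\tdrug response",
    "11\t17409572\tT\tC\trs5219\tKCNJ11\tother submission\tBenign"
  ))
  ann <- read_clinvar_table(p)
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$significance[1], "risk factor")
  expect_equal(ann$significance[2], "drug response")   # no normalisation
  expect_equal(sum(ann$rsid == "rs5219"), 2L)          # duplicates kept

  empty <- write_mini_clinvar(character(0))
  expect_equal(nrow(read_clinvar_table(empty)), 0L)
  noschema <- tempfile()
  writeLines("chrom\tpos\tref\talt", noschema)
  expect_error(read_clinvar_table(noschema), "missing column")
})

test_that("report writing rounds p-values for display and keeps precision in JSON", {
  res <- data.frame(
    chrom = "8", pos = 118184783L, ref = "C", alt = "T",
    rsid = "rs13266634", gene = "SLC30A8", change = "c.973C>T",
    significance = "risk factor",
    obs_ref = 298, obs_alt = 44, exp_ref = 244, exp_alt = 98,
    p_allele = 0.0004,
    obs_homref = 130, obs_het = 38, obs_homalt = 3,
    exp_homref = 88, exp_het = 68, exp_homalt = 15, p_genotype = 0.0004,
    bh_allele = TRUE, bh_genotype = TRUE, clinically_significant = TRUE,
    stringsAsFactors = FALSE
  )
  dir <- tempfile("rep")
  paths <- write_report(res, dir, funnel = list(n_tested = 1))
  tsv <- read.delim(paths[["tsv"]], check.names = FALSE,
                    colClasses = "character")
  expect_equal(tsv$p_allele, "0.000")            # display rounding
  expect_equal(tsv$marks, "*#§")                 # mark rendering
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(js$results$p_allele, 0.0004)      # full precision retained
  expect_equal(js$funnel$n_tested, 1)
})

test_that("report writing with no rows still emits header and funnel", {
  res <- data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), rsid = character(0), gene = character(0),
    change = character(0), significance = character(0),
    obs_ref = numeric(0), obs_alt = numeric(0), exp_ref = numeric(0),
    exp_alt = numeric(0), p_allele = numeric(0), obs_homref = numeric(0),
    obs_het = numeric(0), obs_homalt = numeric(0),
    exp_homref = numeric(0), exp_het = numeric(0),
    exp_homalt = numeric(0), p_genotype = numeric(0),
    bh_allele = logical(0), bh_genotype = logical(0),
    clinically_significant = logical(0), stringsAsFactors = FALSE
  )
  dir <- tempfile("rep0")
  paths <- write_report(res, dir, funnel = list(n_tested = 0))
  lines <- readLines(paths[["tsv"]])
  expect_length(lines, 1L)                        # header only
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(js$funnel$n_tested, 0)
})

test_that("written cohorts re-read to identical counts (round trip)", {
  cfg <- sim_config(n_variants = 60, seed = 77, missing_rate = 0.1)
  dir <- tempfile("rt")
  paths <- simulate_cohort(cfg, dir)
  gn1 <- read_gnomad_vcf(paths$vcf, default_populations())
  gm1 <- read_gme_table(paths$gme, default_regions())
  # re-simulating with the same config is byte-identical, so re-reading
  # must reproduce the same catalogues
  dir2 <- tempfile("rt2")
  paths2 <- simulate_cohort(cfg, dir2)
  expect_identical(readLines(paths$vcf), readLines(paths2$vcf))
  gn2 <- read_gnomad_vcf(paths2$vcf, default_populations())
  expect_identical(gn1$an, gn2$an)
  expect_identical(gn1$ac, gn2$ac)
  # every present cell accounts for the full label cohort
  lab <- default_labels()
  for (r in default_regions()) {
    tot <- gm1$homref[, r] + gm1$het[, r] + gm1$homalt[, r]
    expect_true(all(is.na(tot) | tot == lab$n[lab$name == r]))
  }
  expect_true(all(is.na(gn1$an) | gn1$an == 10000))
})
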