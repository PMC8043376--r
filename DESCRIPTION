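Package: exomediff
Title: Population-Differentiated Disease Variants from Integrated Exome
    Catalogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Finds disease-associated single-nucleotide variants whose allele
    or genotype frequencies deviate in a focal population. Integrates a
    gnomAD-dialect VCF (per-population AN/AC/nhomalt INFO fields) with a
    region-level genotype-count table and a clinical-annotation table, removes
    rare variants, aggregates focal-versus-other-population allele and genotype
    counts, computes expected counts under frequency homogeneity, runs exact
    tests (Fisher 2x2 and its 2xK extension) with Benjamini-Hochberg false
    discovery control, and characterises significant variants with adjusted
    standardized residuals. Ships a Hardy-Weinberg cohort simulator with
    planted frequency deviations for end-to-end validation and a bundled
    18-SNP type 2 diabetes reference set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
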