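## Bundled reference set: 18 type 2 diabetes-associated SNPs (GRCh37) with
## observed Arabian-Peninsula genotype counts, pooled-reference expected
## counts, reported exact-test p-values and clinical-significance labels.

#' Default population roster of the gnomAD-dialect catalogue
#' @return Character vector of the eight exome population labels.
#' @export
default_populations <- function() {
  c("afr", "amr", "asj", "eas", "fin", "nfe", "sas", "oth")
}

#' Default region roster of the genotype-table catalogue
#' @return Character vector of the seven Greater-Middle-East region labels.
#' @export
default_regions <- function() {
  c("NorthEastAfrica", "NorthWestAfrica", "ArabianPeninsula", "Israel",
    "SyrianDesert", "TurkishPeninsula", "CentralAsia")
}

#' Reference table of 18 T2D-associated SNPs
#'
#' A curated set of 18 type 2 diabetes-associated biallelic SNVs (GRCh37)
#' found in both a worldwide exome catalogue and a Greater-Middle-East
#' genotype catalogue and carrying clinical annotations. For each SNP the
#' table records the observed Arabian-Peninsula genotype counts, the focal
#' counts expected if the Arabian Peninsula matched the pooled remaining
#' populations (rounded to integers), the reported focal-vs-others exact-test
#' p-values for the allele and genotype comparisons (3 decimals), and the
#' reported significance calls at FDR level 0.05.
#'
#' Observed allele counts are implied by the genotype counts
#' (`REF = 2*homref + het`, `ALT = 2*homalt + het`).
#'
#' @return A data frame with one row per SNP.
#' @export
t2d_snp_table <- function() {
  df <- data.frame(
    rsid = c("rs41265094", "rs1801276", "rs1044498", "rs1799999",
             "rs13266634", "rs5219", "rs566325901", "rs121434581",
             "rs1801483", "rs41309435", "rs776435289", "rs199761368",
             "rs139125633", "rs35588791", "rs1799816", "rs142204928",
             "rs147638455", "rs2076026"),
    chrom = c("2", "2", "6", "7", "8", "11", "12", "17", "17", "19", "19",
              "19", "19", "19", "19", "20", "20", "20"),
    pos = c(227661003L, 227661921L, 132172368L, 113518434L, 118184783L,
            17409572L, 121177120L, 7189048L, 79767715L, 40741862L,
            40743996L, 40744854L, 40761070L, 40762915L, 7125518L,
            43043159L, 43058267L, 43942676L),
    ref = c("C", "C", "A", "C", "C", "T", "A", "G", "G", "C", "C", "G",
            "G", "G", "C", "G", "A", "T"),
    alt = c("G", "G", "C", "A", "T", "C", "G", "A", "A", "A", "G", "A",
            "A", "A", "T", "A", "G", "C"),
    gene = c("IRS1", "IRS1", "ENPP1", "PPP1R3A", "SLC30A8", "KCNJ11",
             "ACADS", "SLC2A4", "GCGR", "AKT2", "AKT2", "AKT2", "AKT2",
             "AKT2", "INSR", "HNF4A", "HNF4A", "RBPJL"),
    change = c("c.2452G>C (p.Gly818Arg)", "c.1534G>C (p.Ala512Pro)",
               "c.517A>C (p.Lys173Gln)", "c.2713G>T (p.Asp905Tyr)",
               "c.973C>T (p.Arg325Trp)", "c.67A>G (p.Lys23Glu)",
               "c.1108A>G (p.Met370Val)", "c.1147G>A (p.Val383Ile)",
               "c.118G>A (p.Gly40Ser)", "c.1110G>T (p.Pro370=)",
               "c.711G>C (p.Leu237=)", "c.666C>T (p.His222=)",
               "c.282C>T (p.Asp94=)", "c.93C>T (p.Ser31=)",
               "c.3034G>A (p.Val1012Met)", "c.439G>A (p.Val147Ile)",
               "c.1321A>G (p.Ile441Val)", "c.759T>C (p.Ala253=)"),
    significance = c("Likely benign", "Benign", "Benign",
                     "Uncertain significance", "risk factor",
                     "drug response",
                     "Conflicting interpretations of pathogenicity",
                     "Uncertain significance", "Benign", "Benign",
                     "Likely benign", "Benign", "Likely benign", "Benign",
                     "Conflicting interpretations of pathogenicity",
                     "Conflicting interpretations of pathogenicity",
                     "Uncertain significance", "Benign"),
    obs_homref = c(171L, 171L, 92L, 117L, 130L, 12L, 170L, 167L, 106L,
                   171L, 171L, 170L, 171L, 171L, 164L, 170L, 160L, 159L),
    obs_het = c(0L, 0L, 61L, 51L, 38L, 46L, 1L, 3L, 13L, 0L, 0L, 1L, 0L,
                0L, 7L, 1L, 11L, 11L),
    obs_homalt = c(0L, 0L, 18L, 3L, 3L, 113L, 0L, 1L, 1L, 0L, 0L, 0L, 0L,
                   0L, 0L, 0L, 0L, 1L),
    exp_ref = c(339L, 337L, 275L, 267L, 244L, 123L, 341L, 341L, 238L,
                341L, 342L, 341L, 342L, 341L, 339L, 341L, 342L, 311L),
    exp_alt = c(3L, 5L, 67L, 75L, 98L, 219L, 1L, 1L, 2L, 1L, 0L, 1L, 0L,
                1L, 3L, 1L, 0L, 31L),
    exp_homref = c(168L, 166L, 115L, 109L, 88L, 23L, 170L, 170L, 118L,
                   170L, 171L, 170L, 171L, 170L, 168L, 170L, 171L, 143L),
    exp_het = c(3L, 5L, 45L, 49L, 68L, 76L, 1L, 1L, 2L, 1L, 0L, 1L, 0L,
                1L, 3L, 1L, 0L, 25L),
    exp_homalt = c(0L, 0L, 11L, 13L, 15L, 72L, 0L, 0L, 0L, 0L, 0L, 0L,
                   0L, 0L, 0L, 0L, 0L, 3L),
    p_allele_reported = c(0.249, 0.062, 0.009, 0.099, 0.000, 0.000, 1.000,
                          0.217, 0.002, 1.000, 1.000, 1.000, 1.000, 1.000,
                          0.340, 1.000, 0.001, 0.007),
    p_genotype_reported = c(0.248, 0.061, 0.037, 0.039, 0.000, 0.000,
                            1.000, 0.371, 0.003, 1.000, 1.000, 1.000,
                            1.000, 1.000, 0.337, 1.000, 0.001, 0.016),
    stringsAsFactors = FALSE
  )
  df$obs_ref <- 2L * df$obs_homref + df$obs_het
  df$obs_alt <- 2L * df$obs_homalt + df$obs_het
  df$sig_allele_reported <- df$rsid %in%
    c("rs1044498", "rs13266634", "rs5219", "rs1801483", "rs147638455",
      "rs2076026")
  df$sig_genotype_reported <- df$rsid %in%
    c("rs13266634", "rs5219", "rs1801483", "rs147638455")
  df$clinical_reported <- df$rsid %in% c("rs13266634", "rs5219")
  df
}

# Reference-side ("others") genotype composition used by the bundled
# fixture. The pooled composition reproduces the reference expected
# proportions at roughly 250x the focal cohort size; rs5219's reported
# expected allele and genotype rows are mutually inconsistent by one count
# (independent rounding), so for that SNP a composition is used whose
# implied allele AND genotype expectations are each within +-0.45 of the
# reported cells.
fixture_others_genotypes <- function(row) {
  if (row$rsid == "rs5219") {
    return(c(5477, 17726, 16802))
  }
  250 * c(row$exp_homref, row$exp_het, row$exp_homalt)
}

#' Write the bundled 18-SNP reference cohort as pipeline input files
#'
#' Materialises [t2d_snp_table()] as the three input dialects the pipeline
#' consumes: a gnomAD-dialect VCF carrying the pooled-reference
#' ("others") genotypes split over exome populations, a genotype-count table
#' whose Arabian-Peninsula column holds the observed focal triplets (other
#' regions absent), and a clinical-annotation table.
#'
#' The reference side of each SNP is distributed so that every SNP exceeds
#' 1% ALT frequency in at least one population: SNPs rare in the pooled
#' reference have their carriers concentrated in a 5,000-individual
#' population, and the two SNPs with no ALT allele at all receive a single
#' heterozygous carrier in a 49-individual population (frequency 1/98).
#' These placements shift every expected count by less than 0.005, so the
#' expected cells of [t2d_snp_table()] are reproduced to well within their
#' printed rounding.
#'
#' @param dir Directory to write into (created if needed).
#' @return Invisibly, a named list with elements `vcf`, `gme`, `clinvar`
#'   (file paths) and `table` (the reference data frame).
#' @export
t2d_reference_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- t2d_snp_table()
  ord <- order(as.numeric(tab$chrom), tab$pos)
  tab <- tab[ord, , drop = FALSE]

  pops <- default_populations()
  regions <- default_regions()
  focal <- "ArabianPeninsula"

  info <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    g <- fixture_others_genotypes(row)
    alt_alleles <- 2 * g[3L] + g[2L]
    af <- alt_alleles / (2 * sum(g))
    cells <- list()
    if (alt_alleles == 0) {
      cells$nfe <- g
      cells$oth <- c(48, 1, 0)          # one carrier, AF 1/98 > 0.01
    } else if (af > 0.011) {
      cells$nfe <- g
    } else {
      carriers <- g[2L] + g[3L]
      cells$fin <- c(5000 - carriers, g[2L], g[3L])
      cells$nfe <- c(g[1L] - (5000 - carriers), 0, 0)
    }
    info[i] <- paste(vapply(names(cells), function(p) {
      gc <- cells[[p]]
      sprintf("AN_%s=%d;AC_%s=%d;nhomalt_%s=%d",
              p, as.integer(2 * sum(gc)),
              p, as.integer(2 * gc[3L] + gc[2L]),
              p, as.integer(gc[3L]))
    }, character(1)), collapse = ";")
  }

  vcf_path <- file.path(dir, "t2d_reference.vcf")
  write_simple_vcf(tab, info, pops, vcf_path)

  gme_path <- file.path(dir, "t2d_reference_gme.tsv")
  gme <- data.frame(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                    alt = tab$alt, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (r in regions) gme[[r]] <- "."
  gme[[focal]] <- sprintf("%d,%d,%d", tab$obs_homref, tab$obs_het,
                          tab$obs_homalt)
  utils::write.table(gme, gme_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  clinvar_path <- file.path(dir, "t2d_reference_clinvar.tsv")
  utils::write.table(
    tab[, c("chrom", "pos", "ref", "alt", "rsid", "gene", "change",
            "significance")],
    clinvar_path, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(vcf = vcf_path, gme = gme_path, clinvar = clinvar_path,
                 table = tab))
}

# internal: write a minimal VCF (shared by the fixture and the simulator)
write_simple_vcf <- function(keys, info, populations, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh37",
    unlist(lapply(populations, function(p) c(
      sprintf("##INFO=<ID=AN_%s,Number=1,Type=Integer,Description=\"Total number of alleles in %s\">", p, p),
      sprintf("##INFO=<ID=AC_%s,Number=1,Type=Integer,Description=\"Alternate allele count in %s\">", p, p),
      sprintf("##INFO=<ID=nhomalt_%s,Number=1,Type=Integer,Description=\"Homozygous-ALT individuals in %s\">", p, p)
    ))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rsid <- if ("rsid" %in% names(keys)) keys$rsid else keys$id
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                   keys$chrom, keys$pos, rsid, keys$ref, keys$alt,
                   ifelse(info == "", ".", info))
  writeLines(c(header, lines), path)
  invisible(path)
}
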