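## Pipeline orchestration: read -> merge -> filter -> annotate -> aggregate ->
## exact tests -> FDR -> residuals -> report, with a stage-count funnel.

#' Pipeline configuration
#'
#' @param vcf_path,gme_path,clinvar_path Input file paths.
#' @param output_dir Directory for the report files.
#' @param focal Focal population/region label.
#' @param populations VCF-side population roster.
#' @param regions Table-side region roster.
#' @param af_threshold Common-variant ALT-frequency threshold in (0, 0.5\].
#' @param af_filter_mode `"any"` (default) or `"all"`; see
#'   [filter_common()].
#' @param q FDR level for the Benjamini-Hochberg correction, in (0, 1).
#' @param clinical_labels Clinical-significance strings that count as
#'   clinically significant.
#' @param comparison Which table the exact tests are run on.
#'   `"expected"` (default) tests the observed focal row against the
#'   (rounded) focal row expected under frequency homogeneity — a
#'   focal-sized comparison that weighs both rows equally; `"others"` tests
#'   the observed focal row directly against the pooled reference counts,
#'   which at large reference sizes approaches a one-sample exact test of
#'   the focal counts against fixed reference proportions and yields far
#'   smaller p-values for the same deviation.
#' @param n_bins Bins of the allele-frequency spectrum written with the
#'   report.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(vcf_path, gme_path, clinvar_path,
                            output_dir = ".",
                            focal = "ArabianPeninsula",
                            populations = default_populations(),
                            regions = default_regions(),
                            af_threshold = 0.01,
                            af_filter_mode = c("any", "all"),
                            q = 0.05,
                            clinical_labels = c("risk factor",
                                                "drug response"),
                            comparison = c("expected", "others"),
                            n_bins = 50L) {
  stopifnot(af_threshold > 0, af_threshold <= 0.5, q > 0, q < 1,
            n_bins >= 1)
  af_filter_mode <- match.arg(af_filter_mode)
  comparison <- match.arg(comparison)
  if (!focal %in% c(populations, regions)) {
    stop("focal label '", focal, "' is in neither roster", call. = FALSE)
  }
  structure(list(vcf_path = vcf_path, gme_path = gme_path,
                 clinvar_path = clinvar_path, output_dir = output_dir,
                 focal = focal, populations = populations,
                 regions = regions, af_threshold = af_threshold,
                 af_filter_mode = af_filter_mode, q = q,
                 clinical_labels = clinical_labels,
                 comparison = comparison,
                 n_bins = as.integer(n_bins)),
            class = "pipeline_config")
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full focal-deviation pipeline
#'
#' Executes, in order: read the three inputs; inner-merge the two catalogues
#' on the variant key; drop variants whose focal cell is absent (they cannot
#' be compared); remove rare variants; intersect with the clinical
#' annotations; aggregate each remaining variant into focal-vs-others allele
#' (2x2) and genotype (2x3) tables with expected focal counts; run both
#' exact tests; apply Benjamini-Hochberg correction separately to the allele
#' and the genotype families; compute adjusted standardized residuals for
#' the significant variants; flag clinical significance; and write the
#' TSV/JSON report, an audit TSV of the tested variants and the
#' allele-frequency spectrum. Deterministic given inputs and config; an
#' empty stage produces empty downstream results, never an error.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with `results` (one row per tested
#'   variant-annotation pair), `funnel` (named stage counts), `residuals`
#'   (named list, significant variants only), `spectrum`, and the report
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gn <- read_gnomad_vcf(config$vcf_path, config$populations)
  log_msg("VCF catalogue: ", gn$n_records, " biallelic SNVs (",
          gn$n_skipped_multiallelic, " multi-allelic, ",
          gn$n_skipped_indel, " indel lines skipped)")
  gm <- read_gme_table(config$gme_path, config$regions)
  log_msg("genotype-table catalogue: ", gm$n_records, " records")
  ann <- read_clinvar_table(config$clinvar_path)
  log_msg("clinical annotations: ", nrow(ann), " rows")

  merged <- merge_by_key(gn, gm)
  log_msg("merged on variant key: ", merged$funnel$n_merged, " variants")

  # variants with an absent focal cell cannot enter the comparison
  if (config$focal %in% merged$labels) {
    called <- !is.na(merged$homref[, config$focal])
  } else {
    stop("focal label '", config$focal, "' not present after merge",
         call. = FALSE)
  }
  merged <- subset_merged(merged, which(called))
  merged$funnel$n_focal_called <- sum(called)

  common <- filter_common(merged, threshold = config$af_threshold,
                          mode = config$af_filter_mode)
  log_msg("common variants (ALT AF > ", config$af_threshold, ", mode ",
          config$af_filter_mode, "): ", common$funnel$n_common)

  annotated <- intersect_clinvar(common, ann)
  log_msg("clinically annotated: ", annotated$funnel$n_annotated)

  nt <- annotated$funnel$n_annotated
  results <- data.frame(
    chrom = character(nt), pos = integer(nt), ref = character(nt),
    alt = character(nt), rsid = character(nt), gene = character(nt),
    change = character(nt), significance = character(nt),
    obs_ref = numeric(nt), obs_alt = numeric(nt),
    exp_ref = numeric(nt), exp_alt = numeric(nt), p_allele = numeric(nt),
    obs_homref = numeric(nt), obs_het = numeric(nt),
    obs_homalt = numeric(nt),
    exp_homref = numeric(nt), exp_het = numeric(nt),
    exp_homalt = numeric(nt), p_genotype = numeric(nt),
    stringsAsFactors = FALSE
  )
  # tables the exact tests (and residuals) run on, per the comparison mode:
  # observed focal row against either the rounded expected focal row or the
  # pooled others row
  test_tables <- function(agg) {
    if (config$comparison == "expected") {
      ae <- agg$allele_expected_focal
      ge <- agg$genotype_expected_focal
      list(allele = rbind(focal = agg$allele_obs["focal", ],
                          expected = if (anyNA(ae)) c(0, 0) else round(ae)),
           genotype = rbind(focal = agg$genotype_obs["focal", ],
                            expected = if (anyNA(ge)) c(0, 0, 0) else
                              round(ge)))
    } else {
      list(allele = agg$allele_obs, genotype = agg$genotype_obs)
    }
  }

  tables <- vector("list", nt)
  for (i in seq_len(nt)) {
    agg <- aggregate_focal_vs_others(annotated, config$focal, i)
    tables[[i]] <- test_tables(agg)
    a <- annotated$annotations[i, ]
    results[i, c("chrom", "ref", "alt", "rsid", "gene", "change",
                 "significance")] <-
      c(a$chrom, a$ref, a$alt, a$rsid, a$gene, a$change, a$significance)
    results$pos[i] <- a$pos
    results[i, c("obs_ref", "obs_alt")] <- agg$allele_obs["focal", ]
    results[i, c("exp_ref", "exp_alt")] <- agg$allele_expected_focal
    results[i, c("obs_homref", "obs_het", "obs_homalt")] <-
      agg$genotype_obs["focal", ]
    results[i, c("exp_homref", "exp_het", "exp_homalt")] <-
      agg$genotype_expected_focal
    results$p_allele[i] <- fisher_exact_2x2(tables[[i]]$allele)
    results$p_genotype[i] <- fisher_exact_2xk(tables[[i]]$genotype)
  }

  results$bh_allele <- benjamini_hochberg(results$p_allele, config$q)
  results$bh_genotype <- benjamini_hochberg(results$p_genotype, config$q)
  results$clinically_significant <-
    results$bh_allele & results$significance %in% config$clinical_labels

  # residuals only for variants significant in either family
  sig <- which(results$bh_allele | results$bh_genotype)
  residuals <- stats::setNames(lapply(sig, function(i) {
    list(allele = adjusted_residuals(tables[[i]]$allele),
         genotype = adjusted_residuals(tables[[i]]$genotype))
  }), results$rsid[sig])

  funnel <- c(annotated$funnel, list(
    n_tested = nt,
    n_sig_allele = sum(results$bh_allele),
    n_sig_genotype = sum(results$bh_genotype),
    n_clinical = sum(results$clinically_significant)
  ))
  log_msg("tested: ", nt, "; significant (allele/genotype): ",
          funnel$n_sig_allele, "/", funnel$n_sig_genotype,
          "; clinically significant: ", funnel$n_clinical)

  paths <- write_report(results, config$output_dir, funnel = funnel,
                        residuals = residuals)

  spectrum <- allele_frequency_spectrum(common, n_bins = config$n_bins,
                                        focal = config$focal)
  spec_path <- file.path(config$output_dir, "spectrum.tsv")
  spec_df <- data.frame(label = rownames(spectrum$counts),
                        spectrum$counts, check.names = FALSE)
  utils::write.table(spec_df, spec_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # audit trail of the tested variants
  audit_path <- file.path(config$output_dir, "tested_variants.tsv")
  utils::write.table(results, audit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(results = results, funnel = funnel,
                 residuals = residuals, spectrum = spectrum,
                 paths = c(paths, spectrum = spec_path,
                           audit = audit_path)))
}
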