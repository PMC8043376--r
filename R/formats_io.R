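## Readers and writers for the three input dialects and the report outputs.
##
## Catalogue objects share one internal layout: a `keys` data frame
## (chrom, pos, ref, alt, rsid) plus per-label count matrices aligned to it.
## Absent (variant, label) cells are NA.

.bases <- c("A", "C", "G", "T")
.autosomes <- as.character(1:22)

variant_key_string <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read a gnomAD-dialect VCF with per-population allele counts
#'
#' Parses a VCF (via \pkg{vcfR}) whose INFO field carries, for each requested
#' population `pop`, the integer keys `AN_<pop>` (total called alleles),
#' `AC_<pop>` (ALT allele count) and `nhomalt_<pop>` (ALT-homozygous
#' individuals). Only biallelic autosomal SNVs are kept: multi-allelic lines,
#' indels and non-autosomal records are skipped and counted. A population
#' whose INFO keys are missing on a line is marked absent (`NA`) for that
#' variant.
#'
#' @param path Path to an uncompressed or bgzipped VCF text file.
#' @param populations Character vector of population labels to extract.
#' @return An object of class `"gnomad_catalog"`: list with `keys`
#'   (data frame chrom/pos/ref/alt/rsid), matrices `an`, `ac`, `nhomalt`
#'   (one column per population), `populations`, and skip counters
#'   `n_data_lines`, `n_records`, `n_skipped_multiallelic`,
#'   `n_skipped_indel`, `n_skipped_other`.
#' @export
read_gnomad_vcf <- function(path, populations) {
  stopifnot(length(populations) >= 1L, is.character(populations))
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n_lines <- nrow(fix)
  chrom <- as.character(fix[, "CHROM"])
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (any(is.na(pos))) {
    stop("malformed VCF: non-numeric POS at data line ",
         which(is.na(pos))[1L], call. = FALSE)
  }
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  rsid <- as.character(fix[, "ID"])

  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L |
                       is.na(alt) | alt == "*")
  snv <- !multi & !indel & ref %in% .bases & alt %in% .bases
  keep <- snv & chrom %in% .autosomes
  other <- snv & !keep  # non-autosomal or non-ACGT oddities
  other <- other | (!multi & !indel & !snv)

  grab <- function(key) {
    m <- vapply(populations, function(p) {
      suppressWarnings(as.numeric(
        vcfR::extract.info(v, element = paste0(key, "_", p))
      ))
    }, numeric(n_lines))
    m <- matrix(m, nrow = n_lines,
                dimnames = list(NULL, populations))
    m[keep, , drop = FALSE]
  }
  an <- grab("AN")
  ac <- grab("AC")
  nh <- grab("nhomalt")
  # a population is absent on a line unless all three keys are present
  absent <- is.na(an) | is.na(ac) | is.na(nh)
  an[absent] <- NA; ac[absent] <- NA; nh[absent] <- NA

  keys <- data.frame(chrom = chrom[keep], pos = pos[keep],
                     ref = ref[keep], alt = alt[keep], rsid = rsid[keep],
                     stringsAsFactors = FALSE)
  validate_allele_info(an, ac, nh, keys)

  structure(list(
    keys = keys, an = an, ac = ac, nhomalt = nh,
    populations = populations,
    n_data_lines = n_lines,
    n_records = sum(keep),
    n_skipped_multiallelic = sum(multi),
    n_skipped_indel = sum(indel),
    n_skipped_other = sum(other)
  ), class = "gnomad_catalog")
}

# internal: enforce the AN/AC/nhomalt invariants, naming the first offender
validate_allele_info <- function(an, ac, nh, keys) {
  here <- function(bad) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    with(keys[i[["row"]], ],
         paste0(variant_key_string(chrom, pos, ref, alt)))
  }
  ok <- !is.na(an)
  bad <- ok & (an < 0 | ac < 0 | nh < 0)
  if (any(bad)) stop("negative allele-info field at variant ", here(bad),
                     call. = FALSE)
  bad <- ok & ac > an
  if (any(bad)) stop("AC exceeds AN at variant ", here(bad), call. = FALSE)
  bad <- ok & (an %% 2 != 0)
  if (any(bad)) stop("odd AN (cannot form diploid genotypes) at variant ",
                     here(bad), call. = FALSE)
  bad <- ok & 2 * nh > ac
  if (any(bad)) stop("2*nhomalt exceeds AC at variant ", here(bad),
                     call. = FALSE)
  bad <- ok & (ac - 2 * nh) > (an / 2 - nh)
  if (any(bad)) stop("implied heterozygote count exceeds remaining ",
                     "individuals at variant ", here(bad), call. = FALSE)
  invisible(TRUE)
}

#' Genotype counts implied by allele-level fields
#'
#' Reconstructs the diploid genotype distribution of a population from its
#' allele-level summary: `homalt = nhomalt`, `het = AC - 2*nhomalt`,
#' `homref = AN/2 - het - homalt`. The implied allele counts are then exactly
#' `(AN - AC, AC)`. Inputs are recycled and may contain `NA` (absent cells),
#' which propagate.
#'
#' @param an Total called alleles (non-negative even integer vector).
#' @param ac ALT allele counts.
#' @param nhomalt ALT-homozygous individual counts.
#' @return A data frame with columns `homref`, `het`, `homalt`.
#' @examples
#' genotype_counts_from_allele_info(342, 44, 3)  # 130 / 38 / 3
#' @export
genotype_counts_from_allele_info <- function(an, ac, nhomalt) {
  n <- max(length(an), length(ac), length(nhomalt))
  an <- rep_len(as.numeric(an), n)
  ac <- rep_len(as.numeric(ac), n)
  nh <- rep_len(as.numeric(nhomalt), n)
  ok <- !(is.na(an) | is.na(ac) | is.na(nh))
  if (any(ok & (an < 0 | ac < 0 | nh < 0))) {
    stop("allele-info fields must be non-negative", call. = FALSE)
  }
  if (any(ok & an %% 2 != 0)) {
    stop("odd AN: cannot form diploid genotypes", call. = FALSE)
  }
  if (any(ok & ac > an)) stop("AC exceeds AN", call. = FALSE)
  if (any(ok & 2 * nh > ac)) stop("2*nhomalt exceeds AC", call. = FALSE)
  het <- ac - 2 * nh
  homref <- an / 2 - het - nh
  if (any(ok & homref < 0)) {
    stop("implied homozygous-reference count is negative", call. = FALSE)
  }
  data.frame(homref = homref, het = het, homalt = nh)
}

#' Read a region-level genotype-count table
#'
#' Parses a tab-separated table with header columns `chrom`, `pos`, `ref`,
#' `alt` followed by one column per region, each cell either a comma-joined
#' triplet `homref,het,homalt` of non-negative integers or `"."` for absent
#' data.
#'
#' @param path Path to the TSV file.
#' @param regions Character vector of region column names to extract.
#' @return An object of class `"gme_catalog"`: list with `keys`, matrices
#'   `homref`, `het`, `homalt` (one column per region), `regions`, and
#'   `n_records`.
#' @export
read_gme_table <- function(path, regions) {
  stopifnot(length(regions) >= 1L, is.character(regions))
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(c(need, regions), names(df))
  if (length(miss)) {
    stop("missing column(s) in genotype table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (nrow(df) > 0 && any(is.na(pos))) {
    stop("non-integer pos at row ", which(is.na(pos))[1L], call. = FALSE)
  }
  n <- nrow(df)
  homref <- het <- homalt <-
    matrix(NA_real_, n, length(regions), dimnames = list(NULL, regions))
  for (r in regions) {
    cell <- df[[r]]
    present <- !is.na(cell) & cell != "."
    if (!any(present)) next
    parts <- strsplit(cell[present], ",", fixed = TRUE)
    len <- lengths(parts)
    if (any(len != 3L)) {
      stop("malformed genotype triplet (expected 3 comma-joined integers) ",
           "in region '", r, "' at row ", which(present)[len != 3L][1L],
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(unlist(parts)))
    if (anyNA(vals) || any(vals != round(vals))) {
      stop("non-integer genotype count in region '", r, "'", call. = FALSE)
    }
    if (any(vals < 0)) {
      stop("negative genotype count in region '", r, "'", call. = FALSE)
    }
    m <- matrix(vals, ncol = 3L, byrow = TRUE)
    homref[present, r] <- m[, 1L]
    het[present, r] <- m[, 2L]
    homalt[present, r] <- m[, 3L]
  }
  keys <- data.frame(chrom = df$chrom, pos = pos, ref = df$ref,
                     alt = df$alt,
                     rsid = if ("rsid" %in% names(df)) df$rsid else
                       NA_character_,
                     stringsAsFactors = FALSE)
  structure(list(keys = keys, homref = homref, het = het, homalt = homalt,
                 regions = regions, n_records = n),
            class = "gme_catalog")
}

#' Read a clinical-annotation table
#'
#' Parses a tab-separated export of clinical variant annotations with
#' columns `chrom`, `pos`, `ref`, `alt`, `rsid`, `gene`, `change`,
#' `significance`. Duplicate variant keys are allowed and preserved;
#' significance labels are kept verbatim (no normalisation).
#'
#' @param path Path to the TSV file.
#' @return A data frame, one row per annotation.
#' @export
read_clinvar_table <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "rsid", "gene", "change",
            "significance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in annotation table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  df$pos <- suppressWarnings(as.integer(df$pos))
  if (nrow(df) > 0 && any(is.na(df$pos))) {
    stop("non-integer pos in annotation table", call. = FALSE)
  }
  if (nrow(df) > 0 && any(is.na(df$significance) | df$significance == "")) {
    stop("empty clinical-significance label in annotation table",
         call. = FALSE)
  }
  df
}

#' Write the per-variant report
#'
#' Writes (i) a display TSV, one row per tested variant, with observed and
#' expected allele and genotype counts, both exact-test p-values rounded to
#' three decimals, and the significance marks (`*` clinically significant,
#' `#` allele-test significant after FDR control, `S` genotype-test
#' significant; the genotype mark is written as the section sign), and (ii) a
#' JSON file carrying full-precision p-values, the stage-count funnel, and
#' the adjusted residuals of significant variants.
#'
#' @param results Results data frame as produced by [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; default `"report"`.
#' @param funnel Optional named list of funnel counts.
#' @param residuals Optional named list of residual matrices.
#' @return Invisibly, a named character vector with the `tsv` and `json`
#'   paths.
#' @export
write_report <- function(results, dir, prefix = "report", funnel = NULL,
                         residuals = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  json <- file.path(dir, paste0(prefix, ".json"))

  if (nrow(results) > 0) {
    ord <- order(as.numeric(results$chrom), results$pos)
    results <- results[ord, , drop = FALSE]
  }
  marks <- if (nrow(results) > 0) {
    paste0(ifelse(results$clinically_significant, "*", ""),
           ifelse(results$bh_allele, "#", ""),
           ifelse(results$bh_genotype, "§", ""))
  } else character(0)
  disp <- data.frame(
    rsid = results$rsid, marks = marks,
    chrom = results$chrom, pos = results$pos,
    ref = results$ref, alt = results$alt, gene = results$gene,
    obs_ref = results$obs_ref, obs_alt = results$obs_alt,
    exp_ref = round(results$exp_ref), exp_alt = round(results$exp_alt),
    p_allele = sprintf("%.3f", results$p_allele),
    obs_homref = results$obs_homref, obs_het = results$obs_het,
    obs_homalt = results$obs_homalt,
    exp_homref = round(results$exp_homref),
    exp_het = round(results$exp_het),
    exp_homalt = round(results$exp_homalt),
    p_genotype = sprintf("%.3f", results$p_genotype),
    significance = results$significance,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  con <- file(tsv, open = "w", encoding = "UTF-8")
  utils::write.table(disp, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  payload <- list(funnel = funnel, results = results)
  if (!is.null(residuals)) payload$residuals <- residuals
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
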