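## Merging the two catalogues, rare-variant filtering, clinical intersection
## and focal-vs-others aggregation.

#' Merge two variant catalogues on the exact variant key
#'
#' Inner join of a gnomAD-dialect catalogue and a region-level genotype-count
#' catalogue on `(chrom, pos, ref, alt)` equality. Allele-level fields on the
#' VCF side are first converted to genotype counts with
#' [genotype_counts_from_allele_info()], so the merged object carries one
#' homref/het/homalt triple per (variant, label). Labels must be unique
#' across the union of the two catalogues; a duplicated key inside either
#' catalogue is an error.
#'
#' @param gnomad A `"gnomad_catalog"` from [read_gnomad_vcf()].
#' @param gme A `"gme_catalog"` from [read_gme_table()].
#' @return An object of class `"merged_variants"`: list with `keys`
#'   (chrom/pos/ref/alt/rsid), matrices `homref`, `het`, `homalt` over the
#'   union of labels, `labels`, `source` (named vector, `"vcf"` or
#'   `"table"`), and a `funnel` list (`n_vcf`, `n_table`, `n_merged`).
#' @export
merge_by_key <- function(gnomad, gme) {
  stopifnot(inherits(gnomad, "gnomad_catalog"), inherits(gme, "gme_catalog"))
  if (length(intersect(gnomad$populations, gme$regions))) {
    stop("label collision between catalogues: ",
         paste(intersect(gnomad$populations, gme$regions), collapse = ", "),
         call. = FALSE)
  }
  kg <- with(gnomad$keys, variant_key_string(chrom, pos, ref, alt))
  km <- with(gme$keys, variant_key_string(chrom, pos, ref, alt))
  if (anyDuplicated(kg)) {
    stop("duplicate variant key in VCF catalogue: ",
         kg[duplicated(kg)][1L], call. = FALSE)
  }
  if (anyDuplicated(km)) {
    stop("duplicate variant key in genotype-table catalogue: ",
         km[duplicated(km)][1L], call. = FALSE)
  }

  ig <- which(kg %in% km)
  # genomic order: numeric chromosome then position
  ig <- ig[order(as.numeric(gnomad$keys$chrom[ig]), gnomad$keys$pos[ig])]
  im <- match(kg[ig], km)

  g <- genotype_counts_from_allele_info(
    an = gnomad$an[ig, , drop = FALSE],
    ac = gnomad$ac[ig, , drop = FALSE],
    nhomalt = gnomad$nhomalt[ig, , drop = FALSE]
  )
  npop <- length(gnomad$populations)
  shape <- function(v) matrix(v, ncol = npop,
                              dimnames = list(NULL, gnomad$populations))
  labels <- c(gnomad$populations, gme$regions)
  keys <- gnomad$keys[ig, , drop = FALSE]
  rownames(keys) <- NULL
  structure(list(
    keys = keys,
    homref = cbind(shape(g$homref), gme$homref[im, , drop = FALSE]),
    het = cbind(shape(g$het), gme$het[im, , drop = FALSE]),
    homalt = cbind(shape(g$homalt), gme$homalt[im, , drop = FALSE]),
    labels = labels,
    source = stats::setNames(
      rep(c("vcf", "table"), c(npop, length(gme$regions))), labels),
    funnel = list(n_vcf = nrow(gnomad$keys), n_table = nrow(gme$keys),
                  n_merged = length(ig))
  ), class = "merged_variants")
}

# internal: subset a merged_variants object by row index
subset_merged <- function(x, idx) {
  x$keys <- x$keys[idx, , drop = FALSE]
  rownames(x$keys) <- NULL
  x$homref <- x$homref[idx, , drop = FALSE]
  x$het <- x$het[idx, , drop = FALSE]
  x$homalt <- x$homalt[idx, , drop = FALSE]
  x
}

#' Drop merged variants without any common population
#'
#' Retains a variant if its ALT allele frequency strictly exceeds
#' `threshold` in at least one (`mode = "any"`, the default) or in every
#' (`mode = "all"`) non-absent population/region. Labels with zero called
#' alleles contribute no frequency. The `"any"` mode keeps variants that are
#' common in a single population even when rare elsewhere, which is what a
#' focal-deviation scan needs; `"all"` is the stricter literal reading of a
#' per-population threshold.
#'
#' @param x A `"merged_variants"` object.
#' @param threshold ALT-frequency threshold in (0, 0.5\]; default 0.01.
#' @param mode `"any"` or `"all"`.
#' @return The filtered `"merged_variants"` object; its funnel gains
#'   `n_common`.
#' @export
filter_common <- function(x, threshold = 0.01, mode = c("any", "all")) {
  stopifnot(inherits(x, "merged_variants"),
            threshold > 0, threshold <= 0.5)
  mode <- match.arg(mode)
  af <- alt_frequency_matrix(x)
  exceeds <- af > threshold    # NA where absent, NaN -> NA where 0 alleles
  keep <- if (mode == "any") {
    rowSums(exceeds, na.rm = TRUE) > 0
  } else {
    informative <- rowSums(!is.na(exceeds)) > 0
    informative & rowSums(!exceeds, na.rm = TRUE) == 0
  }
  out <- subset_merged(x, which(keep))
  out$funnel$n_common <- sum(keep)
  out
}

#' Intersect merged variants with clinical annotations
#'
#' Inner join on the variant key. Each matching annotation produces one
#' output row, so a variant with several annotations is duplicated (one test
#' per annotation row downstream).
#'
#' @param x A `"merged_variants"` object (typically after
#'   [filter_common()]).
#' @param annotations Annotation data frame from [read_clinvar_table()].
#' @return An object of class `"annotated_variants"`: the subsetted merged
#'   structure plus an aligned `annotations` data frame; the funnel gains
#'   `n_annotated`.
#' @export
intersect_clinvar <- function(x, annotations) {
  stopifnot(inherits(x, "merged_variants"))
  kv <- with(x$keys, variant_key_string(chrom, pos, ref, alt))
  ka <- with(annotations, variant_key_string(chrom, pos, ref, alt))
  hit <- match(ka, kv)
  sel <- which(!is.na(hit))
  idx <- hit[sel]
  ord <- order(as.numeric(annotations$chrom[sel]), annotations$pos[sel])
  sel <- sel[ord]
  idx <- idx[ord]
  out <- subset_merged(x, idx)
  ann <- annotations[sel, , drop = FALSE]
  rownames(ann) <- NULL
  out$annotations <- ann
  out$funnel$n_annotated <- length(idx)
  class(out) <- c("annotated_variants", "merged_variants")
  out
}

#' Aggregate one variant into focal-vs-others tables
#'
#' Builds the 2x2 allele and 2x3 genotype contingency tables comparing the
#' focal population/region against the elementwise sum of all other
#' non-absent labels, together with the focal counts expected if the focal
#' frequencies matched the pooled others (via [expected_counts()]). Allele
#' rows are derived from the genotype rows (`REF = 2*homref + het`,
#' `ALT = 2*homalt + het`). If every non-focal label is absent the others
#' row is all zeros and the expected counts are `NA` (the downstream exact
#' test on such a table is 1 by degeneracy).
#'
#' @param x A `"merged_variants"` object.
#' @param focal Focal label; must be present (non-absent) for this variant.
#' @param i Row index of the variant in `x` (default 1).
#' @return An object of class `"aggregated_tables"`: list with `allele_obs`
#'   (2x2), `genotype_obs` (2x3), `allele_expected_focal` (length 2),
#'   `genotype_expected_focal` (length 3).
#' @export
aggregate_focal_vs_others <- function(x, focal, i = 1L) {
  stopifnot(inherits(x, "merged_variants"))
  if (!focal %in% x$labels) stop("unknown focal label: ", focal,
                                 call. = FALSE)
  key <- with(x$keys[i, ], variant_key_string(chrom, pos, ref, alt))
  gf <- c(x$homref[i, focal], x$het[i, focal], x$homalt[i, focal])
  if (anyNA(gf)) {
    stop("focal label '", focal, "' is absent for variant ", key,
         call. = FALSE)
  }
  oth <- setdiff(x$labels, focal)
  go <- c(sum(x$homref[i, oth], na.rm = TRUE),
          sum(x$het[i, oth], na.rm = TRUE),
          sum(x$homalt[i, oth], na.rm = TRUE))
  alleles <- function(g) c(REF = unname(2 * g[1L] + g[2L]),
                           ALT = unname(2 * g[3L] + g[2L]))
  af <- alleles(gf)
  ao <- alleles(go)
  allele_obs <- rbind(focal = af, others = ao)
  genotype_obs <- rbind(focal = gf, others = go)
  colnames(genotype_obs) <- c("homref", "het", "homalt")
  structure(list(
    key = key,
    allele_obs = allele_obs,
    genotype_obs = genotype_obs,
    allele_expected_focal =
      if (sum(ao) > 0) expected_counts(af, ao) else rep(NA_real_, 2L),
    genotype_expected_focal =
      if (sum(go) > 0) expected_counts(gf, go) else rep(NA_real_, 3L)
  ), class = "aggregated_tables")
}
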