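## Synthetic cohort generator: Hardy-Weinberg genotypes at population-specific
## ALT frequencies over a 15-label roster (8 VCF populations + 7 table
## regions), with planted focal-frequency deviations, per-cell missingness,
## a rare-variant stratum and a sparse clinical-annotation overlay.

#' Default label roster for simulated cohorts
#'
#' Eight VCF-catalogue populations and seven table-catalogue regions. The
#' focal region gets `focal_n` individuals (default 171, a realistic
#' regional exome cohort) and every other label `others_n` (default 5,000,
#' a large reference population).
#'
#' @param focal Focal label; default `"ArabianPeninsula"`.
#' @param focal_n Individuals in the focal label.
#' @param others_n Individuals in each non-focal label.
#' @return Data frame with columns `name`, `catalogue` (`"vcf"`/`"table"`),
#'   `n`.
#' @export
default_labels <- function(focal = "ArabianPeninsula", focal_n = 171L,
                           others_n = 5000L) {
  labels <- data.frame(
    name = c(default_populations(), default_regions()),
    catalogue = rep(c("vcf", "table"), c(8L, 7L)),
    stringsAsFactors = FALSE
  )
  labels$n <- ifelse(labels$name == focal, focal_n, others_n)
  if (!focal %in% labels$name) stop("focal label not in roster",
                                    call. = FALSE)
  labels
}

#' Simulation configuration
#'
#' Bundles and validates every knob of [simulate_cohort()]. The defaults
#' describe the study conditions the package is designed around: 500
#' variants over 15 populations/regions, a 171-individual focal region
#' against 5,000-individual reference labels, baseline ALT frequencies drawn
#' from a Beta(0.2, 2) (a rare-skewed site-frequency spectrum), a quarter of
#' the variants rare everywhere (< 1% ALT), 2% missing cells, and 18 of 500
#' variants carrying a clinical annotation.
#'
#' @param n_variants Number of variants to simulate.
#' @param labels Label roster as from [default_labels()].
#' @param focal Focal label name (exactly one).
#' @param baseline_af_params Shape pair of the Beta distribution for
#'   baseline ALT frequencies of common variants (truncated to
#'   \[0.02, 0.95\] so "common" variants really are common).
#' @param planted Data frame with columns `index`, `delta`: focal ALT
#'   frequency of variant `index` is shifted by `delta` (clipped to
#'   \[0, 1\] with a warning). Planted variants are always common and always
#'   annotated, so planted deviations are recoverable by the pipeline.
#' @param missing_rate Probability that a (variant, label) cell is absent.
#' @param rare_fraction Fraction of variants drawn from a very rare stratum
#'   (true ALT frequency uniform on \[1e-4, 1e-3\] in every label, the
#'   singleton/doubleton scale that dominates real exome catalogues), so
#'   rare variants stay below a 1% frequency filter even after sampling
#'   noise.
#' @param annotation_fraction Fraction of variants receiving a clinical
#'   annotation.
#' @param significance_pool Data frame with columns `label`, `weight` used
#'   to sample clinical-significance strings; the default mirrors the mix
#'   of the bundled reference set (mostly benign/uncertain, one risk-factor
#'   and one drug-response SNP per 18).
#' @param seed Integer seed; fully determines all outputs.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_variants = 500L,
                       labels = default_labels(),
                       focal = "ArabianPeninsula",
                       baseline_af_params = c(0.2, 2),
                       planted = NULL,
                       missing_rate = 0.02,
                       rare_fraction = 0.25,
                       annotation_fraction = 18 / 500,
                       significance_pool = data.frame(
                         label = c("Benign", "Likely benign",
                                   "Uncertain significance",
                                   "Conflicting interpretations of pathogenicity",
                                   "risk factor", "drug response"),
                         weight = c(7, 3, 3, 3, 1, 1),
                         stringsAsFactors = FALSE
                       ),
                       seed = 1L) {
  stopifnot(n_variants >= 1,
            all(c("name", "catalogue", "n") %in% names(labels)),
            all(labels$catalogue %in% c("vcf", "table")),
            sum(labels$name == focal) == 1L,
            length(baseline_af_params) == 2L, all(baseline_af_params > 0),
            missing_rate >= 0, missing_rate < 1,
            rare_fraction >= 0, rare_fraction <= 1,
            annotation_fraction >= 0, annotation_fraction <= 1,
            is.numeric(seed), length(seed) == 1L)
  if (anyDuplicated(labels$name)) stop("duplicate label names",
                                       call. = FALSE)
  if (!is.null(planted)) {
    stopifnot(all(c("index", "delta") %in% names(planted)),
              all(planted$index >= 1 & planted$index <= n_variants),
              !anyDuplicated(planted$index))
  }
  structure(list(n_variants = as.integer(n_variants), labels = labels,
                 focal = focal, baseline_af_params = baseline_af_params,
                 planted = planted, missing_rate = missing_rate,
                 rare_fraction = rare_fraction,
                 annotation_fraction = annotation_fraction,
                 significance_pool = significance_pool,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# internal: run code with a local RNG state
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a cohort and write it in the three input dialects
#'
#' Per variant, a baseline ALT frequency is drawn (Beta for common variants,
#' uniform below 0.01 for the rare stratum); per label, `n` diploid
#' individuals are drawn multinomially from Hardy-Weinberg proportions
#' `((1-p)^2, 2p(1-p), p^2)` at that label's frequency - the baseline
#' everywhere except the focal label, where planted deltas apply. VCF-side
#' labels are emitted as `AN`/`AC`/`nhomalt` INFO fields consistent with the
#' drawn genotypes; table-side labels as `homref,het,homalt` triplets.
#' Absent cells are drawn at `missing_rate` (the focal cell of annotated
#' variants is always kept so every annotated variant is testable). A truth
#' table records every variant's baseline and focal frequency, planted and
#' annotated status.
#'
#' @param config A [sim_config()] object.
#' @param dir Directory to write into (created if needed).
#' @return Invisibly, a list with paths `vcf`, `gme`, `clinvar`, `truth`
#'   and the truth data frame `truth_table`.
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(config$seed, simulate_cohort_impl(config, dir))
}

simulate_cohort_impl <- function(config, dir) {
  n <- config$n_variants
  labels <- config$labels
  focal <- config$focal

  # variant keys: unique autosomal positions in genomic order
  chrom <- sort(sample(1:22, n, replace = TRUE))
  pos <- integer(n)
  for (ch in unique(chrom)) {
    i <- chrom == ch
    pos[i] <- cumsum(sample(100:10000, sum(i), replace = TRUE)) + 10000L
  }
  ref <- sample(.bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.bases, b), 1L),
                character(1))
  rsid <- sprintf("rs9%06d", seq_len(n))

  planted_idx <- if (is.null(config$planted)) integer(0) else
    as.integer(config$planted$index)

  # rare stratum (never includes planted variants)
  n_rare <- round(config$rare_fraction * n)
  rare_pool <- setdiff(seq_len(n), planted_idx)
  if (n_rare > length(rare_pool)) n_rare <- length(rare_pool)
  rare_idx <- sort(sample(rare_pool, n_rare))
  is_rare <- seq_len(n) %in% rare_idx

  # baseline ALT frequencies
  a <- config$baseline_af_params[1L]
  b <- config$baseline_af_params[2L]
  baseline <- numeric(n)
  n_common <- sum(!is_rare)
  draws <- numeric(0)
  while (length(draws) < n_common) {           # truncated Beta for common
    x <- stats::rbeta(2L * (n_common - length(draws)) + 10L, a, b)
    draws <- c(draws, x[x >= 0.02 & x <= 0.95])
  }
  baseline[!is_rare] <- draws[seq_len(n_common)]
  # very rare tail (singleton/doubleton scale): frequencies low enough that
  # sampling noise cannot lift a rare variant over a 1% filter
  baseline[is_rare] <- stats::runif(n_rare, 1e-4, 1e-3)

  focal_af <- baseline
  if (length(planted_idx)) {
    shifted <- baseline[planted_idx] + config$planted$delta
    if (any(shifted < 0 | shifted > 1)) {
      warning("planted delta pushed frequency outside [0, 1]; clipped")
    }
    focal_af[planted_idx] <- pmin(1, pmax(0, shifted))
  }

  # annotation overlay: planted variants always annotated
  n_ann <- max(round(config$annotation_fraction * n), length(planted_idx))
  extra <- setdiff(seq_len(n), planted_idx)
  ann_idx <- sort(c(planted_idx,
                    sample(extra, max(0L, n_ann - length(planted_idx)))))
  is_ann <- seq_len(n) %in% ann_idx

  # genotype draws per (variant, label); NA = absent cell
  nl <- nrow(labels)
  homref <- het <- homalt <-
    matrix(NA_real_, n, nl, dimnames = list(NULL, labels$name))
  miss <- matrix(stats::runif(n * nl) < config$missing_rate, n, nl)
  foc_col <- which(labels$name == focal)
  miss[is_ann, foc_col] <- FALSE   # annotated variants stay testable
  for (j in seq_len(nl)) {
    p <- if (j == foc_col) focal_af else baseline
    hw <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)
    for (i in which(!miss[, j])) {
      g <- stats::rmultinom(1L, labels$n[j], hw[, i])
      homref[i, j] <- g[1L]; het[i, j] <- g[2L]; homalt[i, j] <- g[3L]
    }
  }

  keys <- data.frame(chrom = as.character(chrom), pos = pos, ref = ref,
                     alt = alt, rsid = rsid, stringsAsFactors = FALSE)

  # VCF side
  vcf_pops <- labels$name[labels$catalogue == "vcf"]
  info <- vapply(seq_len(n), function(i) {
    fields <- character(0)
    for (p in vcf_pops) {
      if (is.na(homref[i, p])) next
      an <- 2 * (homref[i, p] + het[i, p] + homalt[i, p])
      ac <- 2 * homalt[i, p] + het[i, p]
      fields <- c(fields, sprintf("AN_%s=%d;AC_%s=%d;nhomalt_%s=%d",
                                  p, as.integer(an), p, as.integer(ac),
                                  p, as.integer(homalt[i, p])))
    }
    paste(fields, collapse = ";")
  }, character(1))
  vcf_path <- file.path(dir, "cohort.vcf")
  write_simple_vcf(keys, info, vcf_pops, vcf_path)

  # table side
  regions <- labels$name[labels$catalogue == "table"]
  gme <- keys[, c("chrom", "pos", "ref", "alt")]
  for (r in regions) {
    gme[[r]] <- ifelse(is.na(homref[, r]), ".",
                       sprintf("%d,%d,%d", as.integer(homref[, r]),
                               as.integer(het[, r]),
                               as.integer(homalt[, r])))
  }
  gme_path <- file.path(dir, "cohort_gme.tsv")
  utils::write.table(gme, gme_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # clinical annotations
  pool <- config$significance_pool
  signif <- rep(NA_character_, n)
  signif[ann_idx] <- sample(pool$label, length(ann_idx), replace = TRUE,
                            prob = pool$weight)
  clinvar <- data.frame(
    chrom = keys$chrom[ann_idx], pos = keys$pos[ann_idx],
    ref = keys$ref[ann_idx], alt = keys$alt[ann_idx],
    rsid = keys$rsid[ann_idx],
    gene = sprintf("GENE%03d", ann_idx),
    change = sprintf("c.%d%s>%s", keys$pos[ann_idx] %% 1000 + 1L,
                     keys$ref[ann_idx], keys$alt[ann_idx]),
    significance = signif[ann_idx],
    stringsAsFactors = FALSE
  )
  clinvar_path <- file.path(dir, "cohort_clinvar.tsv")
  utils::write.table(clinvar, clinvar_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # truth table
  truth <- data.frame(
    keys,
    baseline_af = baseline, focal_af = focal_af,
    planted = seq_len(n) %in% planted_idx,
    annotated = is_ann,
    significance = ifelse(is_ann, signif, ""),
    stringsAsFactors = FALSE
  )
  truth_path <- file.path(dir, "cohort_truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(vcf = vcf_path, gme = gme_path, clinvar = clinvar_path,
                 truth = truth_path, truth_table = truth))
}
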