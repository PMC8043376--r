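# Helpers that materialise tiny catalogue files for the readers.

write_mini_vcf <- function(data_lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AN_p1,Number=1,Type=Integer,Description=\"AN\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    data_lines
  ), path)
  path
}

write_mini_gme <- function(rows, regions, path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    paste(c("chrom", "pos", "ref", "alt", regions), collapse = "\t"),
    rows
  ), path)
  path
}

write_mini_clinvar <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "chrom\tpos\tref\talt\trsid\tgene\tchange\tsignificance",
    rows
  ), path)
  path
}

# build a merged_variants object from inline genotype triples:
# `vcf_counts` and `gme_counts` are lists label -> n x 3 matrix (or NA rows)
make_merged <- function(keys, vcf_counts, gme_counts) {
  vcf_lines <- vapply(seq_len(nrow(keys)), function(i) {
    fields <- character(0)
    for (p in names(vcf_counts)) {
      g <- vcf_counts[[p]][i, ]
      if (anyNA(g)) next
      fields <- c(fields, sprintf(
        "AN_%s=%d;AC_%s=%d;nhomalt_%s=%d",
        p, as.integer(2 * sum(g)), p, as.integer(2 * g[3] + g[2]),
        p, as.integer(g[3])))
    }
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s", keys$chrom[i], keys$pos[i],
            "rs0", keys$ref[i], keys$alt[i],
            if (length(fields)) paste(fields, collapse = ";") else ".")
  }, character(1))
  gme_lines <- vapply(seq_len(nrow(keys)), function(i) {
    cells <- vapply(names(gme_counts), function(r) {
      g <- gme_counts[[r]][i, ]
      if (anyNA(g)) "." else sprintf("%d,%d,%d", g[1], g[2], g[3])
    }, character(1))
    paste(c(keys$chrom[i], keys$pos[i], keys$ref[i], keys$alt[i], cells),
          collapse = "\t")
  }, character(1))
  gn <- read_gnomad_vcf(write_mini_vcf(vcf_lines), names(vcf_counts))
  gm <- read_gme_table(write_mini_gme(gme_lines, names(gme_counts)),
                       names(gme_counts))
  merge_by_key(gn, gm)
}
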