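# Shared fixtures, built in code.

# genotype matrix from a dosage matrix given as a list of sample rows
toy_matrix <- function(rows, chrom = NULL, pos = NULL, qual = NULL,
                       alt = NULL, populations = NULL) {
  dos <- do.call(rbind, rows)
  rownames(dos) <- if (is.null(names(rows))) {
    paste0("s", seq_along(rows))
  } else names(rows)
  n <- ncol(dos)
  loci <- data.frame(
    chrom = if (is.null(chrom)) rep("chr1", n) else chrom,
    pos = if (is.null(pos)) seq_len(n) * 100L else pos,
    ref = rep("A", n),
    alt = if (is.null(alt)) rep("G", n) else alt,
    qual = if (is.null(qual)) rep(NA_real_, n) else qual)
  genotype_matrix(dos, loci, populations = populations)
}

# write a VCF from raw body lines (header generated)
write_toy_vcf <- function(samples, body_lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

# ingroup-only view of a simulated matrix (outgroup removed)
drop_outgroup <- function(gm) {
  keep <- sample_ids(gm)[gm$populations != "outgroup"]
  gm$dosage <- gm$dosage[keep, , drop = FALSE]
  if (!is.null(gm$gt)) gm$gt <- gm$gt[keep, , drop = FALSE]
  gm$populations <- gm$populations[keep]
  gm
}

# donor-side ancestry of a recipient-species sample: its Q in the cluster
# occupied by the anchor (a donor-species individual)
minor_ancestry <- function(res, sample, anchor = "A1") {
  acl <- which.max(res$Q_mean[anchor, ])
  res$Q_mean[sample, acl]
}

# parse NM:i tags out of simulated SAM lines
nm_tags <- function(sam_lines) {
  body <- grep("^@", sam_lines, value = TRUE, invert = TRUE)
  as.integer(sub(".*NM:i:([0-9]+).*", "\\1", body))
}
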