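#' Read a multi-sample VCF into a genotype matrix
#'
#' Unphased diploid GT fields are parsed to alt-allele dosages (count of the
#' first ALT allele); `./.` becomes `NA`. QUAL is captured per locus.
#' Multiallelic records are retained with their full allele lists and raw GT
#' strings; they must be removed with [filter_biallelic()] before any
#' dosage-based statistic.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) {
    # header-only VCF: recover the sample ids from the column line
    hdr <- grep("^#CHROM", readLines(path), value = TRUE)
    cols <- strsplit(hdr[1], "\t")[[1]]
    samples <- if (length(cols) > 9) cols[-(1:9)] else character()
    dos <- matrix(integer(), nrow = length(samples), ncol = 0,
                  dimnames = list(samples, NULL))
    return(genotype_matrix(dos, sim_loci_table(0, 1)))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)
  gt_raw[is.na(gt_raw)] <- "./."
  alleles <- strsplit(as.vector(gt_raw), "[/|]")
  n_all <- lengths(alleles)
  if (any(n_all != 2L)) {
    k <- which(n_all != 2L)[1]
    rec <- (k - 1L) %% n + 1L
    stop("unsupported ploidy (", n_all[which(n_all != 2L)[1]],
         " allele(s) in GT) at record ", rec, "; only diploid GT is supported")
  }
  am <- matrix(unlist(alleles), nrow = 2L)
  dose_vec <- colSums(am == "1")
  dose_vec[am[1, ] == "." | am[2, ] == "."] <- NA_integer_
  dos <- matrix(as.integer(dose_vec), nrow = n)  # records x samples
  dos <- t(dos)
  rownames(dos) <- samples
  gt_mat <- t(matrix(as.vector(gt_raw), nrow = n))
  rownames(gt_mat) <- samples
  loci <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    stringsAsFactors = FALSE)
  ord <- order(factor(loci$chrom, levels = unique(loci$chrom)), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  dos <- dos[, ord, drop = FALSE]
  gt_mat <- gt_mat[, ord, drop = FALSE]
  genotype_matrix(dos, loci, gt = gt_mat)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Raw GT strings captured at read time are preserved (so multiallelic
#' genotypes round-trip); otherwise GT is reconstructed from the dosage.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output file.
#' @export
write_vcf <- function(matrix, path) {
  q <- matrix$loci$qual
  q[is.na(q)] <- "."
  write_sim_vcf(matrix, path, qual = q)
  invisible(path)
}

#' Keep only biallelic loci
#'
#' Retains loci with exactly one REF and one ALT allele; the sample set is
#' unchanged. The number removed is recorded in the [filter_log()].
#'
#' @param matrix a [genotype_matrix()].
#' @return filtered `genotype_matrix`; `attr(, "n_removed")` gives the count
#'   of loci removed.
#' @export
filter_biallelic <- function(matrix) {
  keep <- !is_multiallelic(matrix) & matrix$loci$alt != "." &
    matrix$loci$alt != ""
  out <- subset_loci(matrix, keep, "biallelic")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Filter loci by genotyping quality
#'
#' Keeps loci with QUAL strictly greater than `min_qual` ("more than"
#' semantics). Loci with missing QUAL are dropped.
#'
#' @param matrix a [genotype_matrix()].
#' @param min_qual quality threshold (default 500).
#' @return filtered `genotype_matrix` with `attr(, "n_removed")`.
#' @export
filter_quality <- function(matrix, min_qual = 500) {
  q <- matrix$loci$qual
  keep <- !is.na(q) & q > min_qual
  if (n_loci(matrix) > 0 && all(is.na(q))) {
    warning("all loci have missing QUAL; every locus removed")
  }
  out <- subset_loci(matrix, keep, "quality")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove invariant loci
#'
#' Drops loci whose non-missing dosages are identical across all samples
#' (including loci that are entirely missing).
#'
#' @param matrix a [genotype_matrix()].
#' @return filtered `genotype_matrix` with `attr(, "n_removed")`.
#' @export
drop_invariant <- function(matrix) {
  dos <- matrix$dosage
  n_distinct <- apply(dos, 2, function(x) length(unique(x[!is.na(x)])))
  keep <- n_distinct >= 2L
  out <- subset_loci(matrix, keep, "invariant")
  attr(out, "n_removed") <- sum(!keep)
  out
}
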