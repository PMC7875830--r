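#' Construct a genotype matrix
#'
#' The common currency of all statistical stages: a samples x loci table of
#' diploid alt-allele dosages (count of the first ALT allele, 0/1/2, `NA` for
#' missing calls) together with per-locus metadata. Dosage semantics are only
#' defined for biallelic loci; multiallelic records may be carried through
#' reading and writing but must be removed with [filter_biallelic()] before
#' any statistics are computed.
#'
#' @param dosage integer matrix, samples in rows (rownames = sample ids),
#'   loci in columns; entries in `{0, 1, 2, NA}`.
#' @param loci data.frame with one row per locus and columns `chrom`, `pos`
#'   (1-based), `ref`, `alt` (comma-separated string for multiallelic
#'   records) and `qual` (numeric, `NA` when absent). An optional `id`
#'   column is kept as-is.
#' @param populations optional named character vector mapping sample id to
#'   population label.
#' @param gt optional character matrix of raw GT strings (same shape as
#'   `dosage`), kept so that multiallelic genotypes survive a write/read
#'   round trip.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, loci, populations = NULL, gt = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) {
    stop("dosage matrix must have sample ids as rownames")
  }
  if (anyDuplicated(rownames(dosage))) stop("duplicate sample ids")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols)) {
    stop("loci table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(loci$qual)) loci$qual <- NA_real_
  if (is.null(loci$id)) loci$id <- paste0(loci$chrom, ":", loci$pos)
  if (nrow(loci) != ncol(dosage)) {
    stop("loci table (", nrow(loci), ") and dosage columns (", ncol(dosage),
         ") disagree")
  }
  if (nrow(loci)) {
    if (any(loci$pos < 1)) stop("locus positions must be >= 1")
    key <- paste(loci$chrom, loci$pos)
    if (anyDuplicated(key)) stop("duplicate (chrom, pos) pairs in loci table")
    # chromosome blocks contiguous, positions strictly increasing within them
    chrom_rle <- rle(loci$chrom)
    if (anyDuplicated(chrom_rle$values)) {
      stop("loci of one chromosome must be contiguous; sort the input")
    }
    inc <- tapply(loci$pos, factor(loci$chrom, levels = chrom_rle$values),
                  function(p) all(diff(p) > 0))
    if (!all(unlist(inc))) stop("positions must be increasing within chromosome")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (!is.null(populations)) {
    populations <- populations[rownames(dosage)]
    names(populations) <- rownames(dosage)
  }
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    stopifnot(identical(dim(gt), dim(dosage)))
  }
  structure(
    list(dosage = dosage, loci = loci, populations = populations, gt = gt,
         filter_log = data.frame(filter = character(), n_in = integer(),
                                 n_out = integer(), n_removed = integer())),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_loci(x), "loci\n")
  if (n_loci(x)) {
    cat("  multiallelic loci:", sum(is_multiallelic(x)), "\n")
    cat("  missing calls:", sum(is.na(x$dosage)), "\n")
  }
  if (!is.null(x$populations)) {
    tab <- table(x$populations)
    cat("  populations:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  if (nrow(x$filter_log)) {
    cat("  filters applied:", paste(x$filter_log$filter, collapse = " -> "),
        "\n")
  }
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname genotype_matrix
#' @export
n_loci <- function(x) ncol(x$dosage)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(x) rownames(x$dosage)

#' Multiallelic indicator per locus
#' @param x a `genotype_matrix`.
#' @return logical vector, `TRUE` where a locus has more than one ALT allele.
#' @export
is_multiallelic <- function(x) {
  grepl(",", x$loci$alt, fixed = TRUE)
}

# Keep a subset of loci, preserving metadata and appending to the filter log.
subset_loci <- function(x, keep, filter_name = NULL) {
  keep <- which(keep)
  out <- x
  out$dosage <- x$dosage[, keep, drop = FALSE]
  out$loci <- x$loci[keep, , drop = FALSE]
  rownames(out$loci) <- NULL
  if (!is.null(x$gt)) out$gt <- x$gt[, keep, drop = FALSE]
  if (!is.null(filter_name)) {
    out$filter_log <- rbind(
      x$filter_log,
      data.frame(filter = filter_name, n_in = n_loci(x),
                 n_out = length(keep), n_removed = n_loci(x) - length(keep)))
  }
  out
}

#' Filter report accumulated by the locus filters
#'
#' @param x a `genotype_matrix` that has been through one or more of
#'   [filter_biallelic()], [filter_quality()], [drop_invariant()].
#' @return data.frame with columns `filter`, `n_in`, `n_out`, `n_removed`.
#' @export
filter_log <- function(x) x$filter_log

#' Write the filter report as TSV
#' @param x a `genotype_matrix`.
#' @param path output file.
#' @export
write_filter_report <- function(x, path) {
  utils::write.table(filter_log(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Resolve population specifications to sample id lists.
# `spec` may be: a list(name = sample ids), a population label present in
# x$populations, or sample ids themselves.
resolve_samples <- function(x, spec) {
  ids <- sample_ids(x)
  if (all(spec %in% ids)) return(spec)
  if (!is.null(x$populations)) {
    hit <- names(x$populations)[x$populations %in% spec]
    if (length(hit)) return(hit)
  }
  unknown <- setdiff(spec, c(ids, unique(x$populations)))
  stop("unknown sample or population name(s): ",
       paste(unknown, collapse = ", "))
}
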