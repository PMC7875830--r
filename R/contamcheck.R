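#' Per-sample alignment mismatch (error) rate
#'
#' The contamination indicator: the ratio of substitution mismatches to the
#' total number of mapped nucleotides, computed from CIGAR strings and
#' NM/MD tags. Mismatches are `NM - inserted bases - deleted bases` per
#' primary mapped read (so indel bases, which NM counts, are excluded and
#' only substitutions remain); mapped bases are the summed lengths of the
#' M/=/X CIGAR operations. Unmapped, secondary, supplementary and duplicate
#' records are skipped. Reads lacking NM fall back to counting the
#' substitution letters of the MD tag; reads with neither tag are skipped
#' and counted.
#'
#' @param sam_path SAM or BAM file.
#' @param sample_id label for the report; default: file name.
#' @return list of class `mismatch_stats`: `sample_id`, `mapped_bases`,
#'   `mismatches`, `error_rate`, `n_reads`, `n_skipped_no_tag`.
#' @export
mismatch_rate <- function(sam_path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(sam_path))
  }
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam_path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("flag", "cigar"),
                               tag = c("NM", "MD"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- x$flag
  keep <- !bitwAnd(flag, 0x4) & !bitwAnd(flag, 0x100) &
    !bitwAnd(flag, 0x800) & !bitwAnd(flag, 0x400) & !is.na(x$cigar)
  cigar <- x$cigar[keep]
  n_all <- length(x$cigar)
  pad <- function(v, mode) {
    if (is.null(v) || !length(v)) v <- rep(as.vector(NA, mode = mode), n_all)
    v
  }
  nm <- pad(x$tag$NM, "integer")[keep]
  md <- pad(x$tag$MD, "character")[keep]
  if (!length(cigar)) stop("no primary mapped reads in ", sam_path)
  ops <- GenomicAlignments::cigarOpTable(cigar)
  aligned <- ops[, "M"] + ops[, "="] + ops[, "X"]
  ins <- ops[, "I"]
  del <- ops[, "D"]
  sub_counts <- nm - ins - del
  no_nm <- is.na(nm)
  if (any(no_nm)) {
    has_md <- no_nm & !is.na(md)
    sub_counts[has_md] <- md_mismatch_count(md[has_md])
  }
  usable <- !is.na(sub_counts)
  n_skipped <- sum(!usable)
  mapped_bases <- sum(aligned[usable])
  if (mapped_bases == 0) stop("zero mapped bases; error rate undefined")
  mismatches <- sum(sub_counts[usable])
  structure(list(sample_id = sample_id,
                 mapped_bases = mapped_bases,
                 mismatches = mismatches,
                 error_rate = mismatches / mapped_bases,
                 n_reads = sum(usable), n_skipped_no_tag = n_skipped),
            class = "mismatch_stats")
}

# Substitutions in an MD tag: reference letters outside ^-deletion runs.
md_mismatch_count <- function(md) {
  vapply(md, function(s) {
    s <- gsub("\\^[ACGTN]+", "", s)
    sum(strsplit(gsub("[0-9]", "", s), "")[[1]] %in%
          c("A", "C", "G", "T", "N"))
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
print.mismatch_stats <- function(x, ...) {
  cat(sprintf("%s: %d mismatches / %d mapped bases = %.5f\n",
              x$sample_id, x$mismatches, x$mapped_bases, x$error_rate))
  invisible(x)
}

#' Cross-sample mismatch-rate comparison
#'
#' Formalizes the contamination argument: a contaminated library stands out
#' from the cohort, while a genuinely admixed sample does not. Each
#' sample's rate is given a robust z-score `(rate - median) / MAD` and
#' flagged as contamination-suspect when it exceeds `median + k * MAD`.
#' When the MAD is zero the rule falls back to flagging any rate above
#' twice the median.
#'
#' @param stats list of [mismatch_rate()] results (>= 3 samples).
#' @param k MAD multiplier for the flag threshold (default 5).
#' @return data.frame with columns `sample_id`, `mapped_bases`,
#'   `mismatches`, `error_rate`, `robust_z`, `flagged`.
#' @export
compare_samples <- function(stats, k = 5) {
  if (length(stats) < 3) stop("need at least 3 samples to compare")
  rate <- vapply(stats, function(s) s$error_rate, numeric(1))
  med <- stats::median(rate)
  madv <- stats::mad(rate)
  if (madv > 0) {
    z <- (rate - med) / madv
    flagged <- rate > med + k * madv
  } else {
    z <- rep(NA_real_, length(rate))
    flagged <- rate > 2 * med
  }
  data.frame(
    sample_id = vapply(stats, function(s) s$sample_id, character(1)),
    mapped_bases = vapply(stats, function(s) s$mapped_bases, numeric(1)),
    mismatches = vapply(stats, function(s) s$mismatches, numeric(1)),
    error_rate = rate, robust_z = z, flagged = flagged,
    stringsAsFactors = FALSE)
}
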