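#' Find coverage gaps on a TE reference
#'
#' Maximal runs of positions whose depth is at most `max_depth` and whose
#' length is at least `min_length`, in coordinate order. These are the TE
#' fragments not covered by the non-target species' reads, i.e. the regions
#' where a species-discriminating amplicon can be placed.
#'
#' @param coverage integer vector of per-base depth along the TE (or the
#'   list returned by [simulate_te_coverage()]).
#' @param max_depth maximum depth still considered "uncovered" (default 0).
#' @param min_length minimum gap length in bp (default 250, so that
#'   amplicons of 200-500 bp fit with their primer footprints).
#' @return data.frame with 0-based half-open columns `start`, `end` and
#'   `length`.
#' @export
coverage_gaps <- function(coverage, max_depth = 0, min_length = 250) {
  if (is.list(coverage)) coverage <- coverage$coverage
  r <- rle(coverage <= max_depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_length
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Melting temperature, Wallace rule
#'
#' `Tm = 2 (A + T) + 4 (G + C)` degrees C.
#'
#' @param primer_seq primer sequence over ACGT, length >= 8.
#' @return Tm in degrees C.
#' @export
tm_wallace <- function(primer_seq) {
  b <- check_primer_seq(primer_seq)
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

check_primer_seq <- function(primer_seq) {
  b <- strsplit(toupper(primer_seq), "")[[1]]
  if (length(b) < 8) stop("primer must be at least 8 nt")
  if (!all(b %in% c("A", "C", "G", "T"))) {
    stop("ambiguous or non-ACGT base in primer sequence")
  }
  b
}

# SantaLucia unified nearest-neighbor parameters:
# dH in kcal/mol, dS in cal/(mol K)
.nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
            TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
            GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            CC = -8.0)
.nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
            TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
            GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            CC = -19.9)

#' Melting temperature, nearest-neighbor thermodynamics
#'
#' Unified nearest-neighbor parameters with duplex-initiation terms,
#' monovalent-salt entropy correction `0.368 (N - 1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS_corrected + R ln(C_T)) - 273.15` where the effective
#' strand concentration is `C_T = dnac1 - dnac2 / 2` (primer in excess over
#' template).
#'
#' @param primer_seq primer sequence over ACGT, length >= 8.
#' @param Na monovalent cation concentration, mol/L (default 0.05).
#' @param dnac1,dnac2 concentrations of the two strands in nM (defaults
#'   25 and 25).
#' @return Tm in degrees C.
#' @export
tm_nn <- function(primer_seq, Na = 0.05, dnac1 = 25, dnac2 = 25) {
  b <- check_primer_seq(primer_seq)
  n <- length(b)
  pairs <- paste0(b[-n], b[-1])
  dH <- sum(.nn_dH[pairs])
  dS <- sum(.nn_dS[pairs])
  for (term in c(b[1], b[n])) {
    if (term %in% c("G", "C")) {
      dH <- dH + 0.1; dS <- dS - 2.8
    } else {
      dH <- dH + 2.3; dS <- dS + 4.1
    }
  }
  dS <- dS + 0.368 * (n - 1) * log(Na)
  ct <- (dnac1 - dnac2 / 2) * 1e-9
  1000 * dH / (dS + 1.987 * log(ct)) - 273.15
}

#' Default primer design constraints
#'
#' Physicochemical acceptance windows for candidate primers; the defaults
#' were calibrated once so that the shipped reference panel of 24 published
#' stickleback TE primers (see
#' `system.file("extdata", "te_primer_panel.tsv", package = "introkit")`)
#' passes every check.
#'
#' @param min_len,max_len primer length bounds (nt).
#' @param min_gc,max_gc GC fraction bounds.
#' @param min_tm,max_tm Tm window, degrees C.
#' @param max_dtm maximum |Tm difference| within a pair, degrees C.
#' @param max_homopolymer longest allowed single-base run.
#' @param gc_clamp require a 3' terminal G or C.
#' @param min_product,max_product amplicon length bounds (nt).
#' @param tm_method `"nn"` or `"wallace"`.
#' @return named list of constraints.
#' @export
primer_constraints <- function(min_len = 18, max_len = 25,
                               min_gc = 0.35, max_gc = 0.65,
                               min_tm = 51, max_tm = 66, max_dtm = 3.5,
                               max_homopolymer = 4, gc_clamp = FALSE,
                               min_product = 200, max_product = 500,
                               tm_method = c("nn", "wallace")) {
  list(min_len = min_len, max_len = max_len, min_gc = min_gc,
       max_gc = max_gc, min_tm = min_tm, max_tm = max_tm,
       max_dtm = max_dtm, max_homopolymer = max_homopolymer,
       gc_clamp = gc_clamp, min_product = min_product,
       max_product = max_product, tm_method = match.arg(tm_method))
}

gc_fraction <- function(seqs) {
  vapply(strsplit(toupper(seqs), ""), function(b) {
    mean(b %in% c("G", "C"))
  }, numeric(1))
}

has_long_homopolymer <- function(seqs, max_run) {
  grepl(sprintf("([ACGT])\\1{%d,}", max_run), toupper(seqs))
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Check primer sequences against the per-primer constraints
#'
#' @param seqs character vector of primer sequences.
#' @param constraints a [primer_constraints()] list.
#' @return logical matrix (one row per primer) with per-constraint columns
#'   `length`, `gc`, `tm`, `homopolymer`, `clamp` plus `all`.
#' @export
check_primer_constraints <- function(seqs, constraints = primer_constraints()) {
  cn <- constraints
  len <- nchar(seqs)
  gc <- gc_fraction(seqs)
  tmfun <- if (cn$tm_method == "nn") tm_nn else tm_wallace
  tm <- vapply(seqs, tmfun, numeric(1), USE.NAMES = FALSE)
  ok <- cbind(
    length = len >= cn$min_len & len <= cn$max_len,
    gc = gc >= cn$min_gc & gc <= cn$max_gc,
    tm = tm >= cn$min_tm & tm <= cn$max_tm,
    homopolymer = !has_long_homopolymer(seqs, cn$max_homopolymer),
    clamp = if (cn$gc_clamp) {
      substr(seqs, nchar(seqs), nchar(seqs)) %in% c("G", "C", "g", "c")
    } else rep(TRUE, length(seqs)))
  res <- cbind(ok, all = apply(ok, 1, all))
  attr(res, "tm") <- tm
  attr(res, "gc") <- gc
  res
}

#' Design primer pairs inside a coverage gap
#'
#' Enumerates forward primers starting in the first portion of the gap and
#' reverse primers ending in the last portion such that the amplicon lies
#' entirely inside the gap and its length is within
#' `[min_product, max_product]`. Candidates must pass the per-primer
#' constraints; pairs must additionally satisfy `|dTm| <= max_dtm`. Pairs
#' are ranked by `score = |dTm| + 10 * (|gcF - 0.5| + |gcR - 0.5|) +
#' 0.01 * |product - target|` (target = midpoint of the product window),
#' ties broken by coordinates, and the best `max_pairs` returned.
#'
#' @param te TE reference: list with `name` and `sequence` (as produced by
#'   [simulate_te_coverage()]), or a plain sequence string.
#' @param gap one row of [coverage_gaps()] (0-based half-open `start`,
#'   `end`), or a length-2 vector.
#' @param constraints a [primer_constraints()] list.
#' @param max_pairs maximum number of ranked pairs returned.
#' @return data.frame of class `primer_pairs` with columns `te_name`,
#'   `fwd_seq`, `rev_seq`, `fwd_start`, `rev_end` (0-based half-open on the
#'   TE), `product_length`, `fwd_tm`, `rev_tm`, `fwd_gc`, `rev_gc`,
#'   `score`. When empty, `attr(, "rejections")` tallies the candidates
#'   removed by each constraint.
#' @export
design_primers <- function(te, gap, constraints = primer_constraints(),
                           max_pairs = 20) {
  if (is.character(te)) te <- list(name = "TE", sequence = te)
  if (!is.null(te$te)) te <- te$te
  seq_str <- toupper(te$sequence)
  g0 <- as.integer(gap[["start"]]); g1 <- as.integer(gap[["end"]])
  cn <- constraints
  rejections <- c(product_length = 0L, length = 0L, gc = 0L, tm = 0L,
                  homopolymer = 0L, clamp = 0L, dtm = 0L)
  empty <- function() {
    out <- data.frame(te_name = character(), fwd_seq = character(),
                      rev_seq = character(), fwd_start = integer(),
                      rev_end = integer(), product_length = integer(),
                      fwd_tm = numeric(), rev_tm = numeric(),
                      fwd_gc = numeric(), rev_gc = numeric(),
                      score = numeric())
    attr(out, "rejections") <- rejections
    class(out) <- c("primer_pairs", "data.frame")
    out
  }
  if (g1 - g0 < cn$min_product) {
    rejections["product_length"] <- 1L
    return(empty())
  }
  cand <- function(forward) {
    # forward: 0-based starts in [g0, g1 - min_product]
    # reverse: 0-based exclusive ends in [g0 + min_product, g1]
    grid <- expand.grid(
      anchor = if (forward) g0:(g1 - cn$min_product) else
        (g0 + cn$min_product):g1,
      len = cn$min_len:cn$max_len)
    if (forward) {
      start <- grid$anchor
      end <- grid$anchor + grid$len          # half-open end
    } else {
      end <- grid$anchor
      start <- grid$anchor - grid$len
    }
    keep <- start >= g0 & end <= g1
    grid <- grid[keep, , drop = FALSE]
    start <- start[keep]; end <- end[keep]
    tmpl <- substring(seq_str, start + 1L, end)
    seqs <- if (forward) tmpl else revcomp(tmpl)
    chk <- check_primer_constraints(seqs, cn)
    rej <- colSums(!chk[, c("length", "gc", "tm", "homopolymer", "clamp"),
                        drop = FALSE])
    ok <- chk[, "all"]
    list(df = data.frame(seq = seqs[ok], start = start[ok], end = end[ok],
                         tm = attr(chk, "tm")[ok], gc = attr(chk, "gc")[ok],
                         stringsAsFactors = FALSE),
         rejections = rej)
  }
  fw <- cand(TRUE)
  rv <- cand(FALSE)
  rejections[names(fw$rejections)] <- rejections[names(fw$rejections)] +
    fw$rejections + rv$rejections
  if (!nrow(fw$df) || !nrow(rv$df)) return(empty())
  pairs <- expand.grid(i = seq_len(nrow(fw$df)), j = seq_len(nrow(rv$df)))
  prod_len <- rv$df$end[pairs$j] - fw$df$start[pairs$i]
  ok_len <- prod_len >= cn$min_product & prod_len <= cn$max_product &
    rv$df$start[pairs$j] >= fw$df$end[pairs$i]
  rejections["product_length"] <- rejections["product_length"] +
    sum(!ok_len)
  pairs <- pairs[ok_len, , drop = FALSE]
  prod_len <- prod_len[ok_len]
  if (!nrow(pairs)) return(empty())
  dtm <- abs(fw$df$tm[pairs$i] - rv$df$tm[pairs$j])
  ok_dtm <- dtm <= cn$max_dtm
  rejections["dtm"] <- sum(!ok_dtm)
  pairs <- pairs[ok_dtm, , drop = FALSE]
  prod_len <- prod_len[ok_dtm]; dtm <- dtm[ok_dtm]
  if (!nrow(pairs)) return(empty())
  target <- (cn$min_product + cn$max_product) / 2
  score <- dtm +
    10 * (abs(fw$df$gc[pairs$i] - 0.5) + abs(rv$df$gc[pairs$j] - 0.5)) +
    0.01 * abs(prod_len - target)
  out <- data.frame(
    te_name = te$name,
    fwd_seq = fw$df$seq[pairs$i], rev_seq = rv$df$seq[pairs$j],
    fwd_start = fw$df$start[pairs$i], rev_end = rv$df$end[pairs$j],
    product_length = as.integer(prod_len),
    fwd_tm = fw$df$tm[pairs$i], rev_tm = rv$df$tm[pairs$j],
    fwd_gc = fw$df$gc[pairs$i], rev_gc = rv$df$gc[pairs$j],
    score = score, stringsAsFactors = FALSE)
  out <- out[order(out$score, out$fwd_start, out$rev_end), , drop = FALSE]
  out <- utils::head(out, max_pairs)
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  class(out) <- c("primer_pairs", "data.frame")
  out
}

#' Predict amplification of primer pairs on target sequences
#'
#' Dry-run of the diagnostic PCR: both primers are searched in the correct
#' orientation (forward on the plus strand, reverse-complemented reverse
#' primer downstream) allowing up to `max_mismatch` mismatches but
#' requiring the `anchor` 3'-terminal bases of each primer to match
#' exactly; a predicted amplicon is reported for every such pair of binding
#' sites at most `max_product` apart.
#'
#' @param primer_pairs a [design_primers()] result or data.frame with
#'   `fwd_seq` and `rev_seq`.
#' @param subjects target sequences: a named character vector, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param max_mismatch allowed mismatches per primer outside the anchor.
#' @param anchor number of 3'-terminal bases that must match exactly.
#' @param max_product maximum amplicon length considered.
#' @return data.frame with one row per predicted amplicon: `subject`,
#'   `pair`, `start`, `end` (1-based inclusive) and `length`.
#' @export
screen_primers_in_silico <- function(primer_pairs, subjects,
                                     max_mismatch = 2, anchor = 3,
                                     max_product = 2000) {
  if (is.character(subjects) && length(subjects) == 1 &&
      file.exists(subjects)) {
    subjects <- Biostrings::readDNAStringSet(subjects)
  }
  if (!methods::is(subjects, "DNAStringSet")) {
    subjects <- Biostrings::DNAStringSet(subjects)
  }
  if (is.null(names(subjects))) {
    names(subjects) <- paste0("seq", seq_along(subjects))
  }
  hits <- list()
  for (si in seq_along(subjects)) {
    subj <- subjects[[si]]
    for (pi in seq_len(nrow(primer_pairs))) {
      fwd <- toupper(primer_pairs$fwd_seq[pi])
      rev_site <- revcomp(toupper(primer_pairs$rev_seq[pi]))
      f_hits <- anchored_matches(fwd, subj, max_mismatch, anchor,
                                 anchor_at = "end")
      r_hits <- anchored_matches(rev_site, subj, max_mismatch, anchor,
                                 anchor_at = "start")
      if (!length(f_hits$start) || !length(r_hits$start)) next
      for (fs in f_hits$start) {
        for (ri in seq_along(r_hits$start)) {
          re <- r_hits$end[ri]
          len <- re - fs + 1L
          if (r_hits$start[ri] > fs + nchar(fwd) - 1L &&
              len <= max_product) {
            hits[[length(hits) + 1L]] <-
              data.frame(subject = names(subjects)[si], pair = pi,
                         start = fs, end = re, length = len)
          }
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(subject = character(), pair = integer(),
                      start = integer(), end = integer(),
                      length = integer()))
  }
  do.call(rbind, hits)
}

# matches of `pattern` in `subject` with <= mm mismatches overall and an
# exact match over `anchor` bases at the given pattern end
anchored_matches <- function(pattern, subject, mm, anchor, anchor_at) {
  m <- Biostrings::matchPattern(pattern, subject, max.mismatch = mm)
  if (!length(m)) return(list(start = integer(), end = integer()))
  starts <- Biostrings::start(m); ends <- Biostrings::end(m)
  ok <- vapply(seq_along(starts), function(i) {
    if (starts[i] < 1 || ends[i] > length(subject)) return(FALSE)
    site <- as.character(subject[starts[i]:ends[i]])
    pb <- strsplit(pattern, "")[[1]]
    sb <- strsplit(site, "")[[1]]
    idx <- if (anchor_at == "end") {
      (length(pb) - anchor + 1L):length(pb)
    } else seq_len(anchor)
    all(pb[idx] == sb[idx])
  }, logical(1))
  list(start = starts[ok], end = ends[ok])
}

#' Read a per-base coverage track from disk
#'
#' Accepts samtools-depth style TSV (`chrom`, 1-based `pos`, `depth`) or
#' 4-column BEDgraph (`chrom`, 0-based `start`, `end`, `depth`). Positions
#' absent from the file get depth 0.
#'
#' @param path coverage file.
#' @param te_length track length (bp).
#' @return integer vector of length `te_length`.
#' @export
read_coverage <- function(path, te_length) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  cov <- integer(te_length)
  if (ncol(df) == 3) {
    cov[df[[2]]] <- as.integer(df[[3]])
  } else if (ncol(df) >= 4) {
    for (i in seq_len(nrow(df))) {
      if (df[[3]][i] > df[[2]][i]) {
        cov[(df[[2]][i] + 1L):df[[3]][i]] <- as.integer(df[[4]][i])
      }
    }
  } else {
    stop("unrecognized coverage format: need 3 (depth TSV) or 4 (BEDgraph) columns")
  }
  cov
}

#' Write a primer table as TSV
#' @param pairs a [design_primers()] result.
#' @param path output file.
#' @export
write_primer_table <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
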