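#' Outgroup-polarized derived-allele frequencies for a population trio
#'
#' The ancestral allele at each site is the allele carried by the outgroup:
#' either the REF allele of the assembly the variants were called against
#' (`outgroup = "reference"`, mirroring polarization by the reference-genome
#' nucleotide) or the allele fixed in a set of outgroup samples. Sites where
#' the outgroup is heterozygous, polymorphic among its samples, or entirely
#' missing are dropped; so are sites with missing calls in any involved
#' sample (complete case) and sites with no derived variation
#' (`p1 = p2 = p3 = 0`). Retained sites are assigned to contiguous
#' equal-count jackknife blocks.
#'
#' @param matrix a biallelic-filtered [genotype_matrix()].
#' @param outgroup `"reference"`, or sample ids / a population label
#'   identifying the outgroup samples.
#' @param p1,p2,test sample ids or population labels for Population 1,
#'   Population 2, and the test individual/population. Positive D reports an
#'   excess of derived alleles shared between `test` and `p1`.
#' @param n_blocks number of contiguous equal-count jackknife blocks.
#' @return data.frame of class `polarized_freq` with columns `chrom`, `pos`,
#'   `p1`, `p2`, `p3`, `block`; attributes record the drop tallies.
#' @export
polarize <- function(matrix, outgroup, p1, p2, test, n_blocks = 50) {
  if (any(is_multiallelic(matrix))) {
    stop("polarization requires a biallelic matrix; run filter_biallelic()")
  }
  g1 <- resolve_samples(matrix, p1)
  g2 <- resolve_samples(matrix, p2)
  g3 <- resolve_samples(matrix, test)
  dos <- matrix$dosage
  n <- n_loci(matrix)
  if (identical(outgroup, "reference")) {
    anc_is_ref <- rep(TRUE, n)
    defined <- rep(TRUE, n)
  } else {
    og <- resolve_samples(matrix, outgroup)
    od <- dos[og, , drop = FALSE]
    n_obs <- colSums(!is.na(od))
    hom0 <- colSums(od == 0L, na.rm = TRUE) == n_obs
    hom2 <- colSums(od == 2L, na.rm = TRUE) == n_obs
    defined <- n_obs > 0L & (hom0 | hom2)
    anc_is_ref <- hom0
  }
  if (!any(defined)) {
    warning("outgroup allele undefined at every site; empty output")
  }
  freq <- function(gr) {
    d <- dos[gr, , drop = FALSE]
    colMeans(d) / 2  # NA when any member is missing (complete case)
  }
  f1 <- freq(g1); f2 <- freq(g2); f3 <- freq(g3)
  complete <- !is.na(f1) & !is.na(f2) & !is.na(f3)
  flip <- !anc_is_ref
  f1[flip] <- 1 - f1[flip]; f2[flip] <- 1 - f2[flip]; f3[flip] <- 1 - f3[flip]
  informative <- f1 > 0 | f2 > 0 | f3 > 0
  keep <- which(defined & complete & informative)
  out <- data.frame(chrom = matrix$loci$chrom[keep],
                    pos = matrix$loci$pos[keep],
                    p1 = f1[keep], p2 = f2[keep], p3 = f3[keep])
  m <- min(n_blocks, max(1L, nrow(out)))
  out$block <- if (nrow(out)) {
    as.integer(ceiling(seq_len(nrow(out)) / (nrow(out) / m)))
  } else integer()
  attr(out, "n_input") <- n
  attr(out, "n_outgroup_undefined") <- sum(!defined)
  attr(out, "n_missing") <- sum(defined & !complete)
  attr(out, "n_uninformative") <- sum(defined & complete & !informative)
  class(out) <- c("polarized_freq", "data.frame")
  out
}

#' Per-site ABBA/BABA weights
#'
#' Frequency-weighted site patterns for the quadruple
#' (Outgroup, P1, P2, Test) with the outgroup fixed ancestral:
#' `abba_s = p1 (1 - p2) p3` (derived allele shared by Test and P1) and
#' `baba_s = p1 p2 (1 - p3)` (derived allele shared by P2 and P1). Their
#' normalized difference is the D-statistic of this design: mean zero when
#' P2 and Test are exchangeable sister samples, positive when Test shares
#' excess derived alleles with P1. For haploid-coded single-individual
#' populations (frequencies 0/1) the weights reduce to literal pattern
#' counts.
#'
#' @param pf a [polarize()] result.
#' @return data.frame with columns `abba` and `baba`.
#' @export
site_patterns <- function(pf) {
  data.frame(abba = pf$p1 * (1 - pf$p2) * pf$p3,
             baba = pf$p1 * pf$p2 * (1 - pf$p3))
}

#' D-statistic for one polarized trio
#'
#' `D = (sum abba_s - sum baba_s) / (sum abba_s + sum baba_s)`.
#'
#' @param pf a [polarize()] result.
#' @return list of class `dstat_result`: `abba_sum`, `baba_sum`, `D`,
#'   `n_snps` (plus `SE`, `Z`, `n_blocks` once [block_jackknife()] has run).
#' @export
dstat <- function(pf) {
  sp <- site_patterns(pf)
  abba <- sum(sp$abba); baba <- sum(sp$baba)
  if (abba + baba <= 0) {
    stop("D undefined: no site carries ABBA or BABA weight")
  }
  structure(list(abba_sum = abba, baba_sum = baba,
                 D = (abba - baba) / (abba + baba),
                 SE = NA_real_, Z = NA_real_,
                 n_snps = nrow(pf), n_blocks = NA_integer_),
            class = "dstat_result")
}

#' Block-jackknife standard error and Z-score for D
#'
#' Delete-one-block jackknife over the contiguous blocks assigned by
#' [polarize()]: `SE^2 = ((m - 1) / m) * sum_j (D_(-j) - mean(D_(-j)))^2`,
#' `Z = D / SE`. Blocks carrying zero ABBA+BABA weight are skipped from the
#' block count m.
#'
#' @param pf a [polarize()] result with at least 2 informative blocks.
#' @return the [dstat()] result completed with `SE`, `Z` and `n_blocks`;
#'   when all leave-one-out estimates coincide `SE` is 0 and `Z` is `Inf`
#'   (flagged via `attr(, "degenerate")`).
#' @export
block_jackknife <- function(pf) {
  res <- dstat(pf)
  sp <- site_patterns(pf)
  a_j <- tapply(sp$abba, pf$block, sum)
  b_j <- tapply(sp$baba, pf$block, sum)
  informative <- (a_j + b_j) > 0
  a_j <- a_j[informative]; b_j <- b_j[informative]
  m <- length(a_j)
  if (m < 2) stop("block jackknife needs at least 2 informative blocks")
  A <- res$abba_sum; B <- res$baba_sum
  d_minus <- ((A - a_j) - (B - b_j)) / ((A - a_j) + (B - b_j))
  se <- sqrt((m - 1) / m * sum((d_minus - mean(d_minus))^2))
  res$SE <- se
  res$n_blocks <- m
  if (se == 0) {
    res$Z <- sign(res$D) * Inf
    attr(res, "degenerate") <- TRUE
  } else {
    res$Z <- res$D / se
  }
  res
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f  Z = %.3f  (ABBA %.1f, BABA %.1f, %d SNPs, %s blocks)\n",
              x$D, x$Z, x$abba_sum, x$baba_sum, x$n_snps,
              ifelse(is.na(x$n_blocks), "?", x$n_blocks)))
  invisible(x)
}

#' D-statistic table for a set of trios
#'
#' One row per ordered trio, in the layout of a qpDstat-style report:
#' outgroup, P1, P2, Test, D, Z, ABBA and BABA sums, number of SNPs.
#'
#' @param matrix a biallelic-filtered [genotype_matrix()].
#' @param outgroup as in [polarize()].
#' @param trios list of character triples `c(p1, p2, test)` (sample ids or
#'   population labels).
#' @param n_blocks jackknife block count.
#' @return data.frame with one row per trio.
#' @export
qp_dstat_table <- function(matrix, outgroup, trios, n_blocks = 50) {
  rows <- lapply(trios, function(tr) {
    stopifnot(length(tr) == 3)
    pf <- polarize(matrix, outgroup, tr[1], tr[2], tr[3],
                   n_blocks = n_blocks)
    r <- block_jackknife(pf)
    data.frame(outgroup = paste(outgroup, collapse = ","),
               pop1 = tr[1], pop2 = tr[2], pop3 = tr[3],
               D = r$D, Z = r$Z, ABBA = r$abba_sum, BABA = r$baba_sum,
               n_snps = r$n_snps, n_blocks = r$n_blocks,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(outgroup = character(), pop1 = character(),
                      pop2 = character(), pop3 = character(), D = numeric(),
                      Z = numeric(), ABBA = numeric(), BABA = numeric(),
                      n_snps = integer(), n_blocks = integer()))
  }
  do.call(rbind, rows)
}
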