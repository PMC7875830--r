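#' Configuration for the synthetic RAD-seq study
#'
#' Describes the generative model every downstream stage is tested against:
#' two species diverged from a common ancestor under Balding-Nichols drift,
#' an outgroup fixed for the ancestral allele at every site, and one focal
#' individual of the recipient species carrying a small fraction of loci
#' whose genotypes are drawn from the donor species' allele frequencies.
#'
#' The defaults mirror the study conditions the package is built around:
#' about 10^4 biallelic RAD-like SNPs spread over 21 chromosomes (the
#' three-spined stickleback karyotype), three donor-species and five
#' recipient-species diploids plus one outgroup (the sample layout of the
#' motivating dataset), and drift parameters `F_A = F_B = 0.6` reflecting
#' the near-complete lineage sorting expected between two distinct genera.
#'
#' @param n_loci number of biallelic loci.
#' @param n_chrom number of chromosomes; loci are assigned evenly, positions
#'   increasing.
#' @param samples_per_pop named integer vector with entries `speciesA`,
#'   `speciesB`, `outgroup`.
#' @param F_A,F_B Balding-Nichols drift parameters in (0, 1) for the
#'   divergence of each species from the common ancestor.
#' @param ancestral_freq_dist length-2 numeric, Beta(a, b) hyperparameters
#'   of the ancestral derived-allele frequency.
#' @param introgression_alpha fraction in \[0, 1\] of loci at which the focal
#'   individual's genotype is drawn from the donor species' frequency.
#' @param donor donor population label (`"speciesA"` or `"speciesB"`).
#' @param recipient_sample sample id of the focal individual; default: the
#'   first sample of the non-donor species.
#' @param tract_length if `NULL` (default) introgressed loci are an i.i.d.
#'   Bernoulli mask; otherwise introgression is laid down in contiguous
#'   tracts of this many loci (exercises block-jackknife correlation).
#' @param missing_rate per-call missing-data probability (ingroup samples).
#' @param seed integer seed; all simulation randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 10000, n_chrom = 21,
                       samples_per_pop = c(speciesA = 3, speciesB = 5,
                                           outgroup = 1),
                       F_A = 0.6, F_B = 0.6,
                       ancestral_freq_dist = c(1, 1),
                       introgression_alpha = 0,
                       donor = "speciesA", recipient_sample = NULL,
                       tract_length = NULL, missing_rate = 0, seed = 1) {
  stopifnot(n_loci >= 0, n_chrom >= 1)
  need <- c("speciesA", "speciesB", "outgroup")
  if (!all(need %in% names(samples_per_pop))) {
    stop("samples_per_pop must name speciesA, speciesB and outgroup")
  }
  if (F_A <= 0 || F_A >= 1 || F_B <= 0 || F_B >= 1) {
    stop("drift parameters F_A and F_B must lie strictly between 0 and 1")
  }
  if (introgression_alpha < 0 || introgression_alpha > 1) {
    stop("introgression_alpha must lie in [0, 1]")
  }
  if (!donor %in% c("speciesA", "speciesB")) {
    stop("donor must be 'speciesA' or 'speciesB'")
  }
  ids <- c(
    if (samples_per_pop[["speciesA"]] > 0)
      paste0("A", seq_len(samples_per_pop[["speciesA"]])),
    if (samples_per_pop[["speciesB"]] > 0)
      paste0("B", seq_len(samples_per_pop[["speciesB"]])),
    if (samples_per_pop[["outgroup"]] > 0)
      paste0("OUT", seq_len(samples_per_pop[["outgroup"]])))
  pops <- c(rep("speciesA", samples_per_pop[["speciesA"]]),
            rep("speciesB", samples_per_pop[["speciesB"]]),
            rep("outgroup", samples_per_pop[["outgroup"]]))
  names(pops) <- ids
  if (is.null(recipient_sample)) {
    recipient_pop <- setdiff(c("speciesA", "speciesB"), donor)
    cand <- ids[pops == recipient_pop]
    recipient_sample <- if (length(cand)) cand[1] else NA_character_
  }
  if (!is.na(recipient_sample) && !recipient_sample %in% ids) {
    stop("recipient_sample '", recipient_sample, "' is not a simulated sample")
  }
  structure(
    list(n_loci = as.integer(n_loci), n_chrom = as.integer(n_chrom),
         samples_per_pop = samples_per_pop, F_A = F_A, F_B = F_B,
         ancestral_freq_dist = ancestral_freq_dist,
         introgression_alpha = introgression_alpha, donor = donor,
         recipient_sample = recipient_sample, tract_length = tract_length,
         missing_rate = missing_rate, seed = as.integer(seed),
         sample_ids = ids, populations = pops),
    class = "sim_config")
}

#' Simulate per-locus allele frequencies under Balding-Nichols divergence
#'
#' Ancestral derived-allele frequencies are i.i.d. Beta(a, b); each species'
#' frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), so that
#' `E[f] = p` and `Var(f) = F p (1 - p)`. The outgroup carries the
#' ancestral allele, i.e. its derived-allele frequency is 0 at every locus.
#'
#' @param config a [sim_config()].
#' @return list with numeric vectors `p_anc`, `p_A`, `p_B` (length
#'   `n_loci`) and `p_out` (all zeros).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_loci
  ab <- config$ancestral_freq_dist
  p <- stats::rbeta(n, ab[1], ab[2])
  bn <- function(p, F) {
    f <- stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
    # rbeta returns NaN when a shape underflows to 0 (p numerically 0 or 1)
    f[p <= 0] <- 0
    f[p >= 1] <- 1
    f
  }
  list(p_anc = p, p_A = bn(p, config$F_A), p_B = bn(p, config$F_B),
       p_out = numeric(n))
}

#' Simulate diploid genotypes and the introgression truth record
#'
#' Each individual's dosage at locus l is Binomial(2, species frequency).
#' For the focal (recipient) individual a per-locus mask -- Bernoulli(alpha)
#' by default, or contiguous tracts when `tract_length` is set -- switches
#' the sampling frequency to the donor species. The realized mask is
#' returned as the truth record.
#'
#' @param freqs output of [simulate_frequencies()].
#' @param config the same [sim_config()].
#' @return list with elements `matrix` (a [genotype_matrix()]) and `truth`
#'   (data.frame `locus_id`, `chrom`, `pos`, `introgressed` plus attributes
#'   `q_true` -- the realized introgressed fraction -- and `seed`).
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_loci
  ids <- config$sample_ids
  pops <- config$populations
  dos <- matrix(0L, nrow = length(ids), ncol = n, dimnames = list(ids, NULL))
  for (pop in c("speciesA", "speciesB")) {
    members <- ids[pops == pop]
    if (!length(members)) next
    f <- if (pop == "speciesA") freqs$p_A else freqs$p_B
    dos[members, ] <- matrix(
      stats::rbinom(length(members) * n, 2L, rep(f, each = length(members))),
      nrow = length(members))
  }
  # outgroup fixed for the ancestral allele: dosage 0 everywhere (default)
  mask <- rep(FALSE, n)
  focal <- config$recipient_sample
  if (!is.na(focal) && config$introgression_alpha > 0 && n > 0) {
    if (is.null(config$tract_length)) {
      mask <- stats::runif(n) < config$introgression_alpha
    } else {
      tl <- as.integer(config$tract_length)
      n_tracts <- max(0L, round(config$introgression_alpha * n / tl))
      starts <- sample.int(max(1L, n - tl + 1L), n_tracts, replace = TRUE)
      for (s in starts) mask[s:min(n, s + tl - 1L)] <- TRUE
    }
    donor_f <- if (config$donor == "speciesA") freqs$p_A else freqs$p_B
    if (any(mask)) {
      dos[focal, mask] <- stats::rbinom(sum(mask), 2L, donor_f[mask])
    }
  }
  if (config$missing_rate > 0) {
    ingroup <- ids[pops != "outgroup"]
    miss <- matrix(stats::runif(length(ingroup) * n) < config$missing_rate,
                   nrow = length(ingroup))
    dos[ingroup, ][miss] <- NA_integer_
  }
  loci <- sim_loci_table(n, config$n_chrom)
  gm <- genotype_matrix(dos, loci, populations = pops)
  truth <- data.frame(locus_id = loci$id, chrom = loci$chrom, pos = loci$pos,
                      introgressed = as.integer(mask))
  attr(truth, "q_true") <- if (n > 0) mean(mask) else 0
  attr(truth, "seed") <- config$seed
  list(matrix = gm, truth = truth)
}

# Even assignment of loci to chromosomes, fixed REF/ALT alleles chosen so
# that every locus is biallelic; positions increase by 1 kb within a
# chromosome (deterministic: locus coordinates are bookkeeping, not data).
sim_loci_table <- function(n, n_chrom) {
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      qual = numeric(), id = character()))
  }
  chrom_idx <- ceiling(seq_len(n) / ceiling(n / n_chrom))
  within <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along)
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_len(n) - 1L) %% 4L + 1L]
  alt <- bases[seq_len(n) %% 4L + 1L]
  data.frame(chrom = sprintf("chr%02d", chrom_idx),
             pos = within * 1000L, ref = ref, alt = alt,
             qual = NA_real_,
             id = sprintf("L%06d", seq_len(n)))
}

#' One-call simulation of a genotype matrix with truth
#'
#' Convenience wrapper: [simulate_frequencies()] then
#' [simulate_genotypes()].
#'
#' @param config a [sim_config()].
#' @return as [simulate_genotypes()], plus the frequencies as `freqs`.
#' @export
simulate_study <- function(config) {
  freqs <- simulate_frequencies(config)
  out <- simulate_genotypes(freqs, config)
  out$freqs <- freqs
  out
}

#' Write a simulated genotype matrix as VCF 4.2
#'
#' One record per locus, unphased diploid GT, 1-based ascending positions.
#' Optionally a number of loci can be forced triallelic (a second ALT allele
#' plus one carrier genotype) to exercise the biallelic filter downstream.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output file.
#' @param qual QUAL column: scalar or per-locus vector; per-locus metadata
#'   `qual` takes precedence where non-missing.
#' @param n_multiallelic number of loci to force triallelic (deterministic,
#'   evenly spaced).
#' @return `path`, invisibly; the indices of injected multiallelic loci are
#'   attached as attribute `multiallelic_idx`.
#' @export
write_sim_vcf <- function(matrix, path, qual = 1000, n_multiallelic = 0) {
  gm <- matrix
  n <- n_loci(gm)
  quals <- rep_len(qual, n)
  if (n > 0 && any(!is.na(gm$loci$qual))) {
    quals[!is.na(gm$loci$qual)] <- gm$loci$qual[!is.na(gm$loci$qual)]
  }
  alt <- gm$loci$alt
  gt_chr <- dosage_to_gt(gm$dosage)
  if (!is.null(gm$gt)) {
    keep <- !is.na(gm$gt)
    gt_chr[keep] <- gm$gt[keep]
  }
  idx <- integer()
  if (n_multiallelic > 0) {
    if (n_multiallelic > n) stop("more multiallelic loci requested than loci")
    idx <- unique(round(seq(1, n, length.out = n_multiallelic)))
    bases <- c("A", "C", "G", "T")
    for (i in idx) {
      used <- c(gm$loci$ref[i], strsplit(alt[i], ",")[[1]])
      alt2 <- setdiff(bases, used)[1]
      alt[i] <- paste0(alt[i], ",", alt2)
      # make the extra allele observable: first sample carries one copy
      carrier <- 1L
      gt_chr[carrier, i] <- if (!is.na(gm$dosage[carrier, i]) &&
                                gm$dosage[carrier, i] > 0) "1/2" else "0/2"
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=introkit-simdata",
    paste0("##contig=<ID=", unique(gm$loci$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")), con)
  if (n > 0) {
    body <- paste(gm$loci$chrom, gm$loci$pos, gm$loci$id, gm$loci$ref, alt,
                  format(quals, trim = TRUE, scientific = FALSE), "PASS", ".",
                  "GT",
                  apply(gt_chr, 2, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(structure(path, multiallelic_idx = idx))
}

dosage_to_gt <- function(dos) {
  out <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos),
                dimnames = dimnames(dos))
  out[!is.na(dos) & dos == 0L] <- "0/0"
  out[!is.na(dos) & dos == 1L] <- "0/1"
  out[!is.na(dos) & dos == 2L] <- "1/1"
  out
}

#' Write the introgression truth table as TSV
#' @param truth truth record from [simulate_genotypes()].
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate aligned reads in SAM format with controlled mismatch rates
#'
#' Reads are copied from a random reference with i.i.d. substitutions at
#' `per_base_mismatch` (substitutions always change the base). A fraction of
#' reads is instead copied from a contaminant reference diverged from the
#' primary one at rate `contaminant_divergence`; those reads keep their
#' coordinates on the primary reference, mimicking cross-species
#' contamination surviving mapping. NM and MD tags are computed from the
#' realized alignment. By default the CIGAR is all-match; with
#' `indel_rate > 0` a read may carry one short insertion or deletion
#' (1-3 bp), in which case NM includes the indel bases, as in real aligner
#' output.
#'
#' @param n_reads number of reads.
#' @param read_len read length (<= `ref_len`).
#' @param per_base_mismatch substitution probability per base.
#' @param contaminant_fraction fraction of reads from the contaminant.
#' @param contaminant_divergence per-base divergence of the contaminant
#'   reference.
#' @param seed integer seed.
#' @param ref_len reference length.
#' @param indel_rate per-read probability of carrying one 1-3 bp indel.
#' @return list with `sam` (character vector: header + one line per read),
#'   `reference` and `contaminant` (character DNA strings), and `ref_name`.
#' @export
simulate_sam <- function(n_reads, read_len, per_base_mismatch,
                         contaminant_fraction = 0,
                         contaminant_divergence = 0, seed = 1,
                         ref_len = 1000, indel_rate = 0) {
  for (p in c(per_base_mismatch, contaminant_fraction,
              contaminant_divergence, indel_rate)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (read_len > ref_len) stop("read_len exceeds the reference length")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ref_len, replace = TRUE)
  contam <- ref
  div_sites <- which(stats::runif(ref_len) < contaminant_divergence)
  if (length(div_sites)) {
    contam[div_sites] <- vapply(ref[div_sites], function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1))
  }
  ref_name <- "simref"
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", ref_name, "\tLN:", ref_len))
  lines <- character(n_reads)
  is_contam <- stats::runif(n_reads) < contaminant_fraction
  for (r in seq_len(n_reads)) {
    src <- if (is_contam[r]) contam else ref
    start <- sample.int(ref_len - read_len + 1L, 1L)
    tmpl <- src[start:(start + read_len - 1L)]
    has_indel <- indel_rate > 0 && stats::runif(1) < indel_rate
    if (!has_indel) {
      aln <- sim_read_segment(tmpl, ref[start:(start + read_len - 1L)],
                              per_base_mismatch, bases)
      cigar <- paste0(read_len, "M")
      seq_out <- aln$seq
      nm <- aln$nm
      md <- aln$md
    } else {
      out <- sim_read_with_indel(src, ref, start, read_len,
                                 per_base_mismatch, bases)
      cigar <- out$cigar
      seq_out <- out$seq
      nm <- out$nm
      md <- out$md
    }
    lines[r] <- paste(
      paste0("read", r), 0L, ref_name, start, 60L, cigar, "*", 0L, 0L,
      seq_out, strrep("I", nchar(seq_out)),
      paste0("NM:i:", nm), paste0("MD:Z:", md), sep = "\t")
  }
  list(sam = c(header, lines), reference = paste(ref, collapse = ""),
       contaminant = paste(contam, collapse = ""), ref_name = ref_name)
}

# Apply substitution errors to a template and compute NM/MD against the
# primary reference window.
sim_read_segment <- function(tmpl, refwin, err, bases) {
  read <- tmpl
  hits <- which(stats::runif(length(read)) < err)
  if (length(hits)) {
    read[hits] <- vapply(read[hits], function(b) sample(setdiff(bases, b), 1),
                         character(1))
  }
  mm <- which(read != refwin)
  md <- md_from_mismatches(length(read), mm, refwin)
  list(seq = paste(read, collapse = ""), nm = length(mm), md = md)
}

md_from_mismatches <- function(len, mm_pos, refwin) {
  if (!length(mm_pos)) return(as.character(len))
  parts <- character(0)
  prev <- 0L
  for (p in mm_pos) {
    parts <- c(parts, as.character(p - prev - 1L), refwin[p])
    prev <- p
  }
  paste0(paste(parts, collapse = ""), len - prev)
}

# One internal indel: split the read-length budget around an insertion of
# random bases or a deletion of reference bases.
sim_read_with_indel <- function(src, ref, start, read_len, err, bases) {
  ilen <- sample(1:3, 1)
  insertion <- stats::runif(1) < 0.5
  if (insertion) {
    a <- sample.int(read_len - ilen - 1L, 1L)
    b <- read_len - ilen - a
    refwin <- ref[start:(start + a + b - 1L)]
    tmpl <- src[start:(start + a + b - 1L)]
    left <- sim_read_segment(tmpl[seq_len(a)], refwin[seq_len(a)], err, bases)
    right <- sim_read_segment(tmpl[(a + 1):(a + b)], refwin[(a + 1):(a + b)],
                              err, bases)
    ins <- paste(sample(bases, ilen, replace = TRUE), collapse = "")
    list(cigar = paste0(a, "M", ilen, "I", b, "M"),
         seq = paste0(left$seq, ins, right$seq),
         nm = left$nm + right$nm + ilen,
         md = md_join(left$md, right$md))
  } else {
    if (start + read_len + ilen - 1L > length(ref)) {
      start <- length(ref) - read_len - ilen + 1L
    }
    a <- sample.int(read_len - 1L, 1L)
    b <- read_len - a
    ref_a <- ref[start:(start + a - 1L)]
    del <- ref[(start + a):(start + a + ilen - 1L)]
    ref_b <- ref[(start + a + ilen):(start + a + ilen + b - 1L)]
    src_a <- src[start:(start + a - 1L)]
    src_b <- src[(start + a + ilen):(start + a + ilen + b - 1L)]
    left <- sim_read_segment(src_a, ref_a, err, bases)
    right <- sim_read_segment(src_b, ref_b, err, bases)
    list(cigar = paste0(a, "M", ilen, "D", b, "M"),
         seq = paste0(left$seq, right$seq),
         nm = left$nm + right$nm + ilen,
         md = paste0(left$md, "^", paste(del, collapse = ""),
                     md_lstrip_zero(right$md)))
  }
}

# Concatenate two MD runs: trailing match count of the left fuses with the
# leading match count of the right.
md_join <- function(left, right) {
  lt <- regmatches(left, regexpr("[0-9]+$", left))
  rt <- regmatches(right, regexpr("^[0-9]+", right))
  fused <- as.integer(lt) + as.integer(rt)
  paste0(sub("[0-9]+$", "", left), fused, sub("^[0-9]+", "", right))
}

md_lstrip_zero <- function(md) md

#' Write simulated SAM records (and reference) to disk
#' @param sim output of [simulate_sam()].
#' @param sam_path output SAM file.
#' @param ref_path optional FASTA path for the primary reference.
#' @export
write_sam <- function(sim, sam_path, ref_path = NULL) {
  writeLines(sim$sam, sam_path)
  if (!is.null(ref_path)) {
    seqs <- Biostrings::DNAStringSet(stats::setNames(sim$reference,
                                                     sim$ref_name))
    Biostrings::writeXStringSet(seqs, ref_path)
  }
  invisible(sam_path)
}

#' Simulate a TE reference with a per-base coverage track
#'
#' Emulates mapping non-target-species reads onto a transposable-element
#' consensus: uniform depth (optionally Poisson-noised) everywhere except
#' inside the specified gaps, which have exactly zero coverage.
#'
#' @param te_length TE consensus length.
#' @param gaps list of 0-based half-open `c(start, end)` intervals with zero
#'   coverage; must be non-overlapping and within the TE.
#' @param depth expected depth outside gaps.
#' @param noise if `TRUE`, depth outside gaps is Poisson(depth).
#' @param seed integer seed.
#' @param name,te_class TE metadata (class is `"DNA"` or `"RNA"`).
#' @return list with `te` (list `name`, `te_class`, `sequence`) and
#'   `coverage` (integer vector of length `te_length`).
#' @export
simulate_te_coverage <- function(te_length, gaps = list(), depth = 30,
                                 noise = FALSE, seed = 1, name = "TE1",
                                 te_class = "DNA") {
  stopifnot(te_length >= 1, depth >= 1)
  if (length(gaps)) {
    m <- do.call(rbind, gaps)
    if (any(m[, 1] < 0) || any(m[, 2] > te_length) || any(m[, 1] >= m[, 2])) {
      stop("gaps must be 0-based half-open intervals within the TE")
    }
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2])) {
      stop("gaps must not overlap")
    }
  }
  set.seed(seed)
  sequence <- paste(sample(c("A", "C", "G", "T"), te_length, replace = TRUE),
                    collapse = "")
  cov <- if (noise) stats::rpois(te_length, depth) else
    rep(as.integer(depth), te_length)
  for (g in gaps) cov[(g[1] + 1L):g[2]] <- 0L
  list(te = list(name = name, te_class = te_class, sequence = sequence),
       coverage = as.integer(cov))
}
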