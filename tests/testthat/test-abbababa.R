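# haploid coding: single diploid samples fixed hom (dosage 0 or 2) so
# derived frequencies are exactly 0/1 and weights reduce to pattern counts
haploid_matrix <- function(g1, g2, g3, og = NULL) {
  n <- length(g1)
  rows <- list(P1 = 2L * g1, P2 = 2L * g2, T1 = 2L * g3)
  if (!is.null(og)) rows$OG <- 2L * og else rows$OG <- rep(0L, n)
  dos <- do.call(rbind, rows)
  rownames(dos) <- names(rows)
  genotype_matrix(dos, data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                                  ref = "A", alt = "G", qual = NA_real_))
}

test_that("polarization follows the outgroup allele and drops bad sites", {
  dos <- rbind(P1 = c(2L, 1L, 0L, 2L, 1L),
               P2 = c(0L, 1L, 2L, 0L, 1L),
               T1 = c(2L, 0L, 1L, 2L, 0L),
               OG = c(0L, 0L, 2L, 1L, 0L))
  gm <- genotype_matrix(dos, data.frame(chrom = "chr1", pos = 1:5 * 10L,
                                        ref = "A", alt = "G",
                                        qual = NA_real_))
  pf <- polarize(gm, "OG", "P1", "P2", "T1", n_blocks = 2)
  # site 4 dropped (outgroup het); site 3 kept but flipped (outgroup hom ALT)
  expect_equal(nrow(pf), 4)
  expect_equal(pf$pos, c(10L, 20L, 30L, 50L))
  expect_equal(pf$p1, c(1, 0.5, 1, 0.5))   # site 3: 1 - 0/2
  expect_equal(pf$p3[3], 0.5)              # site 3: 1 - 1/2

  # reference-allele polarization keeps the het-outgroup site
  pf_ref <- polarize(gm, "reference", "P1", "P2", "T1", n_blocks = 2)
  expect_equal(nrow(pf_ref), 5)

  # missing call in an involved sample drops the site (complete case)
  dos2 <- dos; dos2["P2", 1] <- NA
  gm2 <- genotype_matrix(dos2, gm$loci)
  pf2 <- polarize(gm2, "OG", "P1", "P2", "T1", n_blocks = 2)
  expect_false(10L %in% pf2$pos)
  expect_equal(attr(pf2, "n_missing"), 1)

  # outgroup heterozygous everywhere: empty with a warning
  dos3 <- dos; dos3["OG", ] <- 1L
  gm3 <- genotype_matrix(dos3, gm$loci)
  expect_warning(pf3 <- polarize(gm3, "OG", "P1", "P2", "T1"), "undefined")
  expect_equal(nrow(pf3), 0)
})

test_that("site patterns match their defining corner cases", {
  pf <- data.frame(p1 = c(1, 0, 1, 1), p2 = c(0, 1, 1, 0),
                   p3 = c(1, 1, 0, 0), block = 1L)
  class(pf) <- c("polarized_freq", "data.frame")
  sp <- site_patterns(pf)
  expect_equal(sp$abba, c(1, 0, 0, 0))  # derived shared by Test and P1
  expect_equal(sp$baba, c(0, 0, 1, 0))  # derived shared by P2 and P1
})

test_that("frequency weights equal exhaustive pattern counts (haploid oracle)", {
  set.seed(101)
  for (r in 1:15) {
    n <- sample(6:20, 1)
    g1 <- rbinom(n, 1, 0.5); g2 <- rbinom(n, 1, 0.5); g3 <- rbinom(n, 1, 0.5)
    gm <- haploid_matrix(g1, g2, g3)
    pf <- polarize(gm, "OG", "P1", "P2", "T1", n_blocks = 2)
    informative <- g1 + g2 + g3 > 0
    # independent oracle: literal counting of site patterns
    abba_count <- sum(g1 == 1 & g2 == 0 & g3 == 1)
    baba_count <- sum(g1 == 1 & g2 == 1 & g3 == 0)
    if (abba_count + baba_count == 0) {
      expect_error(dstat(pf), "undefined")
      next
    }
    r1 <- dstat(pf)
    expect_identical(r1$abba_sum, as.numeric(abba_count))
    expect_identical(r1$baba_sum, as.numeric(baba_count))
    expect_identical(r1$n_snps, sum(informative))
    expect_equal(r1$D, (abba_count - baba_count) / (abba_count + baba_count))
  }
})

test_that("D hits its symmetry point and bounds", {
  pf_eq <- data.frame(p1 = c(1, 1), p2 = c(0, 1), p3 = c(1, 0), block = 1L)
  class(pf_eq) <- c("polarized_freq", "data.frame")
  expect_equal(dstat(pf_eq)$D, 0)

  pf_abba <- data.frame(p1 = 1, p2 = 0, p3 = 1, block = 1L)
  class(pf_abba) <- c("polarized_freq", "data.frame")
  expect_equal(dstat(pf_abba)$D, 1)

  pf_zero <- data.frame(p1 = 0, p2 = 1, p3 = 1, block = 1L)
  class(pf_zero) <- c("polarized_freq", "data.frame")
  expect_error(dstat(pf_zero), "undefined")
})

test_that("swapping P2 and the test sample negates D exactly", {
  set.seed(55)
  for (r in 1:10) {
    sim <- simulate_study(sim_config(n_loci = 500,
                                     introgression_alpha = 0.05, seed = r))
    gm <- filter_biallelic(sim$matrix)
    a <- dstat(polarize(gm, "outgroup", "speciesA", "B2", "B1"))
    b <- dstat(polarize(gm, "outgroup", "speciesA", "B1", "B2"))
    expect_equal(a$D, -b$D, tolerance = 1e-12)
    expect_equal(a$abba_sum, b$baba_sum, tolerance = 1e-12)
  }
})

test_that("block jackknife agrees with a naive delete-one reimplementation", {
  set.seed(77)
  pf <- data.frame(p1 = runif(40), p2 = runif(40), p3 = runif(40),
                   block = rep(1:4, each = 10))
  class(pf) <- c("polarized_freq", "data.frame")
  res <- block_jackknife(pf)
  # brute-force oracle: recompute D from scratch on each reduced data set
  d_of <- function(df) {
    a <- sum(df$p1 * (1 - df$p2) * df$p3)
    b <- sum(df$p1 * df$p2 * (1 - df$p3))
    (a - b) / (a + b)
  }
  d_minus <- sapply(1:4, function(j) d_of(pf[pf$block != j, ]))
  se <- sqrt(3 / 4 * sum((d_minus - mean(d_minus))^2))
  expect_equal(res$SE, se, tolerance = 1e-12)
  expect_equal(res$Z, d_of(pf) / se, tolerance = 1e-12)
  expect_equal(res$n_blocks, 4)
})

test_that("degenerate jackknife cases are flagged or rejected", {
  # identical blocks: SE 0, infinite Z flagged
  one <- data.frame(p1 = c(1, 1), p2 = c(0, 0), p3 = c(1, 1), block = 1:2)
  class(one) <- c("polarized_freq", "data.frame")
  res <- block_jackknife(one)
  expect_equal(res$SE, 0)
  expect_true(is.infinite(res$Z))
  expect_true(isTRUE(attr(res, "degenerate")))

  single <- data.frame(p1 = 1, p2 = 0, p3 = 1, block = 1L)
  class(single) <- c("polarized_freq", "data.frame")
  expect_error(block_jackknife(single), "at least 2")
})

test_that("null D is centred at zero with calibrated jackknife Z", {
  set.seed(19)
  n_rep <- 120
  D <- Z <- numeric(n_rep)
  for (r in 1:n_rep) {
    sim <- simulate_study(sim_config(n_loci = 4000, introgression_alpha = 0,
                                     seed = 5000 + r))
    pf <- polarize(sim$matrix, "outgroup", "speciesA", "B2", "B1",
                   n_blocks = 40)
    res <- block_jackknife(pf)
    D[r] <- res$D; Z[r] <- res$Z
  }
  expect_lt(abs(mean(D)), 3 * stats::sd(D) / sqrt(n_rep))
  expect_lte(mean(abs(Z) > 3), 0.02)
  # jackknife Z approximately standard normal under the null
  expect_gt(stats::ks.test(Z, "pnorm")$p.value, 0.01)
})

test_that("the trio table reports each requested quadruple", {
  sim <- simulate_study(sim_config(n_loci = 2000, introgression_alpha = 0.05,
                                   seed = 3))
  gm <- sim$matrix
  tab <- qp_dstat_table(gm, "outgroup",
                        list(c("speciesA", "B2", "B1"),
                             c("speciesA", "B2", "B3"),
                             c("speciesA", "B2", "B4")),
                        n_blocks = 25)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$pop3, c("B1", "B3", "B4"))
  expect_true(all(c("D", "Z", "ABBA", "BABA", "n_snps") %in% names(tab)))
  # the introgressed focal individual tops the table
  expect_gt(tab$D[1], max(tab$D[2:3]))

  expect_equal(nrow(qp_dstat_table(gm, "outgroup", list())), 0)
  expect_error(qp_dstat_table(gm, "outgroup", list(c("speciesA", "nope", "B1"))),
               "nope")
})
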