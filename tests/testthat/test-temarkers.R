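test_that("coverage gaps are maximal runs with exact boundaries", {
  flat <- simulate_te_coverage(600, gaps = list(), depth = 10, seed = 1)
  expect_equal(nrow(coverage_gaps(flat, min_length = 1)), 0)

  one <- simulate_te_coverage(1000, gaps = list(c(100, 600)), depth = 10,
                              seed = 2)
  g <- coverage_gaps(one)
  expect_equal(g$start, 100)
  expect_equal(g$end, 600)

  # two gaps separated by a single covered base stay separate
  cov <- rep(5L, 900)
  cov[101:400] <- 0L   # gap [100, 400)
  cov[402:700] <- 0L   # gap [401, 700)
  g2 <- coverage_gaps(cov, min_length = 250)
  expect_equal(g2$start, c(100, 401))
  expect_equal(g2$end, c(400, 700))

  # min_length and max_depth behave as thresholds
  expect_equal(nrow(coverage_gaps(cov, min_length = 301)), 0)
  cov2 <- rep(2L, 600); cov2[101:400] <- 1L
  expect_equal(nrow(coverage_gaps(cov2, max_depth = 0, min_length = 100)), 0)
  expect_equal(coverage_gaps(cov2, max_depth = 1, min_length = 100)$start, 100)
})

test_that("Wallace and nearest-neighbor Tm formulas", {
  expect_equal(tm_wallace("AAAATTTT"), 16)
  expect_equal(tm_wallace("GGGGCCCC"), 32)
  expect_error(tm_wallace("AAAANTTT"), "ambiguous|non-ACGT")
  expect_error(tm_nn("ACGT"), "at least 8")

  # frozen oracle values from an independent nearest-neighbor calculator
  # (unified parameter set, Na 50 mM, 25 nM strand concentrations)
  expect_equal(tm_nn("AGTTCCAGGGAGCTATGCTGGGT"), 59.100, tolerance = 0.01)
  expect_equal(tm_nn("CACAGATGGAGCCCCTGCTA"), 55.403, tolerance = 0.01)
  expect_equal(tm_nn("ACGTTGTGTTGATGTAGCTTGGT"), 55.091, tolerance = 0.01)
})

test_that("primer design fills a balanced gap and explains empty results", {
  te <- simulate_te_coverage(1500, gaps = list(c(500, 1000)), depth = 25,
                             seed = 5)
  gap <- coverage_gaps(te)
  pairs <- design_primers(te, gap[1, ])
  expect_gt(nrow(pairs), 0)
  seq_str <- te$te$sequence
  for (i in seq_len(nrow(pairs))) {
    expect_gte(pairs$fwd_start[i], gap$start[1])
    expect_lte(pairs$rev_end[i], gap$end[1])
    expect_true(pairs$product_length[i] >= 200 &
                  pairs$product_length[i] <= 500)
    expect_equal(pairs$product_length[i],
                 pairs$rev_end[i] - pairs$fwd_start[i])
    # sequences are literal template substrings / reverse complements
    fl <- nchar(pairs$fwd_seq[i])
    expect_identical(pairs$fwd_seq[i],
                     substr(seq_str, pairs$fwd_start[i] + 1,
                            pairs$fwd_start[i] + fl))
    rl <- nchar(pairs$rev_seq[i])
    tmpl <- substr(seq_str, pairs$rev_end[i] - rl + 1, pairs$rev_end[i])
    expect_identical(pairs$rev_seq[i], introkit:::revcomp(tmpl))
  }

  short <- design_primers(te, c(start = 100, end = 250))
  expect_equal(nrow(short), 0)
  expect_gt(attr(short, "rejections")[["product_length"]], 0)

  at_te <- list(name = "atTE",
                sequence = paste(rep("AT", 400), collapse = ""))
  at_pairs <- design_primers(at_te, c(start = 100, end = 700))
  expect_equal(nrow(at_pairs), 0)
  rej <- attr(at_pairs, "rejections")
  expect_equal(names(which.max(rej[c("gc", "tm", "homopolymer", "clamp")])),
               "gc")
})

test_that("design output is deterministic and invariant-safe on random TEs", {
  for (s in 1:6) {
    te <- simulate_te_coverage(1200, gaps = list(c(300, 900)), depth = 20,
                               seed = s)
    p1 <- design_primers(te, c(start = 300, end = 900))
    p2 <- design_primers(te, c(start = 300, end = 900))
    expect_identical(p1, p2)
    if (nrow(p1)) {
      expect_true(all(p1$fwd_start >= 300 & p1$rev_end <= 900))
      expect_true(all(p1$product_length >= 200 & p1$product_length <= 500))
      expect_true(all(abs(p1$fwd_tm - p1$rev_tm) <= 3.5))
    }
  }
})

test_that("in-silico screen amplifies planted TEs and respects 3' anchoring", {
  te <- simulate_te_coverage(1200, gaps = list(c(300, 900)), depth = 20,
                             seed = 17)
  pairs <- design_primers(te, c(start = 300, end = 900))
  expect_gt(nrow(pairs), 0)
  best <- pairs[1, ]
  set.seed(1)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  genome_with <- paste0(flank(500), te$te$sequence, flank(500))
  # deleting the gap region removes the amplicon template
  genome_without <- paste0(flank(500),
                           paste0(substr(te$te$sequence, 1, 300),
                                  substr(te$te$sequence, 901, 1200)),
                           flank(500))
  hits <- screen_primers_in_silico(best, c(target = genome_with,
                                           deleted = genome_without))
  expect_true("target" %in% hits$subject)
  expect_false("deleted" %in% hits$subject)
  expect_equal(hits$length[hits$subject == "target"],
               best$product_length)

  # one mismatch at the forward primer's 3'-terminal base kills the product
  fwd_end <- 500 + best$fwd_start + nchar(best$fwd_seq)  # 1-based in genome
  g <- strsplit(genome_with, "")[[1]]
  g[fwd_end] <- setdiff(c("A", "C", "G", "T"), g[fwd_end])[1]
  mutated <- paste(g, collapse = "")
  hits_mut <- screen_primers_in_silico(best, c(mut = mutated))
  expect_equal(nrow(hits_mut), 0)
})

test_that("the published TE primer panel passes the default constraints", {
  panel <- utils::read.delim(system.file("extdata", "te_primer_panel.tsv",
                                         package = "introkit"))
  expect_equal(nrow(panel), 24)
  expect_equal(sum(panel$te_class == "DNA") / 2, 7)
  expect_equal(sum(panel$te_class == "RNA") / 2, 5)
  chk <- check_primer_constraints(panel$sequence)
  expect_true(all(chk[, "all"]))
  # pairs stay within the Tm-difference window
  tm <- attr(chk, "tm")
  by_te <- split(tm, panel$te_name)
  expect_true(all(vapply(by_te, function(x) abs(diff(x)) <= 3.5,
                         logical(1))))
  # printed product lengths all sit inside the default design window
  expect_true(all(panel$product_length >= 200 & panel$product_length <= 500))
})

test_that("coverage files round-trip through both supported formats", {
  cov <- simulate_te_coverage(400, gaps = list(c(50, 120)), depth = 9,
                              seed = 3)$coverage
  depth_tsv <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame("te", seq_along(cov), cov)[cov > 0, ],
                     depth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_equal(read_coverage(depth_tsv, 400), cov)

  r <- rle(cov)
  ends <- cumsum(r$lengths)
  bg <- data.frame("te", ends - r$lengths, ends, r$values)
  bg_path <- tempfile(fileext = ".bedgraph")
  utils::write.table(bg, bg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_equal(read_coverage(bg_path, 400), cov)
})
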