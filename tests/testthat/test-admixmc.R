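test_that("chain initialization: copy bookkeeping, K=1, determinism", {
  gm <- toy_matrix(list(c(0L, 1L, NA), c(2L, 1L, 0L)))
  cfg <- admix_config(K = 2, burnin = 0, reps = 10, seed = 1)
  set.seed(1)
  st <- init_chain(gm, cfg)
  copies <- Reduce(`+`, st$z_alt) + Reduce(`+`, st$z_ref)
  non_missing <- !is.na(gm$dosage)
  expect_equal(copies, 2L * non_missing + 0L, ignore_attr = TRUE)
  expect_equal(rowSums(st$Q), c(1, 1), ignore_attr = TRUE,
               tolerance = 1e-12)

  cfg1 <- admix_config(K = 1, burnin = 0, reps = 10, seed = 1)
  set.seed(1)
  st1 <- init_chain(gm, cfg1)
  expect_true(all(st1$Q == 1))
  expect_length(st1$z_alt, 1)

  set.seed(42); a <- init_chain(gm, cfg)
  set.seed(42); b <- init_chain(gm, cfg)
  expect_identical(a, b)
})

test_that("ancestry update matches the closed-form Dirichlet mean", {
  n_ik <- rbind(c(3, 1), c(0, 4))
  alpha <- 0.7
  set.seed(8)
  draws <- replicate(4000, introkit:::update_Q(n_ik, alpha))
  m <- apply(draws, c(1, 2), mean)
  expected <- (alpha + n_ik) / (2 * alpha + rowSums(n_ik))
  expect_lt(max(abs(m - expected)), 0.02)
})

test_that("MH acceptance ratios are exactly zero for identity proposals", {
  set.seed(3)
  f_row <- runif(50, 0.05, 0.95)
  pa <- runif(50, 0.05, 0.95)
  expect_identical(introkit:::mh_logratio_F(f_row, pa, 0.3, 0.3, 2, 0.05), 0)
  Q <- introkit:::rdirichlet(5, c(1, 1))
  expect_identical(introkit:::mh_logratio_alpha(Q, 1.3, 1.3), 0)
  f <- rbind(f_row, f_row)
  expect_identical(introkit:::mh_logratio_p_anc(f, c(0.2, 0.2), pa, pa),
                   rep(0, 50))
})

test_that("full-conditional sweep matches exhaustive enumeration on a toy", {
  # 2 samples x 2 loci, all heterozygous: 8 allele copies, 2^8 assignments.
  # Uncorrelated model, fixed alpha; frequencies and Q integrated out
  # analytically in the oracle, sampled by MCMC in the implementation.
  gm <- toy_matrix(list(c(1L, 1L), c(1L, 1L)))
  lambda <- 1; alpha <- 1; K <- 2
  # oracle: enumerate origin vectors for the 8 copies (4 alt, 4 ref)
  copies <- expand.grid(rep(list(0:1), 8))  # 1 = cluster 2
  # copy layout: (sample, locus, type): s1l1 alt, s1l1 ref, s1l2 alt,
  # s1l2 ref, s2l1 alt, s2l1 ref, s2l2 alt, s2l2 ref
  log_post <- apply(copies, 1, function(z) {
    n_i1 <- c(4 - sum(z[1:4]), 4 - sum(z[5:8]))   # copies in cluster 1
    lp <- 0
    for (i in 1:2) {
      lp <- lp + lgamma(K * alpha) - lgamma(K * alpha + 4) +
        lgamma(alpha + n_i1[i]) + lgamma(alpha + 4 - n_i1[i]) -
        2 * lgamma(alpha)
    }
    for (k in 0:1) {
      for (l in 1:2) {
        alt_idx <- c(1, 5) + (l - 1) * 2
        ref_idx <- alt_idx + 1
        ca <- sum(z[alt_idx] == k)
        cr <- sum(z[ref_idx] == k)
        lp <- lp + lbeta(lambda + ca, lambda + cr) - lbeta(lambda, lambda)
      }
    }
    lp
  })
  w <- exp(log_post - max(log_post)); w <- w / sum(w)
  # label-invariant statistic: probability the two samples' alt copies at
  # locus 1 share an origin
  co_exact <- sum(w * (copies[[1]] == copies[[5]]))

  cfg <- admix_config(K = 2, burnin = 0, reps = 1, model = "uncorrelated",
                      alpha_mode = "fixed", alpha_init = alpha,
                      lambda = lambda, seed = 1)
  set.seed(99)
  st <- init_chain(gm, cfg)
  n_sweep <- 6000
  co <- logical(n_sweep)
  for (s in seq_len(n_sweep)) {
    st <- gibbs_sweep(st)
    z1 <- st$z_alt[[1]]
    co[s] <- z1[1, 1] == z1[2, 1]
  }
  co_mcmc <- mean(co[-(1:500)])
  expect_lt(abs(co_mcmc - co_exact), 0.03)
})

test_that("symmetric one-sample problem returns symmetric ancestry", {
  gm <- toy_matrix(list(c(1L)))
  cfg <- admix_config(K = 2, burnin = 200, reps = 2000,
                      model = "uncorrelated", alpha_mode = "fixed", seed = 5)
  res <- run_admixture(gm, cfg)
  expect_equal(unname(res$Q_mean[1, ]), c(0.5, 0.5), tolerance = 0.06)
  expect_equal(sum(res$Q_mean[1, ]), 1, tolerance = 1e-9)
})

test_that("well-separated species are assigned pure ancestry", {
  cfg <- sim_config(n_loci = 2000, F_A = 0.3, F_B = 0.3,
                    introgression_alpha = 0, seed = 21)
  gm <- drop_outgroup(simulate_study(cfg)$matrix)
  res <- run_admixture(gm, admix_config(K = 2, burnin = 200, reps = 300,
                                        seed = 7))
  expect_true(all(apply(res$Q_mean, 1, max) >= 0.99))
  expect_true(all(abs(rowSums(res$Q_mean) - 1) < 1e-9))
  expect_true(all(res$Q_lo <= res$Q_mean + 1e-12 &
                    res$Q_mean <= res$Q_hi + 1e-12))
})

test_that("K = 1 and reps = 0 degenerate cases", {
  gm <- toy_matrix(list(c(0L, 1L), c(2L, 1L)))
  res <- run_admixture(gm, admix_config(K = 1, burnin = 10, reps = 50,
                                        seed = 2))
  expect_true(all(res$Q_mean == 1))
  expect_true(all(res$Q_lo == 1 & res$Q_hi == 1))
  expect_error(run_admixture(gm, admix_config(K = 2, reps = 0)), "reps")
})

test_that("independent chains agree after label alignment", {
  cfg <- sim_config(n_loci = 1500, introgression_alpha = 0.3, seed = 33)
  gm <- drop_outgroup(simulate_study(cfg)$matrix)
  res <- run_admixture(gm, admix_config(K = 2, burnin = 300, reps = 400,
                                        alpha_mode = "fixed", seed = 11,
                                        n_chains = 2))
  expect_false(is.null(res$convergence))
  expect_lt(res$convergence$max_dQ, 0.08)
})

test_that("a lightly admixed focal sample outranks its conspecifics", {
  n_rep <- 6
  focal <- conspec <- numeric(0)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_loci = 5000, introgression_alpha = 0.01,
                      seed = 400 + r)
    gm <- drop_outgroup(simulate_study(cfg)$matrix)
    res <- run_admixture(gm, admix_config(K = 2, burnin = 300, reps = 400,
                                          alpha_mode = "fixed",
                                          seed = 800 + r))
    focal <- c(focal, minor_ancestry(res, "B1"))
    conspec <- c(conspec, vapply(paste0("B", 2:5), minor_ancestry,
                                 numeric(1), res = res))
  }
  wt <- stats::wilcox.test(focal, conspec, alternative = "greater")
  expect_lt(wt$p.value, 0.05)
})
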