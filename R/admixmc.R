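#' Configuration for the Bayesian admixture sampler
#'
#' Settings of the admixture-ancestry mixture model: each of an
#' individual's allele copies originates from one of K clusters with
#' per-individual proportions Q (the ancestry fractions); cluster allele
#' frequencies are either independent Beta(lambda, lambda) draws
#' (`model = "uncorrelated"`) or, in the correlated-frequency F-model, tied
#' to a shared ancestral frequency `p_A` through per-cluster drift
#' parameters `F_k` via `f_kl ~ Beta(p_A(1-F_k)/F_k, (1-p_A)(1-F_k)/F_k)`.
#' Inference is by MCMC: conjugate Gibbs updates for the copy origins, the
#' cluster frequencies and Q; Metropolis-Hastings for `p_A`, `F_k` and
#' (optionally) the Dirichlet concentration alpha, with step sizes adapted
#' to a 20-50% acceptance rate during burn-in.
#'
#' The default chain lengths (10,000 burn-in + 20,000 kept sweeps) are the
#' full-analysis settings; tests and scaled-down studies use shorter
#' chains.
#'
#' @param K number of clusters (default 2).
#' @param burnin,reps burn-in sweeps and kept post-burn-in sweeps.
#' @param model `"correlated"` (default) or `"uncorrelated"`.
#' @param alpha_mode `"infer"` (MH with uniform prior on (0, 10]) or
#'   `"fixed"`.
#' @param alpha_init initial/fixed symmetric Dirichlet concentration.
#' @param lambda Beta prior parameter for allele frequencies.
#' @param F_prior Gamma (shape, scale) prior for the drift parameters.
#' @param seed integer seed.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param n_chains independent chains (>= 2 adds a convergence report:
#'   the maximum absolute difference in Q_mean across chains).
#' @param store_trace keep the full Q trace in the result.
#' @return object of class `admix_config`.
#' @export
admix_config <- function(K = 2, burnin = 10000, reps = 20000,
                         model = c("correlated", "uncorrelated"),
                         alpha_mode = c("infer", "fixed"),
                         alpha_init = 1.0, lambda = 1.0,
                         F_prior = c(shape = 2.0, scale = 0.05),
                         seed = 1, thin = 1, n_chains = 1,
                         store_trace = FALSE) {
  model <- match.arg(model)
  alpha_mode <- match.arg(alpha_mode)
  stopifnot(K >= 1, burnin >= 0, reps >= 0, thin >= 1, alpha_init > 0,
            lambda > 0, all(F_prior > 0))
  structure(list(K = as.integer(K), burnin = as.integer(burnin),
                 reps = as.integer(reps), model = model,
                 alpha_mode = alpha_mode, alpha_init = alpha_init,
                 lambda = lambda, F_prior = F_prior,
                 seed = as.integer(seed), thin = as.integer(thin),
                 n_chains = as.integer(n_chains),
                 store_trace = isTRUE(store_trace)),
            class = "admix_config")
}

#' Initialize an MCMC chain state
#'
#' Copy origins are drawn uniformly over the K clusters, ancestry rows from
#' Dirichlet(alpha_init), and cluster frequencies from their prior. Missing
#' genotypes contribute no allele copies.
#'
#' @param matrix a biallelic-filtered [genotype_matrix()].
#' @param config an [admix_config()].
#' @return chain state (list); fields `z_alt`/`z_ref` hold the per-cluster
#'   origin counts of alt/ref allele copies (one origin per copy, two
#'   copies per sample per non-missing locus).
#' @export
init_chain <- function(matrix, config) {
  if (any(is_multiallelic(matrix))) {
    stop("admixture model requires a biallelic matrix; run filter_biallelic()")
  }
  dos <- matrix$dosage
  S <- nrow(dos); L <- ncol(dos); K <- config$K
  a <- dos; a[is.na(a)] <- 0L                 # alt copies per (i, l)
  r <- 2L - dos; r[is.na(dos)] <- 0L          # ref copies per (i, l)
  eps <- 1e-9
  unif <- lapply(seq_len(K), function(k) matrix(1 / K, S, L))
  z_alt <- sample_multinomial_counts(a, unif)
  z_ref <- sample_multinomial_counts(r, unif)
  Q <- rdirichlet(S, rep(config$alpha_init, K))
  rownames(Q) <- rownames(dos)
  if (config$model == "correlated") {
    p_anc <- stats::runif(L, eps, 1 - eps)
    Fk <- pmin(stats::rgamma(K, shape = config$F_prior[["shape"]],
                             scale = config$F_prior[["scale"]]) + eps, 0.9)
    f <- t(vapply(seq_len(K), function(k) {
      clip01(stats::rbeta(L, p_anc * (1 - Fk[k]) / Fk[k],
                          (1 - p_anc) * (1 - Fk[k]) / Fk[k]), eps)
    }, numeric(L)))
  } else {
    p_anc <- NULL
    Fk <- rep(NA_real_, K)
    f <- matrix(clip01(stats::rbeta(K * L, config$lambda, config$lambda),
                       eps), K, L)
  }
  list(a = a, r = r, z_alt = z_alt, z_ref = z_ref, Q = Q, f = f,
       p_anc = p_anc, Fk = Fk, alpha = config$alpha_init, config = config,
       steps = list(pa = 0.1, F = 0.05, alpha = 0.05),
       acc = list(pa = c(0, 0), F = c(0, 0), alpha = c(0, 0)))
}

clip01 <- function(x, eps = 1e-9) {
  x[!is.finite(x)] <- 0.5
  pmin(pmax(x, eps), 1 - eps)
}

rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  bad <- rowSums(g) == 0
  g[bad, ] <- 1
  g / rowSums(g)
}

# Vectorized multinomial splitting of count matrices: n_mat[i,l] trials are
# assigned to K categories with (unnormalized) weight matrices W[[k]].
sample_multinomial_counts <- function(n_mat, W) {
  K <- length(W)
  S <- nrow(n_mat); L <- ncol(n_mat)
  if (K == 1) return(list(n_mat))
  rem <- n_mat
  prob_rem <- Reduce(`+`, W)
  out <- vector("list", K)
  for (k in seq_len(K - 1)) {
    pk <- W[[k]] / prob_rem
    pk[!is.finite(pk)] <- 1 / (K - k + 1)
    draw <- matrix(stats::rbinom(S * L, c(rem), c(pmin(pmax(pk, 0), 1))),
                   S, L)
    out[[k]] <- draw
    rem <- rem - draw
    prob_rem <- prob_rem - W[[k]]
  }
  out[[K]] <- rem
  out
}

# MH log acceptance ratios, factored out so their detailed-balance
# properties are directly testable.
mh_logratio_F <- function(f_row, p_anc, F_new, F_old, shape, scale) {
  lp <- function(F) {
    sum(stats::dbeta(f_row, p_anc * (1 - F) / F,
                     (1 - p_anc) * (1 - F) / F, log = TRUE)) +
      stats::dgamma(F, shape = shape, scale = scale, log = TRUE)
  }
  lp(F_new) - lp(F_old)
}

mh_logratio_alpha <- function(Q, a_new, a_old) {
  K <- ncol(Q)
  ld <- function(a) {
    nrow(Q) * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * sum(log(Q))
  }
  ld(a_new) - ld(a_old)
}

# per-locus vector of log ratios for the ancestral-frequency update
mh_logratio_p_anc <- function(f, Fk, pa_new, pa_old) {
  out <- 0
  for (k in seq_len(nrow(f))) {
    ck <- (1 - Fk[k]) / Fk[k]
    out <- out +
      stats::dbeta(f[k, ], pa_new * ck, (1 - pa_new) * ck, log = TRUE) -
      stats::dbeta(f[k, ], pa_old * ck, (1 - pa_old) * ck, log = TRUE)
  }
  out
}

#' One full Gibbs/Metropolis sweep
#'
#' (a) every allele copy's origin is resampled with probability
#' proportional to `q_ik f_kl` (alt copies) or `q_ik (1 - f_kl)` (ref
#' copies); (b) cluster allele frequencies are Gibbs-updated from their
#' Beta full conditional (uncorrelated: Beta(lambda + alt, lambda + ref);
#' correlated: the F-model Beta prior plus the copy counts), followed in
#' the correlated model by MH updates of each ancestral frequency and each
#' drift parameter `F_k`; (c) ancestry rows are redrawn from
#' Dirichlet(alpha + n_i1, ..., alpha + n_iK); (d) when alpha is inferred,
#' a Gaussian-step MH update with uniform prior on (0, 10].
#'
#' @param state chain state from [init_chain()] or a previous sweep.
#' @param adapt if `TRUE` (burn-in), MH step sizes are adapted.
#' @return updated state.
#' @export
gibbs_sweep <- function(state, adapt = FALSE) {
  cfg <- state$config
  K <- cfg$K
  S <- nrow(state$a); L <- ncol(state$a)
  eps <- 1e-9
  # (a) copy origins
  W_alt <- lapply(seq_len(K), function(k) outer(state$Q[, k], state$f[k, ]))
  W_ref <- lapply(seq_len(K), function(k) outer(state$Q[, k],
                                                1 - state$f[k, ]))
  state$z_alt <- sample_multinomial_counts(state$a, W_alt)
  state$z_ref <- sample_multinomial_counts(state$r, W_ref)
  c_alt <- t(vapply(state$z_alt, colSums, numeric(L)))
  c_ref <- t(vapply(state$z_ref, colSums, numeric(L)))
  if (L == 1) { c_alt <- matrix(c_alt, K, 1); c_ref <- matrix(c_ref, K, 1) }
  # (b) cluster frequencies (conjugate Beta full conditionals)
  if (cfg$model == "uncorrelated") {
    for (k in seq_len(K)) {
      state$f[k, ] <- clip01(stats::rbeta(L, cfg$lambda + c_alt[k, ],
                                          cfg$lambda + c_ref[k, ]), eps)
    }
  } else {
    for (k in seq_len(K)) {
      ck <- (1 - state$Fk[k]) / state$Fk[k]
      state$f[k, ] <- clip01(
        stats::rbeta(L, state$p_anc * ck + c_alt[k, ],
                     (1 - state$p_anc) * ck + c_ref[k, ]), eps)
    }
    # MH: ancestral frequencies (uniform prior, reflected Gaussian step)
    prop <- state$p_anc + stats::rnorm(L, 0, state$steps$pa)
    prop <- abs(prop); prop <- ifelse(prop > 1, 2 - prop, prop)
    prop <- clip01(prop, eps)
    logr <- mh_logratio_p_anc(state$f, state$Fk, prop, state$p_anc)
    acc <- is.finite(logr) & log(stats::runif(L)) < logr
    state$p_anc[acc] <- prop[acc]
    state$acc$pa <- state$acc$pa + c(sum(acc), L)
    # MH: drift parameters
    for (k in seq_len(K)) {
      Fp <- state$Fk[k] + stats::rnorm(1, 0, state$steps$F)
      ok <- Fp > 1e-4 && Fp < 1 - 1e-4
      if (ok) {
        logr <- mh_logratio_F(state$f[k, ], state$p_anc, Fp, state$Fk[k],
                              cfg$F_prior[["shape"]], cfg$F_prior[["scale"]])
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          state$Fk[k] <- Fp
          state$acc$F <- state$acc$F + c(1, 0)
        }
      }
      state$acc$F <- state$acc$F + c(0, 1)
    }
  }
  # (c) ancestry proportions
  n_ik <- vapply(seq_len(K),
                 function(k) rowSums(state$z_alt[[k]] + state$z_ref[[k]]),
                 numeric(S))
  n_ik <- matrix(n_ik, S, K)
  state$n_ik <- n_ik
  state$Q <- update_Q(n_ik, state$alpha)
  rownames(state$Q) <- rownames(state$a)
  # (d) concentration parameter
  if (cfg$alpha_mode == "infer" && K > 1) {
    ap <- state$alpha + stats::rnorm(1, 0, state$steps$alpha)
    if (ap > 0 && ap <= 10) {
      logr <- mh_logratio_alpha(state$Q, ap, state$alpha)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        state$alpha <- ap
        state$acc$alpha <- state$acc$alpha + c(1, 0)
      }
    }
    state$acc$alpha <- state$acc$alpha + c(0, 1)
  }
  if (adapt) state <- adapt_steps(state)
  state
}

update_Q <- function(n_ik, alpha) {
  S <- nrow(n_ik); K <- ncol(n_ik)
  g <- matrix(stats::rgamma(S * K, shape = c(alpha + n_ik)), S, K)
  bad <- rowSums(g) == 0
  g[bad, ] <- 1
  g / rowSums(g)
}

adapt_steps <- function(state, every = 25) {
  for (nm in names(state$acc)) {
    cnt <- state$acc[[nm]]
    if (cnt[2] >= every) {
      rate <- cnt[1] / cnt[2]
      if (rate < 0.2) state$steps[[nm]] <- state$steps[[nm]] * 0.7
      if (rate > 0.5) state$steps[[nm]] <- state$steps[[nm]] * 1.4
      state$steps$pa <- min(state$steps$pa, 0.5)
      state$acc[[nm]] <- c(0, 0)
    }
  }
  state
}

# best permutation of clusters matching frequency rows to a reference
best_permutation <- function(f, f_ref) {
  K <- nrow(f)
  if (K == 1) return(1L)
  if (K <= 5) {
    perms <- all_permutations(K)
    costs <- vapply(seq_len(nrow(perms)), function(i) {
      sum(abs(f[perms[i, ], , drop = FALSE] - f_ref))
    }, numeric(1))
    perms[which.min(costs), ]
  } else {
    # greedy matching for larger K
    left <- seq_len(K)
    perm <- integer(K)
    for (k in seq_len(K)) {
      costs <- vapply(left, function(j) sum(abs(f[j, ] - f_ref[k, ])),
                      numeric(1))
      perm[k] <- left[which.min(costs)]
      left <- setdiff(left, perm[k])
    }
    perm
  }
}

all_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(K - 1)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    tail_cols <- if (pos <= K - 1) {
      sub[, pos:(K - 1), drop = FALSE]
    } else {
      matrix(0L, nrow(sub), 0)
    }
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE],
                            rep(K, nrow(sub)), tail_cols))
  }
  storage.mode(out) <- "integer"
  out
}

#' Run the Bayesian admixture analysis
#'
#' Burn-in followed by `reps` kept sweeps; the cluster labels of each kept
#' sweep are aligned to a running frequency reference (greedy matching) to
#' resolve label switching, and the posterior mean and 90% equal-tailed
#' interval (5th-95th percentile) of every ancestry fraction are reported.
#' With `n_chains >= 2` the analysis is rerun from independent seeds and
#' the maximum absolute disagreement in Q_mean across chains is reported as
#' a convergence diagnostic.
#'
#' @param matrix a biallelic-filtered [genotype_matrix()] of the ingroup
#'   samples.
#' @param config an [admix_config()].
#' @return object of class `admixture_result`: `Q_mean`, `Q_lo`, `Q_hi`
#'   (samples x K), `F_mean`, `alpha_mean`, `alpha_sd`, `n_draws`,
#'   `convergence`, `config`, and the Q trace when `store_trace = TRUE`.
#' @export
run_admixture <- function(matrix, config = admix_config()) {
  if (config$reps < 1) stop("reps must be >= 1: no posterior sample otherwise")
  chains <- lapply(seq_len(config$n_chains), function(ci) {
    cfg <- config
    cfg$seed <- config$seed + (ci - 1L)
    run_admixture_chain(matrix, cfg)
  })
  res <- chains[[1]]
  if (config$n_chains > 1) {
    base <- res$Q_mean
    max_dq <- 0
    for (ci in 2:length(chains)) {
      qc <- chains[[ci]]$Q_mean
      perm <- best_permutation(t(qc), t(base))
      max_dq <- max(max_dq, max(abs(qc[, perm] - base)))
    }
    res$convergence <- list(n_chains = config$n_chains, max_dQ = max_dq)
  }
  res
}

run_admixture_chain <- function(matrix, config) {
  set.seed(config$seed)
  state <- init_chain(matrix, config)
  for (b in seq_len(config$burnin)) state <- gibbs_sweep(state, adapt = TRUE)
  S <- nrow(state$Q); K <- config$K
  n_keep <- config$reps %/% config$thin
  if (n_keep < 1) stop("reps/thin must be >= 1")
  Q_draws <- array(NA_real_, c(n_keep, S, K))
  F_draws <- matrix(NA_real_, n_keep, K)
  a_draws <- numeric(n_keep)
  f_ref <- state$f
  kept <- 0L
  for (it in seq_len(config$reps)) {
    state <- gibbs_sweep(state, adapt = FALSE)
    if (it %% config$thin == 0 && kept < n_keep) {
      perm <- best_permutation(state$f, f_ref)
      kept <- kept + 1L
      Q_draws[kept, , ] <- state$Q[, perm, drop = FALSE]
      F_draws[kept, ] <- state$Fk[perm]
      a_draws[kept] <- state$alpha
      f_ref <- 0.9 * f_ref + 0.1 * state$f[perm, , drop = FALSE]
    }
  }
  Q_mean <- apply(Q_draws, c(2, 3), mean)
  Q_lo <- apply(Q_draws, c(2, 3), stats::quantile, probs = 0.05)
  Q_hi <- apply(Q_draws, c(2, 3), stats::quantile, probs = 0.95)
  dimnames(Q_mean) <- dimnames(Q_lo) <- dimnames(Q_hi) <-
    list(rownames(state$Q), paste0("cluster", seq_len(K)))
  structure(list(Q_mean = Q_mean, Q_lo = Q_lo, Q_hi = Q_hi,
                 F_mean = colMeans(F_draws),
                 alpha_mean = mean(a_draws), alpha_sd = stats::sd(a_draws),
                 n_draws = kept, convergence = NULL, config = config,
                 Q_trace = if (config$store_trace) Q_draws else NULL),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat("admixture_result: K =", ncol(x$Q_mean), ",", x$n_draws,
      "posterior draws\n")
  q <- round(x$Q_mean, 3)
  print(q)
  if (!is.null(x$convergence)) {
    cat(sprintf("max |dQ| across %d chains: %.4f\n",
                x$convergence$n_chains, x$convergence$max_dQ))
  }
  invisible(x)
}

#' Write the inferred-ancestry table as TSV
#'
#' One row per sample: population label (if known), the K posterior mean
#' ancestry fractions, and the K 90% probability intervals.
#'
#' @param result an [run_admixture()] result.
#' @param path output file.
#' @param populations optional named vector sample -> population.
#' @export
write_q_table <- function(result, path, populations = NULL) {
  K <- ncol(result$Q_mean)
  df <- data.frame(sample = rownames(result$Q_mean))
  df$population <- if (!is.null(populations)) {
    unname(populations[df$sample])
  } else NA_character_
  for (k in seq_len(K)) {
    df[[paste0("Q", k)]] <- sprintf("%.3f", result$Q_mean[, k])
  }
  for (k in seq_len(K)) {
    df[[paste0("interval", k)]] <- sprintf("%.3f,%.3f", result$Q_lo[, k],
                                           result$Q_hi[, k])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
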