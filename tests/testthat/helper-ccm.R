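# Shared test helpers: independent oracles and a memoised benchmark suite.

# Brute-force tree likelihood by full enumeration of internal-node states,
# using Matrix::expm via transitionProbabilities() -- independent of the
# C++ pruning kernel. `Q` defaults to the community rate matrix but any
# generator (e.g. Pagel's 4-state models) can be supplied.
brute_loglik <- function(tree, tip_states, Q, prior) {
  m <- nrow(Q)
  tp <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  Ps <- lapply(seq_len(nrow(tp$edge)),
               function(e) transitionProbabilities(Q, tp$edge.length[e]))
  internal <- (nt + 1):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), length(internal))))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    assign_ <- integer(nn)
    assign_[seq_len(nt)] <- tip_states + 1L
    assign_[internal] <- grid[r, ]
    term <- prior[assign_[nt + 1L]]
    for (e in seq_len(nrow(tp$edge)))
      term <- term * Ps[[e]][assign_[tp$edge[e, 1]], assign_[tp$edge[e, 2]]]
    tot <- tot + term
  }
  log(tot)
}

brute_ccm_loglik <- function(tree, profiles, params, prior = "uniform") {
  n <- nrow(profiles)
  ts <- as.integer(colSums(profiles[, tree$tip.label, drop = FALSE] *
                             2^(seq_len(n) - 1)))
  pr <- switch(prior,
               uniform = rep(1 / 2^n, 2^n),
               stationary = ccmStationary(params))
  brute_loglik(tree, ts, buildRateMatrix(params), pr)
}

# Random symmetric parameter draw.
rand_params <- function(n, sd_alpha = 0.7, sd_beta = 0.6) {
  b <- matrix(rnorm(n * n, 0, sd_beta), n)
  ccmParams(rnorm(n, 0, sd_alpha), (b + t(b)) / 2)
}

# Closed-form 2-state symmetric chain transition probabilities (unit rate).
p_same <- function(t) (1 + exp(-2 * t)) / 2
p_diff <- function(t) (1 - exp(-2 * t)) / 2

# The full null/interacting pair benchmark (fits, baselines), computed once
# per test session and shared by the acceptance blocks. Sizes follow the
# simulation-study design; the seed is fixed for reproducibility.
.bench_env <- new.env(parent = emptyenv())

get_benchmark <- function(n_each = 500L, seed = 424242L) {
  key <- paste0("b", n_each, "_", seed)
  if (!is.null(.bench_env[[key]])) return(.bench_env[[key]])
  recs <- genBenchmarkPairs(n_null = n_each, n_alt = n_each, n_tips = 100L,
                            beta_range = c(0.2, 0.5), seed = seed)
  out <- data.frame(label = vapply(recs, `[[`, integer(1), "label"),
                    beta_true = vapply(recs, `[[`, numeric(1), "beta12"))
  nrec <- length(recs)
  out$beta_hat <- out$z <- out$p <- out$jaccard <- out$pagel_p <-
    out$runadj_p <- out$clade_hg_p <- out$clade_mi <- NA_real_
  for (i in seq_len(nrec)) {
    tr <- recs[[i]]$tree
    pm <- recs[[i]]$profiles
    f <- fitCCM(tr, pm, seed = derive_seed_t(seed, i))
    out$beta_hat[i] <- f$theta[["beta_12"]]
    out$z[i] <- f$z[["beta_12"]]
    out$p[i] <- f$pvalues[["beta_12"]]
    p1 <- pm[1, tr$tip.label]; p2 <- pm[2, tr$tip.label]
    out$jaccard[i] <- jaccardIndex(p1, p2)
    out$pagel_p[i] <- pagelLRT(tr, p1, p2)$p_value
    out$runadj_p[i] <- runAdjustedScore(tr, p1, p2)
    out$clade_hg_p[i] <- cladeAdjustedScore(tr, p1, p2, "hypergeometric")
    out$clade_mi[i] <- cladeAdjustedScore(tr, p1, p2, "mi")
  }
  .bench_env[[key]] <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

derive_seed_t <- function(master, i) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(i)) %% 2147483647)
}
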