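# Pruning likelihood of community profiles on a tree.

# Resolve a root prior specification to a probability vector of length 2^n.
root_prior <- function(prior, params, root_state = NULL) {
  m <- 2L^params$n
  if (is.numeric(prior)) {
    if (length(prior) != m || any(prior < 0) || abs(sum(prior) - 1) > 1e-8)
      stop("numeric prior must be a probability vector of length 2^n")
    return(prior)
  }
  switch(match.arg(prior, c("uniform", "stationary", "fixed")),
    uniform = rep(1 / m, m),
    stationary = ccmStationary(params),
    fixed = {
      if (is.null(root_state)) stop("fixed prior needs `root_state`")
      p <- numeric(m)
      p[root_state + 1L] <- 1
      p
    })
}

#' Pruning log-likelihood of community profiles
#'
#' Computes the log-likelihood of the observed presence/absence profiles of
#' an `n`-gene community on a rooted tree under the community coevolution
#' model, by Felsenstein's pruning algorithm over the `2^n` joint states.
#' Tip partials are indicators of the observed joint state; each internal
#' node multiplies, over its children, the branch-propagated child partials;
#' the root sums against the prior. Partials are rescaled per node so large
#' trees do not underflow. Transition matrices are applied through the
#' eigendecomposition of the (reversible, hence symmetrizable) rate matrix
#' without ever being formed.
#'
#' @param tree an [ape::phylo] rooted tree with branch lengths.
#' @param profiles 0/1 matrix, `n` genes as rows, genomes as columns;
#'   column names must cover the tree's tip labels.
#' @param params a [ccmParams()] object with `n = nrow(profiles)`.
#' @param prior root state prior: `"uniform"` (default), `"stationary"`,
#'   `"fixed"` (with `root_state`), or a probability vector of length `2^n`.
#' @param root_state 0-based state index for the fixed prior.
#' @return the log-likelihood (natural log).
#' @export
#' @examples
#' tr <- readTree(text = "((a:.3,b:.3):.2,(c:.3,d:.3):.2);")
#' pm <- rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 1, 0, 0))
#' colnames(pm) <- tr$tip.label
#' pruneLoglik(tr, pm, ccmParams(c(0, 0), matrix(c(0, .5, .5, 0), 2)))
pruneLoglik <- function(tree, profiles, params, prior = "uniform",
                        root_state = NULL) {
  profiles <- validateProfiles(profiles)
  if (nrow(profiles) != params$n)
    stop("profiles have ", nrow(profiles), " genes but params are for ",
         params$n)
  tp <- prep_tree(tree)
  ts <- tip_state_index(profiles, tree)
  pr <- root_prior(prior, params, root_state)
  Q <- buildRateMatrix(params)
  ll <- prune_loglik_cpp(Q, tp$edge, tp$elen, ts, pr, tp$n_node,
                         ccmStationary(params, log = TRUE))
  if (!is.finite(ll) && !identical(ll, -Inf))
    stop("non-finite likelihood for parameters: ",
         paste(format(params_to_theta(params), digits = 4), collapse = ", "))
  ll
}

# Likelihood closure with the state-space structure precomputed: the
# inference hot path. Builds Q, the stationary log-weights and the root
# prior directly from the packed parameter vector without intermediate
# objects.
ccm_loglik_factory <- function(n, tp, ts, prior_spec, root_state = NULL) {
  m <- 2L^n
  S <- state_matrix(n)                       # states x genes, spins
  pairs <- if (n > 1L) t(combn(n, 2L)) else matrix(integer(0), 0, 2)
  Z <- if (nrow(pairs)) S[, pairs[, 1], drop = FALSE] *
         S[, pairs[, 2], drop = FALSE] else matrix(0, m, 0)
  # Q[i, flip(i, k)] = rate of gene k flipping out of state i
  flip_idx <- matrix(0L, m, n)
  for (k in seq_len(n))
    flip_idx[, k] <- bitwXor(0:(m - 1L), bitwShiftL(1L, k - 1L)) + 1L
  qpos <- cbind(rep(seq_len(m), n), as.vector(flip_idx))
  # theta -> (alphas, diag beta, full beta matrix) index maps
  bpos <- matrix(0L, n, n)
  i <- n
  for (k in seq_len(n)) for (h in seq_len(k)) {
    i <- i + 1L
    bpos[h, k] <- bpos[k, h] <- i
  }
  fixed_prior <- if (is.numeric(prior_spec)) prior_spec
    else if (prior_spec == "uniform") rep(1 / m, m)
    else if (prior_spec == "fixed") {
      p <- numeric(m); p[root_state + 1L] <- 1; p
    } else NULL

  function(theta) {
    alphas <- theta[seq_len(n)]
    B <- matrix(theta[bpos], n, n)
    db <- diag(B)
    # log rate of gene k flipping out of state x:
    # alpha_k + b_kk - b_kk x_k - x_k (B x)_k
    M1 <- S %*% B
    logT <- rep(alphas + db, each = m) - S * rep(db, each = m) - S * M1
    Q <- matrix(0, m, m)
    Q[qpos] <- exp(logT)
    diag(Q) <- -rowSums(Q)
    # reversible stationary log-weights (Ising form)
    s <- as.vector(S %*% db) + if (ncol(Z)) as.vector(Z %*% B[pairs]) else 0
    log_pi <- s - logsumexp(s)
    prior <- if (is.null(fixed_prior)) exp(log_pi) else fixed_prior
    prune_loglik_cpp(Q, tp$edge, tp$elen, ts, prior, tp$n_node, log_pi)
  }
}

# Single-call convenience used by pruneLoglik-independent callers.
ccm_loglik_prepped <- function(theta, n, tp, ts, prior_spec, root_state = NULL) {
  ccm_loglik_factory(n, tp, ts, prior_spec, root_state)(theta)
}

#' Penalized negative log-likelihood
#'
#' The fitting objective: `-log L + lambda * ||theta||_2^2`, where `theta`
#' concatenates all intrinsic rates and the free (upper-triangle, diagonal
#' included) interaction coefficients. The ridge penalty is not meant for
#' sparsity; it smooths the likelihood surface in the occasional
#' ill-conditioned case (see [autoLambda()]).
#'
#' @inheritParams pruneLoglik
#' @param lambda nonnegative penalty weight.
#' @return the penalized objective value.
#' @export
penalizedNll <- function(tree, profiles, params, lambda = 0,
                         prior = "uniform", root_state = NULL) {
  if (lambda < 0) stop("lambda must be nonnegative")
  th <- params_to_theta(params)
  -pruneLoglik(tree, profiles, params, prior, root_state) +
    lambda * sum(th^2)
}
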