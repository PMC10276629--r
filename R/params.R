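#' Community Coevolution Model parameters
#'
#' Bundles the parameters of an `n`-gene community: the intrinsic rates
#' `alphas` (log-scale mean of each gene's gain and loss rates, per unit
#' branch length) and the symmetric `n x n` matrix `beta`, whose off-diagonal
#' entries are pairwise interaction coefficients and whose diagonal entries
#' are half the log-scale difference between each gene's gain and loss rates
#' (so log gain = `alpha + beta_kk`, log loss = `alpha - beta_kk`).
#'
#' @param alphas numeric vector of length `n`.
#' @param beta symmetric numeric `n x n` matrix (a scalar is accepted for
#'   `n = 1`).
#' @param gene_names optional gene ids (default `g1..gn`).
#' @return an object of class `ccm_params` with elements `n`, `alphas`,
#'   `beta`, `gene_names`.
#' @export
#' @examples
#' p <- ccmParams(alphas = c(0, 0), beta = matrix(c(0, .5, .5, 0), 2))
ccmParams <- function(alphas, beta, gene_names = NULL) {
  alphas <- as.numeric(alphas)
  n <- length(alphas)
  if (n < 1L) stop("need at least one gene")
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(n, n)))
    stop("`beta` must be an ", n, " x ", n, " matrix")
  if (!all(is.finite(alphas)) || !all(is.finite(beta)))
    stop("parameters must be finite")
  if (max(abs(beta - t(beta))) > 1e-8)
    stop("`beta` must be symmetric")
  beta <- (beta + t(beta)) / 2
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(n))
  structure(list(n = n, alphas = alphas, beta = beta,
                 gene_names = gene_names),
            class = "ccm_params")
}

#' @export
print.ccm_params <- function(x, ...) {
  cat("CCM parameters for a community of", x$n, "gene(s)\n")
  cat("alphas:", format(x$alphas, digits = 4), "\n")
  cat("beta:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Spin vector of a community state
#'
#' Community states are indexed `0 .. 2^n - 1`, gene `k` occupying bit
#' `k - 1` (little-endian): bit 0 means the gene is absent (`-1`), bit 1
#' present (`+1`).
#'
#' @param index state index in `0 .. 2^n - 1`.
#' @param n community size.
#' @return integer vector in `{-1, +1}^n`.
#' @seealso [stateIndex()] for the inverse.
#' @export
stateVector <- function(index, n) {
  if (index < 0 || index > 2^n - 1) stop("state index out of range")
  bits <- bitwAnd(bitwShiftR(as.integer(index), seq_len(n) - 1L), 1L)
  2L * bits - 1L
}

#' State index of a spin vector
#'
#' @param x vector in `{-1, +1}^n`.
#' @return state index in `0 .. 2^n - 1`.
#' @export
stateIndex <- function(x) {
  if (!all(x %in% c(-1L, 1L))) stop("spin vector entries must be -1 or +1")
  sum((x == 1L) * 2^(seq_along(x) - 1L))
}

# All 2^n spin vectors as a matrix (states in rows, genes in columns).
state_matrix <- function(n) {
  m <- 2L^n
  S <- matrix(0L, m, n)
  for (i in seq_len(m)) S[i, ] <- stateVector(i - 1L, n)
  S
}

#' Instantaneous transition rate of one gene
#'
#' Rate at which gene `k` flips state while the community sits in spin state
#' `x`: `tau = exp(alpha_k - beta_kk x_k - sum_{h != k} beta_hk x_k x_h)`.
#' The first factor `exp(alpha_k - beta_kk x_k)` is the gene's intrinsic
#' gain/loss rate; the remaining factor is the influence of the community,
#' with positive interaction coefficients slowing transitions that would
#' break agreement between coupled genes.
#'
#' @param params a [ccmParams()] object.
#' @param state spin vector in `{-1, +1}^n` or a state index.
#' @param k gene index in `1..n`.
#' @return the positive transition rate.
#' @export
transitionRate <- function(params, state, k) {
  n <- params$n
  if (k < 1 || k > n) stop("gene index out of range")
  x <- if (length(state) == 1L && n > 1L) stateVector(state, n) else state
  if (length(x) == 1L && n == 1L && !x %in% c(-1, 1)) x <- stateVector(x, n)
  b <- params$beta
  inter <- if (n > 1L) sum(b[-k, k] * x[-k]) else 0
  exp(params$alphas[k] - b[k, k] * x[k] - x[k] * inter)
}

# Vector of all n transition rates at spin state x (simulator hot path).
transition_rates <- function(params, x) {
  bx <- as.vector(params$beta %*% x)
  d <- diag(params$beta)
  exp(params$alphas - d * x - x * bx + d)
}

#' Build the community rate matrix Q
#'
#' Constructs the `2^n x 2^n` instantaneous rate matrix over joint presence
#' states: `q_ij` is the single-gene flip rate when states `i` and `j`
#' differ at exactly one gene, 0 when they differ at two or more, and rows
#' sum to zero.
#'
#' @param params a [ccmParams()] object.
#' @param max_n capacity guard on the community size (default 12).
#' @return the rate matrix, rows/columns indexed by state index + 1.
#' @export
buildRateMatrix <- function(params, max_n = 12L) {
  n <- params$n
  if (n > max_n)
    stop("community size ", n, " exceeds the capacity guard (", max_n,
         "); the 2^n state space would be too large")
  m <- 2L^n
  S <- state_matrix(n)
  Q <- matrix(0, m, m)
  for (i in seq_len(m)) {
    x <- S[i, ]
    rates <- transition_rates(params, x)
    for (k in seq_len(n)) {
      j <- bitwXor(i - 1L, bitwShiftL(1L, k - 1L)) + 1L
      Q[i, j] <- rates[k]
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Branch transition probabilities
#'
#' `exp(Q t)` computed by scaling-and-squaring ([Matrix::expm()]), with
#' entries clipped to `[0, 1]`.
#'
#' @param Q rate matrix.
#' @param t nonnegative branch length.
#' @return a stochastic matrix.
#' @export
transitionProbabilities <- function(Q, t) {
  if (t < 0) stop("branch length must be nonnegative")
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` via the eigendecomposition of `t(Q)`.
#'
#' @param Q an irreducible rate matrix.
#' @return probability vector.
#' @export
stationaryDistribution <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  if (abs(e$values[i]) > 1e-6)
    stop("no eigenvalue near zero; Q may not be a rate matrix ",
         "(closest: ", format(e$values[i]), ")")
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-9))
    stop("stationary solve produced negative entries; Q may be reducible")
  v[v < 0] <- 0
  v / sum(v)
}

#' Closed-form stationary distribution of the community model
#'
#' Because the community chain is reversible, its stationary distribution
#' has the closed Ising form `pi_i proportional to exp(sum_k beta_kk x_ik +
#' sum_{h<k} beta_hk x_ih x_ik)`, independent of the intrinsic rates.
#'
#' @param params a [ccmParams()] object.
#' @param log return log-probabilities.
#' @return probability vector over the `2^n` states.
#' @export
ccmStationary <- function(params, log = FALSE) {
  S <- state_matrix(params$n)
  b <- params$beta
  s <- vapply(seq_len(nrow(S)), function(i) {
    x <- S[i, ]
    sum(diag(b) * x) + sum((b * tcrossprod(x))[upper.tri(b)])
  }, numeric(1))
  lp <- s - logsumexp(s)
  if (log) lp else exp(lp)
}

# --- parameter vector packing -------------------------------------------------

# Free parameters: alphas, then the upper triangle of beta (diagonal
# included), column by column: beta_11, beta_12, beta_22, beta_13, ...
theta_names <- function(n) {
  bn <- character(0)
  for (k in seq_len(n)) for (h in seq_len(k))
    bn <- c(bn, paste0("beta_", h, k))
  c(paste0("alpha_", seq_len(n)), bn)
}

n_theta <- function(n) n + n * (n + 1L) / 2L

params_to_theta <- function(params) {
  n <- params$n
  th <- params$alphas
  for (k in seq_len(n)) for (h in seq_len(k))
    th <- c(th, params$beta[h, k])
  setNames(th, theta_names(n))
}

theta_to_params <- function(theta, n, gene_names = NULL) {
  alphas <- theta[seq_len(n)]
  beta <- matrix(0, n, n)
  i <- n
  for (k in seq_len(n)) for (h in seq_len(k)) {
    i <- i + 1L
    beta[h, k] <- theta[i]
    beta[k, h] <- theta[i]
  }
  ccmParams(alphas, beta, gene_names)
}

#' Read or write CCM parameters as JSON
#'
#' The file holds fields `n`, `alphas` (length `n`) and `beta` (`n x n`,
#' symmetry validated on read).
#'
#' @param file path.
#' @param params a [ccmParams()] object (for writing).
#' @return [readParams()] returns a [ccmParams()] object.
#' @export
readParams <- function(file) {
  doc <- jsonlite::fromJSON(file)
  ccmParams(doc$alphas, matrix(unlist(doc$beta), doc$n, doc$n),
            gene_names = doc$gene_names)
}

#' @rdname readParams
#' @export
writeParams <- function(params, file) {
  jsonlite::write_json(
    list(n = params$n, alphas = params$alphas, beta = params$beta,
         gene_names = params$gene_names),
    file, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(file)
}
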