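# Baseline comparison methods: similarity scores, phylogeny-aware
# adjustments, and Pagel's correlated-evolution test.

#' Jaccard Index of two profiles
#'
#' Number of genomes carrying both genes divided by the number carrying
#' either. Undefined (NA) when both profiles are all-zero.
#'
#' @param p1,p2 0/1 vectors of equal length.
#' @return value in `[0, 1]`, or `NA` if undefined.
#' @export
jaccardIndex <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("profiles must have equal length")
  u <- sum(p1 == 1 | p2 == 1)
  if (u == 0) return(NA_real_)
  sum(p1 == 1 & p2 == 1) / u
}

# Upper-tail hypergeometric p-value of >= k co-occurrences given margins.
hyper_p <- function(k, k1, k2, N) {
  phyper(k - 1, k1, N - k1, k2, lower.tail = FALSE)
}

# Empirical mutual information of a 2x2 joint distribution (natural log).
mi_2x2 <- function(tab) {
  N <- sum(tab)
  p <- tab / N
  pr <- rowSums(p); pc <- colSums(p)
  mi <- 0
  for (i in 1:2) for (j in 1:2)
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pr[i] * pc[j]))
  mi
}

joint_table <- function(p1, p2) {
  table(factor(p1, levels = 0:1), factor(p2, levels = 0:1))
}

#' Basic profile similarity scores
#'
#' Hamming distance (count of disagreeing genomes), empirical mutual
#' information of the 2x2 joint distribution (natural log, with
#' `0 log 0 := 0`), and the upper-tail hypergeometric p-value of observing
#' at least as many co-occurrences given the margins.
#'
#' @param p1,p2 0/1 vectors of equal length.
#' @return list with `hamming`, `mutual_information`, `hypergeometric_p`.
#' @export
basicScores <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("profiles must have equal length")
  list(hamming = sum(p1 != p2),
       mutual_information = mi_2x2(joint_table(p1, p2)),
       hypergeometric_p = hyper_p(sum(p1 == 1 & p2 == 1),
                                  sum(p1 == 1), sum(p2 == 1), length(p1)))
}

# Collapse maximal clades whose tips all share the same joint (p1, p2)
# pattern into one pseudo-genome each. Returns the collapsed profile pair.
clade_collapse <- function(tree, p1, p2) {
  n_tip <- length(tree$tip.label)
  pat <- 2L * p1 + p2                     # tip joint pattern in 0..3
  po <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  pure <- rep(NA_integer_, n_node)        # pattern if subtree is uniform
  pure[seq_len(n_tip)] <- pat
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (p in unique(po$edge[, 1])) {
    cp <- pure[kids[[as.character(p)]]]
    pure[p] <- if (!anyNA(cp) && length(unique(cp)) == 1L) cp[1] else NA_integer_
  }
  # preorder walk emitting one observation per maximal uniform subtree
  out <- integer(0)
  walk <- function(node) {
    if (!is.na(pure[node])) {
      out <<- c(out, pure[node])
    } else {
      for (ch in kids[[as.character(node)]]) walk(ch)
    }
  }
  walk(n_tip + 1L)
  list(p1 = out %/% 2L, p2 = out %% 2L)
}

#' Clade-adjusted profile score
#'
#' Counteracts within-clade pseudoreplication by collapsing every maximal
#' clade in which all tips share the identical joint pattern of the two
#' genes into a single pseudo-genome, then computing the chosen metric on
#' the collapsed profiles.
#'
#' @param tree an [ape::phylo] tree aligned with the profiles.
#' @param p1,p2 0/1 vectors in `tree$tip.label` order.
#' @param metric `"hypergeometric"` (upper-tail p-value) or `"mi"`.
#' @return the score on the collapsed profiles.
#' @export
cladeAdjustedScore <- function(tree, p1, p2,
                               metric = c("hypergeometric", "mi")) {
  metric <- match.arg(metric)
  cc <- clade_collapse(tree, p1, p2)
  if (metric == "mi") return(mi_2x2(joint_table(cc$p1, cc$p2)))
  hyper_p(sum(cc$p1 == 1 & cc$p2 == 1), sum(cc$p1 == 1), sum(cc$p2 == 1),
          length(cc$p1))
}

#' Run-adjusted hypergeometric score
#'
#' Orders genomes by the tree's deterministic left-to-right tip order,
#' collapses each maximal run of consecutive genomes sharing the same joint
#' pattern into a single observation, and computes the upper-tail
#' hypergeometric p-value on the collapsed counts, so a block of
#' co-occurrence concentrated in one part of the tree counts as a single
#' run.
#'
#' @inheritParams cladeAdjustedScore
#' @return the hypergeometric p-value on collapsed runs.
#' @export
runAdjustedScore <- function(tree, p1, p2) {
  ord <- match(tip_order(tree), tree$tip.label)
  pat <- (2L * p1 + p2)[ord]
  r <- rle(pat)$values
  q1 <- r %/% 2L; q2 <- r %% 2L
  hyper_p(sum(q1 == 1 & q2 == 1), sum(q1 == 1), sum(q2 == 1), length(r))
}

# --- Pagel's correlated-evolution test ---------------------------------------

# 4-state generator for a gene pair; states indexed little-endian like the
# community model: 1 = (0,0), 2 = (1,0), 3 = (0,1), 4 = (1,1).
# rates = c(gain1|g2=0, gain1|g2=1, loss1|g2=0, loss1|g2=1,
#           gain2|g1=0, gain2|g1=1, loss2|g1=0, loss2|g1=1)
pagel_Q <- function(rates) {
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- rates[1]; Q[3, 4] <- rates[2]
  Q[2, 1] <- rates[3]; Q[4, 3] <- rates[4]
  Q[1, 3] <- rates[5]; Q[2, 4] <- rates[6]
  Q[3, 1] <- rates[7]; Q[4, 2] <- rates[8]
  diag(Q) <- -rowSums(Q)
  Q
}

# Fit a single binary trait's 2-state chain (gain, loss) by ML; log-rate
# parameterization, uniform root prior. Returns log-rates and loglik.
fit_two_state <- function(tp, tip01, rate_cap = 100) {
  ub <- log(rate_cap)
  nll <- function(lr) {
    g <- exp(lr[1]); l <- exp(lr[2])
    Q <- matrix(c(-g, l, g, -l), 2, 2)
    ll <- prune_loglik_cpp(Q, tp$edge, tp$elen, as.integer(tip01),
                           c(0.5, 0.5), tp$n_node, numeric(0))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  res <- nlminb(c(0, 0), nll, lower = -18, upper = ub,
                control = list(rel.tol = 1e-9))
  list(log_rates = res$par, loglik = -res$objective,
       converged = res$convergence == 0L)
}

#' Pagel's independent/dependent model likelihood-ratio test
#'
#' Fits the classical pairwise correlated-evolution models for two binary
#' traits on a tree: the independent model (4 free rates, each gene's gain
#' and loss) and the dependent model (8 free rates, each gene's gain/loss
#' conditional on the other's state), both by maximum likelihood with the
#' pruning algorithm, uniform root prior and rates bounded by `rate_cap`.
#' Under independence the 4-state likelihood factorizes, so the independent
#' model is fitted as two 2-state chains; the dependent fit is initialized
#' from the independent estimates. The likelihood-ratio statistic
#' `2 (logL_dep - logL_indep)` is referred to chi-square with 4 degrees of
#' freedom.
#'
#' @param tree an [ape::phylo] tree.
#' @param p1,p2 0/1 vectors; either named by genome or in `tree$tip.label`
#'   order.
#' @param rate_cap upper bound on every rate (default 100).
#' @return an object of class `pagel_fit`: list with `rates_indep` (gain1,
#'   loss1, gain2, loss2), `rates_dep` (8 conditional rates), `loglik_indep`,
#'   `loglik_dep`, `lrt`, `df`, `p_value`, `converged`.
#' @export
pagelLRT <- function(tree, p1, p2, rate_cap = 100) {
  tp <- prep_tree(tree)
  p1 <- align_profile_vec(p1, tree)
  p2 <- align_profile_vec(p2, tree)

  f1 <- fit_two_state(tp, p1, rate_cap)
  f2 <- fit_two_state(tp, p2, rate_cap)
  ll_indep <- f1$loglik + f2$loglik

  ts <- as.integer(p1 + 2L * p2)          # little-endian joint state
  ub <- log(rate_cap)
  nll_dep <- function(lr) {
    ll <- prune_loglik_cpp(pagel_Q(exp(lr)), tp$edge, tp$elen, ts,
                           rep(0.25, 4), tp$n_node, numeric(0))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start <- c(f1$log_rates[1], f1$log_rates[1], f1$log_rates[2], f1$log_rates[2],
             f2$log_rates[1], f2$log_rates[1], f2$log_rates[2], f2$log_rates[2])
  res <- nlminb(start, nll_dep, lower = -18, upper = ub,
                control = list(rel.tol = 1e-9))
  ll_dep <- -res$objective
  lrt <- max(0, 2 * (ll_dep - ll_indep))
  structure(list(
    rates_indep = setNames(exp(c(f1$log_rates, f2$log_rates)),
                           c("gain1", "loss1", "gain2", "loss2")),
    rates_dep = setNames(exp(res$par),
                         c("gain1.g2abs", "gain1.g2pres", "loss1.g2abs",
                           "loss1.g2pres", "gain2.g1abs", "gain2.g1pres",
                           "loss2.g1abs", "loss2.g1pres")),
    loglik_indep = ll_indep, loglik_dep = ll_dep,
    lrt = lrt, df = 4L, p_value = pchisq(lrt, 4L, lower.tail = FALSE),
    converged = f1$converged && f2$converged && res$convergence == 0L),
    class = "pagel_fit")
}

#' @export
print.pagel_fit <- function(x, ...) {
  cat("Pagel correlated-evolution LRT\n")
  cat("  logL independent:", format(x$loglik_indep, digits = 6),
      " dependent:", format(x$loglik_dep, digits = 6), "\n")
  cat("  LRT =", format(x$lrt, digits = 4), "on", x$df,
      "df, p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

# Put a profile vector in tree$tip.label order (by names if present).
align_profile_vec <- function(p, tree) {
  if (!is.null(names(p))) {
    miss <- setdiff(tree$tip.label, names(p))
    if (length(miss))
      stop("profile lacks genomes: ", paste(miss, collapse = ", "))
    p <- p[tree$tip.label]
  } else if (length(p) != length(tree$tip.label)) {
    stop("profile length does not match the number of tips")
  }
  as.integer(p)
}
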