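# Event-driven simulation of coevolving profiles and benchmark scenarios.

#' Simulate community evolution along one branch
#'
#' Implements the per-branch procedure exactly as the model defines it:
#' compute the current transition rate of every gene, draw each gene's
#' waiting time from its exponential distribution, flip the gene with the
#' minimal waiting time if that time fits within the remaining branch
#' length, subtract the waiting time, and repeat until the branch is
#' exhausted. (Resampling every clock after each event is statistically
#' equivalent to the classical Gillespie scheme by the memoryless property.)
#'
#' Uses the current R random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param params a [ccmParams()] object.
#' @param state starting spin vector in `{-1, +1}^n`.
#' @param b nonnegative branch length.
#' @param details if `TRUE`, also return the number of flip events.
#' @return the end-state spin vector, or (with `details`) a list with
#'   `state` and `n_events`.
#' @export
simulateBranch <- function(params, state, b, details = FALSE) {
  if (b < 0) stop("branch length must be nonnegative")
  x <- as.integer(state)
  n_events <- 0L
  while (b > 0) {
    tau <- transition_rates(params, x)
    t_h <- rexp(length(x), tau)
    k <- which.min(t_h)
    t_min <- t_h[k]
    if (t_min <= b) {
      x[k] <- -x[k]
      n_events <- n_events + 1L
    }
    b <- b - t_min
  }
  if (details) list(state = x, n_events = n_events) else x
}

#' Simulate coevolving profiles on a tree
#'
#' Draws a root state (from the community's stationary distribution by
#' default) and applies [simulateBranch()] along every edge from the root to
#' the tips, each child branch starting from its parent's end state.
#'
#' @param tree an [ape::phylo] rooted tree with branch lengths.
#' @param params a [ccmParams()] object.
#' @param root_mode `"stationary"` (default) or `"fixed"`.
#' @param root_state spin vector for `root_mode = "fixed"`.
#' @return 0/1 profile matrix, genes as rows (named from `params`), genomes
#'   as columns in `tree$tip.label` order.
#' @export
simulateProfiles <- function(tree, params,
                             root_mode = c("stationary", "fixed"),
                             root_state = NULL) {
  root_mode <- match.arg(root_mode)
  validate_tree(tree)
  n <- params$n
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L

  if (root_mode == "stationary") {
    idx <- sample.int(2L^n, 1L, prob = ccmStationary(params)) - 1L
    x0 <- stateVector(idx, n)
  } else {
    if (is.null(root_state)) stop("fixed root mode needs `root_state`")
    x0 <- as.integer(root_state)
  }

  cw <- ape::reorder.phylo(tree, "cladewise")
  states <- matrix(NA_integer_, n, n_node)
  states[, root] <- x0
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    states[, ch] <- simulateBranch(params, states[, p], cw$edge.length[e])
  }
  pm <- (states[, seq_len(n_tip), drop = FALSE] + 1L) %/% 2L
  rownames(pm) <- params$gene_names
  colnames(pm) <- tree$tip.label
  storage.mode(pm) <- "integer"
  pm
}

#' Random tree generator
#'
#' Yule (pure-birth, unit rate) topology via [ape::rphylo()], with branch
#' lengths rescaled so the mean branch length equals `mean_bl` (0.1 by
#' default, the conventional scaling for comparative analyses of profiles).
#'
#' @param n_tips number of tips (>= 2).
#' @param mean_bl target mean branch length.
#' @param seed optional integer seed.
#' @return an [ape::phylo] tree.
#' @export
randomTree <- function(n_tips, mean_bl = 0.1, seed = NULL) {
  if (n_tips < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length * (mean_bl / mean(tr$edge.length))
  tr
}

#' Generate the paired null/interacting benchmark
#'
#' Simulates `n_null` two-gene communities with interaction coefficient 0
#' (the negatives) and `n_alt` with the coefficient drawn uniformly from
#' `beta_range` (the positives), each pair on a fresh random tree (or on a
#' supplied fixed tree). Intrinsic parameters default to the neutral
#' symmetric model (`alpha = 0`, diagonal `beta = 0`).
#'
#' @param n_null,n_alt group sizes.
#' @param n_tips tips per random tree (ignored when `tree` is given).
#' @param beta_range range of the interacting group's coefficient.
#' @param alphas,beta_diag intrinsic parameters shared by both genes.
#' @param mean_bl mean branch length of the random trees.
#' @param tree optional fixed tree used for every pair.
#' @param seed integer seed; per-pair seeds are derived from it.
#' @return list of records, each with `tree`, `profiles`, `beta12` (truth)
#'   and `label` (0 null / 1 interacting).
#' @export
genBenchmarkPairs <- function(n_null = 500L, n_alt = 500L, n_tips = 100L,
                              beta_range = c(0.2, 0.5),
                              alphas = c(0, 0), beta_diag = c(0, 0),
                              mean_bl = 0.1, tree = NULL, seed = 1L) {
  if (beta_range[1] > beta_range[2]) stop("beta_range must be (lo, hi)")
  total <- n_null + n_alt
  out <- vector("list", total)
  for (i in seq_len(total)) {
    set.seed(derive_seed(seed, i))
    label <- as.integer(i > n_null)
    b12 <- if (label == 1L) runif(1, beta_range[1], beta_range[2]) else 0
    tr <- if (is.null(tree)) randomTree(n_tips, mean_bl) else tree
    beta <- diag(beta_diag)
    beta[1, 2] <- beta[2, 1] <- b12
    pars <- ccmParams(alphas, beta)
    out[[i]] <- list(tree = tr, profiles = simulateProfiles(tr, pars),
                     beta12 = b12, label = label)
  }
  out
}

#' Construct a single-origin (Darwin's scenario) gene pair
#'
#' Picks an internal non-root clade uniformly at random and makes both genes
#' present on exactly the tips of that clade and absent elsewhere — a single
#' concurrent origin producing clade-confined perfect codistribution, the
#' textbook case of within-clade pseudoreplication. An optional noise
#' fraction flips in-clade tips to "almost perfect" codistribution.
#'
#' @param tree an [ape::phylo] tree with at least one internal non-root node.
#' @param noise fraction of in-clade tips flipped to absent, per gene.
#' @return list with `profiles` (2 x tips) and `clade` (the node id).
#' @export
genDarwinPair <- function(tree, noise = 0) {
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  nodes <- setdiff(seq_len(n_tip + tree$Nnode), c(seq_len(n_tip), n_tip + 1L))
  if (!length(nodes)) stop("tree has no internal non-root clade")
  node <- if (length(nodes) == 1L) nodes else sample(nodes, 1L)
  tips <- clade_tip_sets(tree)[[node]]
  pm <- matrix(0L, 2L, n_tip,
               dimnames = list(c("g1", "g2"), tree$tip.label))
  pm[, tips] <- 1L
  if (noise > 0) for (g in 1:2) {
    nf <- floor(noise * length(tips))
    if (nf > 0) pm[g, sample(tips, nf)] <- 0L
  }
  list(profiles = pm, clade = node)
}

#' Construct a replicated-codistribution gene pair
#'
#' Both genes are made present on the same uniformly sampled set of
#' `n_present` tips, resampled (up to `max_tries`) if the set happens to be
#' monophyletic — the phylogenetically dispersed counterpart of the
#' single-origin scenario, with the same co-occurrence count.
#'
#' @param tree an [ape::phylo] tree.
#' @param n_present number of tips carrying both genes.
#' @param max_tries resampling bound.
#' @return list with `profiles` (2 x tips) and `tips` (the present set).
#' @export
genReplicatedPair <- function(tree, n_present, max_tries = 100L) {
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  if (n_present < 1 || n_present > n_tip)
    stop("n_present must be between 1 and the number of tips")
  clades <- clade_tip_sets(tree)
  clade_keys <- vapply(clades, function(s) paste(sort(s), collapse = ","),
                       character(1))
  for (t in seq_len(max_tries)) {
    tips <- sort(sample.int(n_tip, n_present))
    if (!(paste(tips, collapse = ",") %in% clade_keys)) {
      pm <- matrix(0L, 2L, n_tip,
                   dimnames = list(c("g1", "g2"), tree$tip.label))
      pm[, tips] <- 1L
      return(list(profiles = pm, tips = tips))
    }
  }
  stop("could not sample a non-monophyletic tip set in ", max_tries,
       " tries")
}

#' Simulate a community with a given interaction topology
#'
#' Builds the interaction matrix with `beta_value` on the listed undirected
#' edges and 0 elsewhere (neutral intrinsic parameters), then simulates the
#' community. Covers the standard five-node structures (line, star,
#' partially connected, fully connected) and arbitrary edge lists such as
#' the conditionally independent triplet chain.
#'
#' @param edges two-column matrix of gene index pairs (no self-edges).
#' @param n_genes community size.
#' @param beta_value interaction coefficient placed on every listed edge, or
#'   a vector with one value per edge.
#' @param tree optional fixed tree; otherwise a fresh [randomTree()].
#' @param n_tips,mean_bl random-tree parameters.
#' @param alphas,beta_diag intrinsic parameters (defaults neutral).
#' @param seed optional integer seed.
#' @return list with `tree`, `profiles`, `params` (the true parameters).
#' @export
genTopologyCommunity <- function(edges, n_genes = 5L, beta_value = 0.5,
                                 tree = NULL, n_tips = 100L, mean_bl = 0.1,
                                 alphas = NULL, beta_diag = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) && any(edges[, 1] == edges[, 2]))
    stop("self-edges are not allowed")
  if (nrow(edges) && max(edges) > n_genes)
    stop("edge list references a gene beyond n_genes")
  if (is.null(alphas)) alphas <- rep(0, n_genes)
  if (is.null(beta_diag)) beta_diag <- rep(0, n_genes)
  bv <- rep_len(beta_value, max(1L, nrow(edges)))
  beta <- diag(beta_diag, n_genes)
  for (e in seq_len(nrow(edges))) {
    beta[edges[e, 1], edges[e, 2]] <- bv[e]
    beta[edges[e, 2], edges[e, 1]] <- bv[e]
  }
  pars <- ccmParams(alphas, beta)
  if (is.null(tree)) tree <- randomTree(n_tips, mean_bl)
  list(tree = tree, profiles = simulateProfiles(tree, pars), params = pars)
}
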