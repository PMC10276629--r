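# All-versus-all pairwise scanning, multiple-testing correction, network
# construction, triplet-based conditional-independence pruning, and ROC.

#' All-versus-all pairwise community scan
#'
#' Fits the two-gene community model to every unordered gene pair (or a
#' supplied candidate list), recording the interaction estimate, its
#' standard error, Wald Z and p-value, and fit diagnostics. Per-pair seeds
#' are derived deterministically from the master seed, so results do not
#' depend on evaluation order. Benjamini-Yekutieli adjusted p-values
#' (valid under arbitrary dependence between the correlated tests) are
#' appended across all computed pairs.
#'
#' @param tree an [ape::phylo] tree.
#' @param pm profile matrix (genes x genomes), at least 2 genes.
#' @param pairs optional two-column matrix of gene indices or names to
#'   restrict the scan.
#' @param lambda ridge penalty (default 0); `auto_lambda = TRUE` reruns
#'   ill-conditioned pairs through [autoLambda()].
#' @param auto_lambda rerun pairs whose condition number exceeds `cond_max`.
#' @param cond_max condition-number threshold for the rerun.
#' @param restarts optimizer restarts per pair.
#' @param seed master seed.
#' @return data.frame with one row per pair: `gene1`, `gene2`, `beta`, `se`,
#'   `z`, `p`, `p_by`, `converged`, `lambda`, `cond_number`, `alpha1`,
#'   `alpha2`.
#' @export
pairwiseScan <- function(tree, pm, pairs = NULL, lambda = 0,
                         auto_lambda = FALSE, cond_max = 200,
                         restarts = 3L, seed = 1L) {
  pm <- validateProfiles(pm)
  if (nrow(pm) < 2L) stop("need at least 2 genes to scan")
  genes <- rownames(pm)
  if (is.null(genes)) genes <- rownames(pm) <- paste0("g", seq_len(nrow(pm)))
  if (is.null(pairs)) {
    pairs <- t(combn(nrow(pm), 2L))
  } else if (is.character(pairs)) {
    pairs <- matrix(match(pairs, genes), ncol = 2L)
  }
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    sub <- pm[c(g1, g2), , drop = FALSE]
    fit <- tryCatch({
      f <- fitCCM(tree, sub, lambda = lambda, restarts = restarts,
                  seed = derive_seed(seed, i))
      if (auto_lambda && (!is.finite(f$condition_number) ||
                          f$condition_number > cond_max))
        f <- autoLambda(tree, sub, cond_max = cond_max,
                        restarts = restarts, seed = derive_seed(seed, i))
      f
    }, error = function(e) NULL)
    res[[i]] <- if (is.null(fit)) {
      data.frame(gene1 = genes[g1], gene2 = genes[g2], beta = NA_real_,
                 se = NA_real_, z = NA_real_, p = NA_real_,
                 converged = FALSE, lambda = lambda,
                 cond_number = NA_real_, alpha1 = NA_real_,
                 alpha2 = NA_real_)
    } else {
      data.frame(gene1 = genes[g1], gene2 = genes[g2],
                 beta = unname(fit$theta["beta_12"]),
                 se = unname(fit$se["beta_12"]),
                 z = unname(fit$z["beta_12"]),
                 p = unname(fit$pvalues["beta_12"]),
                 converged = fit$converged, lambda = fit$lambda,
                 cond_number = fit$condition_number,
                 alpha1 = unname(fit$theta["alpha_1"]),
                 alpha2 = unname(fit$theta["alpha_2"]))
    }
  }
  out <- do.call(rbind, res)
  out$p_by <- adjustBY(out$p)
  out[, c("gene1", "gene2", "beta", "se", "z", "p", "p_by", "converged",
          "lambda", "cond_number", "alpha1", "alpha2")]
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with the harmonic-sum factor,
#' valid under arbitrary dependence among the tests. NA p-values are left
#' NA and do not count toward the number of tests.
#'
#' @param pvalues vector in `[0, 1]`.
#' @return adjusted p-values, capped at 1.
#' @export
adjustBY <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BY")
}

#' Threshold a scanned edge table into a gene network
#'
#' Keeps edges whose interaction estimate exceeds `beta_threshold` and whose
#' Wald Z exceeds `z_threshold` (both conditions required; the defaults are
#' the strict 0.75 / 7.5 rule for highly significant coevolving pairs).
#'
#' @param edges data.frame from [pairwiseScan()] (columns `gene1`, `gene2`,
#'   `beta`, `z`).
#' @param beta_threshold,z_threshold thresholds.
#' @param keep_isolated retain genes with no surviving edge as isolated
#'   vertices (default drops them).
#' @param genes optional full gene set for `keep_isolated = TRUE`.
#' @return an [igraph::graph] with edge attributes carried over from the
#'   table, plus a `provenance` graph attribute recording the thresholds.
#' @export
buildNetwork <- function(edges, beta_threshold = 0.75, z_threshold = 7.5,
                         keep_isolated = FALSE, genes = NULL) {
  keep <- !is.na(edges$beta) & !is.na(edges$z) &
    edges$beta > beta_threshold & edges$z > z_threshold
  kept <- edges[keep, , drop = FALSE]
  verts <- if (keep_isolated && !is.null(genes)) genes else
    unique(c(kept$gene1, kept$gene2))
  g <- igraph::graph_from_data_frame(kept, directed = FALSE,
                                     vertices = if (length(verts)) verts else NULL)
  g <- igraph::set_graph_attr(g, "provenance",
                              list(beta_threshold = beta_threshold,
                                   z_threshold = z_threshold))
  g
}

#' Prune conditionally independent edges with triplet fits
#'
#' For every edge (i, j) of the network and every third gene k adjacent to
#' i or j, fits the three-gene community model and re-tests the (i, j)
#' interaction in the presence of k. An edge is pruned when, in at least
#' one such triplet, its re-estimated p-value exceeds `p_threshold` and its
#' interaction coefficient falls below `beta_threshold` — the signature of a
#' pairwise association explained away by the third gene. `mode = "all"`
#' requires every triplet to condemn the edge.
#'
#' @param tree an [ape::phylo] tree.
#' @param pm profile matrix containing at least the network's genes.
#' @param network an [igraph::graph] from [buildNetwork()].
#' @param p_threshold,beta_threshold pruning rule (defaults 0.001 and 0.5).
#' @param mode `"any"` (default) or `"all"` condemning triplets.
#' @param restarts,seed fit configuration.
#' @return list with `network` (pruned graph) and `report` (data.frame of
#'   examined triplets: `gene1`, `gene2`, `conditioning`, `beta`, `p`,
#'   `condemns`; failed triplet fits are recorded with NA and skipped).
#' @export
tripletPrune <- function(tree, pm, network, p_threshold = 0.001,
                         beta_threshold = 0.5, mode = c("any", "all"),
                         restarts = 3L, seed = 1L) {
  mode <- match.arg(mode)
  pm <- validateProfiles(pm)
  el <- igraph::as_edgelist(network)
  if (nrow(el) == 0L)
    return(list(network = network, report = data.frame()))
  rows <- list()
  condemned <- logical(nrow(el))
  cnt <- 0L
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    nbrs <- setdiff(unique(c(
      names(igraph::neighbors(network, i)),
      names(igraph::neighbors(network, j)))), c(i, j))
    verdicts <- logical(0)
    for (k in nbrs) {
      cnt <- cnt + 1L
      sub <- pm[c(i, j, k), , drop = FALSE]
      fit <- tryCatch(
        fitCCM(tree, sub, restarts = restarts,
               seed = derive_seed(seed, cnt)),
        error = function(err) NULL)
      if (is.null(fit)) {
        warning("triplet fit failed for {", i, ",", j, ",", k,
                "}; skipping")
        rows[[length(rows) + 1L]] <-
          data.frame(gene1 = i, gene2 = j, conditioning = k,
                     beta = NA_real_, p = NA_real_, condemns = NA)
        next
      }
      b <- unname(fit$theta["beta_12"])
      p <- unname(fit$pvalues["beta_12"])
      condemns <- isTRUE(p > p_threshold && b < beta_threshold)
      verdicts <- c(verdicts, condemns)
      rows[[length(rows) + 1L]] <-
        data.frame(gene1 = i, gene2 = j, conditioning = k,
                   beta = b, p = p, condemns = condemns)
    }
    condemned[e] <- if (!length(verdicts)) FALSE
      else if (mode == "any") any(verdicts) else all(verdicts)
  }
  pruned <- igraph::delete_edges(network, which(condemned))
  list(network = pruned, report = do.call(rbind, rows))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form with midranks for ties: the probability that a
#' randomly chosen positive outranks a randomly chosen negative. Higher
#' scores must indicate the positive class (rank p-value-like scores by
#' their negation).
#'
#' @param labels 0/1 truth vector (both classes present).
#' @param scores numeric ranking scores.
#' @return AUC in `[0, 1]`.
#' @export
rocAUC <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  ok <- !is.na(scores)
  labels <- labels[ok]; scores <- scores[ok]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
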