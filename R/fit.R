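# Penalized maximum-likelihood inference for the community model.

# Central-difference Hessian with relative step sizes.
num_hessian <- function(fn, theta, rel_step = 1e-4) {
  d <- length(theta)
  h <- rel_step * pmax(1, abs(theta))
  f0 <- fn(theta)
  H <- matrix(NA_real_, d, d)
  for (j in seq_len(d)) {
    tp <- theta; tm <- theta
    tp[j] <- theta[j] + h[j]; tm[j] <- theta[j] - h[j]
    H[j, j] <- (fn(tp) + fn(tm) - 2 * f0) / h[j]^2
  }
  if (d > 1) for (j in seq_len(d - 1)) for (k in (j + 1):d) {
    tpp <- theta; tpm <- theta; tmp <- theta; tmm <- theta
    tpp[c(j, k)] <- theta[c(j, k)] + h[c(j, k)]
    tmm[c(j, k)] <- theta[c(j, k)] - h[c(j, k)]
    tpm[j] <- theta[j] + h[j]; tpm[k] <- theta[k] - h[k]
    tmp[j] <- theta[j] - h[j]; tmp[k] <- theta[k] + h[k]
    H[j, k] <- H[k, j] <-
      (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) / (4 * h[j] * h[k])
  }
  (H + t(H)) / 2
}

# Standard errors from a Hessian of the negative log-likelihood; parameters
# whose inverse-Hessian diagonal is nonpositive get NA. Singular Hessians
# fall back to the eigendecomposition pseudo-inverse with a warning.
hessian_se <- function(H) {
  Hinv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Hinv)) {
    warning("singular Hessian; using pseudo-inverse for standard errors")
    e <- eigen(H, symmetric = TRUE)
    pos <- abs(e$values) > 1e-10 * max(abs(e$values))
    Hinv <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  }
  v <- diag(Hinv)
  se <- rep(NA_real_, length(v))
  ok <- is.finite(v) & v > 0
  se[ok] <- sqrt(v[ok])
  se
}

#' Fit the community coevolution model
#'
#' Minimizes the penalized negative log-likelihood over the
#' `n + n(n+1)/2` free parameters with the quasi-Newton optimizer
#' [stats::nlminb()], under box constraints `|theta| <= 10`. The default
#' start is the neutral model `theta = 0`; additional restarts jitter the
#' start by `N(0, 0.1^2)` and the best optimum is kept. Standard errors come
#' from the central-difference Hessian of the (unpenalized) negative
#' log-likelihood; Wald Z-scores and two-sided p-values test each parameter
#' against zero. The condition number reported is that of the penalized
#' Hessian `H + 2 lambda I`.
#'
#' @inheritParams pruneLoglik
#' @param init optional [ccmParams()] starting value.
#' @param lambda ridge penalty weight (default 0; see [autoLambda()]).
#' @param restarts number of optimizer starts (default 3).
#' @param seed optional integer seed controlling the restart jitter.
#' @param compute_se compute the Hessian, standard errors and tests
#'   (default `TRUE`; skipping saves time in large scans).
#' @param control optimizer control passed to [stats::nlminb()].
#' @return an object of class `ccm_fit`: list with `params` (the estimates
#'   as [ccmParams()]), `theta`, `loglik` (unpenalized log-likelihood at the
#'   optimum), `objective`, `lambda`, `hessian`, `se`, `z`, `pvalues`,
#'   `condition_number`, `converged`, `n_restarts_used`, `seed`.
#' @export
fitCCM <- function(tree, profiles, init = NULL, lambda = 0,
                   prior = "uniform", root_state = NULL, restarts = 3L,
                   seed = NULL, compute_se = TRUE,
                   control = list(rel.tol = 1e-9, eval.max = 2000L,
                                  iter.max = 500L)) {
  profiles <- validateProfiles(profiles)
  n <- nrow(profiles)
  tp <- prep_tree(tree)
  ts <- tip_state_index(profiles, tree)
  d <- n_theta(n)
  gene_names <- rownames(profiles)

  lik <- ccm_loglik_factory(n, tp, ts, prior, root_state)
  nll <- function(th) {
    ll <- lik(th)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  obj <- function(th) nll(th) + lambda * sum(th^2)

  th0 <- if (is.null(init)) rep(0, d) else params_to_theta(init)
  if (!is.finite(obj(th0)))
    stop("objective is non-finite at the starting value")

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  n_used <- 0L
  any_conv <- FALSE
  for (r in seq_len(max(1L, restarts))) {
    start <- if (r == 1L) th0 else th0 + rnorm(d, 0, 0.1)
    res <- tryCatch(
      nlminb(start, obj, lower = -10, upper = 10, control = control),
      error = function(e) NULL)
    n_used <- n_used + 1L
    if (is.null(res) || !is.finite(res$objective)) next
    if (res$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("optimizer failed on all restarts")

  theta_hat <- setNames(best$par, theta_names(n))
  ll_hat <- -nll(theta_hat)

  H <- se <- z <- p <- cond <- NULL
  if (compute_se) {
    H <- num_hessian(nll, theta_hat)
    dimnames(H) <- list(theta_names(n), theta_names(n))
    se <- hessian_se(H)
    z <- theta_hat / se
    p <- 2 * pnorm(-abs(z))
    ev <- eigen(H + 2 * lambda * diag(d), symmetric = TRUE,
                only.values = TRUE)$values
    cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  }

  structure(list(
    params = theta_to_params(theta_hat, n, gene_names),
    theta = theta_hat, loglik = ll_hat, objective = best$objective,
    lambda = lambda, hessian = H,
    se = if (is.null(se)) NULL else setNames(se, theta_names(n)),
    z = z, pvalues = p, condition_number = cond,
    converged = any_conv, n_restarts_used = n_used, seed = seed,
    prior = prior, n = n, gene_names = gene_names),
    class = "ccm_fit")
}

#' @export
print.ccm_fit <- function(x, ...) {
  cat("Community coevolution model fit (", x$n, " gene(s), ",
      "logLik = ", format(x$loglik, digits = 6), ", lambda = ", x$lambda,
      ")\n", sep = "")
  if (!is.null(x$se)) print(waldTest(x))
  if (!is.null(x$condition_number))
    cat("Hessian condition number:", format(x$condition_number, digits = 4),
        if (!x$converged) " [optimizer did not report convergence]", "\n")
  invisible(x)
}

#' Wald tests for the fitted parameters
#'
#' Z-score `estimate / se` and two-sided normal p-value for each parameter;
#' the interesting hypotheses are `beta_hk = 0` (no interaction between
#' genes `h` and `k`). Parameters with undefined standard errors get `NA`
#' p-values, not 1.
#'
#' @param fit a [fitCCM()] result with standard errors.
#' @return data.frame with columns `parameter`, `estimate`, `se`, `z`, `p`.
#' @export
waldTest <- function(fit) {
  if (is.null(fit$se)) stop("fit has no standard errors; refit with compute_se = TRUE")
  data.frame(parameter = names(fit$theta),
             estimate = unname(fit$theta),
             se = unname(fit$se),
             z = unname(fit$z),
             p = unname(fit$pvalues),
             row.names = NULL)
}

#' Parametric-bootstrap standard errors
#'
#' Simulates `n_boot` profile sets from the fitted parameters on the same
#' tree, refits each, and returns the per-parameter standard deviation of
#' the bootstrap estimates. Replicates whose refit fails to converge are
#' dropped with a warning; more than 20% dropped is an error.
#'
#' @param tree the tree the fit used.
#' @param fit a [fitCCM()] result.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed (replicate seeds are derived from it, so results
#'   are reproducible bit for bit).
#' @param restarts optimizer restarts per replicate (default 1; the truth is
#'   a good neighbourhood).
#' @return named vector of bootstrap standard errors.
#' @export
bootstrapSE <- function(tree, fit, n_boot = 100L, seed = 1L, restarts = 1L) {
  if (n_boot < 2L) stop("n_boot must be at least 2")
  est <- matrix(NA_real_, n_boot, length(fit$theta))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, b))
    pm <- simulateProfiles(tree, fit$params)
    rf <- tryCatch(
      fitCCM(tree, pm, init = fit$params, lambda = fit$lambda,
             prior = fit$prior, restarts = restarts,
             seed = derive_seed(seed, n_boot + b), compute_se = FALSE),
      error = function(e) NULL)
    if (is.null(rf) || !rf$converged) {
      dropped <- dropped + 1L
      next
    }
    est[b, ] <- rf$theta
  }
  if (dropped > 0L)
    warning(dropped, " bootstrap replicate(s) dropped for non-convergence")
  if (dropped > 0.2 * n_boot)
    stop("more than 20% of bootstrap replicates failed to converge")
  setNames(apply(est, 2, sd, na.rm = TRUE), names(fit$theta))
}

#' Choose the ridge penalty by the condition-number rule
#'
#' Fits with increasing penalty weights until the condition number of the
#' penalized Hessian drops to `cond_max` (200 by default): a condition
#' number below 200 is the working rule for a well-behaved optimum without
#' overshooting. Returns the first satisfying fit; if none qualifies the
#' last fit is returned with a warning.
#'
#' @inheritParams fitCCM
#' @param lambda_grid ascending penalty grid starting at 0.
#' @param cond_max condition-number threshold.
#' @param ... passed to [fitCCM()].
#' @return the chosen `ccm_fit` (its `lambda` element records the choice).
#' @export
autoLambda <- function(tree, profiles,
                       lambda_grid = c(0, 0.01, 0.1, 0.5, 1, 2, 5, 10),
                       cond_max = 200, ...) {
  if (is.unsorted(lambda_grid) || lambda_grid[1] != 0)
    stop("lambda_grid must be ascending and start at 0")
  fit <- NULL
  for (lam in lambda_grid) {
    fit <- fitCCM(tree, profiles, lambda = lam, ...)
    if (is.finite(fit$condition_number) &&
        fit$condition_number <= cond_max)
      return(fit)
  }
  warning("no penalty in the grid brought the condition number below ",
          cond_max, "; returning the last fit (lambda = ",
          fit$lambda, ")")
  fit
}
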