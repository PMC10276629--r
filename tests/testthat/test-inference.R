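# Penalized ML fitting, standard errors, Wald tests and the penalty rule.

test_that("numerical Hessian recovers a known quadratic exactly", {
  A <- matrix(c(4, 1, 1, 3), 2)
  fn <- function(th) 0.5 * drop(t(th) %*% A %*% th)
  H <- phyloCCM:::num_hessian(fn, c(0.3, -0.2))
  expect_equal(H, A, tolerance = 1e-6)
  expect_equal(phyloCCM:::hessian_se(H), sqrt(diag(solve(A))),
               tolerance = 1e-6)
})

test_that("a balanced pattern on a symmetric tree gives no gain/loss asymmetry", {
  tr <- readTree(text = "(A:1,B:1);")
  pm <- matrix(c(1L, 0L), 1, 2, dimnames = list("g1", c("A", "B")))
  f <- fitCCM(tr, pm, seed = 1)
  expect_lt(abs(f$theta[["beta_11"]]), 1e-3)
})

test_that("Wald p-values follow the two-sided normal rule", {
  set.seed(31)
  tr <- randomTree(40)
  pm <- simulateProfiles(tr, ccmParams(c(0, 0), diag(0, 2)))
  f <- fitCCM(tr, pm, seed = 2)
  wt <- waldTest(f)
  expect_equal(wt$p, 2 * pnorm(-abs(wt$z)))
  expect_true(all(wt$p >= 0 & wt$p <= 1, na.rm = TRUE))
  expect_true(all(wt$se > 0, na.rm = TRUE))
  expect_gte(f$condition_number, 1)
})

test_that("identical seeds reproduce the fit bit for bit", {
  set.seed(32)
  tr <- randomTree(50)
  pm <- simulateProfiles(tr, ccmParams(c(0, 0), matrix(c(0, .4, .4, 0), 2)))
  f1 <- fitCCM(tr, pm, seed = 99)
  f2 <- fitCCM(tr, pm, seed = 99)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$se, f2$se)
})

test_that("interaction recovery is unbiased at moderate coupling", {
  est <- se <- numeric(25)
  for (i in 1:25) {
    set.seed(700 + i)
    tr <- randomTree(100)
    pm <- simulateProfiles(tr, ccmParams(c(0, 0), matrix(c(0, .8, .8, 0), 2)))
    f <- fitCCM(tr, pm, restarts = 1)
    est[i] <- f$theta[["beta_12"]]; se[i] <- f$se[["beta_12"]]
  }
  # the median is robust to occasional overshooting replicates (flat
  # likelihood surfaces; the documented remedy is the ridge penalty)
  expect_lt(abs(median(est) - 0.8), 0.15)
  # +-2 se covers the truth most of the time
  cover <- mean(abs(est - 0.8) < 2 * se, na.rm = TRUE)
  expect_gte(cover, 0.7)
})

test_that("doubling the data shrinks standard errors by about sqrt(2)", {
  set.seed(33)
  tr <- randomTree(40)
  p <- ccmParams(0.1, matrix(0.2, 1, 1))
  pm <- simulateProfiles(tr, p)
  s1 <- writeTree(tr)
  sub <- sub(";$", "", s1)
  sub2 <- gsub("([A-Za-z0-9]+):", "\\1x:", sub)
  tr2 <- readTree(text = paste0("(", sub, ":0,", sub2, ":0);"))
  pm2 <- cbind(pm, pm)
  colnames(pm2) <- c(colnames(pm), paste0(colnames(pm), "x"))
  nll1 <- function(th) -pruneLoglik(tr, pm, ccmParams(th[1], matrix(th[2])))
  nll2 <- function(th) -pruneLoglik(tr2, pm2, ccmParams(th[1], matrix(th[2])))
  th <- phyloCCM:::params_to_theta(p)
  se1 <- phyloCCM:::hessian_se(phyloCCM:::num_hessian(nll1, th))
  se2 <- phyloCCM:::hessian_se(phyloCCM:::num_hessian(nll2, th))
  expect_equal(se1 / se2, rep(sqrt(2), 2), tolerance = 0.1)
})

test_that("stronger penalties shrink the estimate norm monotonically", {
  set.seed(34)
  tr <- randomTree(60)
  pm <- simulateProfiles(tr, ccmParams(c(0, 0), matrix(c(0, .6, .6, 0), 2)))
  norms <- vapply(c(0, 0.5, 2, 8), function(lam)
    sqrt(sum(fitCCM(tr, pm, lambda = lam, restarts = 1,
                    compute_se = FALSE)$theta^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("bootstrap standard errors are reproducible and sane", {
  set.seed(35)
  tr <- randomTree(150)   # informative enough that replicates stay regular
  pm <- simulateProfiles(tr, ccmParams(0, matrix(0, 1, 1)))
  f <- fitCCM(tr, pm, seed = 3)
  b1 <- bootstrapSE(tr, f, n_boot = 6, seed = 11)
  b2 <- bootstrapSE(tr, f, n_boot = 6, seed = 11)
  expect_identical(b1, b2)
  expect_true(all(b1 > 0))
  expect_no_error(bootstrapSE(tr, f, n_boot = 2, seed = 12))
  # asymptotic agreement with the Hessian on the symmetric single-gene chain
  b <- bootstrapSE(tr, f, n_boot = 60, seed = 13)
  expect_lt(abs(b[["beta_11"]] / f$se[["beta_11"]] - 1), 0.35)
})

test_that("the condition-number rule keeps lambda at zero when well posed", {
  set.seed(36)
  tr <- randomTree(80)
  pm <- simulateProfiles(tr, ccmParams(c(0, 0), matrix(c(0, .3, .3, 0), 2)))
  f <- autoLambda(tr, pm, seed = 4)
  expect_equal(f$lambda, 0)
  expect_lte(f$condition_number, 200)
})
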