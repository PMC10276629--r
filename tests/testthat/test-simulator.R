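# The event-driven simulator against closed forms and the matrix exponential.

test_that("zero-length branches change nothing", {
  p <- rand_params(3)
  x <- c(-1L, 1L, -1L)
  expect_identical(simulateBranch(p, x, 0), x)
})

test_that("single-gene flip probability matches the closed form", {
  p <- ccmParams(0, matrix(0, 1, 1))
  t <- 0.3
  set.seed(41)
  nrep <- 30000L
  flips <- sum(vapply(seq_len(nrep),
                      function(i) simulateBranch(p, -1L, t) == 1L, logical(1)))
  expect_lt(abs(flips / nrep - p_diff(t)),
            3 * sqrt(p_diff(t) * (1 - p_diff(t)) / nrep))
})

test_that("event counts on a constant-rate branch are Poisson", {
  p <- ccmParams(0, matrix(0, 1, 1))   # rate 1 in both states
  b <- 2
  set.seed(42)
  ev <- vapply(seq_len(4000L),
               function(i) simulateBranch(p, 1L, b, details = TRUE)$n_events,
               integer(1))
  expect_lt(abs(mean(ev) - b), 3 * sqrt(b / 4000))
  expect_lt(abs(var(ev) / mean(ev) - 1), 0.1)   # unit dispersion
})

test_that("branch end-state distribution matches exp(Qb)", {
  set.seed(43)
  p <- rand_params(2)
  Q <- buildRateMatrix(p)
  b <- 0.7
  start <- 2L  # state index, spins (-1, +1)
  target <- transitionProbabilities(Q, b)[start + 1L, ]
  nrep <- 100000L
  counts <- integer(4)
  x0 <- stateVector(start, 2)
  for (i in seq_len(nrep)) {
    xe <- simulateBranch(p, x0, b)
    j <- stateIndex(xe) + 1L
    counts[j] <- counts[j] + 1L
  }
  tv <- 0.5 * sum(abs(counts / nrep - target))
  expect_lt(tv, 0.01)
})

test_that("profiles on a degenerate tree copy the root; long branches reach stationarity", {
  tr0 <- readTree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  p <- rand_params(2)
  set.seed(44)
  pm <- simulateProfiles(tr0, p)
  expect_true(all(pm == pm[, 1]))

  star <- readTree(text = paste0("(", paste0("s", 1:300, ":50",
                                             collapse = ","), ");"))
  p1 <- ccmParams(0, matrix(0.6, 1, 1))   # asymmetric gain/loss
  set.seed(45)
  pm1 <- simulateProfiles(star, p1)
  expect_lt(abs(mean(pm1) - ccmStationary(p1)[2]), 0.09)
})

test_that("the simulator is reproducible under a fixed seed", {
  tr <- randomTree(30, seed = 5)
  p <- rand_params(2)
  set.seed(46); a <- simulateProfiles(tr, p)
  set.seed(46); b <- simulateProfiles(tr, p)
  expect_identical(a, b)
})

test_that("within-group coupling produces stronger profile correlation", {
  b <- matrix(0, 6, 6)
  b[1:3, 1:3] <- 1.5; b[4:6, 4:6] <- 1.5; diag(b) <- 0
  p <- ccmParams(rep(0, 6), b)
  wins <- 0L; valid <- 0L
  for (rep in 1:12) {
    tr <- randomTree(150, mean_bl = 0.5, seed = 500 + rep)
    set.seed(600 + rep)
    pm <- simulateProfiles(tr, p)
    cors <- suppressWarnings(cor(t(pm)))
    within <- c(cors[1, 2], cors[1, 3], cors[2, 3],
                cors[4, 5], cors[4, 6], cors[5, 6])
    between <- as.vector(cors[1:3, 4:6])
    w <- mean(abs(within), na.rm = TRUE)
    b <- mean(abs(between), na.rm = TRUE)
    if (is.finite(w) && is.finite(b)) {   # constant profiles give NA cor
      valid <- valid + 1L
      if (w > b) wins <- wins + 1L
    }
  }
  expect_gte(valid, 6L)
  expect_gte(wins / valid, 0.9)
})

test_that("random trees are reproducible with the requested scale", {
  t1 <- randomTree(100, seed = 8)
  t2 <- randomTree(100, seed = 8)
  expect_identical(writeTree(t1), writeTree(t2))
  expect_equal(mean(t1$edge.length), 0.1)
  expect_true(all(t1$edge.length > 0))
  cherry <- randomTree(2, seed = 9)
  expect_equal(length(cherry$tip.label), 2L)
})

test_that("scenario generators construct what they claim", {
  tr <- randomTree(60, seed = 10)
  set.seed(47)
  dp <- genDarwinPair(tr)
  tips <- phyloCCM:::clade_tip_sets(tr)[[dp$clade]]
  expect_true(all(dp$profiles[, tips] == 1L))
  expect_true(all(dp$profiles[, -tips] == 0L))
  expect_equal(jaccardIndex(dp$profiles[1, ], dp$profiles[2, ]), 1)

  rp <- genReplicatedPair(tr, length(tips))
  expect_equal(sum(rp$profiles[1, ]), length(tips))
  expect_equal(jaccardIndex(rp$profiles[1, ], rp$profiles[2, ]), 1)
  keys <- vapply(phyloCCM:::clade_tip_sets(tr),
                 function(s) paste(sort(s), collapse = ","), character(1))
  expect_false(paste(rp$tips, collapse = ",") %in% keys)

  expect_error(genDarwinPair(readTree(text = "(A:1,B:1);")), "clade")
})

test_that("benchmark pair generator labels and truths are consistent", {
  recs <- genBenchmarkPairs(n_null = 4, n_alt = 5, n_tips = 20, seed = 3)
  labs <- vapply(recs, `[[`, integer(1), "label")
  expect_equal(sum(labs == 0L), 4L)
  expect_equal(sum(labs == 1L), 5L)
  b <- vapply(recs, `[[`, numeric(1), "beta12")
  expect_true(all(b[labs == 0L] == 0))
  expect_true(all(b[labs == 1L] >= 0.2 & b[labs == 1L] <= 0.5))
  fixed <- genBenchmarkPairs(2, 3, n_tips = 20, beta_range = c(0.5, 0.5),
                             seed = 4)
  expect_true(all(vapply(fixed, `[[`, numeric(1), "beta12")[3:5] == 0.5))
  again <- genBenchmarkPairs(n_null = 4, n_alt = 5, n_tips = 20, seed = 3)
  expect_identical(lapply(recs, `[[`, "profiles"),
                   lapply(again, `[[`, "profiles"))
})

test_that("estimation error shrinks as the tree grows", {
  mae <- function(n_tips, base) {
    err <- numeric(30)
    for (i in 1:30) {
      set.seed(base + i)
      tr <- randomTree(n_tips)
      pm <- simulateProfiles(tr, ccmParams(c(0, 0),
                                           matrix(c(0, .4, .4, 0), 2)))
      f <- fitCCM(tr, pm, restarts = 1, compute_se = FALSE)
      err[i] <- abs(f$theta[["beta_12"]] - 0.4)
    }
    median(err)
  }
  expect_lt(mae(300, 8100), mae(100, 8200))
})

test_that("topology community generator validates and wires edges", {
  expect_error(genTopologyCommunity(rbind(c(1, 1)), seed = 1), "elf-edge")
  expect_error(genTopologyCommunity(rbind(c(1, 9)), seed = 1), "beyond")
  com <- genTopologyCommunity(rbind(c(1, 3), c(2, 3)), n_genes = 3,
                              beta_value = c(0.5, 0.8), n_tips = 20, seed = 2)
  expect_equal(com$params$beta[1, 3], 0.5)
  expect_equal(com$params$beta[2, 3], 0.8)
  expect_equal(com$params$beta[1, 2], 0)
  expect_equal(dim(com$profiles), c(3L, 20L))
})
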