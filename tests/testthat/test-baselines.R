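# Similarity scores, phylogeny-aware adjustments and Pagel's LRT.

test_that("Jaccard Index handles the standard cases", {
  expect_equal(jaccardIndex(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccardIndex(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(jaccardIndex(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_true(is.na(jaccardIndex(c(0, 0), c(0, 0))))
  expect_equal(jaccardIndex(c(1, 0), c(0, 1)), jaccardIndex(c(0, 1), c(1, 0)))
})

test_that("basic scores match their definitions", {
  p <- c(1, 1, 0, 0); q <- c(1, 0, 1, 0)
  s <- basicScores(p, q)
  expect_equal(s$hamming, 2)
  expect_equal(basicScores(p, p)$hamming, 0)
  # exactly factorized 2x2 joint has zero mutual information
  expect_equal(unname(basicScores(p, q)$mutual_information), 0)
  # hypergeometric upper tail vs exhaustive subset enumeration
  p1 <- c(rep(1, 4), rep(0, 6))
  p2 <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)   # both = 3, margins 4/4, N = 10
  got <- basicScores(p1, p2)$hypergeometric_p
  subsets <- combn(10, 4)
  overl <- apply(subsets, 2, function(s) length(intersect(s, 1:4)))
  expect_equal(got, mean(overl >= 3))
})

test_that("clade adjustment collapses exactly the uniform-pattern clades", {
  star <- readTree(text = "(a:1,b:1,c:1,d:1,e:1);")
  p1 <- c(1, 1, 0, 0, 1); p2 <- c(1, 0, 0, 1, 1)
  expect_equal(cladeAdjustedScore(star, p1, p2),
               basicScores(p1, p2)$hypergeometric_p)

  tr <- readTree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):1);")
  # genes present exactly on the {a,b,c,d} clade: collapses to one
  # pseudo-genome of joint presence plus one of joint absence
  dar1 <- c(1, 1, 1, 1, 0, 0); dar2 <- dar1
  cc <- phyloCCM:::clade_collapse(tr, dar1, dar2)
  expect_equal(length(cc$p1), 2L)
  expect_equal(sum(cc$p1 == 1 & cc$p2 == 1), 1L)

  # invariant to tip order within a clade
  tr_sw <- readTree(text = "(((b:1,a:1):1,(d:1,c:1):1):1,(f:1,e:1):1);")
  ord <- match(tr_sw$tip.label, tr$tip.label)
  p1r <- c(1, 0, 1, 0, 1, 0); p2r <- c(1, 1, 0, 0, 1, 0)
  expect_equal(cladeAdjustedScore(tr, p1r, p2r, "mi"),
               cladeAdjustedScore(tr_sw, p1r[ord], p2r[ord], "mi"))
})

test_that("run adjustment collapses consecutive identical joint patterns", {
  lad <- readTree(text = "(a:1,(b:1,(c:1,(d:1,(e:1,f:1):1):1):1):1);")
  # alternating pattern: no runs longer than one
  p1 <- c(1, 0, 1, 0, 1, 0); p2 <- c(0, 1, 0, 1, 0, 1)
  expect_equal(runAdjustedScore(lad, p1, p2),
               basicScores(p1, p2)$hypergeometric_p)
  # one co-occurrence block collapses to a single run
  b1 <- c(1, 1, 1, 0, 0, 0); b2 <- b1
  cc_p <- runAdjustedScore(lad, b1, b2)
  expect_equal(cc_p, phyloCCM:::hyper_p(1, 1, 1, 2))
  # mirror tree leaves the run structure unchanged
  mir <- readTree(text = "(((((f:1,e:1):1,d:1):1,c:1):1,b:1):1,a:1);")
  ordm <- match(mir$tip.label, lad$tip.label)
  expect_equal(runAdjustedScore(mir, p1[ordm], p2[ordm]),
               runAdjustedScore(lad, p1, p2))
})

test_that("Pagel dependent likelihood matches brute-force enumeration", {
  set.seed(51)
  tr <- randomTree(5, mean_bl = 0.4)
  p1 <- c(1L, 0L, 1L, 1L, 0L); p2 <- c(1L, 1L, 0L, 1L, 0L)
  rates <- exp(rnorm(8, 0, 0.5))
  Q <- phyloCCM:::pagel_Q(rates)
  tp <- phyloCCM:::prep_tree(tr)
  ts <- as.integer(p1 + 2L * p2)
  got <- phyloCCM:::prune_loglik_cpp(Q, tp$edge, tp$elen, ts,
                                     rep(0.25, 4), tp$n_node, numeric(0))
  expect_equal(got, brute_loglik(tr, ts, Q, rep(0.25, 4)), tolerance = 1e-9)
})

test_that("Pagel independent model equals two single-gene community chains", {
  set.seed(52)
  tr <- randomTree(30)
  g <- 1.4; l <- 0.6
  pm <- simulateProfiles(tr, ccmParams(log(sqrt(g * l)),
                                       matrix(log(sqrt(g / l)), 1, 1)))
  tp <- phyloCCM:::prep_tree(tr)
  Q2 <- matrix(c(-g, l, g, -l), 2, 2)
  ll_pagel <- phyloCCM:::prune_loglik_cpp(Q2, tp$edge, tp$elen,
                                          as.integer(pm[1, tr$tip.label]),
                                          c(0.5, 0.5), tp$n_node, numeric(0))
  ll_ccm <- pruneLoglik(tr, pm, ccmParams(log(sqrt(g * l)),
                                          matrix(log(sqrt(g / l)), 1, 1)))
  expect_equal(ll_pagel, ll_ccm, tolerance = 1e-6)
})

test_that("Pagel LRT nests correctly and is roughly calibrated under the null", {
  set.seed(53)
  pvals <- numeric(40)
  for (i in 1:40) {
    tr <- randomTree(60)
    pm <- simulateProfiles(tr, ccmParams(c(0, 0), diag(0, 2)))
    pg <- pagelLRT(tr, pm[1, ], pm[2, ])
    expect_gte(pg$loglik_dep, pg$loglik_indep - 1e-6)
    expect_true(all(pg$rates_dep <= 100 + 1e-9))
    pvals[i] <- pg$p_value
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
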