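test_that("models are valid and P(t) behaves like a transition matrix", {
  m <- substitutionModel("GTR", "NT", freqs = c(0.4, 0.3, 0.2, 0.1),
                         rates = c(1, 2, 1, 1, 3, 1))
  P <- transitionMatrix(m, 0.37)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_equal(transitionMatrix(m, 0), diag(4), tolerance = 1e-12)
  # detailed balance of the reversible model: diag(pi) P is symmetric
  B <- m@freqs * P
  expect_equal(B, t(B), tolerance = 1e-12)
  # rate scaling: expected substitutions per unit time equal 1
  Q <- (transitionMatrix(m, 1e-6) - diag(4)) / 1e-6
  expect_equal(-sum(m@freqs * diag(Q)), 1, tolerance = 1e-4)
})

test_that("site likelihoods reproduce closed forms", {
  m <- substitutionModel("JC", "NT")
  x <- ntMat(a = "AA", b = "AA")
  # zero-distance limit: log pi_A
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(siteLogLik(x, tr0, m)[1], log(0.25), tolerance = 1e-10)
  # two-taxon JC at total length t
  t <- 0.5
  pSame <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
  tr <- ape::read.tree(text = "(a:0.2,b:0.3);")
  expect_equal(siteLogLik(x, tr, m)[1], log(0.25 * pSame), tolerance = 1e-10)
  xd <- ntMat(a = "A", b = "C")
  expect_equal(siteLogLik(xd, tr, m)[1], log(0.25 * (1 - pSame) / 3),
               tolerance = 1e-10)
  # a fully missing column has likelihood 1
  xm <- ntMat(a = "-", b = "-")
  expect_equal(siteLogLik(xm, tr, m)[1], 0, tolerance = 1e-12)
})

test_that("pruning equals exhaustive summation over internal states", {
  # 100 random instances on 3-5 taxa, random models, occasional missing
  # data, checked to 1e-8
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0, 1.2)
    v <- runif(4, 0.5, 2)
    f <- v / sum(v)
    m <- substitutionModel("GTR", "NT", freqs = f,
                           rates = runif(6, 0.5, 2),
                           gammaShape = runif(1, 0.3, 2),
                           nCat = sample(c(0L, 4L), 1))
    col <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                  prob = c(rep(0.23, 4), 0.08))
    x <- residueMatrix(setNames(col, tr$tip.label), "NT")
    got <- siteLogLik(x, tr, m)[1]
    states <- setNames(match(col, c("A", "C", "G", "T")), tr$tip.label)
    want <- log(bruteForceSiteLik(tr, states, m))
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("likelihood obeys the pulley principle and pattern compression", {
  set.seed(12)
  tr <- ape::rtree(5)
  m <- substitutionModel("Poisson", "AA", freqs = empiricalFreqs(
    randomMatrix(2, 50, seed = 1)), gammaShape = 0.9, nCat = 4L)
  x <- randomMatrix(5, 60, missFrac = 0.1, seed = 7)
  rownames(x@seqs) <- rownames(x@mask) <- tr$tip.label
  base <- sum(siteLogLik(x, tr, m))
  # re-rooting the (reversible) tree never changes the likelihood
  for (tip in tr$tip.label[1:3]) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(sum(siteLogLik(x, rr, m)), base, tolerance = 1e-8)
  }
  # duplicated columns (compressed internally) change nothing
  x2 <- residueMatrix(x@seqs[, c(seq_len(60), 1:20)], "AA")
  expect_equal(sum(siteLogLik(x2, tr, m)),
               base + sum(siteLogLik(x, tr, m)[1:20]), tolerance = 1e-10)
})

test_that("branch-length optimisation is monotone and recovers truth", {
  mj <- substitutionModel("JC", "NT")
  # identical sequences: all lengths at the lower bound
  xid <- ntMat(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC",
               d = "ACGTACGTAC")
  topo <- ape::read.tree(text = "((a,b),(c,d));")
  fit0 <- optimizeBranchLengths(xid, topo, mj)
  expect_true(all(fit0$tree$edge.length < 1e-4))

  # optimised logL never below the starting point
  x <- simulateAlignment(simulationConfig(
    ape::read.tree(text = "((a:0.15,b:0.25):0.1,(c:0.2,d:0.3):0.0);"),
    mj, nSites = 10000L, seed = 6L))
  start <- topo
  start$edge.length <- rep(0.1, nrow(topo$edge))
  init <- sum(siteLogLik(x, start, mj))
  fit <- optimizeBranchLengths(x, topo, mj)
  expect_gte(fit$logL, init)
  expect_true(fit$converged)
  expect_equal(fit$logL, sum(fit$siteLogLik), tolerance = 1e-8)

  # parameter recovery within 10% relative error at n = 10,000
  est <- fit$tree
  tipLen <- setNames(est$edge.length[match(seq_len(4), est$edge[, 2])],
                     est$tip.label)
  truth <- c(a = 0.15, b = 0.25, c = 0.2, d = 0.3)
  expect_true(all(abs(tipLen[names(truth)] - truth) / truth < 0.10))
  internal <- sum(est$edge.length[est$edge[, 2] > 4])
  expect_lt(abs(internal - 0.1) / 0.1, 0.10)
})

test_that("site log-likelihood matrices reproduce totals and round-trip", {
  mj <- substitutionModel("JC", "NT")
  x <- simulateAlignment(simulationConfig(
    quartetGroupsTree(1), mj, nSites = 300L, seed = 8L))
  trees <- lapply(quartetTopologies(c("a1", "b1", "c1", "d1")),
                  rootedDerivatives)
  cands <- list(T1 = trees$T1$internal, T2 = trees$T2$internal)
  slm <- siteLogLikMatrix(x, cands, mj)
  expect_equal(unname(rowSums(slm@logl %*% diag(slm@weights))),
               vapply(cands, function(t)
                 optimizeBranchLengths(x, t, mj)$logL, 0,
                 USE.NAMES = FALSE), tolerance = 1e-6)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSlm(slm, f)
  back <- readSlm(f)
  expect_equal(sum(back@weights), sum(slm@weights))
  expect_equal(unname(back@logl %*% rep(1, ncol(back@logl))),
               unname(slm@logl %*% slm@weights), tolerance = 1e-4)
})
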