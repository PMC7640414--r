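test_that("simulation is reproducible and respects degenerate limits", {
  tr <- quartetGroupsTree(2)
  mod <- substitutionModel("Poisson", "AA", gammaShape = 1, nCat = 4L)
  cfg <- simulationConfig(tr, mod, partitionLengths = c(50L, 50L),
                          missingProb = 0.05, dropoutProb = 0.1, seed = 7L)
  a <- simulateAlignment(cfg)
  b <- simulateAlignment(cfg)
  expect_identical(residues(a), residues(b))       # same seed, same bytes
  expect_identical(missingMask(a), missingMask(b))
  c <- simulateAlignment(simulationConfig(tr, mod,
                                          partitionLengths = c(50L, 50L),
                                          missingProb = 0.05,
                                          dropoutProb = 0.1, seed = 8L))
  expect_false(identical(residues(a), residues(c)))

  # all branch lengths zero: every column constant
  tr0 <- tr
  tr0$edge.length[] <- 0
  z <- simulateAlignment(simulationConfig(tr0, mod, nSites = 40L, seed = 1L))
  expect_true(all(apply(residues(z), 2, function(col)
    length(unique(col)) == 1L)))
})

test_that("two-taxon JC divergence matches the closed-form expectation", {
  mj <- substitutionModel("JC", "NT")
  tr <- ape::read.tree(text = "(a:0.25,b:0.25);")
  x <- simulateAlignment(simulationConfig(tr, mj, nSites = 10000L, seed = 4L))
  frac <- mean(residues(x)[1, ] == residues(x)[2, ])
  expected <- 1 / 4 + 3 / 4 * exp(-2 / 3)          # total path length 0.5
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("single-branch transition frequencies follow the matrix exponential", {
  m <- substitutionModel("GTR", "NT", freqs = c(0.35, 0.25, 0.25, 0.15),
                         rates = c(1, 3, 1, 1, 3, 1))
  tr <- ape::read.tree(text = "(a:0.0,b:0.7);")
  x <- simulateAlignment(simulationConfig(tr, m, nSites = 50000L, seed = 9L))
  P <- transitionMatrix(m, 0.7)
  root <- residues(x)[1, ]; tip <- residues(x)[2, ]
  for (u in c("A", "C", "G", "T")) {
    sel <- root == u
    obs <- table(factor(tip[sel], levels = c("A", "C", "G", "T")))
    gof <- suppressWarnings(
      stats::chisq.test(obs, p = P[match(u, c("A", "C", "G", "T")), ]))
    expect_gt(gof$p.value, 1e-3)
  }
})

test_that("composition shifts create Bowker-detectable asymmetry", {
  mj <- substitutionModel("JC", "NT")
  tr <- ape::read.tree(text = "(a:0.4,b:0.4);")
  pv <- vapply(1:40, function(s) {
    x <- simulateAlignment(simulationConfig(
      tr, mj, nSites = 2000L,
      shifts = list(b = c(0.55, 0.25, 0.12, 0.08)), seed = 400 + s))
    bowkerTest(pairCounts(x, "a", "b"))$p.value
  }, 0)
  expect_gt(mean(pv < 0.05), 0.9)                  # near-certain rejection
})

test_that("the myriapod fixture reproduces its design counts", {
  fx <- myriapodFixture(seed = 3L, nSitesPerGene = 60L)
  expect_equal(nTaxa(fx$matrix), 59L)
  myri <- c("Chilopoda", "Diplopoda", "Pauropoda", "Symphyla")
  expect_equal(sum(fx$groupMap %in% myri), 30L)
  expect_equal(as.integer(table(fx$groupMap)[myri]), c(16L, 10L, 1L, 3L))
  expect_equal(countQuartets(fx$groupMap, myri), 480)
  expect_equal(length(partitionScheme(fx$matrix)@partName), 10L)
  expect_gt(sum(missingMask(fx$matrix)), 0)        # non-random missingness
  # the guide tree pairs Chilopoda+Diplopoda and Pauropoda+Symphyla
  expect_equal(topologyKey(classifyTree(fx$tree, fx$groupMap[
    fx$groupMap %in% myri])),
    "Chilopoda,Diplopoda|Pauropoda,Symphyla")
  # determinism end to end
  fx2 <- myriapodFixture(seed = 3L, nSitesPerGene = 60L)
  expect_identical(residues(fx2$matrix), residues(fx$matrix))
})

test_that("simulation configs round-trip through YAML", {
  dir <- withr::local_tempdir()
  cfgFile <- file.path(dir, "sim.yaml")
  writeLines(c(
    "tree: '((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);'",
    "model:",
    "  name: JC",
    "  alphabet: NT",
    "  nCat: 0",
    "partitionLengths: [30, 20]",
    "shifts:",
    "  d: [0.4, 0.3, 0.2, 0.1]",
    "missingProb: 0.05",
    "dropoutProb: 0.1",
    "seed: 12"), cfgFile)
  cfg <- readSimulationConfig(cfgFile)
  expect_s4_class(cfg, "SimulationConfig")
  expect_equal(sum(cfg@partitionLengths), 50L)
  expect_equal(cfg@model@name, "JC")
  expect_equal(cfg@shifts$d, c(0.4, 0.3, 0.2, 0.1))
  x <- simulateAlignment(cfg)
  expect_equal(nSites(x), 50L)
  expect_equal(length(partitionScheme(x)@partName), 2L)
  # identical to the equivalent in-code configuration
  y <- simulateAlignment(simulationConfig(
    ape::read.tree(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);"),
    substitutionModel("JC", "NT"), partitionLengths = c(30L, 20L),
    shifts = list(d = c(0.4, 0.3, 0.2, 0.1)), missingProb = 0.05,
    dropoutProb = 0.1, seed = 12L))
  expect_identical(residues(x), residues(y))

  # CLI path: simulate from a config file
  out <- file.path(dir, "sim")
  expect_equal(suppressMessages(
    runCli(c("simulate", "--config", cfgFile, "--out", out))), 0L)
  z <- readFasta(paste0(out, ".fasta"), "NT")
  expect_identical(residues(z), residues(x))
})
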