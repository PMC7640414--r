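test_that("FASTA reading masks gaps/ambiguities and validates input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MK-", ">b", "MKX"), f)
  x <- readFasta(f, "AA")
  expect_equal(dim(residues(x)), c(2L, 3L))
  expect_equal(unname(missingMask(x)[, 3]), c(TRUE, TRUE))
  expect_false(any(missingMask(x)[, 1:2]))

  writeLines(c(">a", "MK", ">b", "MKL"), f)
  expect_error(readFasta(f, "AA"), "unequal")
  writeLines(c(">a", "MK", ">a", "ML"), f)
  expect_error(readFasta(f, "AA"), "duplicate")
  writeLines(character(0), f)
  expect_error(readFasta(f, "AA"))
})

test_that("write/read FASTA round-trips byte-identically for canonical files", {
  x <- randomMatrix(5, c(40, 37), missFrac = 0.15, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(x, f1)
  y <- readFasta(f1, "AA")
  writeFasta(y, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(residues(y), residues(x))
  expect_identical(missingMask(y), missingMask(x))
})

test_that("concatenation unions taxa, fills missing blocks, conserves cells", {
  g1 <- residueMatrix(c(a = "MKLVF", b = "MKLVF"), "AA")
  g2 <- residueMatrix(c(b = "WYH", c = "WYH"), "AA")
  cc <- concatenateMatrices(list(gene1 = g1, gene2 = g2))
  expect_equal(nTaxa(cc), 3L)
  expect_equal(nSites(cc), 8L)
  expect_true(all(missingMask(cc)["a", 6:8]))
  expect_true(all(missingMask(cc)["c", 1:5]))
  expect_equal(partitionScheme(cc)@partName, c("gene1", "gene2"))
  expect_equal(partitionScheme(cc)@partEnd, c(5L, 8L))

  # single gene: identity up to partition annotation
  one <- concatenateMatrices(list(g1))
  expect_identical(residues(one), residues(g1))

  # conservation oracle over random genes
  genes <- lapply(1:10, function(i)
    randomMatrix(4, sample(5:20, 1), missFrac = 0.3, seed = i))
  cat10 <- concatenateMatrices(genes)
  expect_equal(sum(!missingMask(cat10)),
               sum(vapply(genes, function(g) sum(!missingMask(g)), 0)))
})

test_that("strict filter keeps exactly the fully represented partitions", {
  m <- matrix("A", 3, 9, dimnames = list(c("a", "b", "c"), NULL))
  m["c", 4:6] <- "-"                      # gene 2 lacks taxon c entirely
  sch <- quartetSignal:::newPartitionScheme(c("g1", "g2", "g3"), c(3, 3, 3))
  x <- residueMatrix(m, "AA", sch)
  y <- filterStrict(x)
  expect_equal(partitionScheme(y)@partName, c("g1", "g3"))
  expect_equal(nSites(y), 6L)

  # no missing data: identity
  full <- randomMatrix(4, c(5, 5), missFrac = 0)
  expect_equal(nSites(filterStrict(full)), 10L)

  # brute-force oracle on random masks + idempotence
  x2 <- randomMatrix(6, rep(4, 8), missFrac = 0.35, seed = 11)
  kept <- partitionScheme(filterStrict(x2))@partName
  sch2 <- partitionScheme(x2)
  oracle <- sch2@partName[vapply(seq_along(sch2@partName), function(i) {
    blk <- !missingMask(x2)[, sch2@partStart[i]:sch2@partEnd[i], drop = FALSE]
    all(rowSums(blk) > 0)
  }, logical(1))]
  expect_equal(kept, oracle)
  expect_equal(partitionScheme(filterStrict(filterStrict(x2)))@partName, kept)
})

test_that("relaxed filter requires one representative per required group", {
  m <- matrix("A", 4, 6, dimnames = list(c("c1", "c2", "c3", "p1"), NULL))
  m[c("c2", "c3", "p1"), 1:3] <- "-"      # gene 1: 1/3 chilopods, 0 pauropods
  sch <- quartetSignal:::newPartitionScheme(c("g1", "g2"), c(3, 3))
  x <- residueMatrix(m, "AA", sch)
  gm <- c(c1 = "Chilopoda", c2 = "Chilopoda", c3 = "Chilopoda",
          p1 = "Pauropoda")
  y <- filterRelaxed(x, gm, c("Chilopoda", "Pauropoda"))
  expect_equal(partitionScheme(y)@partName, "g2")

  # vacuous condition keeps everything
  expect_equal(nSites(filterRelaxed(x, gm, character(0))), 6L)
  expect_error(filterRelaxed(x, gm, "Symphyla"), "configuration error")

  # brute-force oracle with 4 groups on random masks + idempotence
  x2 <- randomMatrix(8, rep(5, 6), missFrac = 0.5, seed = 21)
  gm2 <- setNames(rep(c("W", "X", "Y", "Z"), each = 2), taxa(x2))
  y2 <- filterRelaxed(x2, gm2, c("W", "X", "Y", "Z"))
  sch2 <- partitionScheme(x2)
  oracle <- vapply(seq_along(sch2@partName), function(i) {
    blk <- !missingMask(x2)[, sch2@partStart[i]:sch2@partEnd[i], drop = FALSE]
    all(vapply(c("W", "X", "Y", "Z"), function(g)
      any(rowSums(blk[gm2[taxa(x2)] == g, , drop = FALSE]) > 0), logical(1)))
  }, logical(1))
  expect_equal(partitionScheme(y2)@partName, sch2@partName[oracle])
  expect_equal(partitionScheme(filterRelaxed(y2, gm2, c("W", "X", "Y", "Z")))@partName,
               partitionScheme(y2)@partName)
})

test_that("codon-position selection respects per-partition frames", {
  x <- residueMatrix(c(a = "ACGTACGTA", b = "ACGTACGTA"), "NT")
  y <- selectCodonPositions(x, 2)
  expect_equal(nSites(y), 3L)
  expect_equal(unname(residues(y)[1, ]), c("C", "A", "T"))  # sites 2,5,8

  # identity when all positions kept
  expect_identical(residues(selectCodonPositions(x, c(1, 2, 3))), residues(x))

  # two genes 6+9 sites: boundaries preserved, 2+3 sites
  m <- matrix("A", 2, 15, dimnames = list(c("a", "b"), NULL))
  sch <- quartetSignal:::newPartitionScheme(c("g1", "g2"), c(6, 9))
  x2 <- residueMatrix(m, "NT", sch)
  y2 <- selectCodonPositions(x2, 2)
  expect_equal(partitionLengths <- partitionScheme(y2)@partEnd -
                 partitionScheme(y2)@partStart + 1L, c(2L, 3L))

  # the three positions partition the sites exactly
  x3 <- randomMatrix(3, c(6, 9), alphabet = "NT", missFrac = 0.1, seed = 5)
  picked <- lapply(1:3, function(p) {
    sel <- selectCodonPositions(x3, p)
    as.vector(residues(sel))
  })
  expect_equal(sum(lengths(picked)), 3 * nSites(x3))
  expect_error(selectCodonPositions(randomMatrix(2, 7, "NT"), 2), "frame")
})

test_that("completeness scores count non-missing cells exactly", {
  full <- randomMatrix(3, 10, missFrac = 0)
  cov <- completeness(full)
  expect_equal(cov@Ca, 100)
  expect_true(all(cov@pairwiseShared == 1))

  m <- matrix("A", 2, 10, dimnames = list(c("a", "b"), NULL))
  m["b", 1:5] <- "-"
  cov2 <- completeness(residueMatrix(m, "AA"))
  expect_equal(unname(cov2@Cr["b"]), 50)
  expect_equal(cov2@Ca, 75)
  expect_equal(cov2@pairwiseShared["a", "b"], 0.5)

  # counting oracle + Ca is the mean of Cr (equal row lengths)
  x <- randomMatrix(6, c(20, 15), missFrac = 0.3, seed = 9)
  cov3 <- completeness(x)
  expect_equal(cov3@Ca, 100 * sum(!missingMask(x)) / (6 * 35))
  expect_equal(cov3@Ca, mean(cov3@Cr))
  expect_true(isSymmetric(cov3@pairwiseShared))
  i <- "t01"; j <- "t04"
  expect_equal(cov3@pairwiseShared[i, j],
               mean(!missingMask(x)[i, ] & !missingMask(x)[j, ]))
})

test_that("taxon subsetting preserves sites and per-taxon content", {
  x <- randomMatrix(6, c(10, 10), missFrac = 0.2, seed = 4)
  y <- subsetTaxa(x, c("t02", "t05"))
  expect_equal(taxa(y), c("t02", "t05"))
  expect_equal(nSites(y), nSites(x))
  expect_identical(residues(y)["t05", ], residues(x)["t05", ])
  expect_identical(residues(subsetTaxa(x, taxa(x))), residues(x))
  expect_error(subsetTaxa(x, "nope"), "unknown")
})

test_that("partition files round-trip in RAxML 1-based convention", {
  sch <- quartetSignal:::newPartitionScheme(c("g1", "g2"), c(100, 55))
  f <- withr::local_tempfile(fileext = ".txt")
  writePartitions(sch, f, model = "WAG")
  expect_match(readLines(f)[1], "WAG, g1 = 1-100", fixed = TRUE)
  back <- readPartitions(f)
  expect_equal(back@partName, sch@partName)
  expect_equal(back@partStart, sch@partStart)
  expect_equal(back@partEnd, sch@partEnd)
})
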