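# Shared builders for small in-code fixtures.

aaMat <- function(...) residueMatrix(c(...), "AA")
ntMat <- function(...) residueMatrix(c(...), "NT")

# random aligned matrix with a given missing fraction and partitions
randomMatrix <- function(nTaxa, lens, alphabet = "AA", missFrac = 0.2,
                         seed = 1) {
  set.seed(seed)
  alph <- if (alphabet == "AA") c("A","C","D","E","F","G","H","I","K","L",
                                  "M","N","P","Q","R","S","T","V","W","Y")
          else c("A","C","G","T")
  n <- sum(lens)
  m <- matrix(sample(alph, nTaxa * n, replace = TRUE), nTaxa,
              dimnames = list(sprintf("t%02d", seq_len(nTaxa)), NULL))
  m[matrix(runif(nTaxa * n) < missFrac, nTaxa)] <- "-"
  sch <- quartetSignal:::newPartitionScheme(sprintf("g%d", seq_along(lens)),
                                            lens)
  residueMatrix(m, alphabet, sch)
}

# balanced quartet guide tree: 4 clades of `per` (1..3) tips, topology
# (A,B)|(C,D), labelled a1..a<per>, b1.., c1.., d1..
quartetGroupsTree <- function(per = 3, tipLen = 0.05, stemLen = 0.15,
                              internalLen = 0.3) {
  clade <- function(p) {
    switch(per,
           sprintf("%s1:%f", p, tipLen + stemLen),
           sprintf("(%s1:%f,%s2:%f):%f", p, tipLen, p, tipLen, stemLen),
           sprintf("(%s1:%f,(%s2:%f,%s3:%f):%f):%f", p, tipLen, p, tipLen,
                   p, tipLen, tipLen, stemLen))
  }
  ape::read.tree(text = sprintf("((%s,%s):%f,(%s,%s):%f);",
                                clade("a"), clade("b"), internalLen / 2,
                                clade("c"), clade("d"), internalLen / 2))
}

quartetGroupMap <- function(per = 3) {
  setNames(rep(c("A", "B", "C", "D"), each = per),
           paste0(rep(c("a", "b", "c", "d"), each = per), seq_len(per)))
}

# brute-force likelihood of one site by exhaustive summation over all
# internal-node state assignments (the pruning oracle)
bruteForceSiteLik <- function(tree, states, model) {
  tre <- ape::reorder.phylo(tree, "postorder")
  k <- length(model@freqs)
  nTip <- length(tre$tip.label)
  nInternal <- tre$Nnode
  root <- tre$edge[nrow(tre$edge), 1L]
  rates <- quartetSignal:::gammaRates(model)
  perCat <- numeric(length(rates))
  for (ci in seq_along(rates)) {
    Ps <- lapply(seq_len(nrow(tre$edge)), function(e)
      transitionMatrix(model, tre$edge.length[e] * rates[ci]))
    grids <- rep(list(seq_len(k)), nInternal)
    combos <- as.matrix(expand.grid(grids))
    tot <- 0
    for (r in seq_len(nrow(combos))) {
      assign <- integer(nTip + nInternal)
      assign[seq_len(nTip)] <- states[tre$tip.label]
      assign[nTip + seq_len(nInternal)] <- combos[r, ]
      p <- model@freqs[assign[root]]
      ok <- TRUE
      for (e in seq_len(nrow(tre$edge))) {
        u <- assign[tre$edge[e, 1L]]; v <- assign[tre$edge[e, 2L]]
        if (is.na(v)) next                      # missing tip: marginalised
        p <- p * Ps[[e]][u, v]
        if (p == 0) { ok <- FALSE; break }
      }
      if (ok) tot <- tot + p
    }
    # marginalised tips: sum over their states too
    perCat[ci] <- tot
  }
  mean(perCat)
}
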