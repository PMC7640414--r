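## Non-stationary sequence simulator. Sites evolve independently down a
## guide tree: root states from the model frequencies, branch transitions
## by matrix exponential, optional discrete-gamma site rates, optional
## lineage-specific composition shifts (frequency switching at designated
## branches with exchangeabilities held fixed — the simplest generator of
## Bowker-detectable asymmetry), and transcriptome-like missingness
## (whole taxon x gene dropout blocks plus per-cell noise).

#' Construct a simulation configuration
#'
#' @param tree guide tree (\code{phylo}) with branch lengths.
#' @param model a \linkS4class{SubstitutionModel}; its frequencies are the
#'   root composition.
#' @param nSites alignment length (ignored when \code{partitionLengths}
#'   is given).
#' @param partitionLengths optional per-gene lengths.
#' @param shifts named list: names are tip or internal-node labels, values
#'   replacement frequency vectors applied from the branch leading to that
#'   node tipward.
#' @param missingProb per-cell missingness probability.
#' @param dropoutProb probability of dropping a whole taxon x partition
#'   block.
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(tree, model, nSites = 1000L,
                             partitionLengths = integer(0), shifts = list(),
                             missingProb = 0, dropoutProb = 0, seed = 1L) {
  new("SimulationConfig", tree = tree, model = model,
      nSites = as.integer(nSites),
      partitionLengths = as.integer(partitionLengths), shifts = shifts,
      missingProb = as.numeric(missingProb),
      dropoutProb = as.numeric(dropoutProb), seed = as.integer(seed))
}

## resolve a shift label to a node id (tip label or node label)
resolveNode <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(label, tree$node.label)
    if (!is.na(j)) return(length(tree$tip.label) + j)
  }
  stop("input error: shift label not on tree: ", label)
}

#' Simulate an alignment under the configuration
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{ResidueMatrix}; fully reproducible from the
#'   config seed.
#' @export
simulateAlignment <- function(config) {
  tree <- ape::reorder.phylo(config@tree, "cladewise")   # root-to-tip order
  model <- config@model
  k <- length(model@freqs)
  alph <- residueAlphabet(model@alphabet)
  lens <- if (length(config@partitionLengths)) config@partitionLengths
          else config@nSites
  n <- sum(lens)
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  shiftNode <- vapply(names(config@shifts), function(l) resolveNode(tree, l), 0L)
  withSeed(config@seed, {
    rates <- gammaRates(model)
    siteCat <- if (length(rates) > 1L)
      sample.int(length(rates), n, replace = TRUE) else rep(1L, n)
    states <- matrix(NA_integer_, nTip + tree$Nnode, n)
    states[root, ] <- sample.int(k, n, replace = TRUE, prob = model@freqs)
    nodeModel <- vector("list", nTip + tree$Nnode)
    nodeModel[[root]] <- model
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
      mdl <- nodeModel[[p]]
      hit <- which(shiftNode == v)
      if (length(hit))
        mdl <- setModelFreqs(mdl, config@shifts[[hit[1L]]])
      nodeModel[[v]] <- mdl
      t <- tree$edge.length[e]
      for (ci in unique(siteCat)) {
        P <- transitionMatrix(mdl, t * rates[ci])
        P <- P / rowSums(P)
        idx <- which(siteCat == ci)
        parent <- states[p, idx]
        child <- integer(length(idx))
        for (u in unique(parent)) {
          sel <- parent == u
          child[sel] <- sample.int(k, sum(sel), replace = TRUE, prob = P[u, ])
        }
        states[v, idx] <- child
      }
    }
    seqs <- matrix(alph[states[seq_len(nTip), , drop = FALSE]], nTip,
                   dimnames = list(tree$tip.label, NULL))
    sch <- newPartitionScheme(
      if (length(lens) > 1L) sprintf("gene%02d", seq_along(lens)) else "p1",
      lens)
    if (any(config@dropoutProb > 0)) {
      for (i in seq_len(nTip)) for (g in seq_along(lens)) {
        if (runif(1L) < config@dropoutProb)
          seqs[i, sch@partStart[g]:sch@partEnd[g]] <- "-"
      }
    }
    if (any(config@missingProb > 0)) {
      mp <- if (length(config@missingProb) == 1L)
        rep(config@missingProb, nTip)
      else config@missingProb[tree$tip.label]
      for (i in seq_len(nTip)) {
        hitCells <- runif(n) < mp[i]
        seqs[i, hitCells] <- "-"
      }
    }
    residueMatrix(seqs, model@alphabet, sch)
  })
}

## scale a tree so its maximum root-to-tip depth equals `depth`
scaleDepth <- function(tree, depth) {
  d <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / d
  tree
}

randomClade <- function(n, prefix, depth) {
  if (n == 1L) return(NULL)            # single tip: handled by caller
  tr <- ape::rcoal(n, tip.label = sprintf("%s%02d", prefix, seq_len(n)))
  scaleDepth(tr, depth)
}

subNewick <- function(tree, len) {
  s <- ape::write.tree(tree)
  paste0(sub(";$", "", s), ":", format(len, scientific = FALSE))
}

#' Synthetic supermatrix with a realistic myriapod sampling design
#'
#' Simulates a 59-taxon amino-acid supermatrix on a guide tree whose
#' quartet topology pairs Chilopoda with Diplopoda and Pauropoda with
#' Symphyla on a mandibulate backbone (outgroups: 20 pancrustaceans, 7
#' chelicerates, 2 onychophorans), with subgroup sizes typical of
#' myriapod phylogenomics: 16 centipedes, 10 millipedes, 1 pauropod, 3 symphylans. Ten
#' gene partitions, discrete-gamma rate heterogeneity, lineage-specific
#' composition shifts (SRH violations) and non-random missingness
#' (taxon x gene dropout plus cell noise) are included.
#'
#' @param seed RNG seed.
#' @param nSitesPerGene sites per gene partition (10 partitions).
#' @param dropoutProb per taxon x gene dropout probability.
#' @param missingProb per-cell missingness probability.
#' @return list with \code{matrix} (\linkS4class{ResidueMatrix}),
#'   \code{groupMap} (named character vector) and \code{tree} (the guide
#'   \code{phylo}).
#' @export
myriapodFixture <- function(seed = 1L, nSitesPerGene = 150L,
                            dropoutProb = 0.15, missingProb = 0.02) {
  sizes <- c(Chilopoda = 16L, Diplopoda = 10L, Pauropoda = 1L,
             Symphyla = 3L, Pancrustacea = 20L, Chelicerata = 7L,
             Onychophora = 2L)
  prefixes <- c(Chilopoda = "Chil", Diplopoda = "Dipl", Pauropoda = "Paur",
                Symphyla = "Sym", Pancrustacea = "Pan", Chelicerata = "Chel",
                Onychophora = "Ony")
  clades <- withSeed(seed, lapply(names(sizes), function(g)
    randomClade(sizes[[g]], prefixes[[g]], depth = 0.12)))
  names(clades) <- names(sizes)
  sub <- function(g, len) {
    if (sizes[[g]] == 1L) paste0(prefixes[[g]], "01:", len + 0.12)
    else subNewick(clades[[g]], len)
  }
  ## topology-A myriapods: (Chilopoda,Diplopoda) | (Pauropoda,Symphyla)
  myri <- sprintf("((%s,%s):0.18,(%s,%s):0.18):0.08",
                  sub("Chilopoda", 0.10), sub("Diplopoda", 0.10),
                  sub("Pauropoda", 0.10), sub("Symphyla", 0.10))
  nwk <- sprintf("(%s,(%s,(%s,%s):0.06):0.06);",
                 sub("Onychophora", 0.15), sub("Chelicerata", 0.12),
                 sub("Pancrustacea", 0.10), myri)
  tree <- ape::read.tree(text = nwk)
  baseFreqs <- rep(1 / 20, 20L)
  shifted <- baseFreqs
  shifted[1:5] <- shifted[1:5] * 2.2       # enrich ACDEF
  shifted <- shifted / sum(shifted)
  model <- substitutionModel("Poisson", "AA", freqs = baseFreqs,
                             gammaShape = 0.8, nCat = 4L)
  ## heterogeneity crosses the true split (pauropod + one centipede + one
  ## outgroup lineage share a composition), so SRH violations do not
  ## simply reinforce the generating topology
  cfg <- simulationConfig(tree, model,
                          partitionLengths = rep(nSitesPerGene, 10L),
                          shifts = list(Paur01 = shifted,
                                        Chil01 = shifted,
                                        Pan01 = shifted),
                          missingProb = missingProb,
                          dropoutProb = dropoutProb, seed = seed)
  mat <- simulateAlignment(cfg)
  groupMap <- setNames(rep(names(sizes), sizes),
                       unlist(lapply(names(sizes), function(g)
                         sprintf("%s%02d", prefixes[[g]], seq_len(sizes[[g]])))))
  list(matrix = mat, groupMap = groupMap, tree = tree)
}

#' Read a simulation configuration from a YAML file
#'
#' Expected fields: \code{tree} (Newick string or path to a Newick
#' file), \code{model} (list: \code{name}, \code{alphabet}, optional
#' \code{freqs}, \code{gammaShape}, \code{nCat}, \code{rates}),
#' \code{nSites} or \code{partitionLengths}, optional \code{shifts}
#' (map from tip/node label to frequency vector), \code{missingProb},
#' \code{dropoutProb}, \code{seed}.
#'
#' @param path YAML file.
#' @return a \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  tree <- if (file.exists(y$tree)) ape::read.tree(y$tree)
          else ape::read.tree(text = y$tree)
  m <- y$model
  model <- substitutionModel(
    name = if (is.null(m$name)) "Poisson" else m$name,
    alphabet = if (is.null(m$alphabet)) "AA" else m$alphabet,
    freqs = if (is.null(m$freqs)) NULL else as.numeric(m$freqs),
    gammaShape = if (is.null(m$gammaShape)) 1 else m$gammaShape,
    nCat = if (is.null(m$nCat)) 0L else as.integer(m$nCat),
    rates = if (is.null(m$rates)) rep(1, 6) else as.numeric(m$rates))
  simulationConfig(
    tree, model,
    nSites = if (is.null(y$nSites)) 1000L else y$nSites,
    partitionLengths = if (is.null(y$partitionLengths)) integer(0)
                       else as.integer(y$partitionLengths),
    shifts = if (is.null(y$shifts)) list()
             else lapply(y$shifts, as.numeric),
    missingProb = if (is.null(y$missingProb)) 0 else y$missingProb,
    dropoutProb = if (is.null(y$dropoutProb)) 0 else y$dropoutProb,
    seed = if (is.null(y$seed)) 1L else y$seed)
}
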