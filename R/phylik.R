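## Likelihood engine: reversible substitution models, Felsenstein pruning
## on fixed topologies, and coordinate-wise branch-length optimisation.
## Small-tree oriented (quartets and fixtures), but general over any
## binary/multifurcating phylo with branch lengths.

buildEigen <- function(exch, freqs) {
  k <- length(freqs)
  Q <- exch * rep(freqs, each = k)        # Q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))             # expected rate at equilibrium
  Q <- Q / mu
  sq <- sqrt(freqs)
  B <- Q * (sq %o% (1 / sq))              # symmetric similarity transform
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       A = e$vectors / sq,                # diag(1/sq) %*% U
       Ainv = t(e$vectors) * rep(sq, each = k))  # t(U) %*% diag(sq)
}

#' Construct a substitution model
#'
#' \code{"Poisson"} (equal exchangeabilities, any alphabet; the standard
#' amino-acid default here), \code{"JC"} (nucleotide, equal
#' exchangeabilities and frequencies) or \code{"GTR"} (nucleotide, six
#' exchangeabilities in order AC, AG, AT, CG, CT, GT). A custom symmetric
#' exchangeability matrix — e.g. an empirical amino-acid matrix loaded
#' with \code{\link{readRateMatrix}} — may be supplied instead of a name.
#' The rate matrix is always rescaled to one expected substitution per
#' unit branch length.
#'
#' @param name model name, or ignored when \code{exch} is given.
#' @param alphabet \code{"AA"} or \code{"NT"}.
#' @param freqs equilibrium frequencies; default uniform (and forced
#'   uniform for JC).
#' @param gammaShape discrete-gamma shape parameter.
#' @param nCat number of gamma categories; 0 disables rate heterogeneity.
#' @param rates for GTR: numeric(6) exchangeabilities.
#' @param exch optional custom symmetric exchangeability matrix.
#' @return a \linkS4class{SubstitutionModel}.
#' @export
substitutionModel <- function(name = c("Poisson", "JC", "GTR"),
                              alphabet = c("AA", "NT"), freqs = NULL,
                              gammaShape = 1, nCat = 0L, rates = rep(1, 6),
                              exch = NULL) {
  alphabet <- match.arg(alphabet)
  k <- length(residueAlphabet(alphabet))
  if (is.null(exch)) {
    name <- match.arg(name)
    if (name %in% c("JC", "GTR") && alphabet != "NT")
      stop(name, " is a nucleotide model")
    exch <- matrix(1, k, k)
    if (name == "GTR") {
      ## (2,1)=AC (3,1)=AG (4,1)=AT (3,2)=CG (4,2)=CT (4,3)=GT
      exch <- matrix(0, 4L, 4L)
      exch[2L, 1L] <- rates[1L]; exch[3L, 1L] <- rates[2L]; exch[4L, 1L] <- rates[3L]
      exch[3L, 2L] <- rates[4L]; exch[4L, 2L] <- rates[5L]; exch[4L, 3L] <- rates[6L]
      exch <- exch + t(exch)
    }
    if (name == "JC") freqs <- rep(1 / 4, 4L)
  } else {
    name <- if (is.character(name) && length(name) == 1L &&
                !name %in% c("Poisson", "JC", "GTR")) name else "custom"
  }
  diag(exch) <- 0
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  freqs <- freqs / sum(freqs)
  new("SubstitutionModel", alphabet = alphabet, name = name, exch = exch,
      freqs = freqs, gammaShape = as.numeric(gammaShape),
      nCat = as.integer(nCat), eig = buildEigen(exch, freqs))
}

#' Replace the equilibrium frequencies of a model
#'
#' Keeps the exchangeabilities and rate-heterogeneity settings, rebuilds
#' the (rescaled) rate matrix around new frequencies. Used both for
#' empirical \code{+F} frequencies and for lineage-specific composition
#' shifts in the simulator.
#'
#' @param model a \linkS4class{SubstitutionModel}.
#' @param freqs new positive frequency vector.
#' @return a \linkS4class{SubstitutionModel}.
#' @export
setModelFreqs <- function(model, freqs) {
  freqs <- freqs / sum(freqs)
  new("SubstitutionModel", alphabet = model@alphabet, name = model@name,
      exch = model@exch, freqs = freqs, gammaShape = model@gammaShape,
      nCat = model@nCat, eig = buildEigen(model@exch, freqs))
}

#' Empirical residue frequencies of an alignment
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param pseudocount added per state to avoid zero frequencies.
#' @return frequency vector over the core alphabet.
#' @export
empiricalFreqs <- function(x, pseudocount = 0.5) {
  alph <- residueAlphabet(seqAlphabet(x))
  cnt <- table(factor(x@seqs[!x@mask], levels = alph)) + pseudocount
  as.numeric(cnt / sum(cnt))
}

#' Read a PAML-format amino-acid exchangeability matrix
#'
#' Plain-text lower-triangle rows (19 lines for amino acids) followed by a
#' line of 20 equilibrium frequencies, the format in which empirical
#' matrices such as LG or WAG are distributed.
#'
#' @param path text file.
#' @param alphabet alphabet the matrix is for.
#' @return list with \code{exch} (symmetric matrix) and \code{freqs}.
#' @export
readRateMatrix <- function(path, alphabet = "AA") {
  k <- length(residueAlphabet(alphabet))
  nums <- scan(path, quiet = TRUE)
  nLow <- k * (k - 1) / 2
  if (length(nums) < nLow + k)
    stop("expected ", nLow, " exchangeabilities plus ", k, " frequencies")
  exch <- matrix(0, k, k)
  ## PAML lists row by row: element (i, j) for i = 2..k, j < i
  idx <- 1L
  for (i in 2L:k) for (j in 1L:(i - 1L)) {
    exch[i, j] <- nums[idx]; idx <- idx + 1L
  }
  exch <- exch + t(exch)
  freqs <- nums[nLow + seq_len(k)]
  list(exch = exch, freqs = freqs / sum(freqs))
}

## category rates, mean 1
gammaRates <- function(model) {
  if (model@nCat > 0L) phangorn::discrete.gamma(model@gammaShape, model@nCat)
  else 1
}

#' Transition probability matrix P(t)
#' @param model a \linkS4class{SubstitutionModel}.
#' @param t branch length (expected substitutions per site).
#' @return k x k stochastic matrix.
#' @export
transitionMatrix <- function(model, t) {
  e <- model@eig
  P <- e$A %*% (exp(e$values * t) * e$Ainv)
  P[P < 0] <- 0
  P
}

## ---- pattern compression --------------------------------------------

## states: integer matrix tips x patterns (NA = missing), rownames taxa
compressPatterns <- function(x, taxaKeep = taxa(x)) {
  alph <- residueAlphabet(seqAlphabet(x))
  m <- x@seqs[taxaKeep, , drop = FALSE]
  m[x@mask[taxaKeep, , drop = FALSE]] <- NA_character_
  st <- matrix(match(m, alph), nrow = length(taxaKeep),
               dimnames = list(taxaKeep, NULL))
  key <- apply(st, 2L, paste, collapse = ",")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  list(states = st[, uniq, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(uniq))),
       siteIndex = idx)
}

tipPartialMatrix <- function(stateRow, k) {
  P <- length(stateRow)
  out <- matrix(0, k, P)
  obs <- !is.na(stateRow)
  out[cbind(stateRow[obs], which(obs))] <- 1
  out[, !obs] <- 1
  out
}

## postorder down-pass; returns partials and log-scalers per category
## plus cached per-edge transition matrices
downPass <- function(tree, states, model) {
  k <- length(residueAlphabet(model@alphabet))
  P <- ncol(states)
  rates <- gammaRates(model)
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge; elen <- tre$edge.length
  nTip <- length(tre$tip.label)
  nNode <- nTip + tre$Nnode
  tipIdx <- match(tre$tip.label, rownames(states))
  tipPart <- lapply(seq_len(nTip),
                    function(i) tipPartialMatrix(states[tipIdx[i], ], k))
  down <- vector("list", length(rates))
  scal <- vector("list", length(rates))
  Pmats <- vector("list", length(rates))
  for (ci in seq_along(rates)) {
    part <- vector("list", nNode)
    sc <- vector("list", nNode)
    Pc <- vector("list", nrow(edge))
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1L]; v <- edge[e, 2L]
      Pc[[e]] <- transitionMatrix(model, elen[e] * rates[ci])
      dv <- if (v <= nTip) tipPart[[v]] else part[[v]]
      sv <- if (v <= nTip) numeric(P) else sc[[v]]
      contrib <- Pc[[e]] %*% dv
      if (is.null(part[[p]])) {
        part[[p]] <- contrib; sc[[p]] <- sv
      } else {
        part[[p]] <- part[[p]] * contrib; sc[[p]] <- sc[[p]] + sv
      }
      cs <- colSums(part[[p]])
      part[[p]] <- part[[p]] / rep(cs, each = k)
      sc[[p]] <- sc[[p]] + log(cs)
    }
    down[[ci]] <- part; scal[[ci]] <- sc; Pmats[[ci]] <- Pc
  }
  root <- edge[nrow(edge), 1L]
  list(edge = edge, elen = elen, root = root, nTip = nTip,
       tipPart = tipPart, down = down, scal = scal, Pmats = Pmats,
       rates = rates, k = k, nPat = P, tree = tre)
}

## per-pattern log-likelihood from a completed down pass
patternLogLik <- function(dp, model) {
  out <- matrix(0, length(dp$rates), dp$nPat)
  for (ci in seq_along(dp$rates)) {
    lik <- colSums(model@freqs * dp$down[[ci]][[dp$root]])
    out[ci, ] <- log(lik) + dp$scal[[ci]][[dp$root]]
  }
  if (nrow(out) == 1L) return(out[1L, ])
  m <- out[1L, ]
  for (r in 2:nrow(out)) m <- pmax(m, out[r, ])
  acc <- exp(out[1L, ] - m)
  for (r in 2:nrow(out)) acc <- acc + exp(out[r, ] - m)
  m + log(acc / nrow(out))
}

#' Per-site log-likelihoods of an alignment on a fixed tree
#'
#' Felsenstein-pruning likelihood under a reversible model; missing
#' residues are marginalised (all-ones tip partials); with discrete-gamma
#' rates the site likelihood averages the category likelihoods with equal
#' weights.
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param tree a \code{phylo} with non-negative branch lengths whose tips
#'   are taxa of \code{x}.
#' @param model a \linkS4class{SubstitutionModel}.
#' @return numeric vector of per-site log-likelihoods (length
#'   \code{nSites(x)}).
#' @export
siteLogLik <- function(x, tree, model) {
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must carry non-negative branch lengths")
  cp <- compressPatterns(x, tree$tip.label)
  dp <- downPass(tree, cp$states, model)
  ll <- patternLogLik(dp, model)
  if (any(!is.finite(ll)))
    stop("numerical error: non-finite log-likelihood at site(s) ",
         paste(head(which(!is.finite(ll[cp$siteIndex])), 5L), collapse = ", "))
  ll[cp$siteIndex]
}

## above-edge partial F for edge index e (in dp$edge order), per category.
## F satisfies: logL = sum_pat w * logmeanexp_c log( colSums(F_c * P_c(t) D_c) )
## where D is the down partial of the edge's child.
aboveEdgePartial <- function(dp, model, e) {
  k <- dp$k; P <- dp$nPat
  edge <- dp$edge
  parentOf <- integer(max(edge))
  edgeTo <- integer(max(edge))
  parentOf[edge[, 2L]] <- edge[, 1L]
  edgeTo[edge[, 2L]] <- seq_len(nrow(edge))
  ## chain of nodes from root down to the parent of edge e
  p <- edge[e, 1L]
  chain <- p
  while (chain[1L] != dp$root) chain <- c(parentOf[chain[1L]], chain)
  res <- vector("list", length(dp$rates))
  for (ci in seq_along(dp$rates)) {
    A <- matrix(model@freqs, k, P)       # above-partial at the root
    sA <- numeric(P)
    for (ni in seq_along(chain)) {
      node <- chain[ni]
      excl <- if (ni < length(chain)) chain[ni + 1L] else edge[e, 2L]
      sibs <- which(edge[, 1L] == node & edge[, 2L] != excl)
      F <- A
      for (se in sibs) {
        v <- edge[se, 2L]
        dv <- if (v <= dp$nTip) dp$tipPart[[v]] else dp$down[[ci]][[v]]
        if (v > dp$nTip) sA <- sA + dp$scal[[ci]][[v]]
        F <- F * (dp$Pmats[[ci]][[se]] %*% dv)
      }
      cs <- colSums(F)
      F <- F / rep(cs, each = k); sA <- sA + log(cs)
      if (ni < length(chain)) {
        A <- crossprod(dp$Pmats[[ci]][[edgeTo[chain[ni + 1L]]]], F)
      } else {
        res[[ci]] <- list(F = F, scal = sA)
      }
      if (ni == length(chain)) break
    }
  }
  res
}

## After edge e's length changed, refresh its transition matrices and the
## down partials of every node from the edge's parent up to the root;
## partials below the edge are untouched.
refreshAfterEdgeChange <- function(dp, model, e, newLen) {
  dp$elen[e] <- newLen
  edge <- dp$edge
  k <- dp$k
  parentOf <- integer(max(edge))
  parentOf[edge[, 2L]] <- edge[, 1L]
  chain <- edge[e, 1L]
  while (chain[length(chain)] != dp$root)
    chain <- c(chain, parentOf[chain[length(chain)]])
  for (ci in seq_along(dp$rates)) {
    dp$Pmats[[ci]][[e]] <- transitionMatrix(model, newLen * dp$rates[ci])
    for (node in chain) {
      part <- NULL; sc <- numeric(dp$nPat)
      for (ce in which(edge[, 1L] == node)) {
        v <- edge[ce, 2L]
        dv <- if (v <= dp$nTip) dp$tipPart[[v]] else dp$down[[ci]][[v]]
        if (v > dp$nTip) sc <- sc + dp$scal[[ci]][[v]]
        contrib <- dp$Pmats[[ci]][[ce]] %*% dv
        part <- if (is.null(part)) contrib else part * contrib
      }
      cs <- .colSums(part, k, dp$nPat)
      dp$down[[ci]][[node]] <- part / rep(cs, each = k)
      dp$scal[[ci]][[node]] <- sc + log(cs)
    }
  }
  dp
}

## Project above/below partials of edge e into the model eigenbasis, so
## that the likelihood becomes a cheap function of the branch length:
##   colSums(F * P(t) D) = colSums((A'F) * (exp(lambda t) * (Ainv D))).
## Per-category log-scalers do not depend on the branch length, so they
## are folded into a single reference scaler + per-category factors here.
edgeProjection <- function(dp, model, e, above) {
  v <- dp$edge[e, 2L]
  eg <- model@eig
  proj <- lapply(seq_along(dp$rates), function(ci) {
    dv <- if (v <= dp$nTip) dp$tipPart[[v]] else dp$down[[ci]][[v]]
    sD <- if (v <= dp$nTip) numeric(dp$nPat) else dp$scal[[ci]][[v]]
    list(FD = crossprod(eg$A, above[[ci]]$F) * (eg$Ainv %*% dv),
         scal = above[[ci]]$scal + sD)
  })
  ref <- proj[[1L]]$scal
  for (ci in seq_along(proj)[-1L]) ref <- pmax(ref, proj[[ci]]$scal)
  for (ci in seq_along(proj))
    proj[[ci]]$expScal <- exp(proj[[ci]]$scal - ref)
  attr(proj, "ref") <- ref
  proj
}

## log-likelihood as a function of one branch length, via edgeProjection
edgeLogLik <- function(dp, model, proj, t, weights) {
  lam <- model@eig$values
  total <- 0
  for (ci in seq_along(dp$rates)) {
    pr <- proj[[ci]]
    lik <- as.vector(exp(lam * (t * dp$rates[ci])) %*% pr$FD)
    lik[lik < 0] <- 0
    total <- total + pr$expScal * lik
  }
  total[total < 1e-300] <- 1e-300
  sum(weights * (log(total / length(dp$rates)) + attr(proj, "ref")))
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise univariate optimisation: each branch in turn is
#' optimised by bounded scalar search (all other branches held fixed,
#' using cached conditional likelihoods on either side of the branch),
#' cycling until the total log-likelihood improves by less than
#' \code{tol}. The log-likelihood never decreases across cycles.
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param tree a \code{phylo}; existing branch lengths are used as the
#'   starting point, otherwise all branches start at \code{init}.
#' @param model a \linkS4class{SubstitutionModel}.
#' @param bounds branch-length search interval.
#' @param init initial branch length.
#' @param tol convergence tolerance on the log-likelihood.
#' @param maxCycles maximum optimisation sweeps; hitting it sets
#'   \code{converged = FALSE} (with a warning) but still returns the last
#'   iterate.
#' @return list with \code{tree} (lengths filled in), \code{logL},
#'   \code{siteLogLik} (per site), \code{converged}, \code{cycles}.
#' @export
optimizeBranchLengths <- function(x, tree, model, bounds = c(0, 10),
                                  init = 0.1, tol = 1e-6, maxCycles = 100L) {
  cp <- compressPatterns(x, tree$tip.label)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(init, nrow(tree$edge))
  tre <- ape::reorder.phylo(tree, "postorder")
  w <- cp$weights
  dp <- downPass(tre, cp$states, model)
  logL <- sum(w * patternLogLik(dp, model))
  converged <- FALSE
  cycles <- 0L
  for (cyc in seq_len(maxCycles)) {
    cycles <- cyc
    changed <- FALSE
    for (e in seq_len(nrow(dp$edge))) {
      above <- aboveEdgePartial(dp, model, e)
      proj <- edgeProjection(dp, model, e, above)
      f <- function(t) edgeLogLik(dp, model, proj, t, w)
      cur <- dp$elen[e]
      opt <- optimize(f, interval = bounds, maximum = TRUE, tol = 1e-5)
      if (opt$objective > f(cur) + 1e-10 &&
          abs(opt$maximum - cur) > 1e-8) {
        tre$edge.length[e] <- opt$maximum
        dp <- refreshAfterEdgeChange(dp, model, e, opt$maximum)
        changed <- TRUE
      }
    }
    newLogL <- sum(w * patternLogLik(dp, model))
    if (!changed || (abs(newLogL - logL) < tol && cyc > 1L)) {
      logL <- newLogL; converged <- TRUE; break
    }
    logL <- newLogL
  }
  if (!converged)
    warning("branch-length optimisation did not converge in ", maxCycles,
            " cycles")
  pll <- patternLogLik(dp, model)
  list(tree = tre, logL = logL, siteLogLik = pll[cp$siteIndex],
       converged = converged, cycles = cycles)
}

#' Site log-likelihood matrix over candidate trees
#'
#' Optimises branch lengths of every candidate topology on the same
#' alignment and stacks the per-site log-likelihoods into the input object
#' of the AU test. Identical site patterns are collapsed with weights.
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param trees named list of \code{phylo} objects (tips must be taxa of
#'   \code{x}; all trees on the same tip set).
#' @param model a \linkS4class{SubstitutionModel}.
#' @param optimize if \code{FALSE}, trees must already carry branch
#'   lengths which are used as-is.
#' @return a \linkS4class{SiteLogLikelihoodMatrix}.
#' @export
siteLogLikMatrix <- function(x, trees, model, optimize = TRUE) {
  if (is.null(names(trees)))
    names(trees) <- paste0("tree", seq_along(trees))
  cp <- compressPatterns(x, trees[[1L]]$tip.label)
  rows <- matrix(0, length(trees), length(cp$weights),
                 dimnames = list(names(trees), NULL))
  for (i in seq_along(trees)) {
    if (optimize) {
      fit <- optimizeBranchLengths(x, trees[[i]], model)
      dp <- downPass(fit$tree, cp$states, model)
    } else {
      dp <- downPass(trees[[i]], cp$states, model)
    }
    rows[i, ] <- patternLogLik(dp, model)
  }
  new("SiteLogLikelihoodMatrix", logl = rows, weights = cp$weights)
}

#' Write/read a site log-likelihood matrix as TSV
#'
#' The file holds one row per tree and one column per alignment site
#' (patterns are expanded), so it interoperates with external AU-test
#' implementations.
#'
#' @param slm a \linkS4class{SiteLogLikelihoodMatrix}.
#' @param path file path.
#' @return \code{path} (write) or a \linkS4class{SiteLogLikelihoodMatrix}
#'   (read).
#' @export
writeSlm <- function(slm, path) {
  expanded <- slm@logl[, rep(seq_along(slm@weights), slm@weights),
                       drop = FALSE]
  write.table(expanded, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeSlm
#' @export
readSlm <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, row.names = 1L)
  m <- as.matrix(df)
  colnames(m) <- NULL
  new("SiteLogLikelihoodMatrix", logl = m, weights = rep(1, ncol(m)))
}
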