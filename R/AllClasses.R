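#' @import methods
#' @importFrom stats optimize pchisq pnorm qnorm dnorm rgamma runif setNames
#'   lm coef
#' @importFrom utils read.table write.table combn head
NULL

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
NT_ALPHABET <- c("A","C","G","T")

residueAlphabet <- function(alphabet) {
  switch(alphabet, AA = AA_ALPHABET, NT = NT_ALPHABET,
         stop("unknown alphabet: ", alphabet))
}

#' Partition scheme of a supermatrix
#'
#' Ordered, contiguous, non-overlapping site ranges covering all columns of
#' a \linkS4class{ResidueMatrix}. Ranges are stored 1-based inclusive; the
#' same convention is used in RAxML-style partition files written by
#' \code{\link{writePartitions}}.
#'
#' @slot partName character vector of partition (gene) names.
#' @slot partStart,partEnd integer vectors, 1-based inclusive bounds.
#' @exportClass PartitionScheme
setClass("PartitionScheme",
         representation(partName = "character",
                        partStart = "integer",
                        partEnd = "integer"))

setValidity("PartitionScheme", function(object) {
  n <- length(object@partName)
  if (length(object@partStart) != n || length(object@partEnd) != n)
    return("partName, partStart, partEnd must have equal length")
  if (n == 0L) return(TRUE)
  if (anyDuplicated(object@partName)) return("duplicated partition names")
  if (any(object@partEnd < object@partStart)) return("empty partition range")
  if (object@partStart[1L] != 1L) return("first partition must start at 1")
  if (n > 1L && any(object@partStart[-1L] != object@partEnd[-n] + 1L))
    return("partitions must be contiguous and sorted")
  TRUE
})

#' Aligned residue matrix with missing-data mask
#'
#' The supermatrix container: a taxa x sites grid of amino-acid or
#' nucleotide residues, a logical mask marking missing/ambiguous cells
#' (gaps, \code{?}, \code{X}/\code{N} and rarer ambiguity codes), and a
#' \linkS4class{PartitionScheme} recording gene boundaries. Every cell is
#' either a core-alphabet residue or flagged missing; there is no third
#' state.
#'
#' @slot seqs character matrix (taxa in rows, upper-cased symbols).
#' @slot mask logical matrix, \code{TRUE} where the cell is missing.
#' @slot alphabet \code{"AA"} or \code{"NT"}.
#' @slot partitions a \linkS4class{PartitionScheme}.
#' @exportClass ResidueMatrix
setClass("ResidueMatrix",
         representation(seqs = "matrix",
                        mask = "matrix",
                        alphabet = "character",
                        partitions = "PartitionScheme"))

setValidity("ResidueMatrix", function(object) {
  if (!identical(dim(object@seqs), dim(object@mask)))
    return("seqs and mask dimensions differ")
  tx <- rownames(object@seqs)
  if (is.null(tx) || anyDuplicated(tx)) return("taxon labels must be unique")
  if (!object@alphabet %in% c("AA", "NT"))
    return("alphabet must be 'AA' or 'NT'")
  np <- length(object@partitions@partName)
  if (np > 0L && object@partitions@partEnd[np] != ncol(object@seqs))
    return("partitions do not cover all sites")
  ok <- object@mask | matrix(object@seqs %in% residueAlphabet(object@alphabet),
                             nrow(object@seqs))
  if (!all(ok)) return("unmasked cell holds a non-alphabet symbol")
  TRUE
})

#' Alignment completeness report
#'
#' AliStat-style coverage diagnostics: the overall completeness score Ca
#' (percent non-missing cells), per-taxon scores Cr, and the taxon-pairwise
#' fraction of sites covered in both sequences.
#'
#' @slot Ca numeric scalar, percent.
#' @slot Cr named numeric vector, percent per taxon.
#' @slot pairwiseShared symmetric numeric matrix of shared-coverage
#'   fractions with unit diagonal.
#' @exportClass CoverageReport
setClass("CoverageReport",
         representation(Ca = "numeric", Cr = "numeric",
                        pairwiseShared = "matrix"))

#' Unrooted quartet topology on four group labels
#'
#' One of the three ways of pairing four labels into two cherries,
#' e.g. \{Chilopoda,Diplopoda\} | \{Pauropoda,Symphyla\}. Stored in
#' canonical form (labels sorted within pairs, pairs sorted by first
#' label) so equal topologies compare identical.
#'
#' @slot pair1,pair2 character(2), the two cherries.
#' @exportClass QuartetTopology
setClass("QuartetTopology",
         representation(pair1 = "character", pair2 = "character"))

setValidity("QuartetTopology", function(object) {
  labs <- c(object@pair1, object@pair2)
  if (length(labs) != 4L || anyDuplicated(labs))
    return("a quartet topology needs 4 distinct labels")
  if (is.unsorted(object@pair1) || is.unsorted(object@pair2))
    return("pairs must be internally sorted")
  if (object@pair1[1L] > object@pair2[1L])
    return("pairs must be sorted by first label")
  TRUE
})

#' Reversible substitution model with optional discrete-gamma rates
#'
#' Exchangeabilities are symmetric; the rate matrix is rescaled to one
#' expected substitution per unit branch length at the supplied equilibrium
#' frequencies. \code{nCat = 0} disables among-site rate variation;
#' otherwise \code{nCat} equal-probability discrete-gamma categories with
#' mean rate 1 are used.
#'
#' @slot alphabet \code{"AA"} or \code{"NT"}.
#' @slot name model name (\code{"Poisson"}, \code{"JC"}, \code{"GTR"}, or a
#'   user matrix tag).
#' @slot exch symmetric exchangeability matrix (zero diagonal).
#' @slot freqs equilibrium frequencies, positive, summing to 1.
#' @slot gammaShape shape of the gamma rate distribution (ignored when
#'   \code{nCat == 0}).
#' @slot nCat integer number of discrete rate categories (0 = off).
#' @slot eig cached eigen-decomposition used to exponentiate the rate
#'   matrix (internal).
#' @exportClass SubstitutionModel
setClass("SubstitutionModel",
         representation(alphabet = "character", name = "character",
                        exch = "matrix", freqs = "numeric",
                        gammaShape = "numeric", nCat = "integer",
                        eig = "list"))

setValidity("SubstitutionModel", function(object) {
  k <- length(residueAlphabet(object@alphabet))
  if (!identical(dim(object@exch), c(k, k)))
    return("exchangeability matrix has wrong dimension")
  if (max(abs(object@exch - t(object@exch))) > 1e-12)
    return("exchangeability matrix must be symmetric")
  if (length(object@freqs) != k || any(object@freqs <= 0) ||
      abs(sum(object@freqs) - 1) > 1e-8)
    return("freqs must be positive and sum to 1")
  if (object@nCat < 0L) return("nCat must be >= 0")
  if (object@nCat > 0L && object@gammaShape <= 0)
    return("gammaShape must be positive when rate categories are enabled")
  TRUE
})

#' Per-tree, per-site log-likelihood matrix
#'
#' Substrate of the AU test: one row per candidate tree, one column per
#' site pattern, with pattern weights so that the weighted row sums equal
#' each tree's total log-likelihood.
#'
#' @slot logl numeric matrix, trees x patterns, rownames = tree labels.
#' @slot weights numeric pattern weights (1 for uncompressed sites).
#' @exportClass SiteLogLikelihoodMatrix
setClass("SiteLogLikelihoodMatrix",
         representation(logl = "matrix", weights = "numeric"))

setValidity("SiteLogLikelihoodMatrix", function(object) {
  if (ncol(object@logl) != length(object@weights))
    return("weights length must equal number of site columns")
  if (any(!is.finite(object@logl))) return("log-likelihoods must be finite")
  if (any(object@weights <= 0)) return("weights must be positive")
  if (is.null(rownames(object@logl))) return("tree labels required")
  TRUE
})

#' Aggregate FcLM simplex report
#'
#' Counts and percentages of drawn quartets falling into the seven Voronoi
#' regions of the topology simplex: cells 1-3 are the corners (resolved
#' support for T1, T2, T3), cells 4-6 the edge regions (pairwise
#' ambiguity), cell 7 the star-like centre.
#'
#' @slot counts integer(7), quartets per cell.
#' @slot nDrawn number of quartets evaluated.
#' @slot nSkipped quartets skipped for lack of jointly covered sites.
#' @slot groups the four cluster labels in drawing order (c1..c4); the
#'   corner convention is T1 = (c1,c2)|(c3,c4), T2 = (c1,c3)|(c2,c4),
#'   T3 = (c1,c4)|(c2,c3).
#' @exportClass SimplexReport
setClass("SimplexReport",
         representation(counts = "integer", nDrawn = "integer",
                        nSkipped = "integer", groups = "character"))

setValidity("SimplexReport", function(object) {
  if (length(object@counts) != 7L) return("need 7 cell counts")
  if (sum(object@counts) != object@nDrawn)
    return("cell counts must sum to the number of drawn quartets")
  if (length(object@groups) != 4L) return("need 4 cluster labels")
  TRUE
})

#' Configuration of the non-stationary alignment simulator
#'
#' @slot tree guide tree (ape \code{phylo}) with branch lengths.
#' @slot model a \linkS4class{SubstitutionModel}; its frequencies are the
#'   root/ancestral composition.
#' @slot nSites total alignment length (ignored when partitionLengths is
#'   given).
#' @slot partitionLengths optional integer vector of per-gene lengths.
#' @slot shifts named list: element names are tip or node labels; each
#'   value is a replacement frequency vector applied from the branch
#'   leading to that node tipward (non-stationarity generator).
#' @slot missingProb per-cell missingness probability (scalar or named per
#'   taxon).
#' @slot dropoutProb probability that a whole taxon x partition block is
#'   dropped (non-random, transcriptome-like missingness).
#' @slot seed integer RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(tree = "ANY", model = "SubstitutionModel",
                        nSites = "integer", partitionLengths = "integer",
                        shifts = "list", missingProb = "numeric",
                        dropoutProb = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  if (is.null(object@tree$edge.length)) return("guide tree needs branch lengths")
  n <- if (length(object@partitionLengths)) sum(object@partitionLengths)
       else object@nSites
  if (n < 1L) return("need at least one site")
  if (any(object@missingProb < 0 | object@missingProb > 1) ||
      any(object@dropoutProb < 0 | object@dropoutProb > 1))
    return("probabilities must lie in [0,1]")
  for (f in object@shifts) {
    if (length(f) != length(object@model@freqs) || any(f <= 0) ||
        abs(sum(f) - 1) > 1e-8)
      return("each shift must be a positive frequency vector summing to 1")
  }
  TRUE
})
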