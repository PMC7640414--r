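#' @name accessors
#' @title Accessors for quartetSignal objects
#' @param x an object.
#' @param ... unused.
#' @description Small accessor generics used across the package instead of
#'   direct slot access.
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(x, ...) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("nSites", function(x, ...) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("nTaxa", function(x, ...) standardGeneric("nTaxa"))
#' @rdname accessors
#' @export
setGeneric("partitionScheme", function(x, ...) standardGeneric("partitionScheme"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x, ...) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x, ...) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("seqAlphabet", function(x, ...) standardGeneric("seqAlphabet"))
#' @rdname accessors
#' @export
setGeneric("cellCounts", function(x, ...) standardGeneric("cellCounts"))
#' @rdname accessors
#' @export
setGeneric("cellPercentages", function(x, ...) standardGeneric("cellPercentages"))

#' @rdname accessors
#' @export
setMethod("taxa", "ResidueMatrix", function(x, ...) rownames(x@seqs))
#' @rdname accessors
#' @export
setMethod("nSites", "ResidueMatrix", function(x, ...) ncol(x@seqs))
#' @rdname accessors
#' @export
setMethod("nTaxa", "ResidueMatrix", function(x, ...) nrow(x@seqs))
#' @rdname accessors
#' @export
setMethod("partitionScheme", "ResidueMatrix", function(x, ...) x@partitions)
#' @rdname accessors
#' @export
setMethod("residues", "ResidueMatrix", function(x, ...) x@seqs)
#' @rdname accessors
#' @export
setMethod("missingMask", "ResidueMatrix", function(x, ...) x@mask)
#' @rdname accessors
#' @export
setMethod("seqAlphabet", "ResidueMatrix", function(x, ...) x@alphabet)

#' @rdname accessors
#' @export
setMethod("nSites", "PartitionScheme", function(x, ...) {
  n <- length(x@partEnd)
  if (n == 0L) 0L else x@partEnd[n]
})

setMethod("show", "PartitionScheme", function(object) {
  cat("PartitionScheme with", length(object@partName), "partitions,",
      nSites(object), "sites\n")
  if (length(object@partName)) {
    df <- as.data.frame(object)
    print(head(df, 6L))
    if (nrow(df) > 6L) cat("  ...", nrow(df) - 6L, "more\n")
  }
})

#' @export
#' @method as.data.frame PartitionScheme
as.data.frame.PartitionScheme <- function(x, ...) {
  data.frame(name = x@partName, start = x@partStart, end = x@partEnd,
             stringsAsFactors = FALSE)
}

setMethod("show", "ResidueMatrix", function(object) {
  cat("ResidueMatrix:", nTaxa(object), "taxa x", nSites(object),
      sprintf("sites (%s), %d partitions, %.1f%% missing\n",
              object@alphabet, length(object@partitions@partName),
              100 * mean(object@mask)))
})

setMethod("show", "CoverageReport", function(object) {
  cat(sprintf("CoverageReport: Ca = %.2f%%, Cr in [%.2f%%, %.2f%%] over %d taxa\n",
              object@Ca, min(object@Cr), max(object@Cr), length(object@Cr)))
})

setMethod("show", "QuartetTopology", function(object) {
  cat("QuartetTopology:", topologyKey(object), "\n")
})

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf("SubstitutionModel %s (%s), %s\n", object@name, object@alphabet,
              if (object@nCat > 0L)
                sprintf("gamma(alpha=%.3g) x %d categories", object@gammaShape,
                        object@nCat)
              else "uniform rates"))
})

setMethod("show", "SiteLogLikelihoodMatrix", function(object) {
  cat("SiteLogLikelihoodMatrix:", nrow(object@logl), "trees x",
      ncol(object@logl), "patterns (",
      round(sum(object@weights)), "sites )\n")
})

#' @rdname accessors
#' @export
setMethod("cellCounts", "SimplexReport", function(x, ...)
  setNames(x@counts, simplexCellNames(x@groups)))

#' @rdname accessors
#' @export
setMethod("cellPercentages", "SimplexReport", function(x, ...) {
  p <- if (x@nDrawn > 0L) 100 * x@counts / x@nDrawn else rep(NA_real_, 7L)
  setNames(p, simplexCellNames(x@groups))
})

setMethod("show", "SimplexReport", function(object) {
  cat("FcLM SimplexReport on clusters", paste(object@groups, collapse = ", "),
      "\n ", object@nDrawn, "quartets evaluated,", object@nSkipped,
      "skipped\n")
  print(round(cellPercentages(object), 2L))
})

setMethod("show", "SimulationConfig", function(object) {
  np <- length(object@partitionLengths)
  cat("SimulationConfig:", length(object@tree$tip.label), "taxa,",
      if (np) sum(object@partitionLengths) else object@nSites, "sites,",
      if (np) np else 1L, "partitions,",
      length(object@shifts), "composition shifts, seed", object@seed, "\n")
})
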