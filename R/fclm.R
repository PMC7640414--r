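## Four-cluster Likelihood-Mapping: draw one-taxon-per-group quartets,
## compute ML support weights for the three quartet topologies, map each
## quartet onto the 2-simplex and classify it into one of seven Voronoi
## regions (3 corners = resolved topologies, 3 edge regions = pairwise
## ambiguity, centre = star-like signal).

## run expr with a local, restored RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

simplexCellNames <- function(groups) {
  g <- groups
  c(sprintf("T1 (%s,%s)|(%s,%s)", g[1], g[2], g[3], g[4]),
    sprintf("T2 (%s,%s)|(%s,%s)", g[1], g[3], g[2], g[4]),
    sprintf("T3 (%s,%s)|(%s,%s)", g[1], g[4], g[2], g[3]),
    "T1-T2", "T2-T3", "T1-T3", "center")
}

#' Draw one-taxon-per-group quartets
#'
#' Exhaustive Cartesian product over the four clusters when its size does
#' not exceed \code{cap}; otherwise a seeded uniform subsample without
#' replacement of size \code{cap}. Order is deterministic either way.
#'
#' @param groupMap named character vector taxon -> group.
#' @param groups the four cluster labels, in the order fixing the
#'   T1/T2/T3 pairing convention.
#' @param cap maximum number of quartets.
#' @param seed RNG seed used only when subsampling.
#' @return character matrix with one row per quartet, columns named by
#'   the clusters.
#' @export
drawQuartets <- function(groupMap, groups, cap = Inf, seed = 1L) {
  if (length(groups) != 4L) stop("input error: need exactly 4 groups")
  members <- lapply(groups, function(g) names(groupMap)[groupMap == g])
  if (any(lengths(members) == 0L))
    stop("input error: empty group(s): ",
         paste(groups[lengths(members) == 0L], collapse = ", "))
  total <- prod(lengths(members))
  grid <- as.matrix(expand.grid(members, stringsAsFactors = FALSE,
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- groups
  if (total > cap) {
    keep <- withSeed(seed, sort(sample.int(total, cap)))
    grid <- grid[keep, , drop = FALSE]
  }
  rownames(grid) <- NULL
  grid
}

#' ML topology weights of a single quartet
#'
#' Optimises branch lengths on each of the three quartet topologies
#' (taxa in cluster order t1..t4: T1 = (t1,t2)|(t3,t4),
#' T2 = (t1,t3)|(t2,t4), T3 = (t1,t4)|(t2,t3)) and converts the three
#' maximised log-likelihoods into normalised weights by
#' log-sum-exp: \eqn{p_i = \exp(l_i - l_{max}) / \sum_j \exp(l_j - l_{max})}.
#'
#' @param quartet character(4): one taxon per cluster, in cluster order.
#' @param x a \linkS4class{ResidueMatrix}.
#' @param model a \linkS4class{SubstitutionModel}.
#' @return list with \code{logL} (numeric(3)) and \code{weights}
#'   (numeric(3), summing to 1), or \code{NULL} when no site is jointly
#'   covered across the four taxa (the quartet is skipped).
#' @export
quartetWeights <- function(quartet, x, model) {
  joint <- colSums(x@mask[quartet, , drop = FALSE]) == 0L
  if (!any(joint)) return(NULL)
  nwk <- c(sprintf("((%s,%s),(%s,%s));", quartet[1], quartet[2], quartet[3], quartet[4]),
           sprintf("((%s,%s),(%s,%s));", quartet[1], quartet[3], quartet[2], quartet[4]),
           sprintf("((%s,%s),(%s,%s));", quartet[1], quartet[4], quartet[2], quartet[3]))
  logL <- vapply(nwk, function(s) {
    tr <- ape::read.tree(text = s)
    optimizeBranchLengths(x, tr, model)$logL
  }, 0)
  names(logL) <- c("T1", "T2", "T3")
  w <- exp(logL - max(logL))
  list(logL = logL, weights = w / sum(w))
}

## the 7 Voronoi generator points in barycentric coordinates:
## corners, edge midpoints (T1-T2, T2-T3, T1-T3), centroid
simplexGenerators <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(.5, .5, 0), c(0, .5, .5), c(.5, 0, .5),
        c(1, 1, 1) / 3)
}

#' Classify a weight triple into one of the seven simplex regions
#'
#' Nearest-generator (Voronoi) classification in barycentric coordinates
#' under Euclidean distance; generators are the three corners (cells
#' 1-3 supporting T1, T2, T3), the three edge midpoints (cell 4 =
#' T1/T2 ambiguity, cell 5 = T2/T3, cell 6 = T1/T3) and the centroid
#' (cell 7, uninformative). Ties break toward the lowest cell index.
#'
#' @param weights numeric(3), non-negative, summing to 1.
#' @return integer cell index in 1..7.
#' @export
assignCell <- function(weights) {
  if (length(weights) != 3L || any(weights < -1e-9) ||
      abs(sum(weights) - 1) > 1e-6)
    stop("weights must be a barycentric triple")
  d2 <- rowSums(sweep(simplexGenerators(), 2L, weights)^2)
  which.min(round(d2, 12L))   # round so exact ties hit the lowest index
}

defaultModelFor <- function(x) {
  if (seqAlphabet(x) == "AA")
    substitutionModel("Poisson", "AA", freqs = empiricalFreqs(x),
                      gammaShape = 1, nCat = 4L)
  else
    substitutionModel("GTR", "NT", freqs = empiricalFreqs(x),
                      gammaShape = 1, nCat = 4L)
}

#' Four-cluster Likelihood-Mapping report
#'
#' Draws quartets (one taxon per cluster), computes ML topology weights
#' for each, classifies them into the seven simplex regions and
#' aggregates counts and percentages. Quartets without jointly covered
#' sites are skipped and reported.
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param groupMap named character vector taxon -> group.
#' @param groups the four cluster labels in drawing order.
#' @param model a \linkS4class{SubstitutionModel}; default Poisson+G4
#'   (amino acid) or GTR+G4 (nucleotide) with empirical frequencies.
#' @param cap maximum number of quartets (seeded subsample beyond it).
#' @param seed RNG seed for subsampling.
#' @param details if \code{TRUE}, also return the per-quartet weights.
#' @return a \linkS4class{SimplexReport}; with \code{details = TRUE} a
#'   list with elements \code{report} and \code{quartets} (data.frame of
#'   taxa, weights, cell).
#' @export
fclmReport <- function(x, groupMap, groups, model = NULL, cap = Inf,
                       seed = 1L, details = FALSE) {
  if (is.null(model)) model <- defaultModelFor(x)
  groupMap <- groupMap[names(groupMap) %in% taxa(x)]
  qs <- drawQuartets(groupMap, groups, cap = cap, seed = seed)
  counts <- integer(7L)
  nSkip <- 0L
  rows <- vector("list", nrow(qs))
  for (i in seq_len(nrow(qs))) {
    qw <- quartetWeights(qs[i, ], x, model)
    if (is.null(qw)) { nSkip <- nSkip + 1L; next }
    cell <- assignCell(qw$weights)
    counts[cell] <- counts[cell] + 1L
    if (details)
      rows[[i]] <- data.frame(t(qs[i, ]), p1 = qw$weights[1L],
                              p2 = qw$weights[2L], p3 = qw$weights[3L],
                              cell = cell, stringsAsFactors = FALSE)
  }
  if (sum(counts) == 0L)
    stop("empty report: all ", nrow(qs), " quartets were skipped")
  report <- new("SimplexReport", counts = counts,
                nDrawn = sum(counts), nSkipped = nSkip,
                groups = as.character(groups))
  if (!details) return(report)
  list(report = report, quartets = do.call(rbind, rows))
}

#' Write an FcLM report as TSV or JSON
#'
#' @param report a \linkS4class{SimplexReport}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeSimplexReport <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- data.frame(cell = 1:7, region = simplexCellNames(report@groups),
                   count = report@counts,
                   percent = round(100 * report@counts /
                                     max(report@nDrawn, 1L), 4L))
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#clusters\t%s", paste(report@groups, collapse = ",")), con)
    writeLines(sprintf("#quartets\t%d\t#skipped\t%d", report@nDrawn,
                       report@nSkipped), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(clusters = report@groups,
                              nQuartets = report@nDrawn,
                              nSkipped = report@nSkipped, cells = df),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Scatter quartet weights on the 2-simplex
#'
#' @param quartets data.frame with columns \code{p1}, \code{p2},
#'   \code{p3} (e.g. from \code{fclmReport(..., details = TRUE)}).
#' @param main plot title.
#' @return invisibly, the 2D coordinates.
#' @export
plotSimplex <- function(quartets, main = "Four-cluster likelihood mapping") {
  corners <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  xy <- as.matrix(quartets[, c("p1", "p2", "p3")]) %*% corners
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.05, 0.95), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::polygon(corners[c(1, 2, 3), 1], corners[c(1, 2, 3), 2])
  graphics::points(xy[, 1], xy[, 2], pch = 16, cex = 0.6)
  graphics::text(rbind(c(-0.03, -0.03), c(1.03, -0.03), c(0.5, 0.9)),
                 labels = c("T1", "T2", "T3"))
  invisible(xy)
}
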