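## Quartet/rooting enumeration and tree classification. For four labels
## there are exactly three unrooted quartet topologies; each admits five
## rooted derivatives (one per edge carrying the root), fifteen rooted
## trees in total. Trees within one topology differ only in character
## polarisation; trees across topologies are genuinely incongruent.

#' Construct a quartet topology
#'
#' @param pair1,pair2 character(2) vectors: the two cherries. Stored in
#'   canonical order, so construction order does not matter.
#' @return a \linkS4class{QuartetTopology}.
#' @export
quartetTopology <- function(pair1, pair2) {
  pair1 <- sort(as.character(pair1)); pair2 <- sort(as.character(pair2))
  if (pair1[1L] > pair2[1L]) { tmp <- pair1; pair1 <- pair2; pair2 <- tmp }
  new("QuartetTopology", pair1 = pair1, pair2 = pair2)
}

#' Canonical string key of a quartet topology
#' @param topology a \linkS4class{QuartetTopology}.
#' @return character scalar such as \code{"Chil,Dipl|Paur,Sym"}.
#' @export
topologyKey <- function(topology) {
  paste(paste(topology@pair1, collapse = ","),
        paste(topology@pair2, collapse = ","), sep = "|")
}

#' Enumerate the three quartet topologies on four labels
#'
#' With labels in order (c1, c2, c3, c4) the list is returned in the fixed
#' pairing convention T1 = (c1,c2)|(c3,c4), T2 = (c1,c3)|(c2,c4),
#' T3 = (c1,c4)|(c2,c3). As a set the result is invariant under label
#' permutation.
#'
#' @param labels exactly four distinct labels.
#' @return named list of three \linkS4class{QuartetTopology} objects
#'   (\code{T1}, \code{T2}, \code{T3}).
#' @export
quartetTopologies <- function(labels) {
  if (length(labels) != 4L || anyDuplicated(labels))
    stop("input error: need exactly 4 distinct labels")
  list(T1 = quartetTopology(labels[c(1L, 2L)], labels[c(3L, 4L)]),
       T2 = quartetTopology(labels[c(1L, 3L)], labels[c(2L, 4L)]),
       T3 = quartetTopology(labels[c(1L, 4L)], labels[c(2L, 3L)]))
}

#' Five rooted derivatives of a quartet topology
#'
#' Places the root on each of the five edges of the unrooted quartet (the
#' four terminal edges and the internal edge), yielding five distinct
#' rooted binary trees whose unrooting recovers the parent topology.
#'
#' @param topology a \linkS4class{QuartetTopology}.
#' @return named list of five rooted \code{phylo} objects; names record
#'   the rooting edge.
#' @export
rootedDerivatives <- function(topology) {
  a <- topology@pair1[1L]; b <- topology@pair1[2L]
  c_ <- topology@pair2[1L]; d <- topology@pair2[2L]
  nwk <- c(internal = sprintf("((%s,%s),(%s,%s));", a, b, c_, d),
           sprintf("(%s,(%s,(%s,%s)));", a, b, c_, d),
           sprintf("(%s,(%s,(%s,%s)));", b, a, c_, d),
           sprintf("(%s,(%s,(%s,%s)));", c_, d, a, b),
           sprintf("(%s,(%s,(%s,%s)));", d, c_, a, b))
  names(nwk) <- c("internal", a, b, c_, d)
  lapply(nwk, function(s) ape::read.tree(text = s))
}

## induced topology of a 4-tip tree (rooted or not)
classifyQuartetPhylo <- function(tree) {
  tr <- ape::unroot(tree)
  tipParents <- tr$edge[match(seq_len(4L), tr$edge[, 2L]), 1L]
  pairIdx <- split(seq_len(4L), tipParents)
  pairIdx <- pairIdx[lengths(pairIdx) == 2L]
  if (length(pairIdx) < 1L) stop("degenerate quartet tree")
  p1 <- tr$tip.label[pairIdx[[1L]]]
  p2 <- setdiff(tr$tip.label, p1)
  quartetTopology(p1, p2)
}

#' Classify a tree to its underlying quartet topology of four groups
#'
#' Restricts the tree to the taxa of the four groups, verifies that each
#' group is cohesive (forms a split of the restricted unrooted tree), and
#' returns the induced quartet topology. Rooting of the input never
#' affects the result.
#'
#' @param tree a \code{phylo}.
#' @param groupMap named character vector taxon -> group covering exactly
#'   four groups; taxa outside the map are pruned first.
#' @return a \linkS4class{QuartetTopology} on the four group labels.
#' @export
classifyTree <- function(tree, groupMap) {
  groupMap <- groupMap[names(groupMap) %in% tree$tip.label]
  groups <- unique(unname(groupMap))
  if (length(groups) != 4L)
    stop("input error: need taxa of exactly 4 groups on the tree, got ",
         length(groups))
  tr <- ape::keep.tip(tree, names(groupMap))
  tr <- ape::unroot(tr)
  sides <- lapply(ape::prop.part(tr), function(i) tr$tip.label[i])
  for (g in groups) {
    members <- names(groupMap)[groupMap == g]
    if (length(members) <= 1L) next
    ok <- any(vapply(sides, function(s)
      setequal(s, members) || setequal(s, setdiff(tr$tip.label, members)),
      logical(1L)))
    if (!ok)
      stop("classification error: group ", g,
           " is not cohesive on the restricted tree")
  }
  reps <- vapply(groups, function(g) names(groupMap)[groupMap == g][1L], "")
  q <- ape::keep.tip(tr, unname(reps))
  topo <- classifyQuartetPhylo(q)
  toGroup <- setNames(groups, reps)
  quartetTopology(unname(toGroup[topo@pair1]), unname(toGroup[topo@pair2]))
}

#' Number of one-taxon-per-group quartets
#'
#' @param groupMap named character vector taxon -> group.
#' @param groups four group labels.
#' @return the product of the group sizes.
#' @export
countQuartets <- function(groupMap, groups) {
  sizes <- vapply(groups, function(g) sum(groupMap == g), 0L)
  if (any(sizes == 0L))
    stop("input error: empty group(s): ",
         paste(groups[sizes == 0L], collapse = ", "))
  prod(sizes)
}

## canonical nontrivial splits of one tree: each split encoded as the
## lexicographically smaller side, labels sorted and comma-joined
canonicalSplits <- function(tree) {
  tr <- ape::unroot(tree)
  n <- length(tr$tip.label)
  parts <- ape::prop.part(tr)
  keys <- character(0)
  for (p in parts) {
    if (length(p) <= 1L || length(p) >= n - 1L) next
    side <- sort(tr$tip.label[p])
    comp <- sort(setdiff(tr$tip.label, side))
    k1 <- paste(side, collapse = ",")
    k2 <- paste(comp, collapse = ",")
    keys <- c(keys, if (k1 < k2) k1 else k2)
  }
  unique(keys)
}

#' Split agreement profile across trees
#'
#' Collects every nontrivial bipartition occurring in a collection of
#' trees on the same taxon set and counts in how many trees each occurs —
#' the substrate for "k out of m splits agree across all topologies"
#' summaries.
#'
#' @param trees list of \code{phylo} objects on identical taxon sets.
#' @return list with \code{profile} (data.frame of canonical split and
#'   count), \code{nTrees}, \code{nDistinct} (distinct splits seen), and
#'   \code{nSharedByAll} (splits present in every tree).
#' @export
splitAgreement <- function(trees) {
  if (length(trees) < 2L) stop("input error: need at least two trees")
  tipSets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(tipSets[-1L], identical, logical(1L), tipSets[[1L]])))
    stop("input error: trees are on different taxon sets")
  keys <- unlist(lapply(trees, canonicalSplits))
  tab <- table(keys)
  profile <- data.frame(split = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  profile <- profile[order(-profile$count, profile$split), ]
  rownames(profile) <- NULL
  list(profile = profile, nTrees = length(trees),
       nDistinct = nrow(profile),
       nSharedByAll = sum(profile$count == length(trees)))
}

#' Write a split profile as TSV
#' @param agreement result of \code{\link{splitAgreement}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSplitProfile <- function(agreement, path) {
  write.table(agreement$profile, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
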