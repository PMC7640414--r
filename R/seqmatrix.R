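## Supermatrix construction, coverage filtering and completeness
## diagnostics. Coverage semantics: a taxon is "represented" in a
## partition when it has at least one non-missing residue there.

newPartitionScheme <- function(names, lengths) {
  lengths <- as.integer(lengths)
  ends <- cumsum(lengths)
  new("PartitionScheme", partName = as.character(names),
      partStart = as.integer(c(1L, head(ends, -1L) + 1L))[seq_along(lengths)],
      partEnd = ends)
}

partitionLengthsOf <- function(scheme) scheme@partEnd - scheme@partStart + 1L

#' Construct a ResidueMatrix
#'
#' @param seqs a character matrix (taxa in rows) or a named character
#'   vector of equal-length aligned sequence strings.
#' @param alphabet \code{"AA"} or \code{"NT"}.
#' @param partitions a \linkS4class{PartitionScheme}, or \code{NULL} for a
#'   single partition spanning the alignment.
#' @param partitionName name of the single default partition.
#' @return a \linkS4class{ResidueMatrix}; symbols are upper-cased and any
#'   symbol outside the core alphabet (gaps, \code{?}, \code{X}/\code{N},
#'   ambiguity codes) is flagged missing.
#' @export
residueMatrix <- function(seqs, alphabet = c("AA", "NT"), partitions = NULL,
                          partitionName = "p1") {
  alphabet <- match.arg(alphabet)
  if (!is.matrix(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("alignment error: sequences have unequal lengths")
    m <- matrix("", length(seqs), lens[1L], dimnames = list(names(seqs), NULL))
    for (i in seq_along(seqs))
      m[i, ] <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    seqs <- m
  }
  if (anyDuplicated(rownames(seqs)))
    stop("input error: duplicate taxon labels")
  seqs[] <- toupper(seqs)
  mask <- matrix(!(seqs %in% residueAlphabet(alphabet)), nrow(seqs),
                 dimnames = dimnames(seqs))
  if (is.null(partitions))
    partitions <- newPartitionScheme(partitionName, ncol(seqs))
  new("ResidueMatrix", seqs = seqs, mask = mask, alphabet = alphabet,
      partitions = partitions)
}

#' Read an aligned FASTA file into a ResidueMatrix
#'
#' @param path FASTA file of aligned sequences (equal lengths).
#' @param alphabet \code{"AA"} or \code{"NT"}.
#' @param partitions optional \linkS4class{PartitionScheme}.
#' @return a \linkS4class{ResidueMatrix}. Header lines are truncated at the
#'   first whitespace.
#' @export
readFasta <- function(path, alphabet = c("AA", "NT"), partitions = NULL) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("input error: no sequences in ", path)
  if (length(unique(Biostrings::width(ss))) > 1L)
    stop("alignment error: sequences have unequal lengths")
  v <- as.character(ss)
  names(v) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(v))) stop("input error: duplicate taxon labels")
  residueMatrix(v, alphabet, partitions)
}

#' Write a ResidueMatrix as FASTA
#'
#' Canonical form: one header token per taxon, upper-case symbols wrapped
#' at \code{width} columns; reading such a file back and re-writing it is
#' byte-identical.
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param path output file.
#' @param width line width.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nTaxa(x))) {
    s <- paste(x@seqs[i, ], collapse = "")
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", taxa(x)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Concatenate per-gene alignments into a partitioned supermatrix
#'
#' The taxon set of the result is the union of the inputs' taxa (order of
#' first appearance); blocks for taxa absent from a gene are filled as
#' missing, and the partition scheme records the gene boundaries in input
#' order.
#'
#' @param mats list of \linkS4class{ResidueMatrix} objects (names, if any,
#'   name the partitions).
#' @return a \linkS4class{ResidueMatrix}.
#' @export
concatenateMatrices <- function(mats) {
  if (length(mats) == 0L) stop("input error: no matrices to concatenate")
  alph <- unique(vapply(mats, seqAlphabet, ""))
  if (length(alph) > 1L) stop("input error: mixed alphabets")
  allTaxa <- unique(unlist(lapply(mats, taxa)))
  fillSym <- "-"
  pnames <- character(0); plens <- integer(0)
  blocks <- vector("list", length(mats))
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    sch <- partitionScheme(m)
    nm <- if (!is.null(names(mats)) && nzchar(names(mats)[k])) {
      if (length(sch@partName) > 1L) paste(names(mats)[k], sch@partName, sep = ".")
      else names(mats)[k]
    } else sch@partName
    pnames <- c(pnames, nm)
    plens <- c(plens, partitionLengthsOf(sch))
    blk <- matrix(fillSym, length(allTaxa), nSites(m),
                  dimnames = list(allTaxa, NULL))
    blk[taxa(m), ] <- residues(m)
    blocks[[k]] <- blk
  }
  seqs <- do.call(cbind, blocks)
  residueMatrix(seqs, alph, newPartitionScheme(make.unique(pnames), plens))
}

## subset a matrix to a set of partitions (re-indexed, order preserved)
keepPartitions <- function(x, idx) {
  sch <- partitionScheme(x)
  idx <- sort(idx)
  cols <- unlist(lapply(idx, function(i) sch@partStart[i]:sch@partEnd[i]),
                 use.names = FALSE)
  if (length(idx) == 0L) cols <- integer(0)
  newSch <- newPartitionScheme(sch@partName[idx], partitionLengthsOf(sch)[idx])
  if (length(idx) == 0L)
    newSch <- new("PartitionScheme", partName = character(0),
                  partStart = integer(0), partEnd = integer(0))
  new("ResidueMatrix", seqs = x@seqs[, cols, drop = FALSE],
      mask = x@mask[, cols, drop = FALSE], alphabet = x@alphabet,
      partitions = newSch)
}

## taxon x partition matrix: TRUE when the taxon has >=1 non-missing
## residue in the partition
representationTable <- function(x) {
  sch <- partitionScheme(x)
  vapply(seq_along(sch@partName), function(i) {
    rowSums(!x@mask[, sch@partStart[i]:sch@partEnd[i], drop = FALSE]) > 0L
  }, logical(nTaxa(x)))
}

#' Strict coverage filter: keep only fully represented partitions
#'
#' Retains exactly those partitions in which every taxon of the matrix has
#' at least one non-missing residue (the 100\%-coverage supermatrix
#' compilation rule).
#'
#' @param x a partitioned \linkS4class{ResidueMatrix}.
#' @return the filtered \linkS4class{ResidueMatrix} (possibly with zero
#'   partitions).
#' @export
filterStrict <- function(x) {
  rep <- representationTable(x)
  keepPartitions(x, which(colSums(rep) == nTaxa(x)))
}

#' Relaxed coverage filter: keep partitions covering every required group
#'
#' Retains partitions in which, for each required group, at least one
#' member taxon has at least one non-missing residue.
#'
#' @param x a partitioned \linkS4class{ResidueMatrix}.
#' @param groupMap named character vector mapping taxon to group.
#' @param requiredGroups character vector of group labels that must each be
#'   represented; empty means no constraint.
#' @return the filtered \linkS4class{ResidueMatrix}.
#' @export
filterRelaxed <- function(x, groupMap, requiredGroups) {
  if (length(requiredGroups) == 0L) return(x)
  missingGrp <- setdiff(requiredGroups, unique(groupMap))
  if (length(missingGrp))
    stop("configuration error: group(s) absent from group map: ",
         paste(missingGrp, collapse = ", "))
  rep <- representationTable(x)
  ok <- rep(TRUE, ncol(rep))
  for (g in requiredGroups) {
    members <- intersect(names(groupMap)[groupMap == g], taxa(x))
    if (length(members) == 0L)
      stop("configuration error: group ", g, " has no taxa in the matrix")
    ok <- ok & (colSums(rep[members, , drop = FALSE]) > 0L)
  }
  keepPartitions(x, which(ok))
}

#' Extract within-codon positions per partition
#'
#' Keeps the requested codon positions in every partition, assuming the
#' reading frame restarts at position 1 of each partition. Used e.g. to
#' retain only second codon positions of a nucleotide supermatrix.
#'
#' @param x a nucleotide \linkS4class{ResidueMatrix}; every partition
#'   length must be divisible by 3.
#' @param positions subset of \code{c(1, 2, 3)}.
#' @return a \linkS4class{ResidueMatrix} with the partition structure
#'   preserved (lengths scaled accordingly).
#' @export
selectCodonPositions <- function(x, positions) {
  if (seqAlphabet(x) != "NT")
    stop("codon positions are defined for nucleotide matrices only")
  positions <- sort(unique(as.integer(positions)))
  if (!all(positions %in% 1:3)) stop("positions must be within 1..3")
  sch <- partitionScheme(x)
  lens <- partitionLengthsOf(sch)
  if (any(lens %% 3L != 0L))
    stop("frame error: partition length not divisible by 3")
  cols <- unlist(lapply(seq_along(lens), function(i) {
    off <- sch@partStart[i] - 1L
    within <- as.vector(outer(positions, seq(0L, lens[i] - 3L, 3L), "+"))
    off + sort(within)
  }), use.names = FALSE)
  newSch <- newPartitionScheme(sch@partName, lens / 3L * length(positions))
  new("ResidueMatrix", seqs = x@seqs[, cols, drop = FALSE],
      mask = x@mask[, cols, drop = FALSE], alphabet = x@alphabet,
      partitions = newSch)
}

#' Alignment completeness diagnostics
#'
#' Computes the overall completeness score Ca (percent non-missing cells),
#' per-taxon scores Cr, and the taxon-pairwise fraction of sites covered in
#' both sequences. The diagonal of the pairwise matrix is set to 1 by
#' convention.
#'
#' @param x a nonempty \linkS4class{ResidueMatrix}.
#' @return a \linkS4class{CoverageReport}.
#' @export
completeness <- function(x) {
  if (nTaxa(x) == 0L || nSites(x) == 0L) stop("empty matrix")
  present <- !x@mask
  Cr <- 100 * rowMeans(present)
  shared <- tcrossprod(present * 1) / nSites(x)
  diag(shared) <- 1
  dimnames(shared) <- list(taxa(x), taxa(x))
  new("CoverageReport", Ca = 100 * mean(present), Cr = Cr,
      pairwiseShared = shared)
}

#' Restrict a matrix to a subset of taxa
#'
#' Rows are restricted (in the requested order); sites and partitions are
#' left untouched — re-filtering, if wanted, is a separate explicit step.
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param keep character vector of taxon labels to retain.
#' @return a \linkS4class{ResidueMatrix}.
#' @export
subsetTaxa <- function(x, keep) {
  unknown <- setdiff(keep, taxa(x))
  if (length(unknown))
    stop("input error: unknown taxa: ", paste(unknown, collapse = ", "))
  new("ResidueMatrix", seqs = x@seqs[keep, , drop = FALSE],
      mask = x@mask[keep, , drop = FALSE], alphabet = x@alphabet,
      partitions = x@partitions)
}

#' Read a RAxML-style partition file
#'
#' Lines of the form \code{"WAG, gene1 = 1-500"} (the model token is
#' optional); ranges are 1-based inclusive and must tile the alignment
#' contiguously.
#'
#' @param path partition file.
#' @return a \linkS4class{PartitionScheme}.
#' @export
readPartitions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nm <- character(0); st <- integer(0); en <- integer(0)
  for (ln in lines) {
    rhs <- sub("^[^,]*,\\s*", "", ln)      # drop optional "MODEL,"
    parts <- strsplit(rhs, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("cannot parse partition line: ", ln)
    rng <- strsplit(trimws(parts[2L]), "-", fixed = TRUE)[[1L]]
    nm <- c(nm, trimws(parts[1L]))
    st <- c(st, as.integer(rng[1L])); en <- c(en, as.integer(rng[2L]))
  }
  o <- order(st)
  new("PartitionScheme", partName = nm[o], partStart = st[o], partEnd = en[o])
}

#' Write a RAxML-style partition file
#'
#' @param scheme a \linkS4class{PartitionScheme}.
#' @param path output file.
#' @param model model token written before each partition name.
#' @return \code{path}, invisibly.
#' @export
writePartitions <- function(scheme, path, model = "WAG") {
  writeLines(sprintf("%s, %s = %d-%d", model, scheme@partName,
                     scheme@partStart, scheme@partEnd), path)
  invisible(path)
}

#' Read a taxon-to-group map
#'
#' Two-column (taxon, group) tab-separated text without header.
#'
#' @param path TSV file.
#' @return named character vector, names are taxa.
#' @export
readGroupMap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("taxon", "group"))
  if (anyDuplicated(df$taxon))
    stop("input error: taxon mapped to more than one group")
  setNames(df$group, df$taxon)
}

#' Write a taxon-to-group map
#' @param groupMap named character vector (taxon to group).
#' @param path output TSV file.
#' @return \code{path}, invisibly.
#' @export
writeGroupMap <- function(groupMap, path) {
  write.table(data.frame(names(groupMap), unname(groupMap)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a coverage report as TSV
#'
#' @param report a \linkS4class{CoverageReport}.
#' @param path output file; per-taxon Cr rows preceded by a Ca header line.
#' @return \code{path}, invisibly.
#' @export
writeCoverageReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#Ca\t%.6f", report@Ca), con)
  write.table(data.frame(taxon = names(report@Cr), Cr = report@Cr),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
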