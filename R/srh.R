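## Pairwise Bowker matched-pairs tests of symmetry. Rejection across many
## taxon pairs diagnoses violation of stationarity, reversibility and
## homogeneity (SRH) of the substitution process, typically visible as
## among-lineage compositional heterogeneity.

#' Pairwise residue contingency table
#'
#' Counts aligned residue pairs (u in taxon i, v in taxon j) over the sites
#' where both sequences are non-missing (pairwise, not listwise, deletion).
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param taxonI,taxonJ taxon labels.
#' @return a square integer matrix over the core alphabet with attribute
#'   \code{degenerate = TRUE} (and a warning) when no site is jointly
#'   covered.
#' @export
pairCounts <- function(x, taxonI, taxonJ) {
  if (!all(c(taxonI, taxonJ) %in% taxa(x)))
    stop("input error: taxon not in matrix")
  alph <- residueAlphabet(seqAlphabet(x))
  keep <- !x@mask[taxonI, ] & !x@mask[taxonJ, ]
  tab <- table(factor(x@seqs[taxonI, keep], levels = alph),
               factor(x@seqs[taxonJ, keep], levels = alph))
  counts <- matrix(as.integer(tab), length(alph), length(alph),
                   dimnames = list(alph, alph))
  if (sum(keep) == 0L) {
    warning("degenerate pair: no jointly covered sites for ", taxonI,
            " / ", taxonJ)
    attr(counts, "degenerate") <- TRUE
  }
  counts
}

#' Bowker matched-pairs test of symmetry
#'
#' For a square contingency table n, the statistic is
#' \deqn{B = \sum_{u<v} (n_{uv} - n_{vu})^2 / (n_{uv} + n_{vu})}
#' summed over unordered residue pairs with \eqn{n_{uv} + n_{vu} > 0}; the
#' degrees of freedom equal the number of such pairs, and the p-value is
#' the upper chi-square tail. An all-symmetric table gives B = 0; a table
#' with no informative off-diagonal pair gives df = 0 and p = 1 by
#' convention.
#'
#' @param counts square counts matrix (e.g. from \code{\link{pairCounts}}).
#' @return an object of class \code{htest} with \code{statistic},
#'   \code{parameter} (df) and \code{p.value}.
#' @export
bowkerTest <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    stop("counts must be a square matrix")
  up <- upper.tri(counts)
  nuv <- counts[up]; nvu <- t(counts)[up]
  tot <- nuv + nvu
  use <- tot > 0
  B <- sum((nuv[use] - nvu[use])^2 / tot[use])
  df <- sum(use)
  p <- if (df == 0L) 1 else pchisq(B, df, lower.tail = FALSE)
  structure(list(statistic = c(B = B), parameter = c(df = df), p.value = p,
                 method = "Bowker matched-pairs test of symmetry",
                 data.name = deparse(substitute(counts))),
            class = "htest")
}

#' All-pairs Bowker scan of an alignment
#'
#' Runs \code{\link{bowkerTest}} on every unordered taxon pair and
#' summarises the fraction of pairs rejecting symmetry (hence SRH
#' conditions) at the given level. Raw p-values are reported without
#' multiple-testing correction, matching how such heatmaps are usually
#' quoted.
#'
#' @param x a \linkS4class{ResidueMatrix} with at least two taxa.
#' @param alpha rejection level.
#' @param partition optional partition name: restrict the scan to that
#'   gene; default is the whole matrix.
#' @return list with \code{pMatrix} (symmetric taxon x taxon p-values, NA
#'   on the diagonal and for degenerate pairs), \code{rejectFraction}
#'   (percent of testable pairs with p < alpha), \code{nPairs},
#'   \code{nDegenerate}.
#' @export
srhScan <- function(x, alpha = 0.05, partition = NULL) {
  if (!is.null(partition)) {
    sch <- partitionScheme(x)
    i <- match(partition, sch@partName)
    if (is.na(i)) stop("unknown partition: ", partition)
    x <- keepPartitions(x, i)
  }
  tx <- taxa(x)
  if (length(tx) < 2L) stop("need at least two taxa")
  p <- matrix(NA_real_, length(tx), length(tx), dimnames = list(tx, tx))
  nDeg <- 0L
  for (i in seq_len(length(tx) - 1L)) {
    for (j in seq(i + 1L, length(tx))) {
      cnt <- suppressWarnings(pairCounts(x, tx[i], tx[j]))
      if (isTRUE(attr(cnt, "degenerate"))) { nDeg <- nDeg + 1L; next }
      p[i, j] <- p[j, i] <- bowkerTest(cnt)$p.value
    }
  }
  pv <- p[upper.tri(p)]
  pv <- pv[!is.na(pv)]
  list(pMatrix = p,
       rejectFraction = if (length(pv)) 100 * mean(pv < alpha) else NA_real_,
       nPairs = choose(length(tx), 2L), nDegenerate = nDeg)
}

#' Write a pairwise p-value matrix as TSV
#' @param scan result of \code{\link{srhScan}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSrhScan <- function(scan, path) {
  write.table(scan$pMatrix, path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}
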