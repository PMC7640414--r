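## Signal-destroying alignment permutations used to expose confounding
## signal in FcLM. All schemes leave the missing-data mask untouched, so
## non-randomly distributed data remain embodied in every permuted matrix:
##   I   - per taxon, shuffle its non-missing residues across its
##         non-missing positions matrix-wide: destroys site-wise
##         (phylogenetic) signal, preserves lineage composition.
##   II  - as I but independently within each partition: additionally
##         preserves per-partition lineage composition.
##   III - per site column, shuffle residues among the taxa covered at
##         that column: destroys lineage-specific composition, preserves
##         per-site composition.

streamSeed <- function(seed, idx) {
  as.integer((as.numeric(seed) + 104729 * idx) %% 2147483647)
}

#' Permute an alignment under a signal-destroying scheme
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param scheme \code{"I"}, \code{"II"} or \code{"III"} (see file-level
#'   description; the mask is never altered).
#' @param seed master seed; one deterministic stream is derived per taxon
#'   (I, II) or per column (III).
#' @return a permuted \linkS4class{ResidueMatrix} with identical mask,
#'   dimensions and partitions.
#' @export
permuteMatrix <- function(x, scheme = c("I", "II", "III"), seed = 1L) {
  scheme <- match.arg(scheme)
  seqs <- x@seqs
  mask <- x@mask
  if (scheme %in% c("I", "II")) {
    sch <- partitionScheme(x)
    blocks <- if (scheme == "I") list(seq_len(nSites(x)))
              else lapply(seq_along(sch@partName),
                          function(i) sch@partStart[i]:sch@partEnd[i])
    for (i in seq_len(nTaxa(x))) {
      withSeed(streamSeed(seed, i), {
        for (cols in blocks) {
          pos <- cols[!mask[i, cols]]
          if (length(pos) > 1L) seqs[i, pos] <- seqs[i, sample(pos)]
        }
      })
    }
  } else {
    for (j in seq_len(nSites(x))) {
      rows <- which(!mask[, j])
      if (length(rows) > 1L)
        withSeed(streamSeed(seed, j),
                 seqs[rows, j] <- seqs[sample(rows), j])
    }
  }
  new("ResidueMatrix", seqs = seqs, mask = mask, alphabet = x@alphabet,
      partitions = x@partitions)
}

#' FcLM on the original matrix and its permutations
#'
#' Runs \code{\link{fclmReport}} on the input matrix and on one permuted
#' copy per requested scheme, drawing the same quartets each time, and
#' flags each corner topology as "explainable by confounding signal" when
#' its support in the original matrix does not exceed its maximum support
#' across the permutation rows by more than \code{margin} percentage
#' points.
#'
#' @param x a \linkS4class{ResidueMatrix}.
#' @param groupMap named character vector taxon -> group.
#' @param groups the four cluster labels in drawing order.
#' @param model a \linkS4class{SubstitutionModel} or \code{NULL} for the
#'   default.
#' @param schemes subset of \code{c("I", "II", "III")}; empty gives the
#'   original row only.
#' @param cap,seed quartet drawing controls (identical across rows).
#' @param margin percentage-point margin of the explainability flag.
#' @return list with \code{reports} (named list of
#'   \linkS4class{SimplexReport}: \code{original} plus one per scheme),
#'   \code{summary} (data.frame of per-row cell percentages) and
#'   \code{explainable} (logical per corner topology T1..T3).
#' @export
fclmWithPermutations <- function(x, groupMap, groups, model = NULL,
                                 schemes = c("I", "II", "III"), cap = Inf,
                                 seed = 1L, margin = 5) {
  if (is.null(model)) model <- defaultModelFor(x)
  reports <- list(original = fclmReport(x, groupMap, groups, model,
                                        cap = cap, seed = seed))
  for (s in schemes) {
    xp <- permuteMatrix(x, s, seed = seed)
    reports[[paste0("permutation", s)]] <-
      fclmReport(xp, groupMap, groups, model, cap = cap, seed = seed)
  }
  pct <- t(vapply(reports, cellPercentages, numeric(7L)))
  summary <- data.frame(row = rownames(pct), pct, check.names = FALSE)
  explainable <- rep(NA, 3L)
  names(explainable) <- c("T1", "T2", "T3")
  if (length(schemes)) {
    permMax <- apply(pct[-1L, 1:3, drop = FALSE], 2L, max)
    explainable <- pct[1L, 1:3] <= permMax + margin
    names(explainable) <- c("T1", "T2", "T3")
  }
  list(reports = reports, summary = summary, explainable = explainable)
}

#' Write a combined FcLM/permutation summary
#'
#' @param result output of \code{\link{fclmWithPermutations}}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writePermutationSummary <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(result$summary, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    jsonlite::write_json(list(summary = result$summary,
                              explainable = as.list(result$explainable)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
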