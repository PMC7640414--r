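## Approximately unbiased (AU) tree test via multiscale RELL bootstrap:
## site log-likelihoods are resampled (no re-optimisation) at several
## scales, per-tree bootstrap proportions are probit-transformed and
## fitted as z(r) = d*sqrt(r) + c/sqrt(r); p_AU = 1 - Phi(d - c).

#' RELL bootstrap proportions at one scale
#'
#' Each replicate resamples \code{round(scale * nSites)} sites with
#' replacement (respecting pattern weights), sums the per-site
#' log-likelihoods per tree, and credits the best tree; exact ties are
#' split equally.
#'
#' @param slm a \linkS4class{SiteLogLikelihoodMatrix}.
#' @param scale resampling scale factor (> 0).
#' @param replicates number of bootstrap replicates.
#' @param seed RNG seed.
#' @return named numeric vector of per-tree bootstrap proportions
#'   (summing to 1).
#' @export
rellBootstrap <- function(slm, scale = 1, replicates = 10000L, seed = 1L) {
  if (scale <= 0) stop("scale must be positive")
  nSites <- sum(slm@weights)
  m <- max(1L, round(scale * nSites))
  prob <- slm@weights / nSites
  counts <- withSeed(seed, stats::rmultinom(replicates, m, prob))
  score <- slm@logl %*% counts                     # trees x replicates
  mx <- apply(score, 2L, max)
  isMax <- score >= rep(mx, each = nrow(score))    # exact ties share credit
  credit <- isMax / rep(colSums(isMax), each = nrow(score))
  setNames(rowMeans(credit), rownames(slm@logl))
}

## collapse trees with (numerically) identical site log-likelihood rows
## into score classes; likelihood cannot distinguish them (e.g. rootings
## of one unrooted topology, whose independently optimised rows agree up
## to the branch-length convergence tolerance)
scoreClasses <- function(slm, tol = 1e-3) {
  n <- nrow(slm@logl)
  cls <- integer(n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (max(abs(slm@logl[i, ] - slm@logl[reps[r], ])) < tol) {
        hit <- r; break
      }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    cls[i] <- hit
  }
  setNames(cls, rownames(slm@logl))
}

#' Approximately unbiased test over candidate trees
#'
#' Multiscale RELL bootstrap of a site log-likelihood matrix. Trees whose
#' per-site log-likelihoods are numerically identical (indistinguishable
#' by likelihood, e.g. rooted variants of one unrooted topology) are
#' collapsed into a single score class before resampling and share a
#' p-value; the mapping is reported. For each class, bootstrap
#' proportions BP(r) are clipped to [1/(2B), 1 - 1/(2B)], transformed to
#' z(r) = qnorm(1 - BP(r)), and fitted by weighted least squares to
#' z(r) = d*sqrt(r) + c/sqrt(r) with binomial delta-method weights
#' B * dnorm(z)^2 / (BP (1 - BP)); then p_AU = 1 - pnorm(d - c). Classes
#' with BP of 0 (or 1) at every scale are flagged degenerate with p = 0
#' (or 1).
#'
#' @param slm a \linkS4class{SiteLogLikelihoodMatrix} with >= 2 trees.
#' @param scales vector of resampling scales.
#' @param replicates bootstrap replicates per scale.
#' @param seed RNG seed (one derived stream per scale).
#' @return list with \code{table} (data.frame: tree, class, d, c, pAU,
#'   degenerate), \code{pAU} (named per input tree), \code{bp} (classes x
#'   scales matrix of bootstrap proportions), \code{scales},
#'   \code{classes} (tree -> class mapping).
#' @export
auTest <- function(slm, scales = seq(0.5, 1.4, by = 0.1),
                   replicates = 10000L, seed = 1L) {
  if (nrow(slm@logl) < 2L) stop("need at least two candidate trees")
  cls <- scoreClasses(slm)
  uniqRows <- !duplicated(cls)
  slmU <- new("SiteLogLikelihoodMatrix",
              logl = slm@logl[uniqRows, , drop = FALSE],
              weights = slm@weights)
  rownames(slmU@logl) <- paste0("class", seq_len(sum(uniqRows)))
  B <- replicates
  bp <- vapply(seq_along(scales), function(k)
    rellBootstrap(slmU, scales[k], B, seed = seed + 7919L * k),
    numeric(nrow(slmU@logl)))
  bp <- matrix(bp, nrow = nrow(slmU@logl),
               dimnames = list(rownames(slmU@logl), paste0("r", scales)))
  nCls <- nrow(bp)
  d <- cN <- pAU <- rep(NA_real_, nCls)
  degenerate <- rep(FALSE, nCls)
  for (i in seq_len(nCls)) {
    raw <- bp[i, ]
    usable <- raw > 0 & raw < 1
    if (sum(usable) < 2L) {
      degenerate[i] <- TRUE
      pAU[i] <- if (mean(raw) >= 0.5) 1 else 0
      next
    }
    bpC <- pmin(pmax(raw, 1 / (2 * B)), 1 - 1 / (2 * B))
    z <- qnorm(1 - bpC)
    wts <- B * dnorm(z)^2 / (bpC * (1 - bpC))
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    fit <- lm.wfit(X, z, wts)
    d[i] <- fit$coefficients[1L]; cN[i] <- fit$coefficients[2L]
    pAU[i] <- 1 - pnorm(d[i] - cN[i])
  }
  treeP <- pAU[cls]
  names(treeP) <- names(cls)
  tab <- data.frame(tree = names(cls), class = unname(cls),
                    d = d[cls], c = cN[cls], pAU = unname(treeP),
                    degenerate = degenerate[cls],
                    stringsAsFactors = FALSE)
  list(table = tab, pAU = treeP, bp = bp, scales = scales, classes = cls)
}

#' Write AU-test results as TSV
#' @param au result of \code{\link{auTest}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAuResult <- function(au, path) {
  write.table(au$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
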