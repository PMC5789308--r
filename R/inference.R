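#' Node-bootstrap test of network density against a theoretical value
#'
#' Tests whether observed weighted density differs from a theoretical
#' reference (0 under the null of no association). The standard error comes
#' from a vertex bootstrap: animals are resampled with replacement, the HWI
#' matrix is re-indexed by the resampled roster, and density is recomputed
#' over pairs of distinct sampled positions whose underlying animals differ
#' (same-animal duplicate pairs are excluded from numerator and
#' denominator). z = (estimate - theoretical) / se with a two-tailed normal
#' p-value.
#'
#' When the bootstrap distribution is degenerate (se < 1e-12) no finite z
#' exists: the result is flagged, z is 0 or +/-Inf, and p is 1 when the
#' estimate equals the theoretical value, otherwise bounded above by 1/B.
#'
#' @param x an \linkS4class{HWIMatrix} with n >= 3 animals.
#' @param theoretical reference density (default 0).
#' @param B bootstrap replicates (>= 100; default 5000).
#' @param seed RNG seed for reproducibility.
#' @return List of class \code{"BootstrapResult"}: \code{estimate},
#'   \code{theoretical}, \code{seBoot}, \code{z}, \code{p},
#'   \code{degenerate}, \code{replicates}, \code{seed}.
#' @export
densityBootstrapTest <- function(x, theoretical = 0, B = 5000L, seed = NULL) {
  stopifnot(is(x, "HWIMatrix"))
  n <- length(x@roster)
  if (n < 3L) stop("density bootstrap needs at least 3 animals", call. = FALSE)
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  w <- x@weights
  est <- networkDensity(x)
  dens <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ii <- rep(seq_len(n), times = n)
      jj <- rep(seq_len(n), each = n)
      keep <- ii < jj & idx[ii] != idx[jj]
      if (!any(keep)) return(0)
      mean(w[cbind(idx[ii[keep]], idx[jj[keep]])])
    }, 0.0)
  })
  se <- sd(dens)
  degenerate <- se < 1e-12
  diffVal <- est - theoretical
  if (degenerate) {
    z <- if (abs(diffVal) < 1e-12) 0 else sign(diffVal) * Inf
    p <- if (abs(diffVal) < 1e-12) 1 else 1 / B
  } else {
    z <- diffVal / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(estimate = est, theoretical = theoretical, seBoot = se,
                 z = z, p = max(p, .Machine$double.xmin),
                 degenerate = degenerate, replicates = as.integer(B),
                 seed = seed),
            class = "BootstrapResult")
}

#' @export
print.BootstrapResult <- function(x, ...) {
  cat(sprintf(
    "Density bootstrap test: estimate %.3f vs theoretical %.3f\n  se %.4f, z %.2f, p %s%s (B = %d)\n",
    x$estimate, x$theoretical, x$seBoot, x$z, format.pval(x$p),
    if (x$degenerate) " [degenerate]" else "", x$replicates))
  invisible(x)
}

#' QAP correlation between two association matrices
#'
#' Pearson correlation of the C(n, 2) upper-triangle cells of two
#' symmetric association matrices over the same roster, with a quadratic
#' assignment permutation null: each replicate applies one random node
#' relabeling simultaneously to the rows and columns of the second matrix,
#' preserving its dependence structure. The two-tailed p-value uses the
#' add-one estimator (1 + #(|r_perm| >= |r_obs|)) / (B + 1).
#'
#' @param m1,m2 \linkS4class{HWIMatrix} objects with identical rosters
#'   (m2 is aligned to m1's roster order if needed).
#' @param B permutation replicates (>= 100; default 5000).
#' @param seed RNG seed.
#' @return List of class \code{"QAPResult"}: \code{r}, \code{p},
#'   \code{replicates}, \code{seed}.
#' @export
qapCorrelation <- function(m1, m2, B = 5000L, seed = NULL) {
  stopifnot(is(m1, "HWIMatrix"), is(m2, "HWIMatrix"))
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  if (!setequal(m1@roster, m2@roster))
    stop("matrices must share the same roster", call. = FALSE)
  ord <- match(m1@roster, m2@roster)
  w1 <- m1@weights
  w2 <- m2@weights[ord, ord]
  v1 <- upperTriVals(w1)
  if (sd(v1) == 0 || sd(upperTriVals(w2)) == 0)
    stop("correlation undefined: an association matrix has zero variance over its ties",
         call. = FALSE)
  rObs <- cor(v1, upperTriVals(w2))
  n <- nrow(w1)
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(B), function(b) {
      pm <- sample.int(n)
      rp <- cor(v1, upperTriVals(w2[pm, pm]))
      abs(rp) >= abs(rObs) - 1e-12
    }, TRUE))
  })
  structure(list(r = rObs, p = (1 + exceed) / (B + 1),
                 replicates = as.integer(B), seed = seed),
            class = "QAPResult")
}

#' @export
print.QAPResult <- function(x, ...) {
  cat(sprintf("QAP correlation: r = %.3f, p = %s (B = %d)\n",
              x$r, format.pval(x$p), x$replicates))
  invisible(x)
}

#' Two-group bootstrap for an animal-level metric
#'
#' Compares the mean of a per-animal metric (strength, eigenvector
#' centrality) between two disjoint groups of animals in a pen, e.g.
#' victimized vs non-victimized pigs. Animals are resampled with
#' replacement within each group; the two-tailed p-value is
#' 2 x min(#(d* <= 0), #(d* >= 0)) / B, clipped to (1/B, 1], where d* is
#' the resampled mean difference.
#'
#' The groups contain different animals, so the comparison is an unpaired
#' difference of group means.
#'
#' @param values named numeric vector of the per-animal metric.
#' @param groupA,groupB disjoint, non-empty character vectors of animal ids
#'   present in \code{names(values)}.
#' @param B bootstrap replicates (>= 100; default 5000).
#' @param seed RNG seed.
#' @return List of class \code{"GroupDifferenceResult"}: \code{meanA},
#'   \code{meanB}, \code{difference}, \code{p}, \code{degenerate},
#'   \code{replicates}, \code{seed}.
#' @export
groupDifferenceBootstrap <- function(values, groupA, groupB, B = 5000L,
                                     seed = NULL) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (length(intersect(groupA, groupB)) > 0L)
    stop("groups must be disjoint", call. = FALSE)
  missing <- setdiff(c(groupA, groupB), names(values))
  if (length(missing) > 0L)
    stop("animals not in metric vector: ", paste(missing, collapse = ", "),
         call. = FALSE)
  vA <- values[groupA]
  vB <- values[groupB]
  dStar <- withSeed(seed, {
    mA <- colMeans(matrix(sample(vA, length(vA) * B, replace = TRUE),
                          nrow = length(vA)))
    mB <- colMeans(matrix(sample(vB, length(vB) * B, replace = TRUE),
                          nrow = length(vB)))
    mA - mB
  })
  degenerate <- sd(dStar) < 1e-12
  p <- if (degenerate) 1
       else min(1, max(1 / B, 2 * min(sum(dStar <= 0), sum(dStar >= 0)) / B))
  structure(list(meanA = mean(vA), meanB = mean(vB),
                 difference = mean(vA) - mean(vB), p = p,
                 degenerate = degenerate, replicates = as.integer(B),
                 seed = seed),
            class = "GroupDifferenceResult")
}

#' @export
print.GroupDifferenceResult <- function(x, ...) {
  cat(sprintf(
    "Group difference bootstrap: %.3f - %.3f = %.3f, p = %s%s (B = %d)\n",
    x$meanA, x$meanB, x$difference, format.pval(x$p),
    if (x$degenerate) " [degenerate]" else "", x$replicates))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Classical Pearson statistic sum((O - E)^2 / E) with expected counts from
#' the row/column margins and df = (rows - 1)(cols - 1); no continuity
#' correction. Used for score-class by treatment-group tables such as
#' maximal tail-injury scores.
#'
#' @param tab matrix of nonnegative integer counts, at least 2 x 2, with
#'   all row and column totals positive.
#' @return List of class \code{"ContingencyResult"}: \code{statistic},
#'   \code{df}, \code{p}, \code{expected}.
#' @examples
#' chiSquareTest(rbind(c(47, 1, 0), c(41, 7, 0), c(35, 6, 7)))
#' @export
chiSquareTest <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers", call. = FALSE)
  zr <- which(rowSums(tab) == 0)
  zc <- which(colSums(tab) == 0)
  if (length(zr) > 0L)
    stop("empty row in contingency table: row ", zr[1L], call. = FALSE)
  if (length(zc) > 0L)
    stop("empty column in contingency table: column ", zc[1L], call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 expected = ct$expected),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("Chi-square = %.1f, df = %d, p = %s\n",
              x$statistic, x$df, format.pval(x$p)))
  invisible(x)
}
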