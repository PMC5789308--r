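#' Weighted network density
#'
#' Mean pairwise HWI: the sum of the weights of all ties divided by the
#' number of possible ties C(n, 2) (28 for a pen of 8). Interpreted as the
#' average fraction of joint lying opportunity any pair spends together.
#'
#' @param x an \linkS4class{HWIMatrix}.
#' @return Density in [0, 1].
#' @examples
#' w <- matrix(0.15, 8, 8); diag(w) <- 0
#' networkDensity(HWIMatrix(w))  # 0.15
#' @export
networkDensity <- function(x) {
  stopifnot(is(x, "HWIMatrix"))
  n <- length(x@roster)
  if (n < 2L) stop("density needs at least two animals", call. = FALSE)
  sum(upperTriVals(x@weights)) / choose(n, 2)
}

#' Classify ties as absent, weak or strong
#'
#' Granovetter-style partition of the pen's pairwise associations. A tie is
#' absent when its HWI is at or below \code{absentCutoff} (default 0.15,
#' the study-wide mean HWI, read as the chance level of co-lying), strong
#' when at or above \code{strongCutoff}, weak otherwise.
#'
#' When \code{strongCutoff} is omitted it is set per pen to
#' \code{max(absentCutoff + 0.01, mean + 1 SD of the pairwise HWI values)},
#' a documented stand-in for break-point procedures that choose the cut-off
#' from the within-pen spread of HWI; the value actually used is echoed in
#' the result.
#'
#' @param x an \linkS4class{HWIMatrix}.
#' @param absentCutoff absent-tie threshold in [0, 1).
#' @param strongCutoff optional strong-tie threshold, must exceed
#'   \code{absentCutoff}.
#' @return List of class \code{"TieClassification"}: \code{ties} (data.frame
#'   with columns a, b, weight, label), \code{counts} (named vector
#'   absent/weak/strong), \code{absentCutoff}, \code{strongCutoff}.
#' @export
classifyTies <- function(x, absentCutoff = 0.15, strongCutoff = NULL) {
  stopifnot(is(x, "HWIMatrix"))
  if (absentCutoff < 0 || absentCutoff >= 1)
    stop("absentCutoff must lie in [0, 1)", call. = FALSE)
  pairs <- rosterPairs(x@roster)
  w <- x@weights[cbind(match(pairs$a, x@roster), match(pairs$b, x@roster))]
  if (is.null(strongCutoff)) {
    spread <- if (length(w) > 1L) sd(w) else 0
    strongCutoff <- max(absentCutoff + 0.01, mean(w) + spread)
  } else if (strongCutoff <= absentCutoff) {
    stop("strongCutoff must exceed absentCutoff", call. = FALSE)
  }
  label <- ifelse(w <= absentCutoff, "absent",
                  ifelse(w >= strongCutoff, "strong", "weak"))
  counts <- c(absent = sum(label == "absent"),
              weak = sum(label == "weak"),
              strong = sum(label == "strong"))
  structure(list(ties = cbind(pairs, weight = w, label = label),
                 counts = counts, absentCutoff = absentCutoff,
                 strongCutoff = strongCutoff),
            class = "TieClassification")
}

#' @export
print.TieClassification <- function(x, ...) {
  cat(sprintf(
    "Tie classification (absent <= %.3f, strong >= %.3f):\n  absent %d, weak %d, strong %d of %d ties\n",
    x$absentCutoff, x$strongCutoff, x$counts["absent"], x$counts["weak"],
    x$counts["strong"], sum(x$counts)))
  invisible(x)
}

#' Animal strength (weighted degree)
#'
#' Sum of an animal's HWI with every pen-mate; the weighted-network
#' counterpart of degree centrality.
#'
#' @param x an \linkS4class{HWIMatrix}.
#' @param animal optional animal id(s); default all, in roster order.
#' @return Named numeric vector of strengths, each in [0, n - 1].
#' @export
strength <- function(x, animal = NULL) {
  stopifnot(is(x, "HWIMatrix"))
  s <- rowSums(x@weights)
  if (!is.null(animal)) {
    if (!all(animal %in% x@roster))
      stop("unknown animal id: ",
           paste(setdiff(animal, x@roster), collapse = ", "), call. = FALSE)
    s <- s[animal]
  }
  s
}

#' Eigenvector centrality of the weighted network
#'
#' Entries of the principal eigenvector of the HWI matrix, scaled to unit
#' Euclidean norm, all nonnegative. High values mark animals tied to
#' well-connected pen-mates ("social hubs"). Computed on the valued matrix,
#' never a binarized one.
#'
#' If the positive-weight graph is disconnected the principal eigenvector
#' concentrates on the dominant component; a warning flags this.
#'
#' @param x an \linkS4class{HWIMatrix} with at least one positive weight.
#' @return Named numeric vector, sum of squares 1.
#' @export
eigenvectorCentrality <- function(x) {
  stopifnot(is(x, "HWIMatrix"))
  w <- x@weights
  if (all(w == 0))
    stop("degenerate network: all weights zero, no principal direction",
         call. = FALSE)
  if (!isConnected(w > 0))
    warning("network is disconnected; centrality concentrates on the dominant component",
            call. = FALSE)
  e <- eigen(w, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  # principal eigenvector of a nonnegative symmetric matrix is nonnegative;
  # abs() also covers the degenerate equal-eigenvalue disconnected case
  v <- if (min(v) < -1e-8) abs(v) else pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  names(v) <- x@roster
  v
}

isConnected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' All pen-level and animal-level network measures
#'
#' Convenience wrapper returning density, tie classification, per-animal
#' strength and eigenvector centrality for one HWI network.
#'
#' @inheritParams classifyTies
#' @return List of class \code{"NetworkMetrics"}: \code{density},
#'   \code{ties} (a \code{TieClassification}), \code{strength},
#'   \code{eigenvector}.
#' @export
networkMetrics <- function(x, absentCutoff = 0.15, strongCutoff = NULL) {
  stopifnot(is(x, "HWIMatrix"))
  ev <- if (all(x@weights == 0)) {
    v <- rep(NA_real_, length(x@roster)); names(v) <- x@roster; v
  } else eigenvectorCentrality(x)
  structure(list(density = networkDensity(x),
                 ties = classifyTies(x, absentCutoff, strongCutoff),
                 strength = strength(x), eigenvector = ev),
            class = "NetworkMetrics")
}

#' @export
print.NetworkMetrics <- function(x, ...) {
  cat(sprintf("Network metrics: density %.3f\n", x$density))
  print(x$ties)
  tab <- data.frame(animal = names(x$strength),
                    strength = round(x$strength, 3),
                    eigenvector = round(x$eigenvector, 3), row.names = NULL)
  print(tab)
  invisible(x)
}
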